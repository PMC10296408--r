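#' Inject motion artifacts into an optical-density recording
#'
#' Adds seeded motion artifacts at homogeneous-Poisson event times:
#' transient spikes (1-3 samples) and persistent step baseline shifts,
#' each applied coherently to every channel and wavelength (a head
#' movement disturbs the whole probe). Event magnitudes are jittered
#' uniformly within +/-20% of the configured value and signed at random.
#' The exact injected-event list is returned so detector performance can
#' be validated against ground truth.
#'
#' @param od An [ODRecording-class].
#' @param rate Events per minute (>= 0).
#' @param spike_mag Spike magnitude, OD units.
#' @param shift_mag Step magnitude, OD units.
#' @param p_spike Probability an event is a spike (else a shift).
#' @param seed Integer seed.
#' @return A list: `recording` (artifacted [ODRecording-class]) and
#'   `events` (data.frame: `time_s`, `sample`, `n_samples`, `kind`,
#'   `magnitude`).
#' @export
injectMotionArtifacts <- function(od, rate = 1.2, spike_mag = 1.0,
                                  shift_mag = 0.5, p_spike = 0.5,
                                  seed = 1) {
  stopifnot(is(od, "ODRecording"))
  assertScalarNumeric(rate, "rate", lower = 0)
  n <- ncol(od)
  fs <- samplingRate(od)
  duration_min <- n / fs / 60

  empty <- data.frame(time_s = numeric(), sample = integer(),
                      n_samples = integer(), kind = character(),
                      magnitude = numeric(), stringsAsFactors = FALSE)
  if (rate == 0) {
    return(list(recording = od, events = empty))
  }

  res <- withSeed(seed, {
    k <- rpois(1L, rate * duration_min)
    if (k == 0L) {
      list(rec = od, events = empty)
    } else {
      ## keep events away from the very edges so steps/spikes are observable
      smp <- sort(sample(seq(10L, n - 10L), k))
      kind <- ifelse(runif(k) < p_spike, "spike", "shift")
      width <- ifelse(kind == "spike", sample(1:3, k, replace = TRUE), 1L)
      mag <- ifelse(kind == "spike", spike_mag, shift_mag) *
        runif(k, 0.8, 1.2) * sample(c(-1, 1), k, replace = TRUE)
      events <- data.frame(time_s = (smp - 1L) / fs, sample = smp,
                           n_samples = as.integer(width), kind = kind,
                           magnitude = mag, stringsAsFactors = FALSE)
      alist <- assays(od)
      for (a in seq_along(alist)) {
        x <- alist[[a]]
        for (e in seq_len(k)) {
          if (kind[e] == "spike") {
            idx <- smp[e]:min(n, smp[e] + width[e] - 1L)
            x[, idx] <- x[, idx] + mag[e]
          } else {
            x[, smp[e]:n] <- x[, smp[e]:n] + mag[e]
          }
        }
        alist[[a]] <- x
      }
      out <- od
      SummarizedExperiment::assays(out) <- alist
      list(rec = out, events = events)
    }
  })
  list(recording = res$rec, events = res$events)
}
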