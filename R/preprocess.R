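## Motion-artifact handling and band-pass filtering on optical density,
## conventional fNIRS processing order: detect -> correct -> band-pass -> MBLL.


.rollSD <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n - w + 1L)
  m <- (cs[i + w] - cs[i]) / w
  v <- pmax(0, (cs2[i + w] - cs2[i]) / w - m^2) * w / (w - 1)
  c(sqrt(v), rep(0, w - 1L))  # value i: SD over [i, i + w - 1]
}

.runsToIntervals <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Detect motion artifacts in optical-density series
#'
#' Flags, per channel, samples adjacent to a sample-to-sample change
#' exceeding `amp_thresh` OD on any wavelength (motion is instantaneous
#' on the sampling grid, while the hemodynamic response moves only a
#' small fraction of that per sample), or samples where the local
#' standard deviation within a `window_s` sliding window exceeds
#' `std_thresh` times the channel's robust (median-absolute-deviation)
#' SD; the SD criterion is skipped on near-constant channels whose
#' robust SD is below `amp_thresh / 100`. Flagged samples are dilated by
#' two samples on each side and merged into intervals, which are
#' classified as persistent baseline `shift`s (the supra-threshold jumps
#' across the interval leave a net displacement above `amp_thresh / 2`)
#' or transient `spike`s (the jumps cancel).
#'
#' @param od An [ODRecording-class].
#' @param window_s Sliding-window length (s, > 0).
#' @param amp_thresh Peak-to-peak threshold, OD units (> 0).
#' @param std_thresh Local-SD threshold, multiples of the robust channel
#'   SD (> 0).
#' @return An [ArtifactMask-class].
#' @export
detectMotion <- function(od, window_s = 0.5, amp_thresh = 0.25,
                         std_thresh = 6) {
  stopifnot(is(od, "ODRecording"))
  assertScalarNumeric(window_s, "window_s", lower = 0, strict_lower = TRUE)
  assertScalarNumeric(amp_thresh, "amp_thresh", lower = 0,
                      strict_lower = TRUE)
  assertScalarNumeric(std_thresh, "std_thresh", lower = 0,
                      strict_lower = TRUE)
  fs <- samplingRate(od)
  n <- ncol(od)
  w <- max(2L, round(window_s * fs))
  pad <- 2L
  ids <- channelIds(od)
  alist <- assays(od)

  events <- list()
  for (ci in seq_along(ids)) {
    flag <- rep(FALSE, n)
    for (a in seq_along(alist)) {
      x <- alist[[a]][ci, ]
      rsd <- stats::mad(x)
      ## jump criterion: flag both samples around each large change
      j <- which(abs(diff(x)) > amp_thresh)
      if (length(j)) {
        flag[j] <- TRUE
        flag[pmin(n, j + 1L)] <- TRUE
      }
      if (rsd > amp_thresh / 100) {
        hit <- which(.rollSD(x, w) > std_thresh * rsd)
        ## a window statistic at i implicates samples i .. i + w - 1
        for (k in 0:(w - 1L)) {
          flag[pmin(n, hit + k)] <- TRUE
        }
      }
    }
    if (!any(flag)) next
    ## dilate and merge
    fi <- which(flag)
    for (k in seq_len(pad)) {
      flag[pmax(1L, fi - k)] <- TRUE
      flag[pmin(n, fi + k)] <- TRUE
    }
    iv <- .runsToIntervals(flag)
    ## classify spike vs shift by the net supra-threshold jump across the
    ## interval: a spike's entry and exit jumps cancel, a step does not,
    ## and the smooth hemodynamic signal contributes no large jumps
    xm <- Reduce(`+`, lapply(alist, function(a) a[ci, ])) / length(alist)
    dm <- diff(xm)
    kind <- character(nrow(iv))
    for (e in seq_len(nrow(iv))) {
      di <- dm[max(1L, iv[e, 1L] - 1L):min(n - 1L, iv[e, 2L])]
      net <- sum(di[abs(di) > amp_thresh])
      kind[e] <- if (abs(net) > amp_thresh / 2) "shift" else "spike"
    }
    events[[ids[ci]]] <- data.frame(
      channel_id = ids[ci], start = iv[, 1L], end = iv[, 2L], kind = kind,
      stringsAsFactors = FALSE
    )
  }
  ev <- if (length(events)) {
    do.call(rbind, c(events, make.row.names = FALSE))
  } else {
    data.frame(channel_id = character(), start = integer(),
               end = integer(), kind = character(), stringsAsFactors = FALSE)
  }
  new("ArtifactMask", events = ev, n_samples = as.integer(n))
}

## Correct one series given this channel's intervals. One whole-series
## regression on clean samples drives both repairs. Its design holds an
## intercept, a discrete-cosine low-frequency drift basis (up to
## ~0.01 Hz), harmonic nuisance regressors (sine/cosine pairs) at the
## nominal physiological frequencies, the stimulus-response regressors
## when the recording carries an event schedule (canonical trial shape
## and its lagged copy, so the evoked signal does not bias the step
## estimates), and one step indicator per shift interval. The fitted
## step heights are subtracted everywhere after their interval starts;
## masked samples are then replaced by the model's prediction (drift +
## oscillations + evoked response), i.e. the best available estimate of
## the underlying signal inside the gap.
## nuisance design shared by every channel: intercept, discrete-cosine
## drift basis below ~0.01 Hz, harmonic pairs at the physiological
## frequencies, and the stimulus-response regressors when available
.correctionBase <- function(n, fs, stimreg = NULL,
                            physio_freqs = c(1.1, 0.3, 0.1)) {
  k_dct <- max(1L, floor(0.02 * n / fs))
  grid <- (seq_len(n) - 0.5) / n
  dct <- vapply(seq_len(k_dct), function(k) cos(pi * k * grid), numeric(n))
  tt <- (seq_len(n) - 1L) / fs
  harm <- NULL
  for (f in physio_freqs) {
    if (f < fs / 2) {
      harm <- cbind(harm, sin(2 * pi * f * tt), cos(2 * pi * f * tt))
    }
  }
  cbind(1, dct, harm, stimreg)
}

## correct one channel's series (columns of ymat, one per wavelength)
## given this channel's intervals and the shared nuisance design
.correctChannel <- function(ymat, iv, base) {
  n <- nrow(ymat)
  masked <- rep(FALSE, n)
  for (e in seq_len(nrow(iv))) masked[iv$start[e]:iv$end[e]] <- TRUE
  if (all(masked)) stop("artifact mask covers an entire channel")

  ord <- order(iv$start)
  iv <- iv[ord, , drop = FALSE]
  shifts <- which(iv$kind == "shift")
  steps <- if (length(shifts)) {
    vapply(shifts, function(e) as.numeric(seq_len(n) >= iv$start[e]),
           numeric(n))
  } else {
    NULL
  }
  design <- cbind(base, steps)
  use <- !masked
  fit <- stats::lm.fit(design[use, , drop = FALSE],
                       ymat[use, , drop = FALSE])
  beta <- as.matrix(fit$coefficients)
  beta[!is.finite(beta)] <- 0

  if (length(shifts)) {
    bstep <- beta[seq.int(ncol(base) + 1L, length.out = length(shifts)), ,
                  drop = FALSE]
    ymat <- ymat - steps %*% bstep
  }
  pred <- base %*% beta[seq_len(ncol(base)), , drop = FALSE]
  ymat[masked, ] <- pred[masked, ]
  ymat
}

#' Correct motion artifacts
#'
#' Applies the mask produced by [detectMotion()] (or built from known
#' events): baseline shifts are re-levelled by step heights estimated
#' jointly in a whole-series regression fitted on clean samples only
#' (drift basis, harmonic nuisance regressors at the physiological
#' frequencies, stimulus-response regressors, step indicators), and
#' masked samples are replaced by that model's prediction of the
#' underlying signal. Unmasked samples outside shifted segments are
#' unchanged, and the correction is idempotent: applying it twice with
#' the same mask changes nothing the second time.
#'
#' @param od An [ODRecording-class].
#' @param mask An [ArtifactMask-class] for the same recording.
#' @param physio_freqs Frequencies (Hz) of the harmonic nuisance
#'   regressors; defaults cover cardiac, respiratory and Mayer bands.
#' @return The corrected [ODRecording-class].
#' @export
correctMotion <- function(od, mask, physio_freqs = c(1.1, 0.3, 0.1)) {
  stopifnot(is(od, "ODRecording"), is(mask, "ArtifactMask"))
  validObject(mask)
  if (mask@n_samples != ncol(od)) {
    stop("mask length does not match the recording")
  }
  ev <- artifactEvents(mask)
  if (!nrow(ev)) return(od)
  fs <- samplingRate(od)
  ids <- channelIds(od)
  alist <- assays(od)

  ## stimulus-response regressors for the shift re-levelling model
  stimreg <- NULL
  sched <- eventSchedule(od)
  if (!is.null(sched)) {
    tr <- trials(sched)
    stim_tr <- tr[tr$condition == "STIM", , drop = FALSE]
    if (nrow(stim_tr)) {
      n <- ncol(od)
      r1 <- numeric(n)
      shape <- trialResponseShape(stim_tr$on_s[1L], fs)
      for (o in stim_tr$onset_s) {
        i0 <- round(o * fs) + 1L
        if (i0 > n) next
        idx <- i0:min(n, i0 + length(shape) - 1L)
        r1[idx] <- r1[idx] + shape[seq_along(idx)]
      }
      lag <- max(1L, round(fs))  # nominal 1 s chromophore lag
      r2 <- c(numeric(lag), r1)[seq_len(n)]
      stimreg <- cbind(r1, r2)
    }
  }

  base <- .correctionBase(ncol(od), fs, stimreg = stimreg,
                          physio_freqs = physio_freqs)
  for (cid in unique(ev$channel_id)) {
    ci <- match(cid, ids)
    if (is.na(ci)) stop("mask refers to unknown channel: ", cid)
    iv <- ev[ev$channel_id == cid, , drop = FALSE]
    ymat <- vapply(alist, function(a) a[ci, ], numeric(ncol(od)))
    ymat <- .correctChannel(ymat, iv, base)
    for (a in seq_along(alist)) {
      alist[[a]][ci, ] <- ymat[, a]
    }
  }
  out <- od
  SummarizedExperiment::assays(out) <- alist
  out
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering: a 2nd-order
#' high-pass at `low_hz` (omitted when `low_hz = 0`) cascaded with a
#' 4th-order low-pass at `high_hz`. The series is extended by odd
#' reflection before filtering to suppress edge transients, then
#' trimmed. Zero-phase filtering leaves peak latencies unbiased.
#'
#' @param x Numeric vector, or a channels x samples matrix (filtered
#'   row-wise).
#' @param low_hz,high_hz Band edges, `0 <= low_hz < high_hz < fs / 2`.
#' @param sampling_rate Hz.
#' @return Filtered series, same shape as `x`.
#' @export
bandpass <- function(x, low_hz = 0.01, high_hz = 0.5, sampling_rate = 10.2) {
  assertScalarNumeric(low_hz, "low_hz", lower = 0)
  assertScalarNumeric(high_hz, "high_hz", lower = 0, strict_lower = TRUE)
  assertScalarNumeric(sampling_rate, "sampling_rate", lower = 0,
                      strict_lower = TRUE)
  nyq <- sampling_rate / 2
  if (low_hz >= high_hz || high_hz >= nyq) {
    stop("invalid band: need 0 <= low_hz < high_hz < sampling_rate / 2")
  }
  if (is.matrix(x)) {
    return(t(apply(x, 1L, bandpass, low_hz = low_hz, high_hz = high_hz,
                   sampling_rate = sampling_rate)))
  }
  n <- length(x)
  if (n < 10L) stop("series too short to filter")
  ## demean when high-passing: the DC level only feeds the startup
  ## transient of the recursive filter, and the high-pass removes it anyway
  if (low_hz > 0) x <- x - mean(x)
  ## odd-reflection padding, several times the slowest filter time constant
  tc <- 1 / (2 * pi * max(low_hz, high_hz / 20))
  pad <- min(n - 1L, ceiling(8 * tc * sampling_rate))
  left <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(left, x, right)

  lp <- signal::butter(4, high_hz / nyq, type = "low")
  xp <- signal::filtfilt(lp, xp)
  if (low_hz > 0) {
    hp <- signal::butter(2, low_hz / nyq, type = "high")
    xp <- signal::filtfilt(hp, xp)
  }
  xp[pad + seq_len(n)]
}

#' Full preprocessing chain: artifacts, filtering, MBLL inversion
#'
#' Runs the standard processing order on an optical-density recording:
#' motion-artifact detection and correction, zero-phase band-pass
#' filtering, and conversion to chromophore concentrations via the
#' inverse modified Beer-Lambert law. Channels whose robust SD is zero
#' (dead channels) are marked unusable in `rowData()` and excluded from
#' downstream averaging.
#'
#' @param od An [ODRecording-class].
#' @param band Pass band in Hz, `c(low, high)`.
#' @param dpf Differential pathlength factor per wavelength.
#' @param extinction 2x2 extinction matrix; default [defaultExtinction()].
#' @param window_s,amp_thresh,std_thresh Passed to [detectMotion()].
#' @return An [HbRecording-class]; the artifact mask is stored in
#'   `metadata()$artifact_mask`.
#' @export
preprocessRecording <- function(od, band = c(0.01, 0.5), dpf = c(6, 6),
                                extinction = NULL, window_s = 0.5,
                                amp_thresh = 0.25, std_thresh = 6) {
  stopifnot(is(od, "ODRecording"))
  dead <- vapply(seq_len(nrow(od)), function(i) {
    all(vapply(assays(od), function(a) {
      r <- range(a[i, ])
      r[1L] == r[2L]    # constant series carries no signal
    }, logical(1)))
  }, logical(1))
  if (any(dead)) {
    message("excluding dead channel(s): ",
            paste(channelIds(od)[dead], collapse = ", "))
  }

  mask <- detectMotion(od, window_s = window_s, amp_thresh = amp_thresh,
                       std_thresh = std_thresh)
  ## never try to correct a dead channel (mask would cover nothing anyway)
  od <- correctMotion(od, mask)

  alist <- assays(od)
  fs <- samplingRate(od)
  for (a in seq_along(alist)) {
    alist[[a]] <- bandpass(alist[[a]], band[1L], band[2L], fs)
  }
  SummarizedExperiment::assays(od) <- alist

  hb <- mbllInverse(od, dpf = dpf, extinction = extinction)
  rowData(hb)$usable <- !dead
  metadata(hb)$artifact_mask <- mask
  hb
}
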