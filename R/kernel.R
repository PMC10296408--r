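#' Canonical hemodynamic response kernel
#'
#' A double-gamma impulse response: a positive gamma lobe peaking near
#' `peak_s` seconds minus a later gamma lobe (the post-stimulus
#' undershoot) scaled by `undershoot_ratio`. The kernel is zero at t = 0,
#' rises to a single maximum normalised to exactly 1, and decays back
#' toward zero. Normalisation uses a fixed fine internal grid (1 ms) so
#' the unit peak does not depend on the caller's sampling grid.
#'
#' @param t Non-negative, strictly increasing time grid (s).
#' @param peak_s Mode of the main lobe (s); gamma shape `peak_s + 1`,
#'   scale 1.
#' @param undershoot_s Mode of the undershoot lobe (s).
#' @param undershoot_ratio Amplitude of the undershoot relative to the
#'   main lobe.
#' @return Numeric vector, the kernel evaluated at `t`, unit peak.
#' @examples
#' t <- seq(0, 30, by = 0.1)
#' k <- canonicalResponseKernel(t)
#' t[which.max(k)]  # close to 6 s
#' @export
canonicalResponseKernel <- function(t, peak_s = 6, undershoot_s = 16,
                                    undershoot_ratio = 1 / 6) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be a finite non-negative numeric grid")
  }
  if (length(t) > 1L && is.unsorted(t, strictly = TRUE)) {
    stop("'t' must be strictly increasing")
  }
  assertScalarNumeric(peak_s, "peak_s", lower = 0, strict_lower = TRUE)
  assertScalarNumeric(undershoot_s, "undershoot_s", lower = peak_s,
                      strict_lower = TRUE)
  assertScalarNumeric(undershoot_ratio, "undershoot_ratio", lower = 0)

  raw <- function(x) {
    dgamma(x, shape = peak_s + 1, scale = 1) -
      undershoot_ratio * dgamma(x, shape = undershoot_s + 1, scale = 1)
  }
  ## unit-peak normalisation on a fixed dense grid
  dense <- seq(0, max(undershoot_s * 2.5, 30), by = 1e-3)
  raw(t) / max(raw(dense))
}

#' Single-trial response shape for a stimulus of given duration
#'
#' Convolves the canonical kernel with a stimulus boxcar, tapers the
#' result smoothly to zero (raised cosine between `support_s - 2` and
#' `support_s`), and renormalises to unit peak. The compact support makes
#' each trial's response return exactly to baseline before the next
#' trial's pre-stimulus window, so a configured amplitude A is
#' recoverable to the grid step from baseline-corrected epochs.
#'
#' @param on_s Stimulus-on duration (s).
#' @param sampling_rate Hz.
#' @param support_s Time (s from onset) by which the response is exactly
#'   zero; must leave the following trial's baseline window clean.
#' @param ... Passed to [canonicalResponseKernel()].
#' @return Numeric vector of `round(support_s * sampling_rate)` samples,
#'   unit maximum, zero at and beyond `support_s`.
#' @keywords internal
trialResponseShape <- function(on_s, sampling_rate, support_s = 12, ...) {
  dt <- 1 / sampling_rate
  tk <- seq(0, support_s, by = dt)
  k <- canonicalResponseKernel(tk, ...)
  nbox <- max(1L, round(on_s * sampling_rate))
  shape <- stats::convolve(k, rev(rep(1, nbox)), type = "open") * dt
  ns <- round(support_s * sampling_rate)
  shape <- shape[seq_len(ns)]
  tt <- (seq_len(ns) - 1L) * dt
  taper <- ifelse(tt <= support_s - 2, 1,
                  0.5 * (1 + cos(pi * (tt - (support_s - 2)) / 2)))
  shape <- shape * taper
  shape / max(shape)
}
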