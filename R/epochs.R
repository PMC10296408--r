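#' Cut a recording into baseline-corrected trial epochs
#'
#' Extracts, for every scheduled trial, the window
#' `[onset - pre_s, onset + post_s]` of each chromophore and channel, and
#' subtracts the per-trial, per-channel mean of the baseline window. A
#' trial whose window does not fit within the recording is dropped with a
#' warning; an error is raised if all trials of a condition are dropped.
#'
#' @param hb An [HbRecording-class].
#' @param schedule An [EventSchedule-class]; defaults to the recording's.
#' @param pre_s,post_s Epoch window (s before / after onset; defaults
#'   cover the 5 s stimulus plus 10 s rest).
#' @param baseline Baseline window `c(start, end)` in seconds relative to
#'   onset, within `[-pre_s, 0]`.
#' @return An [EpochSet-class].
#' @export
epochTrials <- function(hb, schedule = eventSchedule(hb), pre_s = 2,
                        post_s = 15, baseline = c(-2, 0)) {
  stopifnot(is(hb, "HbRecording"), is(schedule, "EventSchedule"))
  assertScalarNumeric(pre_s, "pre_s", lower = 0)
  assertScalarNumeric(post_s, "post_s", lower = 0, strict_lower = TRUE)
  if (length(baseline) != 2L || baseline[1L] < -pre_s || baseline[2L] > 0 ||
      baseline[1L] >= baseline[2L]) {
    stop("'baseline' must be an increasing pair within [-pre_s, 0]")
  }
  fs <- samplingRate(hb)
  n <- ncol(hb)
  rel <- seq(-round(pre_s * fs), round(post_s * fs))
  time_rel <- rel / fs
  bidx <- which(time_rel >= baseline[1L] & time_rel <= baseline[2L])
  if (!length(bidx)) stop("baseline window contains no samples")

  tr <- trials(schedule)
  keep <- logical(nrow(tr))
  onset_idx <- integer(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    i0 <- round(tr$onset_s[i] * fs) + 1L
    onset_idx[i] <- i0
    keep[i] <- (i0 + rel[1L]) >= 1L && (i0 + rel[length(rel)]) <= n
  }
  dropped <- tr[!keep, c("onset_s", "condition"), drop = FALSE]
  if (nrow(dropped)) {
    warning(sprintf("dropped %d trial(s) whose window exceeds the recording",
                    nrow(dropped)))
    dropped$reason <- "window outside recording"
  } else {
    dropped <- data.frame(onset_s = numeric(), condition = character(),
                          reason = character(), stringsAsFactors = FALSE)
  }
  tr <- tr[keep, , drop = FALSE]
  onset_idx <- onset_idx[keep]
  if (!nrow(tr)) stop("all trials were dropped; nothing to epoch")

  ids <- channelIds(hb)
  usable <- rowData(hb)$usable
  if (is.null(usable)) usable <- rep(TRUE, length(ids))
  conds <- unique(tr$condition)
  epochs <- vector("list", length(conds))
  names(epochs) <- conds
  for (cond in conds) {
    which_tr <- which(tr$condition == cond)
    arrs <- lapply(CHROMOPHORES, function(chrom) {
      a <- assay(hb, chrom)
      arr <- array(NA_real_,
                   dim = c(length(which_tr), length(rel), length(ids)),
                   dimnames = list(NULL, NULL, ids))
      for (k in seq_along(which_tr)) {
        idx <- onset_idx[which_tr[k]] + rel
        seg <- a[, idx, drop = FALSE]              # channels x samples
        seg <- seg - rowMeans(seg[, bidx, drop = FALSE])
        arr[k, , ] <- t(seg)
      }
      arr
    })
    names(arrs) <- CHROMOPHORES
    epochs[[cond]] <- arrs
  }

  new("EpochSet", epochs = epochs, time_s = time_rel, pre_s = pre_s,
      post_s = post_s, baseline = as.numeric(baseline), sampling_rate = fs,
      channel_ids = ids,
      hemispheres = structure(rowData(hb)$hemisphere, names = ids),
      usable = structure(usable, names = ids), dropped = dropped)
}

.condArrays <- function(epochs, condition) {
  if (!condition %in% names(epochs@epochs)) {
    stop("no trials of condition '", condition, "' in this EpochSet")
  }
  epochs@epochs[[condition]]
}

#' Block (grand) average of trial epochs
#'
#' Point-wise mean and standard error (sd / sqrt(n), n-1 denominator)
#' across trials of one condition, per channel.
#'
#' @param epochs An [EpochSet-class].
#' @param condition "STIM" or "MOCK".
#' @param chromophore One of "OHb", "DHb", "THb".
#' @return A list with `mean` and `sem`, each a channels x samples
#'   matrix, plus `time_s` and `n_trials`.
#' @export
blockAverage <- function(epochs, condition, chromophore = "OHb") {
  stopifnot(is(epochs, "EpochSet"))
  chromophore <- match.arg(chromophore, CHROMOPHORES)
  arr <- .condArrays(epochs, condition)[[chromophore]]
  ntr <- dim(arr)[1L]
  if (ntr < 1L) stop("no trials to average")
  mu_ts <- colMeans(arr)                       # samples x channels
  mu <- t(mu_ts)
  sem <- if (ntr > 1L) {
    ## sd over trials from first and second moments, n-1 denominator
    v <- (colSums(arr^2) - ntr * mu_ts^2) / (ntr - 1)
    t(sqrt(pmax(v, 0))) / sqrt(ntr)
  } else {
    mu * 0
  }
  list(mean = mu, sem = sem, time_s = epochs@time_s, n_trials = ntr)
}
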