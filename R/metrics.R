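#' Peak amplitude and latency of an averaged trace
#'
#' The response peak is the maximal value within the search window for
#' THb and OHb, and the minimal value for DHb (whose evoked response is a
#' dip). Latency is the peak time relative to stimulus onset. Exact ties
#' are broken by the earliest time.
#'
#' @param trace Numeric vector, an averaged time course.
#' @param time_s Numeric vector of the same length, time relative to
#'   stimulus onset (s).
#' @param chromophore One of "OHb", "DHb", "THb"; decides max vs min.
#' @param search_window `c(start, end)` in seconds, within the trace.
#' @return Named numeric `c(amplitude, latency_s)`.
#' @examples
#' t <- seq(-2, 15, by = 0.1)
#' extractPeak(exp(-(t - 6)^2), t, "OHb")
#' @export
extractPeak <- function(trace, time_s, chromophore = "OHb",
                        search_window = c(0, 15)) {
  chromophore <- match.arg(chromophore, CHROMOPHORES)
  if (length(trace) != length(time_s)) {
    stop("'trace' and 'time_s' must have equal length")
  }
  idx <- which(time_s >= search_window[1L] & time_s <= search_window[2L])
  if (!length(idx)) stop("search window contains no samples")
  seg <- trace[idx]
  k <- if (chromophore == "DHb") which.min(seg) else which.max(seg)
  c(amplitude = seg[k], latency_s = time_s[idx[k]])
}

.usableIds <- function(epochs) {
  ids <- epochs@channel_ids
  ids[epochs@usable[ids]]
}

## block-averaged traces restricted to usable channels
.usableMeans <- function(epochs, condition, chromophore) {
  ba <- blockAverage(epochs, condition, chromophore)
  keep <- .usableIds(epochs)
  if (!length(keep)) stop("no usable channels")
  list(mean = ba$mean[keep, , drop = FALSE], time_s = ba$time_s)
}

#' Channel-average evoked response
#'
#' Averages the block-averaged traces across usable channels, then
#' extracts the peak of the averaged trace, per chromophore.
#'
#' @param epochs An [EpochSet-class].
#' @param condition "STIM" or "MOCK".
#' @param search_window Peak search window (s from onset).
#' @return data.frame with columns `chromophore`, `amplitude`,
#'   `latency_s`.
#' @export
channelAverageResponse <- function(epochs, condition,
                                   search_window = c(0, 15)) {
  out <- lapply(CHROMOPHORES, function(chrom) {
    um <- .usableMeans(epochs, condition, chrom)
    avg <- colMeans(um$mean)
    pk <- extractPeak(avg, um$time_s, chrom, search_window)
    data.frame(chromophore = chrom, amplitude = pk[["amplitude"]],
               latency_s = pk[["latency_s"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Best-channel evoked response
#'
#' Selects the usable channel with the largest block-averaged OHb peak
#' for the requested condition (ties broken by the alphabetically lowest
#' channel id) and reports all three chromophore peaks from that channel.
#'
#' @inheritParams channelAverageResponse
#' @return A list: `channel_id` and `table` (data.frame `chromophore`,
#'   `amplitude`, `latency_s`).
#' @export
bestChannelResponse <- function(epochs, condition,
                                search_window = c(0, 15)) {
  um <- .usableMeans(epochs, condition, "OHb")
  ids <- rownames(um$mean)
  peaks <- vapply(ids, function(cid) {
    extractPeak(um$mean[cid, ], um$time_s, "OHb", search_window)[["amplitude"]]
  }, numeric(1))
  ord <- order(-peaks, ids)   # max amplitude, then lowest channel id
  best <- ids[ord[1L]]
  tab <- lapply(CHROMOPHORES, function(chrom) {
    umc <- .usableMeans(epochs, condition, chrom)
    pk <- extractPeak(umc$mean[best, ], umc$time_s, chrom, search_window)
    data.frame(chromophore = chrom, amplitude = pk[["amplitude"]],
               latency_s = pk[["latency_s"]], stringsAsFactors = FALSE)
  })
  list(channel_id = best, table = do.call(rbind, tab))
}

#' Hemisphere-average OHb peaks
#'
#' For each usable channel, takes the maximum of the block-averaged OHb
#' trace within the search window, then averages those per-channel maxima
#' within each hemisphere ("average maximum", not the maximum of the
#' averaged trace). Midline channels are excluded.
#'
#' @inheritParams channelAverageResponse
#' @return Named numeric `c(peak_left, peak_right)`.
#' @export
hemispherePeaks <- function(epochs, condition, search_window = c(0, 15)) {
  um <- .usableMeans(epochs, condition, "OHb")
  ids <- rownames(um$mean)
  hemi <- epochs@hemispheres[ids]
  maxima <- vapply(ids, function(cid) {
    extractPeak(um$mean[cid, ], um$time_s, "OHb", search_window)[["amplitude"]]
  }, numeric(1))
  if (!any(hemi == "left") || !any(hemi == "right")) {
    stop("need at least one usable channel in each hemisphere")
  }
  c(peak_left = mean(maxima[hemi == "left"]),
    peak_right = mean(maxima[hemi == "right"]))
}

#' Laterality index
#'
#' `LI = (peak_left - peak_right) / (peak_left + peak_right)`. With both
#' peaks positive, LI lies in `[-1, 1]`; negative values indicate
#' rightward dominance. A zero denominator is an error, not a silent NaN.
#'
#' @param peak_left,peak_right Hemisphere-average peak amplitudes.
#' @return The laterality index (dimensionless).
#' @examples
#' lateralityIndex(2e-5, 6e-5)  # -0.5
#' @export
lateralityIndex <- function(peak_left, peak_right) {
  assertScalarNumeric(peak_left, "peak_left")
  assertScalarNumeric(peak_right, "peak_right")
  denom <- peak_left + peak_right
  if (denom == 0) {
    stop("laterality index undefined: peak_left + peak_right is zero")
  }
  (peak_left - peak_right) / denom
}

#' All evoked-response readouts for one subject and condition
#'
#' @inheritParams channelAverageResponse
#' @return A [SubjectResponse-class].
#' @export
subjectResponse <- function(epochs, condition, search_window = c(0, 15)) {
  avg <- channelAverageResponse(epochs, condition, search_window)
  best <- bestChannelResponse(epochs, condition, search_window)
  hp <- hemispherePeaks(epochs, condition, search_window)
  tab <- data.frame(
    chromophore = avg$chromophore,
    avg_amplitude = avg$amplitude,
    avg_latency = avg$latency_s,
    best_amplitude = best$table$amplitude,
    best_latency = best$table$latency_s,
    stringsAsFactors = FALSE
  )
  ## a condition with no response at all (e.g. a noiseless MOCK) has an
  ## undefined LI; record NA rather than refuse the whole readout
  li <- tryCatch(lateralityIndex(hp[["peak_left"]], hp[["peak_right"]]),
                 error = function(e) NA_real_)
  new("SubjectResponse", condition = condition, table = tab,
      best_channel = best$channel_id,
      peak_left = hp[["peak_left"]], peak_right = hp[["peak_right"]],
      li = li)
}

#' Tidy per-subject metric table
#'
#' Epochs a recording and emits one row per (condition, chromophore,
#' metric): channel-average and best-channel amplitude and latency, plus
#' per-condition hemisphere peaks and the laterality index (attached to
#' chromophore "OHb", from which they are computed).
#'
#' @param hb An [HbRecording-class] with a schedule.
#' @param subject_id,group Identifiers copied into the table.
#' @param pre_s,post_s,baseline Passed to [epochTrials()].
#' @param search_window Passed to the peak extractors.
#' @return data.frame with columns `subject_id`, `group`, `condition`,
#'   `chromophore`, `metric`, `value`.
#' @export
subjectMetrics <- function(hb, subject_id = "S01", group = NA_character_,
                           pre_s = 2, post_s = 15, baseline = c(-2, 0),
                           search_window = c(0, 15)) {
  epochs <- epochTrials(hb, pre_s = pre_s, post_s = post_s,
                        baseline = baseline)
  rows <- list()
  for (cond in names(epochs@epochs)) {
    sr <- subjectResponse(epochs, cond, search_window)
    tab <- sr@table
    for (i in seq_len(nrow(tab))) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, chromophore = tab$chromophore[i],
        metric = c("avg_amplitude", "avg_latency", "best_amplitude",
                   "best_latency"),
        value = c(tab$avg_amplitude[i], tab$avg_latency[i],
                  tab$best_amplitude[i], tab$best_latency[i]),
        stringsAsFactors = FALSE
      )
    }
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, chromophore = "OHb",
      metric = c("peak_left", "peak_right", "li"),
      value = c(sr@peak_left, sr@peak_right, sr@li),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  cbind(data.frame(subject_id = subject_id, group = group,
                   stringsAsFactors = FALSE),
        out, row.names = NULL)
}

#' Metric table for a simulated cohort
#'
#' @param cohort The list returned by [simulateCohort()].
#' @param ... Passed to [subjectMetrics()].
#' @return Row-bound tidy metric table for all subjects.
#' @export
cohortMetrics <- function(cohort, ...) {
  do.call(rbind, lapply(cohort$subjects, function(s) {
    subjectMetrics(s$recording, subject_id = s$id, group = s$group, ...)
  }))
}
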