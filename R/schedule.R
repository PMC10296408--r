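#' Generate a pseudorandomly interleaved event schedule
#'
#' Builds the event-related design used throughout the package: `n_stim`
#' patterned-stimulus trials and `n_mock` zero-contrast control trials,
#' each `on_s` seconds of stimulus followed by `off_s` seconds of rest,
#' in a seeded uniformly shuffled order. Onsets are seconds from the
#' start of the schedule; trial k starts where trial k-1's rest ends.
#'
#' @param n_stim,n_mock Number of STIM / MOCK trials (non-negative).
#' @param on_s,off_s Stimulus-on and stimulus-off durations (s, > 0).
#' @param seed Integer seed for the interleaving shuffle.
#' @return An [EventSchedule-class]. With the defaults
#'   (20 + 20 trials, 5 s on / 10 s off) the schedule lasts 600 s.
#' @examples
#' s <- generateEventSchedule(20, 20, 5, 10, seed = 1)
#' totalDuration(s)  # 600
#' @export
generateEventSchedule <- function(n_stim = 20, n_mock = 20, on_s = 5,
                                  off_s = 10, seed = 1) {
  n_stim <- assertCount(n_stim, "n_stim")
  n_mock <- assertCount(n_mock, "n_mock")
  assertScalarNumeric(on_s, "on_s", lower = 0, strict_lower = TRUE)
  assertScalarNumeric(off_s, "off_s", lower = 0, strict_lower = TRUE)

  n <- n_stim + n_mock
  cond <- c(rep("STIM", n_stim), rep("MOCK", n_mock))
  if (n > 0L) {
    cond <- withSeed(seed, sample(cond))
  }
  onset <- if (n > 0L) (seq_len(n) - 1L) * (on_s + off_s) else numeric()
  trials <- data.frame(
    onset_s = onset,
    on_s = rep(on_s, n),
    off_s = rep(off_s, n),
    condition = cond,
    stringsAsFactors = FALSE
  )
  new("EventSchedule", trials = trials,
      total_duration = n * (on_s + off_s), seed = as.integer(seed))
}

#' Shift schedule onsets by a constant offset
#'
#' Used when a schedule is embedded into a longer recording (e.g. after a
#' pre-roll): onsets move, durations and conditions are unchanged, and
#' `totalDuration()` still reports the stimulation time.
#'
#' @param schedule An [EventSchedule-class].
#' @param offset_s Seconds to add to every onset.
#' @return The shifted [EventSchedule-class].
#' @export
shiftSchedule <- function(schedule, offset_s) {
  stopifnot(is(schedule, "EventSchedule"))
  assertScalarNumeric(offset_s, "offset_s")
  tr <- schedule@trials
  tr$onset_s <- tr$onset_s + offset_s
  initialize(schedule, trials = tr)
}
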