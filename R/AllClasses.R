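#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData assayNames assays<- rowData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' MontageLayout: optode and channel geometry
#'
#' Describes an fNIRS probe array: source and detector scalp positions
#' (arbitrary planar units), the source-detector pairs forming measurement
#' channels, the hemisphere each channel samples, the wavelength pair, and
#' the nominal source-detector separation used by the modified
#' Beer-Lambert conversion.
#'
#' @slot sources data.frame with columns `id`, `x`, `y`.
#' @slot detectors data.frame with columns `id`, `x`, `y`.
#' @slot channels data.frame with columns `channel_id`, `source_id`,
#'   `detector_id`, `hemisphere` (one of "left", "right", "midline"),
#'   `distance_cm`, and the channel midpoint `x`, `y`.
#' @slot wavelengths numeric ordered pair of wavelengths in nm.
#' @export
setClass("MontageLayout",
  slots = c(
    sources    = "data.frame",
    detectors  = "data.frame",
    channels   = "data.frame",
    wavelengths = "numeric"
  )
)

setValidity("MontageLayout", function(object) {
  msg <- character()
  ch <- object@channels
  need <- c("channel_id", "source_id", "detector_id", "hemisphere",
            "distance_cm", "x", "y")
  if (!all(need %in% names(ch))) {
    msg <- c(msg, paste("channels must have columns:",
                        paste(need, collapse = ", ")))
  } else {
    if (!all(ch$source_id %in% object@sources$id)) {
      msg <- c(msg, "every channel must reference an existing source")
    }
    if (!all(ch$detector_id %in% object@detectors$id)) {
      msg <- c(msg, "every channel must reference an existing detector")
    }
    if (!all(ch$hemisphere %in% c("left", "right", "midline"))) {
      msg <- c(msg, "hemisphere must be 'left', 'right' or 'midline'")
    }
    if (anyDuplicated(ch$channel_id)) {
      msg <- c(msg, "channel ids must be unique")
    }
    if (any(ch$distance_cm <= 0)) {
      msg <- c(msg, "source-detector distances must be positive")
    }
  }
  if (length(object@wavelengths) != 2L || any(object@wavelengths <= 0)) {
    msg <- c(msg, "wavelengths must be an ordered pair of positive nm values")
  }
  if (length(msg)) msg else TRUE
})

#' EventSchedule: ordered stimulus and mock trials
#'
#' Ordered, non-overlapping trials, each a stimulus-on period followed by a
#' stimulus-off period, labelled STIM (patterned stimulus) or MOCK
#' (zero-contrast control).
#'
#' @slot trials data.frame with columns `onset_s`, `on_s`, `off_s`,
#'   `condition` ("STIM" or "MOCK").
#' @slot total_duration numeric, sum of on+off durations in seconds.
#' @slot seed integer seed used for the condition interleaving.
#' @export
setClass("EventSchedule",
  slots = c(
    trials = "data.frame",
    total_duration = "numeric",
    seed = "integer"
  )
)

setValidity("EventSchedule", function(object) {
  msg <- character()
  tr <- object@trials
  need <- c("onset_s", "on_s", "off_s", "condition")
  if (!all(need %in% names(tr))) {
    msg <- c(msg, paste("trials must have columns:",
                        paste(need, collapse = ", ")))
  } else if (nrow(tr)) {
    if (is.unsorted(tr$onset_s, strictly = TRUE)) {
      msg <- c(msg, "trials must be sorted by onset with unique onsets")
    }
    ends <- tr$onset_s + tr$on_s + tr$off_s
    if (nrow(tr) > 1L && any(tr$onset_s[-1L] < ends[-nrow(tr)] - 1e-9)) {
      msg <- c(msg, "trials must not overlap")
    }
    if (!all(tr$condition %in% c("STIM", "MOCK"))) {
      msg <- c(msg, "condition must be 'STIM' or 'MOCK'")
    }
    if (any(tr$on_s <= 0) || any(tr$off_s <= 0)) {
      msg <- c(msg, "durations must be positive")
    }
  }
  if (abs(object@total_duration - sum(tr$on_s + tr$off_s)) > 1e-9) {
    msg <- c(msg, "total_duration must equal the sum of on+off durations")
  }
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the forward model
#'
#' Parameters controlling a simulated subject: evoked response amplitudes,
#' between-subject variability, hemispheric lateralization, physiological
#' noise amplitudes, and motion-artifact settings.
#'
#' Amplitudes are molar concentration changes (mol/L). `noise` holds the
#' amplitudes of the oxygenated-hemoglobin noise components; the
#' deoxygenated channel receives the same components scaled by
#' `dhb_noise_scale`. `lateralization` is the multiplicative gain applied
#' to right-hemisphere channels (values > 1 produce a rightward response
#' bias); `lateralization_sd` is the standard deviation of a mean-one
#' log-normal subject-level jitter on that gain.
#'
#' @slot sampling_rate numeric, Hz.
#' @slot amplitude_ohb numeric, mean OHb peak amplitude (mol/L, > 0).
#' @slot amplitude_dhb numeric, mean DHb peak amplitude (mol/L, < 0).
#' @slot amplitude_sd numeric, between-subject SD of the OHb amplitude.
#' @slot lateralization numeric, right-hemisphere gain (> 0).
#' @slot lateralization_sd numeric, SD of the log-normal gain jitter.
#' @slot dhb_lag_s numeric, lag of the DHb response relative to OHb.
#' @slot noise named numeric: `cardiac`, `respiratory`, `mayer`
#'   (sinusoid amplitudes, mol/L), `drift` (random-walk step SD per
#'   sample), `white` (Gaussian SD per sample).
#' @slot dhb_noise_scale numeric, DHb noise scaling.
#' @slot artifact_rate numeric, motion artifact events per minute.
#' @slot spike_mag numeric, spike magnitude in optical-density units.
#' @slot shift_mag numeric, baseline-shift magnitude in OD units.
#' @export
setClass("SimulationConfig",
  slots = c(
    sampling_rate = "numeric",
    amplitude_ohb = "numeric",
    amplitude_dhb = "numeric",
    amplitude_sd = "numeric",
    lateralization = "numeric",
    lateralization_sd = "numeric",
    dhb_lag_s = "numeric",
    noise = "numeric",
    dhb_noise_scale = "numeric",
    artifact_rate = "numeric",
    spike_mag = "numeric",
    shift_mag = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@sampling_rate <= 0) msg <- c(msg, "sampling_rate must be > 0")
  if (object@amplitude_ohb <= 0) msg <- c(msg, "amplitude_ohb must be > 0")
  if (object@amplitude_dhb > 0) msg <- c(msg, "amplitude_dhb must be <= 0")
  if (object@amplitude_sd < 0) msg <- c(msg, "amplitude_sd must be >= 0")
  if (object@lateralization <= 0) msg <- c(msg, "lateralization must be > 0")
  if (object@lateralization_sd < 0) {
    msg <- c(msg, "lateralization_sd must be >= 0")
  }
  need <- c("cardiac", "respiratory", "mayer", "drift", "white")
  if (!all(need %in% names(object@noise))) {
    msg <- c(msg, paste("noise must be named:", paste(need, collapse = ", ")))
  } else if (any(object@noise < 0)) {
    msg <- c(msg, "noise amplitudes must be >= 0")
  }
  if (object@artifact_rate < 0) msg <- c(msg, "artifact_rate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: generative parameters of one simulated subject
#'
#' @slot amplitudes matrix, chromophores x channels, true stimulus-evoked
#'   peak amplitudes (mol/L).
#' @slot peak_left,peak_right numeric, true hemisphere-average OHb peaks.
#' @slot li numeric, true laterality index
#'   `(peak_left - peak_right) / (peak_left + peak_right)`.
#' @slot seed integer seed used to generate the subject.
#' @export
setClass("GroundTruth",
  slots = c(
    amplitudes = "matrix",
    peak_left = "numeric",
    peak_right = "numeric",
    li = "numeric",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  denom <- object@peak_left + object@peak_right
  if (denom != 0 &&
      abs(object@li - (object@peak_left - object@peak_right) / denom) > 1e-12) {
    return("li must equal (peak_left - peak_right)/(peak_left + peak_right)")
  }
  TRUE
})

#' HbRecording and ODRecording: multichannel fNIRS time series
#'
#' Both classes extend [SummarizedExperiment::SummarizedExperiment] with
#' channels as rows and time samples as columns. `HbRecording` carries
#' chromophore concentration-change assays `OHb`, `DHb`, `THb` (mol/L)
#' satisfying `THb = OHb + DHb` sample-wise; `ODRecording` carries one
#' optical-density-change assay per wavelength (named `od_<nm>`).
#' Sampling rate, montage and event schedule live in `metadata()`;
#' channel annotation (hemisphere, usability) in `rowData()`; the time
#' axis in `colData()$time_s`.
#'
#' @aliases ODRecording-class
#' @export
setClass("HbRecording", contains = "SummarizedExperiment")

#' @rdname HbRecording-class
#' @export
setClass("ODRecording", contains = "SummarizedExperiment")

.validRecordingCore <- function(object) {
  msg <- character()
  md <- metadata(object)
  if (is.null(md$sampling_rate) || md$sampling_rate <= 0) {
    msg <- c(msg, "metadata()$sampling_rate must be a positive number")
  }
  if (is.null(colData(object)$time_s)) {
    msg <- c(msg, "colData()$time_s is required")
  }
  for (a in assayNames(object)) {
    if (!all(is.finite(assay(object, a)))) {
      msg <- c(msg, sprintf("assay '%s' contains non-finite values", a))
    }
  }
  msg
}

setValidity("HbRecording", function(object) {
  msg <- .validRecordingCore(object)
  if (!all(CHROMOPHORES %in% assayNames(object))) {
    msg <- c(msg, "assays OHb, DHb, THb are required")
  } else {
    resid <- assay(object, "THb") -
      (assay(object, "OHb") + assay(object, "DHb"))
    if (max(abs(resid)) >= 1e-12) {
      msg <- c(msg, "THb must equal OHb + DHb sample-wise (tolerance 1e-12)")
    }
  }
  if (length(msg)) msg else TRUE
})

setValidity("ODRecording", function(object) {
  msg <- .validRecordingCore(object)
  if (!any(grepl("^od_", assayNames(object)))) {
    msg <- c(msg, "at least one 'od_<nm>' assay is required")
  }
  if (length(msg)) msg else TRUE
})

#' ArtifactMask: detected or injected motion-artifact intervals
#'
#' @slot events data.frame with columns `channel_id`, `start`, `end`
#'   (sample indices, inclusive) and `kind` ("spike" or "shift").
#' @slot n_samples integer, recording length the mask refers to.
#' @export
setClass("ArtifactMask",
  slots = c(events = "data.frame", n_samples = "integer")
)

setValidity("ArtifactMask", function(object) {
  ev <- object@events
  need <- c("channel_id", "start", "end", "kind")
  if (!all(need %in% names(ev))) {
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  }
  msg <- character()
  if (nrow(ev)) {
    if (any(ev$start < 1L) || any(ev$end > object@n_samples) ||
        any(ev$end < ev$start)) {
      msg <- c(msg, "intervals must lie within the recording")
    }
    if (!all(ev$kind %in% c("spike", "shift"))) {
      msg <- c(msg, "kind must be 'spike' or 'shift'")
    }
    sp <- split(ev, ev$channel_id)
    for (d in sp) {
      d <- d[order(d$start), ]
      if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
        msg <- c(msg, "intervals must be non-overlapping per channel")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' EpochSet: baseline-corrected peri-stimulus trial epochs
#'
#' Trials cut around each scheduled onset, organised per condition and
#' chromophore as `trials x samples x channels` arrays, baseline-corrected
#' per trial and channel.
#'
#' @slot epochs named list: condition -> chromophore -> 3D array.
#' @slot time_s numeric, epoch time axis relative to stimulus onset.
#' @slot pre_s,post_s numeric, epoch window bounds (s).
#' @slot baseline numeric pair, baseline window in `[-pre_s, 0]`.
#' @slot sampling_rate numeric, Hz.
#' @slot channel_ids character.
#' @slot hemispheres named character, hemisphere per channel.
#' @slot usable named logical, channels entering averages.
#' @slot dropped data.frame of dropped trials (condition, onset_s, reason).
#' @export
setClass("EpochSet",
  slots = c(
    epochs = "list",
    time_s = "numeric",
    pre_s = "numeric",
    post_s = "numeric",
    baseline = "numeric",
    sampling_rate = "numeric",
    channel_ids = "character",
    hemispheres = "character",
    usable = "logical",
    dropped = "data.frame"
  )
)

#' SubjectResponse: one subject's evoked-response readouts
#'
#' Channel-average and best-channel peak amplitude and latency per
#' chromophore, hemisphere-average OHb peaks, and the laterality index
#' `LI = (peak_left - peak_right) / (peak_left + peak_right)`.
#'
#' @slot condition character, "STIM" or "MOCK".
#' @slot table data.frame with columns `chromophore`, `avg_amplitude`,
#'   `avg_latency`, `best_amplitude`, `best_latency`.
#' @slot best_channel character, id of the channel with the largest OHb peak.
#' @slot peak_left,peak_right numeric, hemisphere-average OHb maxima.
#' @slot li numeric, laterality index.
#' @export
setClass("SubjectResponse",
  slots = c(
    condition = "character",
    table = "data.frame",
    best_channel = "character",
    peak_left = "numeric",
    peak_right = "numeric",
    li = "numeric"
  )
)
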