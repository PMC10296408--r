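#' Accessor generics
#'
#' Accessors for the core classes: `samplingRate()` (Hz), `montage()`
#' (the [MontageLayout-class]), `eventSchedule()` (the
#' [EventSchedule-class]), `channelIds()`, `hemispheres()` (named
#' character per channel), `trials()` (the trial table of a schedule),
#' `totalDuration()` (s), `artifactEvents()` (interval table of an
#' [ArtifactMask-class]), and `trueLI()` (ground-truth laterality index).
#'
#' @param x An object of the documented classes.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("montage", function(x) standardGeneric("montage"))

#' @rdname accessors
#' @export
setGeneric("eventSchedule", function(x) standardGeneric("eventSchedule"))

#' @rdname accessors
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))

#' @rdname accessors
#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))

#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @rdname accessors
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

#' @rdname accessors
#' @export
setGeneric("artifactEvents", function(x) standardGeneric("artifactEvents"))

#' @rdname accessors
#' @export
setGeneric("trueLI", function(x) standardGeneric("trueLI"))

## ------------------------------------------------------------------ methods

#' @rdname accessors
setMethod("channelIds", "MontageLayout", function(x) x@channels$channel_id)

#' @rdname accessors
setMethod("hemispheres", "MontageLayout", function(x) {
  structure(x@channels$hemisphere, names = x@channels$channel_id)
})

#' @rdname accessors
setMethod("trials", "EventSchedule", function(x) x@trials)

#' @rdname accessors
setMethod("totalDuration", "EventSchedule", function(x) x@total_duration)

#' @rdname accessors
setMethod("samplingRate", "SummarizedExperiment", function(x) {
  metadata(x)$sampling_rate
})

#' @rdname accessors
setMethod("montage", "SummarizedExperiment", function(x) metadata(x)$montage)

#' @rdname accessors
setMethod("eventSchedule", "SummarizedExperiment", function(x) {
  metadata(x)$schedule
})

#' @rdname accessors
setMethod("channelIds", "SummarizedExperiment", function(x) rownames(x))

#' @rdname accessors
setMethod("hemispheres", "SummarizedExperiment", function(x) {
  structure(rowData(x)$hemisphere, names = rownames(x))
})

#' @rdname accessors
setMethod("artifactEvents", "ArtifactMask", function(x) x@events)

#' @rdname accessors
setMethod("trueLI", "GroundTruth", function(x) x@li)

#' @rdname accessors
setMethod("channelIds", "EpochSet", function(x) x@channel_ids)

#' @rdname accessors
setMethod("hemispheres", "EpochSet", function(x) x@hemispheres)

#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@sampling_rate)

## ------------------------------------------------------------------- show

setMethod("show", "MontageLayout", function(object) {
  h <- table(factor(object@channels$hemisphere,
                    levels = c("left", "right", "midline")))
  cat(sprintf(
    "MontageLayout: %d sources, %d detectors, %d channels (%d left, %d right, %d midline)\n",
    nrow(object@sources), nrow(object@detectors), nrow(object@channels),
    h[["left"]], h[["right"]], h[["midline"]]
  ))
  cat(sprintf("wavelengths: %s nm\n",
              paste(object@wavelengths, collapse = " / ")))
})

setMethod("show", "EventSchedule", function(object) {
  tab <- table(factor(object@trials$condition, levels = c("STIM", "MOCK")))
  cat(sprintf(
    "EventSchedule: %d trials (%d STIM, %d MOCK), total %g s\n",
    nrow(object@trials), tab[["STIM"]], tab[["MOCK"]], object@total_duration
  ))
})

setMethod("show", "ArtifactMask", function(object) {
  cat(sprintf("ArtifactMask: %d intervals on %d channel(s), %d samples\n",
              nrow(object@events),
              length(unique(object@events$channel_id)),
              object@n_samples))
  if (nrow(object@events)) {
    print(table(object@events$kind))
  }
})

setMethod("show", "SubjectResponse", function(object) {
  cat(sprintf("SubjectResponse (%s)\n", object@condition))
  print(object@table, row.names = FALSE)
  cat(sprintf("best channel: %s\n", object@best_channel))
  cat(sprintf("peak_left = %.3e, peak_right = %.3e, LI = %.3f\n",
              object@peak_left, object@peak_right, object@li))
})

setMethod("show", "EpochSet", function(object) {
  conds <- names(object@epochs)
  ntr <- vapply(object@epochs, function(e) dim(e[[1L]])[1L], integer(1))
  cat(sprintf(
    "EpochSet: %s; window [%g, %g] s, baseline [%g, %g] s, %d channels\n",
    paste(sprintf("%s: %d trials", conds, ntr), collapse = ", "),
    -object@pre_s, object@post_s, object@baseline[1L], object@baseline[2L],
    length(object@channel_ids)
  ))
})
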