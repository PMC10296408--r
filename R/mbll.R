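#' Built-in hemoglobin extinction coefficients
#'
#' Molar extinction coefficients (cm^-1 per mol/L) of oxygenated and
#' deoxygenated hemoglobin at the two acquisition wavelengths, from the
#' compilation of whole-blood spectra widely used in continuous-wave
#' NIRS processing. Rows are wavelengths, columns the chromophores.
#' Shipping the table with the package keeps the optical-density <->
#' concentration conversion fully reproducible.
#'
#' @param wavelengths Ordered pair of wavelengths; only 760 and 850 nm
#'   are tabulated.
#' @return 2x2 numeric matrix, `dimnames = list(wavelength, c("OHb","DHb"))`.
#' @export
defaultExtinction <- function(wavelengths = c(760, 850)) {
  tab <- rbind(
    "760" = c(OHb = 1486.5865, DHb = 3843.707),
    "850" = c(OHb = 2526.391,  DHb = 1798.643)
  )
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(tab))) {
    stop("extinction coefficients are tabulated for 760 and 850 nm only")
  }
  tab[key, , drop = FALSE]
}

.checkExtinction <- function(extinction) {
  if (!is.matrix(extinction) || any(dim(extinction) != 2L) ||
      !all(is.finite(extinction))) {
    stop("'extinction' must be a finite 2x2 matrix (wavelength x chromophore)")
  }
  if (abs(det(extinction)) < 1e-8 * max(abs(extinction))^2) {
    stop("extinction matrix is singular; chromophores are not separable")
  }
  invisible(extinction)
}

.newRecording <- function(class, assays, sampling_rate, montage = NULL,
                          schedule = NULL, rowdata = NULL) {
  n <- ncol(assays[[1L]])
  time_s <- (seq_len(n) - 1L) / sampling_rate
  se <- SummarizedExperiment(
    assays = assays,
    rowData = rowdata,
    colData = DataFrame(time_s = time_s)
  )
  metadata(se)$sampling_rate <- sampling_rate
  metadata(se)$montage <- montage
  metadata(se)$schedule <- schedule
  as(se, class)
}

.channelRowData <- function(montage) {
  ch <- montage@channels
  DataFrame(
    channel_id = ch$channel_id,
    source_id = ch$source_id,
    detector_id = ch$detector_id,
    hemisphere = ch$hemisphere,
    distance_cm = ch$distance_cm,
    usable = TRUE,
    row.names = ch$channel_id
  )
}

#' Construct an HbRecording from concentration matrices
#'
#' @param ohb,dhb Channels x samples matrices of concentration changes
#'   (mol/L); THb is set to their exact sum.
#' @param sampling_rate Hz.
#' @param montage A [MontageLayout-class] (rows must match its channels).
#' @param schedule Optional [EventSchedule-class].
#' @return An [HbRecording-class].
#' @export
HbRecording <- function(ohb, dhb, sampling_rate, montage, schedule = NULL) {
  ids <- channelIds(montage)
  stopifnot(nrow(ohb) == length(ids), identical(dim(ohb), dim(dhb)))
  rownames(ohb) <- rownames(dhb) <- ids
  .newRecording("HbRecording",
                list(OHb = ohb, DHb = dhb, THb = ohb + dhb),
                sampling_rate, montage, schedule,
                rowdata = .channelRowData(montage))
}

#' Forward modified Beer-Lambert transform
#'
#' Maps chromophore concentration changes to optical-density changes at
#' the montage's two wavelengths:
#' `dOD(lambda) = (eps_OHb(lambda) * dOHb + eps_DHb(lambda) * dDHb)
#'   * DPF(lambda) * d`,
#' with `d` the per-channel source-detector distance (cm) and DPF the
#' differential pathlength factor.
#'
#' @param hb An [HbRecording-class].
#' @param montage A [MontageLayout-class]; defaults to the recording's.
#' @param dpf Differential pathlength factor, one value per wavelength
#'   (recycled if scalar).
#' @param extinction 2x2 extinction matrix (wavelength x chromophore),
#'   see [defaultExtinction()].
#' @return An [ODRecording-class] with assays `od_<nm>`.
#' @seealso [mbllInverse()] for the inverse conversion.
#' @export
mbllForward <- function(hb, montage = NULL, dpf = c(6, 6),
                        extinction = NULL) {
  stopifnot(is(hb, "HbRecording"))
  if (is.null(montage)) montage <- montage(hb)
  wl <- montage@wavelengths
  if (is.null(extinction)) extinction <- defaultExtinction(wl)
  .checkExtinction(extinction)
  dpf <- rep_len(dpf, 2L)
  dist <- rowData(hb)$distance_cm

  ohb <- assay(hb, "OHb")
  dhb <- assay(hb, "DHb")
  od <- lapply(1:2, function(i) {
    (extinction[i, 1L] * ohb + extinction[i, 2L] * dhb) * dpf[i] * dist
  })
  names(od) <- paste0("od_", wl)
  out <- .newRecording("ODRecording", od, samplingRate(hb),
                       montage, eventSchedule(hb),
                       rowdata = rowData(hb))
  metadata(out)$dpf <- dpf
  out
}

#' Inverse modified Beer-Lambert transform
#'
#' Recovers chromophore concentration changes from dual-wavelength
#' optical-density changes by solving, per channel and sample, the 2x2
#' linear system `dOD(lambda) / (DPF(lambda) * d) = E %*% c(dOHb, dDHb)`
#' where `E` is the extinction matrix. Total hemoglobin is set to the
#' exact sum `THb = OHb + DHb`.
#'
#' @param od An [ODRecording-class] with one assay per wavelength.
#' @param montage A [MontageLayout-class]; defaults to the recording's.
#' @param dpf Differential pathlength factor per wavelength.
#' @param extinction 2x2 extinction matrix (wavelength x chromophore).
#' @return An [HbRecording-class].
#' @export
mbllInverse <- function(od, montage = NULL, dpf = c(6, 6),
                        extinction = NULL) {
  stopifnot(is(od, "ODRecording"))
  if (is.null(montage)) montage <- montage(od)
  wl <- montage@wavelengths
  anames <- paste0("od_", wl)
  if (!all(anames %in% assayNames(od))) {
    stop("recording lacks optical-density assays for wavelengths ",
         paste(wl, collapse = ", "))
  }
  if (is.null(extinction)) extinction <- defaultExtinction(wl)
  .checkExtinction(extinction)
  dpf <- rep_len(dpf, 2L)
  dist <- rowData(od)$distance_cm
  einv <- solve(extinction)

  od1 <- assay(od, anames[1L]) / (dpf[1L] * dist)
  od2 <- assay(od, anames[2L]) / (dpf[2L] * dist)
  ohb <- einv[1L, 1L] * od1 + einv[1L, 2L] * od2
  dhb <- einv[2L, 1L] * od1 + einv[2L, 2L] * od2

  out <- .newRecording("HbRecording",
                       list(OHb = ohb, DHb = dhb, THb = ohb + dhb),
                       samplingRate(od), montage, eventSchedule(od),
                       rowdata = rowData(od))
  out
}
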