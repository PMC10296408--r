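#' Default 22-channel occipital montage
#'
#' Builds the package's standard probe layout: eight sources and seven
#' detectors arranged as a left/right mirror-symmetric two-row grid over
#' the occipital cortex, paired into 22 measurement channels (11 per
#' hemisphere). One detector sits on the midline; every channel midpoint
#' is lateralised, so no channel carries the "midline" label. Positions
#' are planar scalp coordinates in arbitrary units; hemisphere labels
#' derive from the sign of the channel midpoint x-coordinate (x < 0 left,
#' x > 0 right, x = 0 midline). All channels share the nominal 3 cm
#' source-detector separation.
#'
#' @param distance_cm Source-detector separation assigned to every
#'   channel (cm).
#' @param wavelengths Ordered pair of wavelengths in nm.
#' @return A [MontageLayout-class].
#' @examples
#' m <- makeDefaultMontage()
#' nrow(m@channels)  # 22
#' @export
makeDefaultMontage <- function(distance_cm = 3, wavelengths = c(760, 850)) {
  assertScalarNumeric(distance_cm, "distance_cm", lower = 0,
                      strict_lower = TRUE)
  ## right-hemisphere optodes; left is the mirror image (x -> -x)
  right_src <- data.frame(
    id = c("S5", "S6", "S7", "S8"),
    x = c(1, 3, 1, 3), y = c(2, 2, 0, 0),
    stringsAsFactors = FALSE
  )
  left_src <- data.frame(
    id = c("S4", "S3", "S2", "S1"),
    x = -right_src$x, y = right_src$y,
    stringsAsFactors = FALSE
  )
  right_det <- data.frame(
    id = c("D5", "D6", "D7"),
    x = c(2, 2, 4), y = c(2, 0, 1),
    stringsAsFactors = FALSE
  )
  left_det <- data.frame(
    id = c("D1", "D2", "D3"),
    x = -right_det$x, y = right_det$y,
    stringsAsFactors = FALSE
  )
  mid_det <- data.frame(id = "D4", x = 0, y = 1, stringsAsFactors = FALSE)

  sources <- rbind(left_src, right_src)
  sources <- sources[order(sources$id), ]
  detectors <- rbind(left_det, mid_det, right_det)
  detectors <- detectors[order(detectors$id), ]

  right_pairs <- data.frame(
    source_id   = c("S5", "S6", "S7", "S8", "S6", "S8", "S5", "S7", "S5",
                    "S7", "S6"),
    detector_id = c("D5", "D5", "D6", "D6", "D7", "D7", "D6", "D5", "D4",
                    "D4", "D6"),
    stringsAsFactors = FALSE
  )
  ## mirror the pairing through S5<->S4, S6<->S3, S7<->S2, S8<->S1,
  ## D5<->D1, D6<->D2, D7<->D3, D4<->D4
  smap <- c(S5 = "S4", S6 = "S3", S7 = "S2", S8 = "S1")
  dmap <- c(D5 = "D1", D6 = "D2", D7 = "D3", D4 = "D4")
  left_pairs <- data.frame(
    source_id = unname(smap[right_pairs$source_id]),
    detector_id = unname(dmap[right_pairs$detector_id]),
    stringsAsFactors = FALSE
  )
  pairs <- rbind(left_pairs, right_pairs)

  sx <- structure(sources$x, names = sources$id)
  sy <- structure(sources$y, names = sources$id)
  dx <- structure(detectors$x, names = detectors$id)
  dy <- structure(detectors$y, names = detectors$id)
  midx <- (sx[pairs$source_id] + dx[pairs$detector_id]) / 2
  midy <- (sy[pairs$source_id] + dy[pairs$detector_id]) / 2
  hemi <- ifelse(midx < 0, "left", ifelse(midx > 0, "right", "midline"))

  channels <- data.frame(
    channel_id = paste0(pairs$source_id, "_", pairs$detector_id),
    source_id = pairs$source_id,
    detector_id = pairs$detector_id,
    hemisphere = hemi,
    distance_cm = distance_cm,
    x = unname(midx),
    y = unname(midy),
    stringsAsFactors = FALSE
  )
  channels <- channels[order(channels$channel_id), ]
  rownames(channels) <- NULL
  rownames(sources) <- rownames(detectors) <- NULL

  new("MontageLayout", sources = sources, detectors = detectors,
      channels = channels, wavelengths = as.numeric(wavelengths))
}
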