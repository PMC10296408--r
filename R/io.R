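## Plain-text interchange formats. A recording is stored as a family of
## CSV files sharing a stem: <stem>.csv holds the long-format series
## (time_s, channel_id, wavelength_nm_or_chromophore, value); companions
## hold metadata, montage geometry and the event schedule so the full
## in-memory object round-trips.

#' @importFrom data.table fread fwrite as.data.table :=
NULL

.stem <- function(path) sub("\\.csv$", "", path)

.companionPaths <- function(path) {
  s <- .stem(path)
  list(series = paste0(s, ".csv"),
       meta = paste0(s, "_meta.csv"),
       channels = paste0(s, "_montage_channels.csv"),
       optodes = paste0(s, "_montage_optodes.csv"),
       schedule = paste0(s, "_schedule.csv"))
}

#' Write a recording to the CSV dialect
#'
#' Writes the long-format series plus companion files (`_meta`,
#' `_montage_channels`, `_montage_optodes`, `_schedule`) alongside the
#' given path, so [readRecording()] can reconstruct an equal object.
#'
#' @param x An [HbRecording-class] or [ODRecording-class].
#' @param path Output path of the series CSV (`.csv`).
#' @return Invisibly, the list of files written.
#' @export
writeRecording <- function(x, path) {
  stopifnot(is(x, "HbRecording") || is(x, "ODRecording"))
  p <- .companionPaths(path)
  time_s <- colData(x)$time_s
  ids <- channelIds(x)

  parts <- lapply(assayNames(x), function(a) {
    m <- assay(x, a)
    lab <- sub("^od_", "", a)
    data.table::data.table(
      time_s = rep(time_s, each = length(ids)),
      channel_id = rep(ids, times = length(time_s)),
      wavelength_nm_or_chromophore = lab,
      value = as.vector(m)
    )
  })
  fwrite(data.table::rbindlist(parts), p$series)

  mont <- montage(x)
  meta <- data.frame(
    key = c("type", "sampling_rate", "wavelengths"),
    value = c(if (is(x, "HbRecording")) "hb" else "od",
              as.character(samplingRate(x)),
              paste(mont@wavelengths, collapse = ";")),
    stringsAsFactors = FALSE
  )
  fwrite(meta, p$meta)

  ch <- mont@channels
  ch$usable <- rowData(x)[ch$channel_id, "usable"]
  fwrite(ch, p$channels)
  opt <- rbind(
    cbind(kind = "source", mont@sources),
    cbind(kind = "detector", mont@detectors)
  )
  fwrite(opt, p$optodes)

  sched <- eventSchedule(x)
  if (!is.null(sched)) {
    tr <- trials(sched)
    fwrite(data.frame(onset_s = tr$onset_s, duration_s = tr$on_s,
                      off_s = tr$off_s, condition = tr$condition),
           p$schedule)
  }
  invisible(p)
}

.readMontageFiles <- function(p, wavelengths) {
  ch <- as.data.frame(fread(p$channels))
  opt <- as.data.frame(fread(p$optodes))
  usable <- if ("usable" %in% names(ch)) ch$usable else rep(TRUE, nrow(ch))
  ch$usable <- NULL
  for (col in c("distance_cm", "x", "y")) {
    ch[[col]] <- as.numeric(ch[[col]])
  }
  opt$x <- as.numeric(opt$x)
  opt$y <- as.numeric(opt$y)
  mont <- new("MontageLayout",
              sources = opt[opt$kind == "source",
                            c("id", "x", "y"), drop = FALSE],
              detectors = opt[opt$kind == "detector",
                              c("id", "x", "y"), drop = FALSE],
              channels = ch, wavelengths = wavelengths)
  rownames(mont@sources) <- rownames(mont@detectors) <- NULL
  list(montage = mont, usable = usable)
}

#' Read a recording from the CSV dialect
#'
#' Reconstructs an [HbRecording-class] or [ODRecording-class] written by
#' [writeRecording()]. Non-numeric sample values raise an error naming
#' the offending row and column; a missing schedule companion raises an
#' error because downstream epoching requires one.
#'
#' @param path Path to the series CSV.
#' @param require_schedule Error when the schedule companion is absent.
#' @return The reconstructed recording.
#' @export
readRecording <- function(path, require_schedule = TRUE) {
  p <- .companionPaths(path)
  for (f in c(p$series, p$meta, p$channels, p$optodes)) {
    if (!file.exists(f)) stop("missing recording file: ", f)
  }
  series <- fread(p$series)
  need <- c("time_s", "channel_id", "wavelength_nm_or_chromophore", "value")
  if (!all(need %in% names(series))) {
    stop("series CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!is.numeric(series$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(series$value))))[1L]
    stop(sprintf("non-numeric value in column 'value', row %d: '%s'",
                 bad, series$value[bad]))
  }
  if (anyNA(series$value)) {
    stop("series contains missing (NaN/NA) samples in column 'value', row ",
         which(is.na(series$value))[1L])
  }

  meta <- fread(p$meta)
  mget <- function(k) meta$value[match(k, meta$key)]
  type <- mget("type")
  fs <- as.numeric(mget("sampling_rate"))
  wl <- as.numeric(strsplit(mget("wavelengths"), ";")[[1L]])

  mi <- .readMontageFiles(p, wl)
  ids <- channelIds(mi$montage)

  sched <- NULL
  if (file.exists(p$schedule)) {
    sched <- readSchedule(p$schedule)
  } else if (require_schedule) {
    stop("recording has no event schedule (", p$schedule,
         "); a schedule is required")
  }

  time_s <- sort(unique(series$time_s))
  n <- length(time_s)
  labs <- unique(series$wavelength_nm_or_chromophore)
  assays <- lapply(labs, function(lab) {
    d <- series[series$wavelength_nm_or_chromophore == lab]
    d <- d[order(d$time_s, match(d$channel_id, ids))]
    if (nrow(d) != n * length(ids)) {
      stop("series is not complete for '", lab, "'")
    }
    m <- matrix(d$value, nrow = length(ids), ncol = n)
    rownames(m) <- ids
    m
  })
  names(assays) <- ifelse(labs %in% CHROMOPHORES, labs, paste0("od_", labs))

  cls <- if (identical(type, "hb")) "HbRecording" else "ODRecording"
  out <- .newRecording(cls, assays, fs, mi$montage, sched,
                       rowdata = .channelRowData(mi$montage))
  rowData(out)$usable <- mi$usable
  out
}

#' Read / write an event schedule CSV
#'
#' Columns: `onset_s`, `duration_s` (stimulus-on), `off_s`, `condition`.
#'
#' @param path CSV path.
#' @return [EventSchedule-class] (for the reader).
#' @export
readSchedule <- function(path) {
  d <- as.data.frame(fread(path))
  need <- c("onset_s", "duration_s", "off_s", "condition")
  if (!all(need %in% names(d))) {
    stop("schedule CSV must have columns: ", paste(need, collapse = ", "))
  }
  trials <- data.frame(onset_s = as.numeric(d$onset_s),
                       on_s = as.numeric(d$duration_s),
                       off_s = as.numeric(d$off_s),
                       condition = as.character(d$condition),
                       stringsAsFactors = FALSE)
  new("EventSchedule", trials = trials,
      total_duration = sum(trials$on_s + trials$off_s), seed = NA_integer_)
}

#' @rdname readSchedule
#' @param schedule An [EventSchedule-class].
#' @export
writeSchedule <- function(schedule, path) {
  tr <- trials(schedule)
  fwrite(data.frame(onset_s = tr$onset_s, duration_s = tr$on_s,
                    off_s = tr$off_s, condition = tr$condition), path)
  invisible(path)
}

.CLINICAL_COLS <- c("subject_id", "Age", "ADOS_TOT", "ADOS_comp", "AQ_tot",
                    "nv_IQ", "VABS_tot")

#' Read a clinical score table
#'
#' Reads the clinical CSV layout (`subject_id`/`ID`, `Age`, `ADOS_TOT`,
#' `ADOS_comp`, `AQ_tot`, `nv_IQ`, `VABS_tot`; header matching is
#' case-insensitive). Cells equal to "n.a." (any case) or empty parse as
#' missing; any other non-numeric cell in a score column is an error
#' naming the row and column. Unknown columns are dropped with a warning.
#'
#' @param path CSV path.
#' @return data.frame with canonical column names and NA for missing.
#' @export
readClinical <- function(path) {
  d <- as.data.frame(fread(path, colClasses = "character"))
  canon <- c(.CLINICAL_COLS, "ID")
  idx <- match(tolower(names(d)), tolower(canon))
  unknown <- names(d)[is.na(idx)]
  if (length(unknown)) {
    warning("ignoring unknown clinical column(s): ",
            paste(unknown, collapse = ", "))
  }
  d <- d[, !is.na(idx), drop = FALSE]
  names(d) <- canon[idx[!is.na(idx)]]
  if ("ID" %in% names(d) && !"subject_id" %in% names(d)) {
    names(d)[names(d) == "ID"] <- "subject_id"
  }
  for (col in setdiff(intersect(.CLINICAL_COLS, names(d)), "subject_id")) {
    raw <- trimws(d[[col]])
    isna <- tolower(raw) %in% c("n.a.", "na", "") | is.na(raw)
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!isna & is.na(num))
    if (length(bad)) {
      stop(sprintf("malformed numeric in column '%s', row %d: '%s'",
                   col, bad[1L], raw[bad[1L]]))
    }
    num[isna] <- NA_real_
    d[[col]] <- num
  }
  d
}

#' Write a clinical score table
#'
#' Missing values are written as "n.a.".
#'
#' @param clinical data.frame as returned by [readClinical()] or
#'   [simulateCohort()].
#' @param path Output CSV path.
#' @export
writeClinical <- function(clinical, path) {
  out <- clinical
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- as.character(out[[col]])
      v[is.na(v)] <- "n.a."
      out[[col]] <- v
    }
  }
  fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' The full study conditions as a nested list: the default montage, a
#' 20 + 20 trial schedule (5 s on / 10 s off) at 10.2 Hz, the two group
#' simulation configurations (13 TD, 12 ASD), preprocessing parameters
#' (0.01-0.5 Hz band, DPF 6 at both wavelengths, motion thresholds),
#' epoching windows (-2..15 s, baseline -2..0 s, peak search 0..15 s),
#' and statistics options. Serialise with [writeRunConfig()] /
#' [readRunConfig()] (YAML, lossless round trip).
#'
#' @param seed Master seed.
#' @param n_td,n_asd Group sizes.
#' @return A named list (class `run_config`).
#' @export
defaultRunConfig <- function(seed = 1, n_td = 13, n_asd = 12) {
  structure(list(
    montage = "default",
    sampling_rate = 10.2,
    schedule = list(n_stim = 20L, n_mock = 20L, on_s = 5, off_s = 10),
    groups = list(
      TD = list(n = as.integer(n_td), amplitude_ohb = 2e-5,
                lateralization = 1.5, lateralization_sd = 0.15),
      ASD = list(n = as.integer(n_asd), amplitude_ohb = 1.2e-5,
                 lateralization = 1.0, lateralization_sd = 0.3)
    ),
    artifacts = list(rate = 1.2, spike_mag = 1.0, shift_mag = 0.5),
    preprocess = list(band = c(0.01, 0.5), dpf = c(6, 6), window_s = 0.5,
                      amp_thresh = 0.25, std_thresh = 6),
    epoch = list(pre_s = 2, post_s = 15, baseline = c(-2, 0),
                 search = c(0, 15)),
    stats = list(welch = TRUE, alpha = 0.05),
    write_recordings = TRUE,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Checks the fields of a [defaultRunConfig()]-shaped list against the
#' preconditions of the operations that consume them.
#'
#' @param config The configuration list.
#' @return The config, invisibly; errors describe the offending field.
#' @export
validateRunConfig <- function(config) {
  assertScalarNumeric(config$sampling_rate, "sampling_rate", lower = 0,
                      strict_lower = TRUE)
  assertCount(config$schedule$n_stim, "schedule$n_stim")
  assertCount(config$schedule$n_mock, "schedule$n_mock")
  assertScalarNumeric(config$schedule$on_s, "schedule$on_s", lower = 0,
                      strict_lower = TRUE)
  assertScalarNumeric(config$schedule$off_s, "schedule$off_s", lower = 0,
                      strict_lower = TRUE)
  for (g in names(config$groups)) {
    if (config$groups[[g]]$n < 1L) stop("group sizes must be >= 1")
  }
  band <- config$preprocess$band
  if (band[1L] < 0 || band[1L] >= band[2L] ||
      band[2L] >= config$sampling_rate / 2) {
    stop("preprocess$band must satisfy 0 <= low < high < sampling_rate/2")
  }
  assertScalarNumeric(config$artifacts$rate, "artifacts$rate", lower = 0)
  assertScalarNumeric(config$stats$alpha, "stats$alpha", lower = 0,
                      upper = 1)
  assertCount(abs(config$seed), "seed")
  invisible(config)
}

#' @rdname defaultRunConfig
#' @param config Configuration list.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname defaultRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(structure(cfg, class = "run_config"))
}
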