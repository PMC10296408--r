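## Forward simulator: stimulus-locked hemodynamics + physiological noise.

#' Physiological noise for one chromophore
#'
#' Sum of seeded-phase sinusoids (cardiac, respiration, Mayer waves),
#' first-order random-walk drift and white Gaussian noise, independently
#' per channel. Frequencies: cardiac 1.1 Hz, respiration 0.3 Hz, Mayer
#' 0.1 Hz.
#'
#' @param n_channels,time_s Grid dimensions.
#' @param noise Named amplitudes, see [simulationConfig()].
#' @param scale Overall multiplier (used for the DHb series).
#' @return channels x samples matrix. Draws from the current RNG stream.
#' @keywords internal
.physioNoise <- function(n_channels, time_s, noise, scale = 1) {
  n <- length(time_s)
  out <- matrix(0, n_channels, n)
  freqs <- c(cardiac = 1.1, respiratory = 0.3, mayer = 0.1)
  for (comp in names(freqs)) {
    if (noise[[comp]] > 0) {
      phase <- runif(n_channels, 0, 2 * pi)
      wt <- 2 * pi * freqs[[comp]] * time_s
      ## sin(phase + wt) expanded so the channel x sample matrix is two
      ## rank-one products instead of an elementwise sin over the grid
      out <- out + noise[[comp]] *
        (tcrossprod(sin(phase), cos(wt)) + tcrossprod(cos(phase), sin(wt)))
    }
  }
  if (noise[["drift"]] > 0) {
    ## random walk generated at coarse knots and linearly interpolated;
    ## spectrally equivalent in the sub-0.1 Hz band the drift occupies
    K <- 10L
    nk <- ceiling(n / K) + 1L
    steps <- matrix(rnorm(n_channels * nk, sd = noise[["drift"]] * sqrt(K)),
                    n_channels, nk)
    for (ch in seq_len(n_channels)) {
      walk <- cumsum(steps[ch, ])
      out[ch, ] <- out[ch, ] +
        stats::approx(x = seq(0L, by = K, length.out = nk), y = walk,
                      xout = seq_len(n) - 1L)$y
    }
  }
  if (noise[["white"]] > 0) {
    out <- out + matrix(rnorm(n_channels * n, sd = noise[["white"]]),
                        n_channels, n)
  }
  out * scale
}

#' Simulate a single-subject recording
#'
#' Generates one subject's chromophore time series on the montage's
#' channels: subject-level evoked amplitudes (OHb drawn around the
#' configured mean, DHb scaled in proportion), a unit-peak trial response
#' (canonical kernel convolved with the stimulus boxcar) added at every
#' STIM onset, a multiplicative right-hemisphere gain, and additive
#' physiological noise. MOCK trials evoke exactly zero response. The
#' schedule is embedded `pre_roll_s` seconds into the recording so every
#' trial has a full pre-stimulus baseline; the recording's stored
#' schedule carries the shifted onsets.
#'
#' @param montage A [MontageLayout-class].
#' @param schedule An [EventSchedule-class] (onsets from 0).
#' @param config A [SimulationConfig-class].
#' @param seed Integer seed; identical seeds give identical recordings.
#' @param pre_roll_s Pre-stimulation padding (s).
#' @param post_roll_s Padding after the last trial (s).
#' @return A list with elements `recording` ([HbRecording-class]) and
#'   `truth` ([GroundTruth-class]).
#' @examples
#' m <- makeDefaultMontage()
#' s <- generateEventSchedule(2, 2, 5, 10, seed = 1)
#' sub <- simulateSubject(m, s, simulationConfig(), seed = 7)
#' dim(assay(sub$recording, "OHb"))
#' @export
simulateSubject <- function(montage, schedule, config = simulationConfig(),
                            seed = 1, pre_roll_s = 10, post_roll_s = 1) {
  stopifnot(is(montage, "MontageLayout"), is(schedule, "EventSchedule"),
            is(config, "SimulationConfig"))
  validObject(config)
  fs <- config@sampling_rate
  duration <- pre_roll_s + totalDuration(schedule) + post_roll_s
  n <- round(duration * fs)
  if (n < 2L) stop("schedule does not fit within the recording length")
  time_s <- (seq_len(n) - 1L) / fs
  ids <- channelIds(montage)
  nch <- length(ids)
  hemi <- hemispheres(montage)

  res <- withSeed(seed, {
    ## subject-level generative parameters
    a_ohb <- config@amplitude_ohb
    if (config@amplitude_sd > 0) {
      repeat {
        a_ohb <- rnorm(1L, config@amplitude_ohb, config@amplitude_sd)
        if (a_ohb > 0.05 * config@amplitude_ohb) break
      }
    }
    ratio <- config@amplitude_dhb / config@amplitude_ohb
    a_dhb <- ratio * a_ohb
    lam <- config@lateralization
    if (config@lateralization_sd > 0) {
      sdl <- config@lateralization_sd
      lam <- lam * rlnorm(1L, meanlog = -sdl^2 / 2, sdlog = sdl)
    }
    gain <- ifelse(hemi == "right", lam,
                   ifelse(hemi == "left", 1, (1 + lam) / 2))

    ## stimulus regressor: unit-peak trial shape at every STIM onset
    stim <- numeric(n)
    tr <- trials(schedule)
    stim_trials <- tr[tr$condition == "STIM", , drop = FALSE]
    if (nrow(stim_trials)) {
      shape <- trialResponseShape(stim_trials$on_s[1L], fs)
      lag <- round(config@dhb_lag_s * fs)
      for (o in stim_trials$onset_s) {
        i0 <- round((pre_roll_s + o) * fs) + 1L
        idx <- i0:min(n, i0 + length(shape) - 1L)
        stim[idx] <- stim[idx] + shape[seq_along(idx)]
      }
      stim_dhb <- c(numeric(lag), stim)[seq_len(n)]
    } else {
      stim_dhb <- stim
    }

    ohb <- outer(unname(a_ohb * gain), stim)
    dhb <- outer(unname(a_dhb * gain), stim_dhb)
    ohb <- ohb + .physioNoise(nch, time_s, config@noise)
    dhb <- dhb + .physioNoise(nch, time_s, config@noise,
                              scale = config@dhb_noise_scale)
    list(ohb = ohb, dhb = dhb, a_ohb = a_ohb, a_dhb = a_dhb,
         gain = gain, lam = lam)
  })

  shifted <- shiftSchedule(schedule, pre_roll_s)
  rec <- HbRecording(res$ohb, res$dhb, fs, montage, shifted)

  amps <- rbind(OHb = res$a_ohb * res$gain,
                DHb = res$a_dhb * res$gain,
                THb = (res$a_ohb + res$a_dhb) * res$gain)
  colnames(amps) <- ids
  pl <- mean(amps["OHb", hemi == "left"])
  pr <- mean(amps["OHb", hemi == "right"])
  truth <- new("GroundTruth", amplitudes = amps, peak_left = pl,
               peak_right = pr, li = (pl - pr) / (pl + pr),
               seed = as.integer(seed))
  list(recording = rec, truth = truth)
}

#' Simulate a two-group cohort with a clinical table
#'
#' Simulates `n_td` typically developing and `n_asd` ASD subjects, each
#' with their own pseudorandomly interleaved schedule, and generates the
#' clinical score table for the ASD group only (matching the reference
#' layout: ID, Age, ADOS_TOT, ADOS_comp, AQ_tot, nv_IQ, VABS_tot). The
#' AQ total is a monotone function of the subject's true laterality index
#' plus noise, see [clinicalModel()].
#'
#' @param n_td,n_asd Subjects per group (>= 1).
#' @param config_td,config_asd Per-group [SimulationConfig-class].
#' @param clinical_model A [clinicalModel()] list.
#' @param seed Master seed; subject seeds are derived from it.
#' @param n_stim,n_mock,on_s,off_s Schedule parameters.
#' @return A list with `subjects` (list of `list(id, group, recording,
#'   truth)`) and `clinical` (data.frame, ASD rows only).
#' @export
simulateCohort <- function(n_td = 13, n_asd = 12,
                           config_td = tdSimulationConfig(),
                           config_asd = asdSimulationConfig(),
                           clinical_model = clinicalModel(),
                           seed = 1,
                           n_stim = 20, n_mock = 20, on_s = 5, off_s = 10) {
  n_td <- assertCount(n_td, "n_td")
  n_asd <- assertCount(n_asd, "n_asd")
  if (n_td < 1L || n_asd < 1L) stop("group sizes must be >= 1")
  montage <- makeDefaultMontage()
  ntot <- n_td + n_asd
  seeds <- deriveSeeds(seed, 2L * ntot + 1L)
  groups <- c(rep("TD", n_td), rep("ASD", n_asd))
  ids <- c(sprintf("TD%02d", seq_len(n_td)),
           sprintf("ASD%02d", seq_len(n_asd)))

  subjects <- vector("list", ntot)
  for (i in seq_len(ntot)) {
    cfg <- if (groups[i] == "TD") config_td else config_asd
    sched <- generateEventSchedule(n_stim, n_mock, on_s, off_s,
                                   seed = seeds[2L * i - 1L])
    sim <- simulateSubject(montage, sched, cfg, seed = seeds[2L * i])
    subjects[[i]] <- list(id = ids[i], group = groups[i],
                          recording = sim$recording, truth = sim$truth)
  }

  cm <- clinical_model
  asd <- subjects[groups == "ASD"]
  clinical <- withSeed(seeds[2L * ntot + 1L], {
    li <- vapply(asd, function(s) trueLI(s$truth), numeric(1))
    nA <- length(asd)
    data.frame(
      subject_id = vapply(asd, `[[`, character(1), "id"),
      Age = sample(cm$ages, nA, replace = TRUE),
      ADOS_TOT = round(rnorm(nA, cm$ados_tot_mean, cm$ados_tot_sd)),
      ADOS_comp = round(rnorm(nA, cm$ados_comp_mean, cm$ados_comp_sd)),
      AQ_tot = cm$aq_intercept + cm$aq_slope * li +
        rnorm(nA, 0, cm$aq_sd),
      nv_IQ = round(rnorm(nA, cm$nv_iq_mean, cm$nv_iq_sd)),
      VABS_tot = round(rnorm(nA, cm$vabs_mean, cm$vabs_sd)),
      stringsAsFactors = FALSE
    )
  })
  list(subjects = subjects, clinical = clinical)
}
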