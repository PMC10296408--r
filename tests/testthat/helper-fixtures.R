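## shared builders for small in-code fixtures

suppressMessages(library(SummarizedExperiment))

## a noise-free configuration with no subject-level variability
noiselessConfig <- function(...) {
  simulationConfig(
    amplitude_sd = 0, lateralization_sd = 0,
    noise = c(cardiac = 0, respiratory = 0, mayer = 0, drift = 0,
              white = 0),
    ...
  )
}

## minimal montage: two left / two right channels, unit distance available
tinyMontage <- function(distance_cm = 3) {
  sources <- data.frame(id = c("S1", "S2"), x = c(-1, 1), y = c(0, 0))
  detectors <- data.frame(id = c("D1", "D2"), x = c(-2, 2), y = c(1, 1))
  channels <- data.frame(
    channel_id = c("S1_D1", "S1_D1b", "S2_D2", "S2_D2b"),
    source_id = c("S1", "S1", "S2", "S2"),
    detector_id = c("D1", "D1", "D2", "D2"),
    hemisphere = c("left", "left", "right", "right"),
    distance_cm = distance_cm,
    x = c(-1.5, -1.5, 1.5, 1.5), y = 0.5,
    stringsAsFactors = FALSE
  )
  new("MontageLayout", sources = sources, detectors = detectors,
      channels = channels, wavelengths = c(760, 850))
}

## HbRecording whose OHb rows are `gains` x a repeated unit-peak trial
## response on the given schedule; DHb = dhb_ratio x OHb
hbFromGains <- function(gains, montage, schedule, fs = 10.2,
                        dhb_ratio = -1 / 3, pre_roll_s = 10) {
  cfg <- noiselessConfig(sampling_rate = fs)
  sim <- simulateSubject(montage, schedule, cfg, seed = 1,
                         pre_roll_s = pre_roll_s)
  ohb <- assay(sim$recording, "OHb")
  base <- ohb[1L, ] / max(ohb[1L, ])    # unit-peak reference trace
  ohb2 <- outer(gains, base)
  HbRecording(ohb2, dhb_ratio * ohb2, fs, montage,
              eventSchedule(sim$recording))
}

## default-study single subject, simulated and epoch-ed
simulatedEpochs <- function(seed = 1, config = simulationConfig(),
                            n_stim = 20, n_mock = 20) {
  m <- makeDefaultMontage()
  s <- generateEventSchedule(n_stim, n_mock, 5, 10, seed = seed)
  sim <- simulateSubject(m, s, config, seed = seed + 1000L)
  list(montage = m, sim = sim, epochs = epochTrials(sim$recording))
}
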