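test_that("laterality index evaluates its formula exactly", {
  expect_equal(lateralityIndex(2e-5, 6e-5), -0.5)
  expect_identical(lateralityIndex(3e-5, 3e-5), 0)
  expect_identical(lateralityIndex(4e-5, 0), 1)
  expect_error(lateralityIndex(1e-5, -1e-5), "zero")
})

test_that("laterality index is antisymmetric and scale-invariant", {
  set.seed(11)
  for (r in 1:50) {
    a <- runif(1, 1e-6, 1e-4)
    b <- runif(1, 1e-6, 1e-4)
    c <- runif(1, 0.1, 10)
    expect_equal(lateralityIndex(a, b), -lateralityIndex(b, a))
    expect_equal(lateralityIndex(c * a, c * b), lateralityIndex(a, b),
                 tolerance = 1e-12)
    expect_gte(lateralityIndex(a, b), -1)
    expect_lte(lateralityIndex(a, b), 1)
  }
})

test_that("peak extraction respects chromophore sign and tie-breaks early", {
  t <- seq(-2, 15, by = 0.5)
  tr <- numeric(length(t))
  tr[t == 5] <- 1
  tr[t == 8] <- 1
  pk <- extractPeak(tr, t, "OHb")
  expect_identical(unname(pk["latency_s"]), 5)
  expect_identical(unname(pk["amplitude"]), 1)

  shape <- exp(-(t - 6)^2)
  up <- extractPeak(shape, t, "OHb")
  dn <- extractPeak(-shape, t, "DHb")
  expect_equal(dn[["amplitude"]], -up[["amplitude"]])
  expect_equal(dn[["latency_s"]], up[["latency_s"]])

  expect_error(extractPeak(shape, t, "OHb", search_window = c(20, 25)),
               "no samples")
})

test_that("channel-average equals the single-channel result when identical", {
  m <- tinyMontage()
  s <- generateEventSchedule(4, 4, 5, 10, seed = 2)
  hb <- hbFromGains(rep(2e-5, 4), m, s)
  ep <- epochTrials(hb)
  avg <- channelAverageResponse(ep, "STIM")
  one <- blockAverage(ep, "STIM", "OHb")$mean[1, ]
  pk1 <- extractPeak(one, ep@time_s, "OHb")
  expect_equal(avg$amplitude[avg$chromophore == "OHb"],
               pk1[["amplitude"]])
})

test_that("channel-average of peaks A and 3A (same shape) is 2A", {
  m <- tinyMontage()
  s <- generateEventSchedule(4, 4, 5, 10, seed = 2)
  A <- 1e-5
  hb <- hbFromGains(c(A, 3 * A, A, 3 * A), m, s)
  ep <- epochTrials(hb)
  avg <- channelAverageResponse(ep, "STIM")
  expect_equal(avg$amplitude[avg$chromophore == "OHb"], 2 * A,
               tolerance = 1e-9)
})

test_that("best channel has the unique maximum or the lowest id on ties", {
  m <- tinyMontage()
  s <- generateEventSchedule(4, 4, 5, 10, seed = 2)
  A <- 1e-5
  hb <- hbFromGains(c(A, 2 * A, A, A), m, s)
  best <- bestChannelResponse(epochTrials(hb), "STIM")
  expect_identical(best$channel_id, "S1_D1b")

  tie <- hbFromGains(rep(A, 4), m, s)
  best2 <- bestChannelResponse(epochTrials(tie), "STIM")
  expect_identical(best2$channel_id, "S1_D1")  # alphabetically lowest
})

test_that("best-channel amplitude is never below the channel average", {
  for (seed in 1:12) {
    fix <- simulatedEpochs(seed = seed, config = tdSimulationConfig(),
                           n_stim = 6, n_mock = 6)
    avg <- channelAverageResponse(fix$epochs, "STIM")
    best <- bestChannelResponse(fix$epochs, "STIM")
    expect_gte(best$table$amplitude[best$table$chromophore == "OHb"],
               avg$amplitude[avg$chromophore == "OHb"])
  }
})

test_that("hemisphere peaks average the per-channel maxima", {
  m <- tinyMontage()
  s <- generateEventSchedule(4, 4, 5, 10, seed = 2)
  hb <- hbFromGains(c(1e-5, 3e-5, 2e-5, 2e-5), m, s)
  hp <- hemispherePeaks(epochTrials(hb), "STIM")
  expect_equal(unname(hp["peak_left"]), 2e-5, tolerance = 1e-9)
  expect_equal(unname(hp["peak_right"]), 2e-5, tolerance = 1e-9)

  ## identical left/right signals give equal peaks and LI = 0
  same <- hbFromGains(rep(2e-5, 4), m, s)
  hp2 <- hemispherePeaks(epochTrials(same), "STIM")
  expect_equal(unname(hp2["peak_left"]), unname(hp2["peak_right"]))
})

test_that("noiseless lambda = 3 gives peak_right = 3 x peak_left and LI -0.5", {
  fix <- simulatedEpochs(seed = 3, n_stim = 4, n_mock = 4,
                         config = noiselessConfig(lateralization = 3))
  sr <- subjectResponse(fix$epochs, "STIM")
  expect_equal(sr@peak_right / sr@peak_left, 3, tolerance = 1e-6)
  expect_equal(sr@li, -0.5, tolerance = 1e-6)
  expect_equal(sr@li, trueLI(fix$sim$truth), tolerance = 1e-6)
})

test_that("MOCK responses are statistically indistinguishable from zero", {
  amps <- sems <- numeric(40)
  for (seed in 1:40) {
    fix <- simulatedEpochs(seed = seed, n_stim = 4, n_mock = 4)
    avg <- channelAverageResponse(fix$epochs, "MOCK")
    amps[seed] <- avg$amplitude[avg$chromophore == "OHb"]
  }
  ## the mock "peak" is the max of a zero-mean noise trace: positive by
  ## construction, but tiny next to the stimulus amplitude
  expect_lt(mean(amps), 0.15 * 2e-5)
  stim <- channelAverageResponse(simulatedEpochs(seed = 1, n_stim = 4,
                                                 n_mock = 4)$epochs, "STIM")
  expect_gt(stim$amplitude[stim$chromophore == "OHb"], 4 * mean(amps))
})

test_that("tidy subject metrics carry every readout once per condition", {
  fix <- simulatedEpochs(seed = 2, n_stim = 4, n_mock = 4)
  met <- subjectMetrics(fix$sim$recording, subject_id = "X", group = "TD")
  expect_setequal(unique(met$condition), c("STIM", "MOCK"))
  expect_setequal(unique(met$metric),
                  c("avg_amplitude", "avg_latency", "best_amplitude",
                    "best_latency", "peak_left", "peak_right", "li"))
  ## 4 metrics x 3 chromophores + 3 OHb extras, per condition
  expect_identical(nrow(met), 2L * (4L * 3L + 3L))
  li <- met$value[met$metric == "li" & met$condition == "STIM"]
  pl <- met$value[met$metric == "peak_left" & met$condition == "STIM"]
  pr <- met$value[met$metric == "peak_right" & met$condition == "STIM"]
  expect_equal(li, (pl - pr) / (pl + pr))
})
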