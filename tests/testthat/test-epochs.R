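test_that("a 20+20 schedule epochs into 20 trials per condition", {
  fix <- simulatedEpochs(seed = 1)
  ep <- fix$epochs
  expect_identical(dim(ep@epochs$STIM$OHb)[1], 20L)
  expect_identical(dim(ep@epochs$MOCK$OHb)[1], 20L)
  expect_identical(dim(ep@epochs$STIM$OHb)[3], 22L)
  ## baseline mean is zero for every trial and channel
  bidx <- which(ep@time_s >= -2 & ep@time_s <= 0)
  bl <- apply(ep@epochs$STIM$OHb[, bidx, ], c(1, 3), mean)
  expect_lt(max(abs(bl)), 1e-18)
})

test_that("constant recordings give identically zero epochs", {
  m <- makeDefaultMontage()
  s <- generateEventSchedule(3, 3, 5, 10, seed = 2)
  hb <- HbRecording(matrix(4e-5, 22, round(102 * 10.2)),
                    matrix(-1e-5, 22, round(102 * 10.2)),
                    10.2, m, shiftSchedule(s, 10))
  ep <- epochTrials(hb)
  expect_lt(max(abs(ep@epochs$STIM$OHb)), 1e-18)
  expect_lt(max(abs(ep@epochs$MOCK$THb)), 1e-18)
})

test_that("baseline correction subtracts the baseline-window mean of a ramp", {
  m <- makeDefaultMontage()
  fs <- 10.2
  n <- round(100 * fs)
  ramp <- matrix(seq_len(n) * 1e-8, 22, n, byrow = TRUE)
  s <- generateEventSchedule(2, 1, 5, 10, seed = 3)
  hb <- HbRecording(ramp, 0 * ramp, fs, m, shiftSchedule(s, 10))
  ep <- epochTrials(hb)
  tr1 <- ep@epochs$STIM$OHb[1, , 1]
  onset_idx <- round(trials(eventSchedule(hb))$onset_s[1] * fs) + 1L
  rel <- seq(-round(2 * fs), round(15 * fs))
  raw <- ramp[1, onset_idx + rel]
  bidx <- which(ep@time_s >= -2 & ep@time_s <= 0)
  expect_equal(tr1, raw - mean(raw[bidx]), tolerance = 1e-12)
})

test_that("out-of-bounds trials are dropped with a warning; all dropped errors", {
  m <- makeDefaultMontage()
  s <- generateEventSchedule(3, 3, 5, 10, seed = 4)
  ## no pre-roll: the first trial lacks its baseline window
  sim <- simulateSubject(m, s, simulationConfig(), seed = 4, pre_roll_s = 0)
  expect_warning(ep <- epochTrials(sim$recording), "dropped 1 trial")
  n1 <- dim(ep@epochs$STIM$OHb)[1] + dim(ep@epochs$MOCK$OHb)[1]
  expect_identical(n1, 5L)

  tiny <- HbRecording(matrix(0, 22, 10), matrix(0, 22, 10), 10.2, m,
                      shiftSchedule(s, 0))
  expect_error(suppressWarnings(epochTrials(tiny)), "all trials")
})

test_that("block average reproduces hand-computed mean and sem", {
  fix <- simulatedEpochs(seed = 5, n_stim = 4, n_mock = 4)
  ep <- fix$epochs
  arr <- ep@epochs$STIM$OHb
  ba <- blockAverage(ep, "STIM", "OHb")
  expect_equal(unname(ba$mean[3, 17]), mean(arr[, 17, 3]))
  expect_equal(unname(ba$sem[3, 17]), sd(arr[, 17, 3]) / sqrt(4))
  ## the hand example: values 1,2,3,4 -> mean 2.5, sem ~0.6455
  expect_equal(mean(1:4), 2.5)
  expect_equal(sd(1:4) / sqrt(4), 0.6454972, tolerance = 1e-6)
  arr2 <- arr
  arr2[, 17, 3] <- c(1, 2, 3, 4)
  ep@epochs$STIM$OHb <- arr2
  ba2 <- blockAverage(ep, "STIM", "OHb")
  expect_equal(unname(ba2$mean[3, 17]), 2.5)
  expect_equal(unname(ba2$sem[3, 17]), 0.6454972, tolerance = 1e-6)
})

test_that("trials of +x and -x average to zero", {
  fix <- simulatedEpochs(seed = 6, n_stim = 2, n_mock = 2)
  ep <- fix$epochs
  x <- ep@epochs$STIM$OHb[1, , ]
  ep@epochs$STIM$OHb[2, , ] <- -x
  ba <- blockAverage(ep, "STIM", "OHb")
  expect_lt(max(abs(ba$mean)), 1e-18)
})
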