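test_that("band-pass removes DC, keeps the pass band, kills the stop band", {
  fs <- 10.2
  t <- (0:8000) / fs
  mid <- 2000:6000
  const <- bandpass(rep(3, length(t)), 0.01, 0.5, fs)
  expect_lt(max(abs(const)), 1e-6)

  inband <- bandpass(sin(2 * pi * 0.07 * t), 0.01, 0.5, fs)
  expect_equal(max(abs(inband[mid])), 1, tolerance = 0.05)

  cardiac <- bandpass(sin(2 * pi * 1.1 * t), 0.01, 0.5, fs)
  expect_lt(max(abs(cardiac[mid])), 0.1)   # >= 90% attenuated
})

test_that("band-pass is linear and works row-wise on matrices", {
  fs <- 10.2
  set.seed(5)
  x <- rnorm(2000)
  y <- rnorm(2000)
  lin <- bandpass(3 * x - 2 * y, 0.01, 0.5, fs)
  ref <- 3 * bandpass(x, 0.01, 0.5, fs) - 2 * bandpass(y, 0.01, 0.5, fs)
  expect_equal(lin, ref, tolerance = 1e-10)

  m <- rbind(a = x, b = y)
  fm <- bandpass(m, 0.01, 0.5, fs)
  expect_equal(fm["a", ], bandpass(x, 0.01, 0.5, fs))
  expect_identical(rownames(fm), c("a", "b"))
})

test_that("invalid bands are rejected", {
  expect_error(bandpass(rnorm(100), 0.5, 0.01, 10.2), "invalid band")
  expect_error(bandpass(rnorm(100), 0.01, 6, 10.2), "invalid band")
  expect_error(bandpass(rnorm(100), -0.1, 0.5, 10.2), "low_hz")
})

test_that("constant series yield an empty artifact mask", {
  m <- makeDefaultMontage()
  hb <- HbRecording(matrix(1e-5, 22, 500), matrix(-3e-6, 22, 500), 10.2, m)
  od <- mbllForward(hb)
  mask <- detectMotion(od)
  expect_identical(nrow(artifactEvents(mask)), 0L)
})

test_that("in-band oscillation far below threshold is not flagged", {
  m <- makeDefaultMontage()
  fs <- 10.2
  t <- (0:2999) / fs
  amp_od <- 0.25 / 10   # peak-to-peak well under amp_thresh
  ## build concentrations that produce a pure sinusoidal OD trace
  einv <- solve(defaultExtinction())
  odt <- amp_od / 2 * sin(2 * pi * 0.07 * t)
  conc <- einv %*% rbind(odt / (6 * 3), odt / (6 * 3))
  hb <- HbRecording(matrix(conc[1, ], 22, 3000, byrow = TRUE),
                    matrix(conc[2, ], 22, 3000, byrow = TRUE), fs, m)
  mask <- detectMotion(mbllForward(hb))
  expect_identical(nrow(artifactEvents(mask)), 0L)
})

test_that("injected artifacts are detected with high sensitivity", {
  hits <- 0L
  total <- 0L
  for (sd in 1:10) {
    m <- makeDefaultMontage()
    s <- generateEventSchedule(6, 6, 5, 10, seed = sd)
    sim <- simulateSubject(m, s, simulationConfig(), seed = sd + 30L)
    od <- mbllForward(sim$recording)
    art <- injectMotionArtifacts(od, rate = 1.2, seed = sd + 60L)
    ev <- artifactEvents(detectMotion(art$recording))
    for (e in seq_len(nrow(art$events))) {
      total <- total + 1L
      sm <- art$events$sample[e]
      w <- art$events$n_samples[e]
      hits <- hits + any(ev$start <= sm + w & ev$end >= sm)
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("correction is a no-op for an empty mask and is idempotent", {
  m <- makeDefaultMontage()
  s <- generateEventSchedule(4, 4, 5, 10, seed = 2)
  sim <- simulateSubject(m, s, simulationConfig(), seed = 8)
  od <- mbllForward(sim$recording)
  empty <- detectMotion(od)   # clean recording: nothing flagged
  expect_identical(assay(correctMotion(od, empty), "od_760"),
                   assay(od, "od_760"))

  art <- injectMotionArtifacts(od, rate = 2, seed = 3)
  mask <- detectMotion(art$recording)
  once <- correctMotion(art$recording, mask)
  twice <- correctMotion(once, mask)
  expect_equal(assay(twice, "od_850"), assay(once, "od_850"),
               tolerance = 1e-10)
  expect_equal(assay(twice, "od_760"), assay(once, "od_760"),
               tolerance = 1e-10)
})

test_that("a single exactly-known step shift is corrected to within 5% RMS", {
  m <- makeDefaultMontage()
  s <- generateEventSchedule(6, 6, 5, 10, seed = 4)
  sim <- simulateSubject(m, s, noiselessConfig(), seed = 4)
  od <- mbllForward(sim$recording)
  n <- ncol(od)
  step_at <- 700L
  alist <- assays(od)
  shifted <- od
  for (a in seq_along(alist)) {
    alist[[a]][, step_at:n] <- alist[[a]][, step_at:n] + 0.4
  }
  SummarizedExperiment::assays(shifted) <- alist
  mask <- new("ArtifactMask",
              events = data.frame(channel_id = channelIds(od),
                                  start = step_at - 2L, end = step_at + 2L,
                                  kind = "shift", stringsAsFactors = FALSE),
              n_samples = as.integer(n))
  fixed <- correctMotion(shifted, mask)
  for (a in c("od_760", "od_850")) {
    err <- assay(fixed, a) - assay(od, a)
    rel <- sqrt(mean(err^2)) / sqrt(mean(assay(od, a)^2))
    expect_lt(rel, 0.05)
  }
})

test_that("a mask covering a whole channel is an error", {
  m <- makeDefaultMontage()
  hb <- HbRecording(matrix(rnorm(22 * 100, sd = 1e-5), 22, 100),
                    matrix(0, 22, 100), 10.2, m)
  od <- mbllForward(hb)
  mask <- new("ArtifactMask",
              events = data.frame(channel_id = channelIds(od)[1],
                                  start = 1L, end = 100L, kind = "spike",
                                  stringsAsFactors = FALSE),
              n_samples = 100L)
  expect_error(correctMotion(od, mask), "entire channel")
})

test_that("preprocessing a clean noiseless recording preserves the peak", {
  m <- makeDefaultMontage()
  s <- generateEventSchedule(20, 20, 5, 10, seed = 6)
  A <- 2e-5
  sim <- simulateSubject(m, s, noiselessConfig(amplitude_ohb = A), seed = 6)
  od <- mbllForward(sim$recording)
  hb <- preprocessRecording(od)
  resp <- channelAverageResponse(epochTrials(hb), "STIM")
  amp <- resp$amplitude[resp$chromophore == "OHb"]
  expect_lt(abs(amp - A) / A, 0.05)
})

test_that("dead channels are excluded from downstream use", {
  m <- makeDefaultMontage()
  s <- generateEventSchedule(4, 4, 5, 10, seed = 3)
  sim <- simulateSubject(m, s, simulationConfig(), seed = 3)
  ohb <- assay(sim$recording, "OHb")
  dhb <- assay(sim$recording, "DHb")
  ohb[2, ] <- 0
  dhb[2, ] <- 0
  hb <- HbRecording(ohb, dhb, 10.2, m, eventSchedule(sim$recording))
  od <- mbllForward(hb)
  expect_message(out <- preprocessRecording(od), "dead channel")
  expect_false(rowData(out)$usable[2])
  expect_true(all(rowData(out)$usable[-2]))
})
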