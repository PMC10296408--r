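test_that("THb equals OHb + DHb exactly in simulated recordings", {
  fix <- simulatedEpochs(seed = 2, n_stim = 4, n_mock = 4)
  rec <- fix$sim$recording
  resid <- assay(rec, "THb") - (assay(rec, "OHb") + assay(rec, "DHb"))
  expect_lt(max(abs(resid)), 1e-12)
})

test_that("identical seeds give bit-identical recordings", {
  m <- makeDefaultMontage()
  s <- generateEventSchedule(4, 4, 5, 10, seed = 9)
  a <- simulateSubject(m, s, simulationConfig(), seed = 5)
  b <- simulateSubject(m, s, simulationConfig(), seed = 5)
  c <- simulateSubject(m, s, simulationConfig(), seed = 6)
  expect_identical(assay(a$recording, "OHb"), assay(b$recording, "OHb"))
  expect_identical(a$truth@amplitudes, b$truth@amplitudes)
  expect_false(identical(assay(a$recording, "OHb"),
                         assay(c$recording, "OHb")))
})

test_that("noiseless peri-stimulus OHb maximum equals the configured amplitude", {
  m <- makeDefaultMontage()
  s <- generateEventSchedule(4, 4, 5, 10, seed = 9)
  A <- 2e-5
  sim <- simulateSubject(m, s, noiselessConfig(amplitude_ohb = A), seed = 3)
  expect_equal(max(assay(sim$recording, "OHb")), A, tolerance = 1e-12)
  ## every channel reaches A (lambda = 1)
  expect_equal(unname(apply(assay(sim$recording, "OHb"), 1, max)),
               rep(A, 22), tolerance = 1e-12)
})

test_that("lateralization gain scales right-hemisphere channels and truth", {
  m <- makeDefaultMontage()
  s <- generateEventSchedule(4, 4, 5, 10, seed = 9)
  A <- 2e-5
  sim <- simulateSubject(m, s,
                         noiselessConfig(amplitude_ohb = A,
                                         lateralization = 3),
                         seed = 3)
  tr <- sim$truth
  expect_equal(tr@peak_left, A)
  expect_equal(tr@peak_right, 3 * A)
  expect_equal(trueLI(tr), (1 - 3) / (1 + 3))  # -0.5
  hemi <- hemispheres(sim$recording)
  mx <- apply(assay(sim$recording, "OHb"), 1, max)
  expect_equal(unname(mx[hemi == "right"] / mx[hemi == "left"]),
               rep(3, 11), tolerance = 1e-9)
})

test_that("ground-truth LI is antisymmetric under hemisphere swap", {
  for (lam in c(0.5, 1.5, 3)) {
    li <- (1 - lam) / (1 + lam)
    li_swapped <- (lam - 1) / (lam + 1)
    expect_equal(li, -li_swapped)
  }
})

test_that("cohort simulation yields groups, clinical rows and determinism", {
  co <- simulateCohort(n_td = 3, n_asd = 3, seed = 11,
                       n_stim = 2, n_mock = 2)
  expect_length(co$subjects, 6L)
  expect_identical(vapply(co$subjects, `[[`, character(1), "group"),
                   c(rep("TD", 3), rep("ASD", 3)))
  expect_identical(nrow(co$clinical), 3L)  # clinical table for ASD only
  expect_true(all(c("subject_id", "Age", "ADOS_TOT", "ADOS_comp", "AQ_tot",
                    "nv_IQ", "VABS_tot") %in% names(co$clinical)))

  co2 <- simulateCohort(n_td = 3, n_asd = 3, seed = 11,
                        n_stim = 2, n_mock = 2)
  expect_identical(co$clinical, co2$clinical)
  expect_identical(assay(co$subjects[[1]]$recording, "OHb"),
                   assay(co2$subjects[[1]]$recording, "OHb"))
})

test_that("noise-free clinical model makes AQ a strictly monotone map of LI", {
  co <- simulateCohort(n_td = 2, n_asd = 8, seed = 13,
                       clinical_model = clinicalModel(aq_sd = 0),
                       n_stim = 2, n_mock = 2)
  li <- vapply(co$subjects[-(1:2)], function(s) trueLI(s$truth), numeric(1))
  expect_equal(unname(cor(li, co$clinical$AQ_tot, method = "spearman")), 1)
})
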