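test_that("hand-built 2x2 system inverts as computed by hand", {
  ## eps rows (1,2; 3,4), dpf = 1, distance = 1: dOD = (5, 11) comes from
  ## (dOHb, dDHb) = (1, 2)
  m <- tinyMontage(distance_cm = 1)
  s <- generateEventSchedule(1, 1, 5, 10, seed = 1)
  ohb <- matrix(1, 4, 50)
  dhb <- matrix(2, 4, 50)
  hb <- HbRecording(ohb, dhb, 10.2, m, shiftSchedule(s, 1))
  eps <- matrix(c(1, 3, 2, 4), 2, 2)
  od <- mbllForward(hb, dpf = c(1, 1), extinction = eps)
  expect_equal(unique(as.vector(assay(od, "od_760"))), 5)
  expect_equal(unique(as.vector(assay(od, "od_850"))), 11)
  back <- mbllInverse(od, dpf = c(1, 1), extinction = eps)
  expect_equal(assay(back, "OHb"), ohb, ignore_attr = TRUE)
  expect_equal(assay(back, "DHb"), dhb, ignore_attr = TRUE)
})

test_that("forward transform is linear and zero maps to zero", {
  m <- makeDefaultMontage()
  s <- generateEventSchedule(2, 2, 5, 10, seed = 1)
  zero <- HbRecording(matrix(0, 22, 40), matrix(0, 22, 40), 10.2, m,
                      shiftSchedule(s, 1))
  od0 <- mbllForward(zero)
  expect_true(all(assay(od0, "od_760") == 0))
  expect_true(all(assay(od0, "od_850") == 0))

  set.seed(4)
  ohb <- matrix(rnorm(22 * 40, sd = 1e-5), 22, 40)
  dhb <- matrix(rnorm(22 * 40, sd = 1e-5), 22, 40)
  one <- mbllForward(HbRecording(ohb, dhb, 10.2, m, shiftSchedule(s, 1)))
  two <- mbllForward(HbRecording(2 * ohb, 2 * dhb, 10.2, m,
                                 shiftSchedule(s, 1)))
  expect_equal(assay(two, "od_850"), 2 * assay(one, "od_850"))
})

test_that("forward then inverse is the identity to 1e-10 relative", {
  m <- makeDefaultMontage()
  s <- generateEventSchedule(2, 2, 5, 10, seed = 1)
  set.seed(99)
  for (r in 1:5) {
    ohb <- matrix(rnorm(22 * 60, sd = 2e-5), 22, 60)
    dhb <- matrix(rnorm(22 * 60, sd = 1e-5), 22, 60)
    hb <- HbRecording(ohb, dhb, 10.2, m, shiftSchedule(s, 1))
    back <- mbllInverse(mbllForward(hb))
    relerr <- max(abs(assay(back, "OHb") - ohb)) / max(abs(ohb))
    expect_lt(relerr, 1e-10)
    resid <- assay(back, "THb") - (assay(back, "OHb") + assay(back, "DHb"))
    expect_lt(max(abs(resid)), 1e-12)
  }
})

test_that("singular extinction matrices are rejected", {
  m <- makeDefaultMontage()
  s <- generateEventSchedule(1, 1, 5, 10, seed = 1)
  hb <- HbRecording(matrix(1e-5, 22, 30), matrix(-1e-6, 22, 30), 10.2, m,
                    shiftSchedule(s, 1))
  sing <- matrix(c(1, 2, 2, 4), 2, 2)
  expect_error(mbllForward(hb, extinction = sing), "singular")
  od <- mbllForward(hb)
  expect_error(mbllInverse(od, extinction = sing), "singular")
})

test_that("built-in extinction table covers exactly the two wavelengths", {
  e <- defaultExtinction()
  expect_identical(dim(e), c(2L, 2L))
  expect_gt(abs(det(e)), 0)
  expect_error(defaultExtinction(c(690, 830)), "tabulated")
})
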