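test_that("paired t reproduces hand-computed values and symmetries", {
  ## differences {1,2,3}: t = 2 / (1/sqrt(3)) = 2*sqrt(3), df = 2
  x <- c(2, 4, 6)
  y <- c(1, 2, 3)
  r <- pairedT(x, y)
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_identical(r$df, "2")
  expect_identical(r$n, 3L)
  expect_identical(r$direction, 1)

  swapped <- pairedT(y, x)
  expect_equal(swapped$statistic, -r$statistic)
  expect_equal(swapped$p, r$p)

  same <- pairedT(c(1, 2, 3), c(0, 2, 4))  # differences 1, 0, -1
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  expect_error(pairedT(c(1, 2, 3), c(0, 1, 2)), "degenerate")
  expect_error(pairedT(1:2, 1:2 + 0.5), "at least 3")
})

test_that("independent t matches the pooled-variance hand computation", {
  r <- independentT(c(1, 2, 3), c(4, 5, 6), welch = FALSE)
  expect_equal(r$statistic, -3.674235, tolerance = 1e-6)
  expect_identical(r$df, "4")
  expect_identical(r$direction, -1)

  same <- independentT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  ## shifting one group further apart makes p decrease monotonically
  set.seed(2)
  g <- rnorm(10)
  ps <- vapply(c(0.5, 1, 2, 4), function(c) {
    independentT(g + c, g)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  expect_error(independentT(c(1, 1), c(2, 2)), "degenerate")
  expect_error(independentT(1, c(1, 2)), "at least 2")
})

test_that("mixed ANOVA matches a manual sums-of-squares oracle", {
  ## 2 groups x 2 subjects x 2 hemispheres with known cell structure
  v <- rbind(c(10, 14), c(12, 16), c(20, 21), c(22, 25))
  g <- c("A", "A", "B", "B")
  res <- mixedAnova(v, g)
  ## hand decomposition: grand = 17.5; subject means 12, 14, 20.5, 23.5;
  ## group means 13, 22; hemisphere means 16, 19;
  ## cell means: A (11, 15), B (21, 23)
  ss_between <- 2 * sum((c(12, 14, 20.5, 23.5) - 17.5)^2)  # 175
  ss_group <- 2 * 2 * ((13 - 17.5)^2 + (22 - 17.5)^2)      # 162
  ss_subj <- ss_between - ss_group                         # 13
  ss_within <- sum((v - rowMeans(v))^2)                    # 21
  ss_hemi <- 4 * ((16 - 17.5)^2 + (19 - 17.5)^2)           # 18
  cells <- rbind(c(11, 15), c(21, 23))
  ss_int <- 2 * sum((cells - outer(c(13, 22), c(16, 19), "+") +
                       17.5)^2)                            # 2
  ss_err <- ss_within - ss_hemi - ss_int                   # 1
  f_group <- (ss_group / 1) / (ss_subj / 2)                # 24.92...
  f_hemi <- (ss_hemi / 1) / (ss_err / 2)                   # 36
  f_int <- (ss_int / 1) / (ss_err / 2)                     # 4
  expect_equal(res$statistic, c(f_group, f_hemi, f_int), tolerance = 1e-12)
  expect_identical(res$df, rep("1,2", 3))

  ## cross-check against the split-plot aov fit
  d <- data.frame(y = c(v), hemi = rep(c("L", "R"), each = 4),
                  subj = factor(rep(1:4, 2)), grp = factor(rep(g, 2)))
  a <- summary(stats::aov(y ~ grp * hemi + Error(subj), data = d))
  f_aov <- c(a[[1]][[1]]["grp", "F value"],
             a[[2]][[1]]["hemi", "F value"],
             a[[2]][[1]]["grp:hemi", "F value"])
  expect_equal(res$statistic, unname(f_aov), tolerance = 1e-10)
})

test_that("mixed ANOVA invariances and degenerate handling", {
  set.seed(3)
  v <- matrix(rnorm(20), 10, 2)
  g <- rep(c("A", "B"), each = 5)
  r1 <- mixedAnova(v, g)
  r2 <- mixedAnova(v + 100, g)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-9)

  ## duplicated hemispheres: hemisphere and interaction F are exactly 0
  dup <- cbind(v[, 1], v[, 1])
  rd <- mixedAnova(dup, g)
  expect_identical(rd$statistic[rd$test == "anova_hemisphere"], 0)
  expect_equal(rd$p[rd$test == "anova_hemisphere"], 1)

  vna <- v
  vna[1, 2] <- NA
  expect_warning(rna <- mixedAnova(vna, g), "missing a hemisphere")
  expect_identical(rna$n[1], 9L)

  expect_error(mixedAnova(v[1:3, ], c("A", "A", "B")), ">= 2 subjects")
})

test_that("Spearman correlation handles the worked example and missing data", {
  r <- spearmanCor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)

  up <- spearmanCor(1:8, exp(1:8))
  expect_equal(up$rho, 1)
  dn <- spearmanCor(1:8, -(1:8)^3)
  expect_equal(dn$rho, -1)

  ## monotone-transform invariance
  set.seed(4)
  x <- rnorm(15)
  y <- rnorm(15)
  expect_equal(spearmanCor(x, y)$rho, spearmanCor(exp(x), y)$rho)
  expect_equal(spearmanCor(x, y)$p, spearmanCor(x, y^3 + y)$p)

  ## pairwise deletion
  xm <- c(x, NA)
  ym <- c(y, 5)
  expect_identical(spearmanCor(xm, ym)$n, 15L)
  expect_error(spearmanCor(c(1, NA, 3), c(1, 2, NA)), "at least 3")
})

test_that("BH adjustment reproduces the step-up hand example and bounds", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bhFdr(0.3), 0.3)
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  for (r in 1:20) {
    p <- runif(sample(3:12, 1))
    adj <- bhFdr(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= pmin(1, length(p) * p) + 1e-15))
    ## monotone non-decreasing when ordered by raw p
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("demographic summary gives median and n-1 SD with 2 dp reporting", {
  ages <- c(4, 5, 6, 4, 3, 6, 5, 6, 5, 4, 3, 3)
  d <- demographicSummary(ages)
  expect_equal(d$median, 4.5)
  expect_equal(d$sd_2dp, 1.17)
  expect_identical(d$n, 12L)

  expect_equal(demographicSummary(c(1, 1, 1, 1))$sd, 0)
  expect_error(demographicSummary(5), "single value")
  expect_error(demographicSummary(numeric()), "non-empty")
})

test_that("the full statistical plan runs, adjusts within families, flags", {
  co <- simulateCohort(n_td = 5, n_asd = 5, seed = 21, n_stim = 6,
                       n_mock = 6)
  met <- cohortMetrics(co)
  res <- runFullStats(met, clinical = co$clinical)
  expect_setequal(unique(res$family),
                  c("reliability", "amplitude", "latency", "lateralization",
                    "correlations"))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$p_adj >= res$p - 1e-12))
  expect_true(all(res$p_adj <= 1))
  for (fam in unique(res$family)) {
    sel <- res$family == fam
    expect_equal(res$p_adj[sel], bhFdr(res$p[sel]))
  }
  ## deterministic re-run
  res2 <- runFullStats(met, clinical = co$clinical)
  expect_identical(res, res2)
  ## alpha = 0 flags nothing
  res0 <- runFullStats(met, clinical = co$clinical, alpha = 0)
  expect_false(any(res0$significant))

  expect_error(runFullStats(met[, -6]), "missing required column")
})
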