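## Group-level statistical plan: reliability, group differences,
## hemisphere x group mixed ANOVA, clinical correlations, BH-FDR.

.statRow <- function(test, statistic, df, p, n, direction = NA_real_,
                     family = NA_character_) {
  data.frame(test = test, family = family, statistic = unname(statistic),
             df = as.character(df), p = unname(p), p_adj = NA_real_, n = n,
             direction = unname(direction), stringsAsFactors = FALSE)
}

#' Paired t test
#'
#' Classical two-sided paired t test on within-subject differences.
#'
#' @param x,y Equal-length per-subject values, paired by position.
#' @param test Label written into the result row.
#' @return One-row data.frame: `test`, `family`, `statistic`, `df`, `p`,
#'   `p_adj` (NA until adjusted), `n`, `direction` (sign of the mean
#'   difference x - y).
#' @examples
#' pairedT(c(2, 3, 4), c(1, 1, 1))
#' @export
pairedT <- function(x, y, test = "paired_t") {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("paired t test needs at least 3 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("degenerate paired t test: all within-pair differences are equal")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  .statRow(test, unname(tt$statistic), unname(tt$parameter), tt$p.value,
           n = length(x), direction = sign(mean(d)))
}

#' Independent-samples t test
#'
#' Two-sided comparison of two groups; Welch's unequal-variance form by
#' default (the package's group sizes are unequal), Student's
#' pooled-variance form on request.
#'
#' @param g1,g2 Group values (each >= 2 with nonzero variance).
#' @param welch Use the Welch form (default) or Student's.
#' @param test Label written into the result row.
#' @return One-row data.frame as in [pairedT()]; `direction` is the sign
#'   of `mean(g1) - mean(g2)`; `n` is the total.
#' @export
independentT <- function(g1, g2, welch = TRUE, test = "independent_t") {
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
    stop("degenerate t test: both groups have zero variance")
  }
  tt <- stats::t.test(g1, g2, var.equal = !welch)
  .statRow(test, unname(tt$statistic), unname(tt$parameter), tt$p.value,
           n = length(g1) + length(g2),
           direction = sign(mean(g1) - mean(g2)))
}

#' Split-plot (mixed design) two-way ANOVA
#'
#' Hemisphere (within-subject, 2 levels) by group (between-subject)
#' ANOVA computed from the classical split-plot sums-of-squares
#' decomposition. With y_{gij} the value of subject i of group g in
#' hemisphere j, N subjects, G groups, J = 2 hemispheres:
#'
#' - SS_between = J * sum_i (m_i - m)^2, split into
#'   SS_group = J * sum_g n_g (m_g - m)^2 and the between-subject error
#'   SS_subj = SS_between - SS_group with df N - G;
#' - SS_within = sum_{ij} (y_ij - m_i)^2, split into
#'   SS_hemi = N * sum_j (m_j - m)^2,
#'   SS_int = sum_{gj} n_g (m_gj - m_g - m_j + m)^2, and the
#'   within-subject error SS_err = SS_within - SS_hemi - SS_int with
#'   df (N - G)(J - 1).
#'
#' F_group = MS_group / MS_subj; F_hemi and F_interaction use MS_err.
#' Subjects missing one hemisphere are dropped with a warning.
#'
#' @param values Two-column numeric matrix or data.frame, columns
#'   `left` and `right`, one row per subject.
#' @param group Per-subject group labels (>= 2 subjects per group).
#' @return Three-row data.frame (effects `group`, `hemisphere`,
#'   `interaction`) with columns `test`, `family`, `statistic` (F),
#'   `df` ("df1,df2"), `p`, `p_adj`, `n`, `direction`.
#' @export
mixedAnova <- function(values, group) {
  values <- as.matrix(values)
  if (ncol(values) != 2L) {
    stop("'values' must have two columns (one per hemisphere)")
  }
  if (nrow(values) != length(group)) {
    stop("'group' must have one label per subject")
  }
  ok <- stats::complete.cases(values)
  if (!all(ok)) {
    warning(sprintf("dropping %d subject(s) missing a hemisphere value",
                    sum(!ok)))
    values <- values[ok, , drop = FALSE]
    group <- group[ok]
  }
  group <- factor(group)
  if (nlevels(group) < 2L || any(table(group) < 2L)) {
    stop("need at least 2 groups with >= 2 subjects each")
  }
  N <- nrow(values)
  J <- 2L
  G <- nlevels(group)
  grand <- mean(values)
  m_subj <- rowMeans(values)
  m_grp <- tapply(m_subj, group, mean)
  n_g <- as.vector(table(group))
  m_hemi <- colMeans(values)
  ## cell means group x hemisphere
  m_cell <- apply(values, 2L, function(col) tapply(col, group, mean))

  ss_between <- J * sum((m_subj - grand)^2)
  ss_group <- J * sum(n_g * (m_grp - grand)^2)
  ss_subj <- ss_between - ss_group
  ss_within <- sum((values - m_subj)^2)
  ss_hemi <- N * sum((m_hemi - grand)^2)
  ss_int <- sum(n_g * (m_cell - outer(as.vector(m_grp), m_hemi, `+`) +
                         grand)^2)
  ss_err <- ss_within - ss_hemi - ss_int

  df_group <- G - 1L
  df_subj <- N - G
  df_hemi <- J - 1L
  df_int <- (G - 1L) * (J - 1L)
  df_err <- (N - G) * (J - 1L)

  ms_subj <- ss_subj / df_subj
  ms_err <- ss_err / df_err
  ## an effect with exactly zero SS has F = 0 by convention, even when the
  ## error SS is also zero (e.g. hemisphere duplicated for every subject)
  safeF <- function(ss, df, ms) if (ss == 0) 0 else (ss / df) / ms
  f_group <- safeF(ss_group, df_group, ms_subj)
  f_hemi <- safeF(ss_hemi, df_hemi, ms_err)
  f_int <- safeF(ss_int, df_int, ms_err)

  rbind(
    .statRow("anova_group", f_group, sprintf("%d,%d", df_group, df_subj),
             stats::pf(f_group, df_group, df_subj, lower.tail = FALSE),
             n = N),
    .statRow("anova_hemisphere", f_hemi, sprintf("%d,%d", df_hemi, df_err),
             stats::pf(f_hemi, df_hemi, df_err, lower.tail = FALSE),
             n = N, direction = sign(m_hemi[2L] - m_hemi[1L])),
    .statRow("anova_interaction", f_int, sprintf("%d,%d", df_int, df_err),
             stats::pf(f_int, df_int, df_err, lower.tail = FALSE), n = N)
  )
}

#' Spearman rank correlation with pairwise deletion
#'
#' Rank correlation (average ranks for ties) with two-sided p value;
#' incomplete pairs are removed first.
#'
#' @param x,y Numeric vectors; NA allowed.
#' @return A list: `rho`, `p`, `n` (complete pairs used).
#' @examples
#' spearmanCor(c(1, 2, 3, 4), c(1, 3, 2, 4))  # rho = 0.8
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) {
    stop("Spearman correlation needs at least 3 complete pairs")
  }
  ties <- anyDuplicated(x) || anyDuplicated(y)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = if (ties) FALSE else NULL)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment: with p values sorted
#' ascending, the adjusted value at rank i is
#' `min_{j >= i} p_(j) * m / j`, capped at 1, returned in input order.
#'
#' @param pvals Raw p values in `[0, 1]`.
#' @return Adjusted p values, same order as the input.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(pvals) {
  if (!is.numeric(pvals) || any(!is.finite(pvals)) ||
      any(pvals < 0 | pvals > 1)) {
    stop("all p values must be finite and in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Median and sample SD of an age list
#'
#' Median (mean of the central pair for even n) and the n-1 denominator
#' standard deviation, with 2-decimal reporting copies.
#'
#' @param ages Numeric vector of ages in years (>= 1 value; the SD needs
#'   >= 2).
#' @return A list: `median`, `sd`, `median_2dp`, `sd_2dp`, `n`.
#' @examples
#' demographicSummary(c(4, 5, 6, 4, 3, 6, 5, 6, 5, 4, 3, 3))
#' @export
demographicSummary <- function(ages) {
  if (!is.numeric(ages) || length(ages) < 1L || any(!is.finite(ages))) {
    stop("'ages' must be a non-empty finite numeric vector")
  }
  med <- stats::median(ages)
  if (length(ages) < 2L) {
    stop("the sample SD is undefined for a single value")
  }
  s <- stats::sd(ages)
  list(median = med, sd = s, median_2dp = round(med, 2),
       sd_2dp = round(s, 2), n = length(ages))
}

## pull one metric as a named per-subject vector
.metricVector <- function(metrics, cond, chrom, metric, group = NULL) {
  sel <- metrics$condition == cond & metrics$chromophore == chrom &
    metrics$metric == metric
  if (!is.null(group)) sel <- sel & metrics$group == group
  structure(metrics$value[sel], names = metrics$subject_id[sel])
}

#' Run the full group-level statistical plan
#'
#' Executes, on a tidy per-subject metric table (see [subjectMetrics()])
#' and an optional clinical table, the package's statistical plan:
#'
#' 1. reliability: per group, paired t of STIM vs MOCK amplitude per
#'    chromophore, for the channel-average and best-channel readouts;
#' 2. amplitude: TD vs ASD Welch t per chromophore and readout (STIM);
#' 3. latency: the same comparisons on peak latencies;
#' 4. lateralization: hemisphere x group mixed ANOVA on the hemisphere
#'    OHb peaks, plus a TD vs ASD t test on the laterality index;
#' 5. correlations: Spearman of the ASD group's laterality index and
#'    channel-average OHb amplitude against AQ_tot, VABS_tot, ADOS_TOT
#'    and nv_IQ (pairwise deletion of missing scores).
#'
#' Benjamini-Hochberg adjustment is applied within each family. A single
#' degenerate comparison (for instance, grid-quantised peak latencies
#' with zero variance in both groups of a very small cohort) is skipped
#' with a warning rather than aborting the plan.
#'
#' @param metrics Tidy metric table with columns `subject_id`, `group`,
#'   `condition`, `chromophore`, `metric`, `value`.
#' @param clinical Optional clinical table with columns `subject_id`,
#'   `AQ_tot`, `VABS_tot`, `ADOS_TOT`, `nv_IQ` (missing allowed).
#' @param welch Use Welch t tests for group comparisons.
#' @param alpha Significance level used for the `significant` column.
#' @return data.frame: `test`, `family`, `statistic`, `df`, `p`, `p_adj`,
#'   `n`, `direction`, `significant`.
#' @export
runFullStats <- function(metrics, clinical = NULL, welch = TRUE,
                         alpha = 0.05) {
  need <- c("subject_id", "group", "condition", "chromophore", "metric",
            "value")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) {
    stop("metric table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  groups <- unique(metrics$group)
  rows <- list()
  ## a single degenerate comparison (e.g. grid-quantised latencies with no
  ## variance in a tiny cohort) is skipped with a warning rather than
  ## aborting the whole plan
  add <- function(expr, family) {
    row <- tryCatch(expr, error = function(e) {
      warning("skipping one test (", family, "): ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(row)) {
      row$family <- family
      rows[[length(rows) + 1L]] <<- row
    }
  }

  ## 1. reliability: STIM vs MOCK within group
  if (all(c("STIM", "MOCK") %in% metrics$condition)) {
    for (g in groups) {
      for (m in c("avg_amplitude", "best_amplitude")) {
        for (chrom in CHROMOPHORES) {
          x <- .metricVector(metrics, "STIM", chrom, m, g)
          y <- .metricVector(metrics, "MOCK", chrom, m, g)
          y <- y[names(x)]
          add(pairedT(x, y,
                      test = sprintf("stim_vs_mock_%s_%s_%s", g, chrom, m)),
              "reliability")
        }
      }
    }
  }

  two_groups <- length(groups) == 2L
  if (two_groups) {
    g1 <- groups[1L]
    g2 <- groups[2L]
    ## 2. amplitude and 3. latency group comparisons (STIM)
    fams <- list(amplitude = c("avg_amplitude", "best_amplitude"),
                 latency = c("avg_latency", "best_latency"))
    for (fam in names(fams)) {
      for (m in fams[[fam]]) {
        for (chrom in CHROMOPHORES) {
          a <- .metricVector(metrics, "STIM", chrom, m, g1)
          b <- .metricVector(metrics, "STIM", chrom, m, g2)
          add(independentT(a, b, welch = welch,
                           test = sprintf("%s_vs_%s_%s_%s", g1, g2, chrom,
                                          m)),
              fam)
        }
      }
    }
    ## 4. lateralization: mixed ANOVA on hemisphere peaks + LI t test
    pl <- .metricVector(metrics, "STIM", "OHb", "peak_left")
    pr <- .metricVector(metrics, "STIM", "OHb", "peak_right")
    grp <- metrics$group[match(names(pl), metrics$subject_id)]
    an <- tryCatch(mixedAnova(cbind(left = pl, right = pr[names(pl)]), grp),
                   error = function(e) {
                     warning("skipping mixed ANOVA: ", conditionMessage(e),
                             call. = FALSE)
                     NULL
                   })
    for (i in seq_len(NROW(an))) {
      add(an[i, , drop = FALSE], "lateralization")
    }
    li1 <- .metricVector(metrics, "STIM", "OHb", "li", g1)
    li2 <- .metricVector(metrics, "STIM", "OHb", "li", g2)
    add(independentT(li1, li2, welch = welch,
                     test = sprintf("li_%s_vs_%s", g1, g2)),
        "lateralization")
  }

  ## 5. clinical correlations within the ASD group
  if (!is.null(clinical) && nrow(clinical)) {
    scores <- intersect(c("AQ_tot", "VABS_tot", "ADOS_TOT", "nv_IQ"),
                        names(clinical))
    li <- .metricVector(metrics, "STIM", "OHb", "li", "ASD")
    amp <- .metricVector(metrics, "STIM", "OHb", "avg_amplitude", "ASD")
    for (v in list(list(name = "li", val = li),
                   list(name = "ohb_avg_amplitude", val = amp))) {
      x <- v$val[as.character(clinical$subject_id)]
      for (sc in scores) {
        res <- tryCatch(spearmanCor(x, clinical[[sc]]),
                        error = function(e) NULL)
        if (!is.null(res)) {
          add(.statRow(sprintf("spearman_%s_vs_%s", v$name, sc),
                       res$rho, NA_character_, res$p, n = res$n,
                       direction = sign(res$rho)),
              "correlations")
        }
      }
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    out$p_adj[sel] <- bhFdr(out$p[sel])
  }
  out$significant <- out$p_adj < alpha
  out
}
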