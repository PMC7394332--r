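# Statistical kernel shared by probe-level and group-level analysis:
# tertile medians/means, beta-differences, Kolmogorov-Smirnov tests, and
# Pearson correlation with expression.

PAIRS <- list(up_mid = c("up", "mid"), up_down = c("up", "down"),
              mid_down = c("mid", "down"))

#' Tertile medians of beta values
#'
#' Median of the finite beta values falling in each expression tertile; a
#' tertile with no finite value yields `NA`.
#'
#' @param betas Named numeric vector of beta values (names = sample ids).
#' @param tertiles List with `up`, `mid`, `down` sample-id vectors (as in a
#'   `gene_stratification`).
#' @return Named numeric vector `c(up=, mid=, down=)`.
#' @export
tertile_medians <- function(betas, tertiles) {
  vapply(c(up = "up", mid = "mid", down = "down"), function(g) {
    v <- betas[tertiles[[g]]]
    v <- v[is.finite(v)]
    if (length(v)) stats::median(v) else NA_real_
  }, numeric(1))
}

tertile_means <- function(betas, tertiles) {
  vapply(c(up = "up", mid = "mid", down = "down"), function(g) {
    v <- betas[tertiles[[g]]]
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

#' Beta-difference between two group medians
#'
#' @param median_a,median_b Medians of two methylation groups.
#' @return `median_a - median_b`, or `NA` when either median is missing.
#' @export
beta_difference <- function(median_a, median_b) {
  ifelse(is.na(median_a) | is.na(median_b), NA_real_, median_a - median_b)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS p-value via [stats::ks.test()], using the exact small-sample
#' distribution when both groups have at most 25 finite values and the
#' asymptotic distribution otherwise. Methylation beta values commonly fail
#' normality, which is why this non-parametric contrast is used between
#' tertiles.
#'
#' @param values_a,values_b Numeric vectors; missing values dropped first.
#' @return The p-value, or `NA_real_` when a group is empty after
#'   missing-value removal.
#' @export
ks_test <- function(values_a, values_b) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (!length(a) || !length(b)) return(NA_real_)
  exact <- length(a) <= 25L && length(b) <= 25L
  suppressWarnings(stats::ks.test(a, b, exact = exact)$p.value)
}

#' Pearson correlation between expression and methylation
#'
#' Standard Pearson r over pairwise-complete observations across all
#' samples (not per tertile), with the two-sided t-distribution p-value.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r` and `p`; both `NA` when fewer than 3 complete
#'   pairs remain or either vector is constant.
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

# Assemble one output row in the unified column layout, joining the
# methylation statistics with the owning gene's expression contrasts.
make_stat_record <- function(key, gene, probe_id, region, island, level,
                             n_probes, medians, means, ks, pearson, strat) {
  diffs <- c(up_mid = beta_difference(medians[["up"]], medians[["mid"]]),
             up_down = beta_difference(medians[["up"]], medians[["down"]]),
             mid_down = beta_difference(medians[["mid"]], medians[["down"]]))
  data.frame(
    key = key, gene = gene, probe_id = probe_id, region = region,
    island = island, level = level, n_probes = as.integer(n_probes),
    median_up = medians[["up"]], median_mid = medians[["mid"]],
    median_down = medians[["down"]],
    mean_up = means[["up"]], mean_mid = means[["mid"]],
    mean_down = means[["down"]],
    beta_diff_up_mid = diffs[["up_mid"]],
    beta_diff_up_down = diffs[["up_down"]],
    beta_diff_mid_down = diffs[["mid_down"]],
    ks_p_up_mid = ks[["up_mid"]], ks_p_up_down = ks[["up_down"]],
    ks_p_mid_down = ks[["mid_down"]],
    pearson_r = pearson$r, pearson_p = pearson$p,
    expr_mean_up = strat$group_means[["up"]],
    expr_mean_mid = strat$group_means[["mid"]],
    expr_mean_down = strat$group_means[["down"]],
    fc_up_mid = strat$fc[["up_mid"]], fc_up_down = strat$fc[["up_down"]],
    fc_mid_down = strat$fc[["mid_down"]],
    ttest_p_up_mid = strat$ttest_p[["up_mid"]],
    ttest_p_up_down = strat$ttest_p[["up_down"]],
    ttest_p_mid_down = strat$ttest_p[["mid_down"]],
    stringsAsFactors = FALSE
  )
}

#' Per-probe methylation statistics
#'
#' Computes, for one expanded probe-gene-region record, the tertile medians
#' and means, the three beta-differences, the three tertile-pair KS tests,
#' and the all-sample Pearson correlation between the gene's expression and
#' the probe's beta values; the gene's fold changes and t-test p-values are
#' joined to the record for output. A record is always emitted, with
#' missing statistics as `NA`.
#'
#' @param record One-row data frame from [expand_annotation()].
#' @param beta_row Named numeric vector of the probe's beta values.
#' @param strat The gene's `gene_stratification`.
#' @param expr_row Named numeric vector of the gene's expression values.
#' @return One-row data frame in the unified result-column layout.
#' @export
probe_stats <- function(record, beta_row, strat, expr_row) {
  b <- reorder_betas(beta_row, strat)
  tert <- strat[c("up", "mid", "down")]
  medians <- tertile_medians(b, tert)
  means <- tertile_means(b, tert)
  grp <- lapply(tert, function(ids) b[ids])
  ks <- vapply(PAIRS, function(p) ks_test(grp[[p[1L]]], grp[[p[2L]]]),
               numeric(1))
  pe <- pearson_corr(unname(expr_row[strat$ordered_samples]), unname(b))
  make_stat_record(record$key, record$gene, record$probe_id, record$region,
                   record$island, "probe", 1L, medians, means, ks, pe, strat)
}
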