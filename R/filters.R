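# Six-filter post-processing cascade, correlation-direction summaries,
# and top-k hotspot selection.

FILTER_NAMES <- c("monotone_medians", "beta_difference", "ks_p", "fc",
                  "ttest_p", "pearson_p")
PAIR_NAMES <- c("up_mid", "up_down", "mid_down")

#' Filter cascade configuration
#'
#' Thresholds, pair selection and enable flags for the six-filter cascade.
#' Defaults follow the biologically motivated example thresholds: absolute
#' beta-difference >= 0.1, KS p <= 0.01, absolute fold change >= 2, t-test
#' p <= 0.01, Pearson p <= 0.05, and top-50 selection.
#'
#' @param beta_diff_min Minimum absolute beta-difference (filter 2).
#' @param ks_alpha KS significance level (filter 3).
#' @param fc_min Minimum absolute fold change (filter 4).
#' @param ttest_alpha t-test significance level (filter 5).
#' @param pearson_alpha Pearson significance level (filter 6).
#' @param top_k Number of records per direction in top-k selection.
#' @param pairs Which expression-group pair(s) the pairwise thresholds
#'   apply to; subset of `c("up_mid", "up_down", "mid_down")`. Every
#'   selected pair must pass. Default `"up_down"` (largest contrast).
#' @param enabled Named logical vector switching individual filters on/off;
#'   names from `c("monotone_medians", "beta_difference", "ks_p", "fc",
#'   "ttest_p", "pearson_p")`.
#' @param use_magnitude Logical; `TRUE` (default) applies the
#'   beta-difference and fold-change thresholds to magnitudes, so hyper-
#'   and hypomethylation (and up-/down-modulation) are kept symmetrically;
#'   `FALSE` thresholds the signed values.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(beta_diff_min = 0.1, ks_alpha = 0.01, fc_min = 2,
                          ttest_alpha = 0.01, pearson_alpha = 0.05,
                          top_k = 50, pairs = "up_down",
                          enabled = NULL, use_magnitude = TRUE) {
  stopifnot(beta_diff_min > 0, fc_min > 0, top_k >= 1,
            ks_alpha > 0, ks_alpha < 1, ttest_alpha > 0, ttest_alpha < 1,
            pearson_alpha > 0, pearson_alpha < 1,
            all(pairs %in% PAIR_NAMES), length(pairs) >= 1)
  en <- stats::setNames(rep(TRUE, length(FILTER_NAMES)), FILTER_NAMES)
  if (!is.null(enabled)) {
    stopifnot(all(names(enabled) %in% FILTER_NAMES))
    en[names(enabled)] <- enabled
  }
  structure(list(beta_diff_min = beta_diff_min, ks_alpha = ks_alpha,
                 fc_min = fc_min, ttest_alpha = ttest_alpha,
                 pearson_alpha = pearson_alpha, top_k = as.integer(top_k),
                 pairs = pairs, enabled = en,
                 use_magnitude = use_magnitude),
            class = "filter_config")
}

pair_cols <- function(prefix, pairs) paste(prefix, pairs, sep = "_")

all_pairs_pass <- function(tab, prefix, pairs, test) {
  ok <- rep(TRUE, nrow(tab))
  for (cn in pair_cols(prefix, pairs)) {
    v <- tab[[cn]]
    ok <- ok & !is.na(v) & test(v)
  }
  ok
}

#' The six record filters
#'
#' Each filter maps a result table to a logical keep-vector; missing
#' statistics never pass.
#' * `filter_monotone_medians()`: tertile medians strictly ascending
#'   (`median_down < median_mid < median_up`) or strictly descending.
#' * `filter_beta_difference()`: |beta-difference| (signed, when
#'   `use_magnitude = FALSE`) at least `beta_diff_min` for every selected
#'   pair.
#' * `filter_ks_p()`: KS p-value at most `ks_alpha` for every selected pair.
#' * `filter_fc()`: |fold change| at least `fc_min` for every selected pair
#'   of the owning gene.
#' * `filter_ttest_p()`: t-test p-value at most `ttest_alpha` for every
#'   selected pair.
#' * `filter_pearson_p()`: Pearson p-value at most `pearson_alpha`.
#'
#' @param tab Result table (data frame in the unified column layout).
#' @param cfg A [filter_config()].
#' @return Logical vector, one element per row of `tab`.
#' @export
filter_monotone_medians <- function(tab) {
  u <- tab$median_up
  m <- tab$median_mid
  d <- tab$median_down
  ok <- (d < m & m < u) | (d > m & m > u)
  ok & !is.na(ok)
}

#' @rdname filter_monotone_medians
#' @export
filter_beta_difference <- function(tab, cfg) {
  f <- if (cfg$use_magnitude) abs else identity
  all_pairs_pass(tab, "beta_diff", cfg$pairs,
                 function(v) f(v) >= cfg$beta_diff_min)
}

#' @rdname filter_monotone_medians
#' @export
filter_ks_p <- function(tab, cfg) {
  all_pairs_pass(tab, "ks_p", cfg$pairs, function(v) v <= cfg$ks_alpha)
}

#' @rdname filter_monotone_medians
#' @export
filter_fc <- function(tab, cfg) {
  f <- if (cfg$use_magnitude) abs else identity
  all_pairs_pass(tab, "fc", cfg$pairs, function(v) f(v) >= cfg$fc_min)
}

#' @rdname filter_monotone_medians
#' @export
filter_ttest_p <- function(tab, cfg) {
  all_pairs_pass(tab, "ttest_p", cfg$pairs, function(v) v <= cfg$ttest_alpha)
}

#' @rdname filter_monotone_medians
#' @export
filter_pearson_p <- function(tab, cfg) {
  v <- tab$pearson_p
  !is.na(v) & v <= cfg$pearson_alpha
}

#' Apply the filter cascade
#'
#' Applies the enabled filters in succession (1 monotone medians, 2
#' beta-difference, 3 KS, 4 fold change, 5 t-test, 6 Pearson); the
#' surviving set is the conjunction of all enabled filters, so it does not
#' depend on the order of application. Per-filter survivor counts are
#' attached as attribute `"survivors"`.
#'
#' @inheritParams filter_monotone_medians
#' @return The surviving rows of `tab`, with a `"survivors"` attribute
#'   (named integer vector of cumulative survivor counts).
#' @export
apply_filters <- function(tab, cfg = filter_config()) {
  keep <- rep(TRUE, nrow(tab))
  counts <- integer(0)
  steps <- list(
    monotone_medians = function() filter_monotone_medians(tab),
    beta_difference = function() filter_beta_difference(tab, cfg),
    ks_p = function() filter_ks_p(tab, cfg),
    fc = function() filter_fc(tab, cfg),
    ttest_p = function() filter_ttest_p(tab, cfg),
    pearson_p = function() filter_pearson_p(tab, cfg)
  )
  for (nm in FILTER_NAMES) {
    if (!cfg$enabled[[nm]]) next
    keep <- keep & steps[[nm]]()
    counts[nm] <- sum(keep)
  }
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "survivors") <- counts
  out
}

#' Correlation-direction percentages by category
#'
#' For each category (gene region, island relation, region x island cell,
#' or the whole table) the percentage of records whose Pearson r is
#' positive and negative among records with a nonzero, non-missing r.
#'
#' @param tab Result table (typically the surviving rows from
#'   [apply_filters()]).
#' @param by One of `"region"`, `"island"`, `"region_island"`, `"overall"`.
#' @return Data frame with columns `region` and/or `island` (as
#'   applicable), `n_pos`, `n_neg`, `pct_pos`, `pct_neg`; percentages are
#'   `NA` when a category holds no directional record.
#' @export
summarize_directions <- function(tab, by = c("region", "island",
                                             "region_island", "overall")) {
  by <- match.arg(by)
  keys <- switch(by,
    region = data.frame(region = tab$region, stringsAsFactors = FALSE),
    island = data.frame(island = tab$island, stringsAsFactors = FALSE),
    region_island = data.frame(region = tab$region, island = tab$island,
                               stringsAsFactors = FALSE),
    overall = data.frame(group = rep("ALL", nrow(tab)),
                         stringsAsFactors = FALSE)
  )
  r <- tab$pearson_r
  directional <- !is.na(r) & r != 0
  cats <- unique(keys)
  cats <- cats[do.call(order, c(unname(cats), list(method = "radix"))), ,
               drop = FALSE]
  res <- cats
  res$n_pos <- res$n_neg <- 0L
  res$pct_pos <- res$pct_neg <- NA_real_
  for (i in seq_len(nrow(cats))) {
    in_cat <- rep(TRUE, nrow(tab))
    for (cn in colnames(cats)) {
      in_cat <- in_cat & !is.na(keys[[cn]]) & keys[[cn]] == cats[i, cn]
    }
    pos <- sum(in_cat & directional & r > 0)
    neg <- sum(in_cat & directional & r < 0)
    res$n_pos[i] <- pos
    res$n_neg[i] <- neg
    if (pos + neg > 0) {
      res$pct_pos[i] <- 100 * pos / (pos + neg)
      res$pct_neg[i] <- 100 * neg / (pos + neg)
    }
  }
  rownames(res) <- NULL
  res
}

#' Top-k records by correlation
#'
#' Selects the `k` records with the most positive and the `k` with the most
#' negative Pearson r (missing r excluded); ties are broken by key so the
#' selection is deterministic under permutation of the input.
#'
#' @inheritParams filter_monotone_medians
#' @param k Number of records per direction (default from `cfg$top_k` when
#'   a config is given).
#' @return List with data frames `positive` and `negative`.
#' @export
top_k_by_correlation <- function(tab, k = 50) {
  has_r <- !is.na(tab$pearson_r)
  sub <- tab[has_r, , drop = FALSE]
  pos <- sub[order(-sub$pearson_r, sub$key, method = "radix"), ,
             drop = FALSE]
  neg <- sub[order(sub$pearson_r, sub$key, method = "radix"), ,
             drop = FALSE]
  pos <- utils::head(pos, k)
  neg <- utils::head(neg, k)
  rownames(pos) <- rownames(neg) <- NULL
  list(positive = pos, negative = neg)
}

#' Run the filter cascade over a full result set
#'
#' Applies [apply_filters()] to each of the four result tables and derives
#' the direction summaries appropriate to each table (probe table: by
#' region and by region x island; region table: by region; island table: by
#' island; whole-gene table: overall) plus top-k lists.
#'
#' @param results A [methylink()] result or named list of the four tables.
#' @param cfg A [filter_config()].
#' @return Object of class `methylink_filtered`: list with `tables`
#'   (filtered tables), `survivors` (per-table cumulative counts),
#'   `directions` (per-table direction summaries), `top` (per-table top-k
#'   lists) and `config`.
#' @export
filter_cascade <- function(results, cfg = filter_config()) {
  tabs <- if (inherits(results, "methylink")) results$tables else results
  direction_by <- list(cg_individually = c("region", "region_island"),
                       cg_by_position = "region",
                       cg_island = "island",
                       cg_of_genes = "overall")
  filtered <- survivors <- directions <- top <- list()
  for (nm in names(RESULT_FILES)) {
    ft <- apply_filters(tabs[[nm]], cfg)
    survivors[[nm]] <- attr(ft, "survivors")
    attr(ft, "survivors") <- NULL
    filtered[[nm]] <- ft
    directions[[nm]] <- lapply(
      stats::setNames(direction_by[[nm]], direction_by[[nm]]),
      function(by) summarize_directions(ft, by = by))
    top[[nm]] <- top_k_by_correlation(ft, k = cfg$top_k)
  }
  structure(list(tables = filtered, survivors = survivors,
                 directions = directions, top = top, config = cfg),
            class = "methylink_filtered")
}

#' @export
print.methylink_filtered <- function(x, ...) {
  cat("methylink filter cascade results\n")
  for (nm in names(x$tables)) {
    cat(sprintf("  %-16s %d survivor(s)\n", nm, nrow(x$tables[[nm]])))
  }
  invisible(x)
}
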