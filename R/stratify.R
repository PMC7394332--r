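# Per-gene expression stratification: descending sample order, Up/Medium/
# Down tertiles, signed fold changes, and Welch t-tests between tertiles.

#' Order samples by descending expression
#'
#' Samples with missing expression are excluded. Ties are broken by
#' ascending sample id (C-locale, radix sort) so the order is deterministic.
#'
#' @param expr_row Named numeric vector of one gene's expression values,
#'   names = sample ids.
#' @return Character vector of sample ids, highest expression first.
#' @export
order_samples_by_expression <- function(expr_row) {
  stopifnot(!is.null(names(expr_row)))
  v <- expr_row[is.finite(expr_row)]
  if (length(v) < 3L) {
    stop("fewer than 3 samples with finite expression", call. = FALSE)
  }
  names(v)[order(-v, names(v), method = "radix")]
}

#' Split an ordered sample list into Up/Medium/Down tertiles
#'
#' With `n = 3q + r`, the Up group (highest expression) gets `q` samples
#' plus one extra when `r >= 1`, Medium gets `q` plus one extra when
#' `r == 2`, Down gets `q`. Group sizes therefore never differ by more than
#' one and the three groups partition the input.
#'
#' @param ordered_samples Character vector from
#'   [order_samples_by_expression()].
#' @return List with character-vector elements `up`, `mid`, `down`.
#' @export
segment_tertiles <- function(ordered_samples) {
  n <- length(ordered_samples)
  if (n < 3L) stop("need at least 3 samples to form tertiles", call. = FALSE)
  q <- n %/% 3L
  r <- n %% 3L
  n_up <- q + (r >= 1L)
  n_mid <- q + (r == 2L)
  list(up = ordered_samples[seq_len(n_up)],
       mid = ordered_samples[n_up + seq_len(n_mid)],
       down = ordered_samples[(n_up + n_mid) + seq_len(q)])
}

#' Signed fold change between two expression groups
#'
#' Computes the fold change of group A versus group B from the group means
#' `mA` and `mB`:
#' * log2(x+1)-scale data (`is_log = TRUE`): magnitude `2^|mA - mB|`;
#' * linear, concordant means (`mA * mB > 0`): magnitude
#'   `max(|mA|,|mB|) / min(|mA|,|mB|)`;
#' * linear, discordant means or a zero mean: magnitude `|mA - mB|`
#'   (a ratio across zero is undefined).
#'
#' The sign is positive when `mB < mA` (A more expressed), negative when
#' `mB > mA`; equal means give the degenerate magnitude (1 on the ratio and
#' log branches, 0 on the difference branch) with positive sign.
#'
#' @param values_a,values_b Numeric vectors of expression values for the
#'   two groups; missing values are dropped.
#' @param is_log Logical scale flag (see [read_expression_matrix()]).
#' @return A single signed fold change.
#' @export
calc_fc <- function(values_a, values_b, is_log = FALSE) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (!length(a) || !length(b)) {
    stop("fold change needs at least one finite value per group",
         call. = FALSE)
  }
  m_a <- mean(a)
  m_b <- mean(b)
  mag <- if (is_log) {
    2^(max(m_a, m_b) - min(m_a, m_b))
  } else if (m_a * m_b > 0) {
    max(abs(m_a), abs(m_b)) / min(abs(m_a), abs(m_b))
  } else {
    max(m_a, m_b) - min(m_a, m_b)
  }
  if (m_b > m_a) -mag else mag
}

#' Welch t-test between two expression groups
#'
#' Two-sample unpaired unequal-variance t-test via [stats::t.test()].
#' Degenerate inputs return `NA`: a group with fewer than two finite
#' values, two equal-length groups whose elementwise difference is all zero
#' (identical arrays carry no contrast), or two essentially constant groups
#' for which the t statistic is undefined.
#'
#' @param values_a,values_b Numeric vectors.
#' @return The p-value, or `NA_real_`.
#' @export
t_test_groups <- function(values_a, values_b) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (length(a) == length(b) && all(a - b == 0)) return(NA_real_)
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
}

#' Stratify one gene's samples by expression
#'
#' Composes [order_samples_by_expression()], [segment_tertiles()],
#' [calc_fc()] and [t_test_groups()] for a single gene: samples with finite
#' expression are ranked, split into Up/Medium/Down tertiles, and the three
#' group pairs (Up vs Medium, Up vs Down, Medium vs Down) are contrasted by
#' signed fold change and Welch t-test.
#'
#' @inheritParams order_samples_by_expression
#' @inheritParams calc_fc
#' @param gene_id Optional gene identifier carried into the result.
#' @return Object of class `gene_stratification`: list with `gene_id`,
#'   `ordered_samples`, `up`, `mid`, `down`, `group_means` (expression means
#'   named up/mid/down), `fc` and `ttest_p` (each named `up_mid`, `up_down`,
#'   `mid_down`). `NULL` (with a `reason` attribute) when fewer than three
#'   samples have finite expression.
#' @export
stratify_gene <- function(expr_row, is_log = FALSE, gene_id = NA_character_) {
  v <- expr_row[is.finite(expr_row)]
  if (length(v) < 3L) return(NULL)
  ordered <- order_samples_by_expression(v)
  tert <- segment_tertiles(ordered)
  vals <- lapply(tert, function(ids) unname(v[ids]))
  pairs <- list(up_mid = c("up", "mid"), up_down = c("up", "down"),
                mid_down = c("mid", "down"))
  fc <- vapply(pairs, function(p) calc_fc(vals[[p[1L]]], vals[[p[2L]]],
                                          is_log = is_log), numeric(1))
  tt <- vapply(pairs, function(p) t_test_groups(vals[[p[1L]]], vals[[p[2L]]]),
               numeric(1))
  structure(list(
    gene_id = gene_id,
    ordered_samples = ordered,
    up = tert$up, mid = tert$mid, down = tert$down,
    group_means = vapply(vals, mean, numeric(1)),
    fc = fc,
    ttest_p = tt
  ), class = "gene_stratification")
}

#' @export
print.gene_stratification <- function(x, ...) {
  cat(sprintf("gene_stratification for %s: %d samples (up %d / mid %d / down %d)\n",
              x$gene_id, length(x$ordered_samples), length(x$up),
              length(x$mid), length(x$down)))
  cat(sprintf("  FC (up|mid, up|down, mid|down): %s\n",
              paste(signif(x$fc, 4), collapse = ", ")))
  cat(sprintf("  t-test p: %s\n", paste(signif(x$ttest_p, 4), collapse = ", ")))
  invisible(x)
}
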