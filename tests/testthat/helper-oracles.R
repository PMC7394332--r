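# Independent oracles used to cross-check the statistical kernels. These
# re-derive each quantity from its defining formula (or by exhaustive
# enumeration) and never call the code paths they check.

# Fold-change branch table applied directly to the two group means.
fc_oracle <- function(m_a, m_b, is_log) {
  mag <- if (is_log) {
    2^(max(m_a, m_b) - min(m_a, m_b))
  } else if (m_a * m_b > 0) {
    max(abs(m_a), abs(m_b)) / min(abs(m_a), abs(m_b))
  } else {
    max(m_a, m_b) - min(m_a, m_b)
  }
  if (m_b > m_a) -mag else mag
}

# Welch two-sample t-test p-value from the closed-form statistic and
# Welch-Satterthwaite degrees of freedom.
welch_p_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  tt <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(tt), df)
}

# Pearson r from the sum formula; p from the t transform.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  r <- (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# Two-sample KS statistic from the ECDF definition.
ks_D_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  ec <- function(v) vapply(pts, function(t) mean(v <= t), numeric(1))
  max(abs(ec(a) - ec(b)))
}

# Exact null distribution of D for sample sizes (n, m) without ties, by
# exhaustive enumeration of all C(n+m, n) group assignments; cached per
# size pair.
.ks_null_cache <- new.env(parent = emptyenv())
ks_null_D <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.ks_null_cache[[key]])) return(.ks_null_cache[[key]])
  N <- n + m
  cmb <- utils::combn(N, n)
  ds <- apply(cmb, 2L, function(ix) {
    memb <- seq_len(N) %in% ix
    max(abs(cumsum(memb) / n - cumsum(!memb) / m))
  })
  .ks_null_cache[[key]] <- ds
  ds
}

# Exact two-sided KS p-value P(D >= d_obs) by enumeration (no ties).
ks_exact_p_oracle <- function(a, b) {
  d <- ks_D_oracle(a, b)
  mean(ks_null_D(length(a), length(b)) >= d - 1e-12)
}

# Asymptotic two-sided KS p-value from the Kolmogorov series
# Q(x) = 2 * sum_k (-1)^(k-1) exp(-2 k^2 x^2).
ks_asymp_p_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  x <- sqrt(n1 * n2 / (n1 + n2)) * ks_D_oracle(a, b)
  k <- 1:300
  min(max(2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2)), 0), 1)
}
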