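test_that("sample ordering is descending with deterministic tie-breaks", {
  expect_equal(order_samples_by_expression(c(s1 = 1, s2 = 3, s3 = 2)),
               c("s2", "s3", "s1"))
  expect_equal(order_samples_by_expression(c(s1 = 2, s2 = 2, s3 = 1)),
               c("s1", "s2", "s3"))
  expect_equal(order_samples_by_expression(c(s1 = 5, s2 = 5, s3 = 5)),
               c("s1", "s2", "s3"))
  expect_error(order_samples_by_expression(c(s1 = 1, s2 = NA, s3 = 2)),
               "fewer than 3")
})

test_that("tertile sizes follow the remainder rule and partition samples", {
  sizes <- function(n) {
    t <- segment_tertiles(paste0("s", seq_len(n)))
    lengths(t)
  }
  expect_equal(unname(sizes(9)), c(3, 3, 3))
  expect_equal(unname(sizes(10)), c(4, 3, 3))
  expect_equal(unname(sizes(11)), c(4, 4, 3))
  expect_error(segment_tertiles(c("a", "b")), "at least 3")

  for (n in 3:500) {
    ids <- paste0("s", seq_len(n))
    t <- segment_tertiles(ids)
    expect_identical(c(t$up, t$mid, t$down), ids)
    expect_lte(max(lengths(t)) - min(lengths(t)), 1L)
  }
})

test_that("calc_fc follows the stated branch table", {
  expect_equal(calc_fc(rep(4, 3), rep(2, 3)), 2)
  expect_equal(calc_fc(rep(1, 3), rep(-2, 3)), 3)
  expect_equal(calc_fc(5, 3, is_log = TRUE), 4)
  expect_equal(calc_fc(rep(-2, 3), rep(-4, 3)), 2)  # concordant negatives
  expect_equal(calc_fc(c(1, 3), c(5, 7)), -3)       # mB > mA -> negative
  expect_equal(calc_fc(2, 2), 1)                    # tie, ratio branch
  expect_equal(calc_fc(0, 0), 0)                    # tie, difference branch
  expect_equal(calc_fc(3, 3, is_log = TRUE), 1)     # tie, log branch
  expect_error(calc_fc(numeric(0), 1), "finite value")
})

test_that("calc_fc is antisymmetric with invariant magnitudes", {
  set.seed(11)
  for (i in 1:200) {
    m_a <- round(runif(1, -5, 5), 2)
    m_b <- round(runif(1, -5, 5), 2)
    is_log <- i %% 2 == 0
    f_ab <- calc_fc(m_a, m_b, is_log)
    f_ba <- calc_fc(m_b, m_a, is_log)
    if (m_a != m_b) expect_equal(f_ab, -f_ba)
    expect_equal(abs(f_ab), abs(f_ba))
    if (is_log) expect_gte(abs(f_ab), 1)
    if (!is_log && m_a * m_b > 0) expect_gte(abs(f_ab), 1)
  }
})

test_that("t_test_groups guards degenerate inputs and matches Welch", {
  expect_true(is.na(t_test_groups(c(1, 2, 3), c(1, 2, 3))))
  expect_true(is.na(t_test_groups(c(0, 0, 0), c(5, 5, 5))))
  expect_true(is.na(t_test_groups(1, c(2, 3))))
  a <- c(1.1, 2.3, 3.1, 4.2)
  b <- c(5.0, 6.1, 7.2, 8.4)
  expect_equal(t_test_groups(a, b), welch_p_oracle(a, b), tolerance = 1e-10)
})

test_that("stratify_gene composes ordering, tertiles and contrasts", {
  expr <- stats::setNames(9:1, paste0("s", 1:9))
  st <- stratify_gene(expr, gene_id = "G")
  expect_equal(st$up, c("s1", "s2", "s3"))
  expect_equal(st$down, c("s7", "s8", "s9"))
  expect_equal(unname(st$fc["up_down"]), 4)  # means 8 vs 2, linear ratio

  flat <- stats::setNames(rep(2, 6), paste0("s", 1:6))
  st2 <- stratify_gene(flat)
  expect_equal(unname(st2$fc), c(1, 1, 1))
  expect_true(all(is.na(st2$ttest_p)))

  st3 <- stratify_gene(c(a = 3, b = 2, c = 1))
  expect_equal(lengths(st3[c("up", "mid", "down")]),
               c(up = 1L, mid = 1L, down = 1L))
  expect_true(all(is.na(st3$ttest_p)))

  expect_null(stratify_gene(c(a = 1, b = 2)))
})

test_that("tertiles partition the finite samples for random sizes", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(3:80, 1)
    expr <- stats::setNames(rnorm(n), sprintf("s%03d", seq_len(n)))
    expr[sample(n, floor(n / 10))] <- NA
    if (sum(is.finite(expr)) < 3) next
    st <- stratify_gene(expr)
    analyzed <- names(expr)[is.finite(expr)]
    expect_setequal(c(st$up, st$mid, st$down), analyzed)
    expect_equal(anyDuplicated(c(st$up, st$mid, st$down)), 0L)
    expect_setequal(st$ordered_samples, analyzed)
    expect_lte(abs(length(st$up) - length(st$down)), 1L)
    expect_lte(abs(length(st$up) - length(st$mid)), 1L)
  }
})
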