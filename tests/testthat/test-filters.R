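test_that("each filter accepts and rejects per its rule", {
  cfg <- filter_config()
  rec <- passing_record()

  asc <- rec; asc$median_up <- 0.8; asc$median_mid <- 0.5
  asc$median_down <- 0.2
  expect_true(filter_monotone_medians(asc))
  expect_true(filter_monotone_medians(rec))        # descending medians
  bad <- rec; bad$median_down <- 0.5; bad$median_mid <- 0.2
  bad$median_up <- 0.8
  expect_false(filter_monotone_medians(bad))
  na_med <- rec; na_med$median_mid <- NA
  expect_false(filter_monotone_medians(na_med))

  bd <- rec
  bd$beta_diff_up_down <- 0.15
  expect_true(filter_beta_difference(bd, cfg))
  bd$beta_diff_up_down <- -0.15                    # magnitude counts
  expect_true(filter_beta_difference(bd, cfg))
  bd$beta_diff_up_down <- 0.05
  expect_false(filter_beta_difference(bd, cfg))
  bd$beta_diff_up_down <- NA
  expect_false(filter_beta_difference(bd, cfg))

  ks <- rec
  ks$ks_p_up_down <- 0.005
  expect_true(filter_ks_p(ks, cfg))
  ks$ks_p_up_down <- 0.01                          # boundary: <= passes
  expect_true(filter_ks_p(ks, cfg))
  ks$ks_p_up_down <- 0.05
  expect_false(filter_ks_p(ks, cfg))

  fc <- rec
  fc$fc_up_down <- 2.5
  expect_true(filter_fc(fc, cfg))
  fc$fc_up_down <- -2.5
  expect_true(filter_fc(fc, cfg))
  fc$fc_up_down <- 1.5
  expect_false(filter_fc(fc, cfg))

  tt <- rec
  tt$ttest_p_up_down <- 0.001
  expect_true(filter_ttest_p(tt, cfg))
  tt$ttest_p_up_down <- 0.02
  expect_false(filter_ttest_p(tt, cfg))
  tt$ttest_p_up_down <- NA
  expect_false(filter_ttest_p(tt, cfg))

  pe <- rec
  pe$pearson_p <- 0.04
  expect_true(filter_pearson_p(pe, cfg))
  pe$pearson_p <- 0.06
  expect_false(filter_pearson_p(pe, cfg))
  pe$pearson_p <- NA
  expect_false(filter_pearson_p(pe, cfg))
})

test_that("signed thresholds are available behind use_magnitude", {
  cfg <- filter_config(use_magnitude = FALSE)
  rec <- passing_record()
  rec$beta_diff_up_down <- -0.15
  expect_false(filter_beta_difference(rec, cfg))
  rec$beta_diff_up_down <- 0.15
  expect_true(filter_beta_difference(rec, cfg))
})

test_that("the cascade is a pure conjunction applied in succession", {
  tab <- single_violation_fixture()
  cfg <- filter_config()
  out <- apply_filters(tab, cfg)
  expect_equal(nrow(out), 0L)

  # each single-filter run keeps the 5 records that do not violate it
  for (nm in c("monotone_medians", "beta_difference", "ks_p", "fc",
               "ttest_p", "pearson_p")) {
    enabled <- stats::setNames(rep(FALSE, 6),
                               c("monotone_medians", "beta_difference",
                                 "ks_p", "fc", "ttest_p", "pearson_p"))
    enabled[nm] <- TRUE
    solo <- apply_filters(tab, filter_config(enabled = enabled))
    expect_equal(nrow(solo), 5L)
  }

  # all-passing record survives; disabling everything is the identity
  tab2 <- rbind(tab, passing_record(key = "cgOK_Body_G1"))
  expect_equal(apply_filters(tab2, cfg)$key, "cgOK_Body_G1")
  all_off <- apply_filters(tab2, filter_config(
    enabled = stats::setNames(rep(FALSE, 6),
                              c("monotone_medians", "beta_difference",
                                "ks_p", "fc", "ttest_p", "pearson_p"))))
  expect_equal(nrow(all_off), nrow(tab2))

  # survivor set does not depend on filter order (conjunction)
  tab3 <- reference_run()$tables$cg_individually
  keep_fwd <- apply_filters(tab3, cfg)$key
  rev_keep <- tab3
  for (f in rev(list(function(t) filter_pearson_p(t, cfg),
                     function(t) filter_ttest_p(t, cfg),
                     function(t) filter_fc(t, cfg),
                     function(t) filter_ks_p(t, cfg),
                     function(t) filter_beta_difference(t, cfg),
                     filter_monotone_medians))) {
    rev_keep <- rev_keep[f(rev_keep), , drop = FALSE]
  }
  expect_setequal(keep_fwd, rev_keep$key)
})

test_that("survivor count is monotone non-increasing in each threshold", {
  tab <- reference_run()$tables$cg_individually
  n_prev <- Inf
  for (bd in c(0.05, 0.1, 0.2, 0.4)) {
    n <- nrow(apply_filters(tab, filter_config(beta_diff_min = bd)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- -1
  for (alpha in c(0.001, 0.01, 0.1, 0.5)) {
    n <- nrow(apply_filters(tab, filter_config(ks_alpha = alpha)))
    expect_gte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (fc in c(1.2, 2, 4, 8)) {
    n <- nrow(apply_filters(tab, filter_config(fc_min = fc)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("direction percentages are complementary and bounded", {
  tab <- rbind(passing_record("k1", "G1"), passing_record("k2", "G1"),
               passing_record("k3", "G1"))
  tab$region <- "TSS200"
  tab$pearson_r <- c(-0.5, -0.4, 0.3)
  d <- summarize_directions(tab, by = "region")
  expect_equal(d$pct_pos, 100 * 1 / 3, tolerance = 1e-12)
  expect_equal(d$pct_neg, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(d$pct_pos + d$pct_neg, 100)

  # r = 0 and missing r are excluded from the denominator
  tab$pearson_r <- c(0, NA, 0.3)
  d2 <- summarize_directions(tab, by = "region")
  expect_equal(d2$n_pos, 1L)
  expect_equal(d2$n_neg, 0L)

  # empty category yields missing percentages
  tab$pearson_r <- c(NA, NA, NA)
  d3 <- summarize_directions(tab, by = "region")
  expect_true(is.na(d3$pct_pos))

  run_tab <- reference_run()$tables$cg_individually
  d4 <- summarize_directions(run_tab, by = "region_island")
  ok <- !is.na(d4$pct_pos)
  expect_true(all(d4$pct_pos[ok] >= 0 & d4$pct_pos[ok] <= 100))
  expect_equal(d4$pct_pos[ok] + d4$pct_neg[ok], rep(100, sum(ok)))
})

test_that("top-k selection is deterministic and permutation-invariant", {
  tab <- rbind(passing_record("a", "G1"), passing_record("b", "G2"),
               passing_record("c", "G3"))
  tab$pearson_r <- c(0.9, -0.95, 0.2)
  top <- top_k_by_correlation(tab, k = 1)
  expect_equal(top$positive$key, "a")
  expect_equal(top$negative$key, "b")

  top_all <- top_k_by_correlation(tab, k = 10)
  expect_equal(nrow(top_all$positive), 3L)

  set.seed(61)
  perm <- tab[sample(nrow(tab)), ]
  top_perm <- top_k_by_correlation(perm, k = 2)
  expect_identical(top_perm$positive$key, top_k_by_correlation(tab, 2)$positive$key)
})
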