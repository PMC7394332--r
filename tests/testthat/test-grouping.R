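# A small gene with known group structure: cgA in TSS200 (Island), cgB in
# Body (OpenSea), cgC annotated to both 1stExon and Body (N_Shore), cgD in
# TSS200 (Island).
grouping_fixture <- function(n = 12) {
  ann <- suppressMessages(probe_annotation(
    probe_id = c("cgA", "cgB", "cgC", "cgD"),
    gene_field = c("G1", "G1", "G1;G1", "G1"),
    region_field = c("TSS200", "Body", "1stExon;Body", "TSS200"),
    island_relation = c("Island", NA, "N_Shore", "Island")))
  rec <- expand_annotation(ann)
  set.seed(7)
  meth <- methylation_matrix(matrix(
    runif(4 * n), nrow = 4,
    dimnames = list(c("cgA", "cgB", "cgC", "cgD"), sprintf("s%02d", 1:n))))
  expr <- stats::setNames(seq_len(n) * 10, sprintf("s%02d", 1:n))
  list(pg = probes_for_gene(rec, "G1", meth),
       strat = stratify_gene(expr, gene_id = "G1"),
       expr = expr)
}

test_that("region grouping keeps one matrix per occupied region", {
  fx <- grouping_fixture()
  gms <- group_by_region(fx$pg)
  expect_setequal(names(gms), c("TSS200", "1stExon", "Body"))
  expect_equal(nrow(gms$TSS200$betas), 2)       # cgA, cgD
  expect_equal(nrow(gms$Body$betas), 2)         # cgB, cgC (dual region)
  expect_equal(nrow(gms$`1stExon`$betas), 1)    # cgC appears here too
  expect_true("cgC_1stExon_G1" %in% gms$`1stExon`$member_keys)
  expect_true("cgC_Body_G1" %in% gms$Body$member_keys)
})

test_that("island grouping dedups probes and excludes open sea", {
  fx <- grouping_fixture()
  gms <- group_by_island(fx$pg)
  expect_setequal(names(gms), c("Island", "N_Shore"))
  expect_equal(nrow(gms$Island$betas), 2)       # cgA, cgD
  expect_equal(nrow(gms$N_Shore$betas), 1)      # cgC once despite 2 records
  expect_false("OpenSea" %in% names(gms))
})

test_that("whole-gene grouping holds each distinct probe once", {
  fx <- grouping_fixture()
  gm <- group_all(fx$pg)
  expect_equal(gm$label, "ALL")
  expect_equal(sort(rownames(gm$betas)), c("cgA", "cgB", "cgC", "cgD"))
})

test_that("grouped_stats on a 1-member group equals probe_stats", {
  fx <- grouping_fixture()
  gms <- group_by_region(fx$pg)
  gm <- gms$`1stExon`
  grouped <- grouped_stats(gm, fx$strat, fx$expr)
  i <- which(fx$pg$records$key == "cgC_1stExon_G1")
  single <- probe_stats(fx$pg$records[i, ], fx$pg$betas[i, ], fx$strat,
                        fx$expr)
  cols <- c("median_up", "median_mid", "median_down",
            "beta_diff_up_mid", "beta_diff_up_down", "beta_diff_mid_down",
            "ks_p_up_mid", "ks_p_up_down", "ks_p_mid_down")
  expect_equal(grouped[cols], single[cols], ignore_attr = TRUE)
})

test_that("pooling is invariant to duplicated member rows for medians", {
  fx <- grouping_fixture()
  gm <- group_by_region(fx$pg)$TSS200
  dup <- gm
  dup$betas <- gm$betas[c(1, 1, 2, 2), , drop = FALSE]
  dup$member_keys <- gm$member_keys[c(1, 1, 2, 2)]
  a <- grouped_stats(gm, fx$strat, fx$expr)
  b <- grouped_stats(dup, fx$strat, fx$expr)
  cols <- c("median_up", "median_mid", "median_down", "pearson_r")
  expect_equal(a[cols], b[cols], ignore_attr = TRUE)
})

test_that("pooled tertile sizes sum member finite values", {
  fx <- grouping_fixture()
  gm <- group_by_region(fx$pg)$TSS200
  gm$betas[1, 2] <- NA
  ord <- fx$strat$ordered_samples
  betas <- gm$betas[, ord]
  for (g in c("up", "mid", "down")) {
    ids <- fx$strat[[g]]
    pooled_n <- sum(is.finite(as.vector(betas[, ids])))
    member_n <- sum(vapply(seq_len(nrow(betas)),
                           function(i) sum(is.finite(betas[i, ids])),
                           numeric(1)))
    expect_equal(pooled_n, member_n)
  }
})

test_that("a planted anti-correlated promoter group recovers r < -0.9", {
  # both promoter probes decline affinely in expression, plus small noise
  n <- 30
  expr <- stats::setNames(seq(50, 400, length.out = n),
                          sprintf("s%02d", 1:n))
  strat <- stratify_gene(expr, gene_id = "G1")
  u <- (expr - min(expr)) / diff(range(expr))
  set.seed(13)
  betas <- rbind(
    0.9 - 0.6 * u + rnorm(n, 0, 0.03),
    0.8 - 0.5 * u + rnorm(n, 0, 0.03)
  )
  betas <- pmin(pmax(betas, 0), 1)
  dimnames(betas) <- list(c("cgP_TSS200_G1", "cgQ_TSS200_G1"), names(expr))
  gm <- methylink:::new_grouped_matrix("G1", "TSS200",
                                       rownames(betas), betas,
                                       "region_group")
  out <- grouped_stats(gm, strat, expr)
  expect_lt(out$pearson_r, -0.9)
})

test_that("region matrices partition records; ALL counts distinct probes", {
  run <- reference_run()
  d <- reference_synth()
  probe_tab <- run$tables$cg_individually
  region_tab <- run$tables$cg_by_position
  # per gene, region-group member counts sum to the record count
  for (g in unique(probe_tab$gene)[1:10]) {
    expect_equal(sum(region_tab$n_probes[region_tab$gene == g]),
                 sum(probe_tab$gene == g))
  }
  all_tab <- run$tables$cg_of_genes
  for (g in unique(probe_tab$gene)[1:10]) {
    expect_equal(all_tab$n_probes[all_tab$gene == g],
                 length(unique(probe_tab$probe_id[probe_tab$gene == g])))
  }
})
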