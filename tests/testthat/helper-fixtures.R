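# Fixtures built in code: tiny input files, a constructed annotation table
# exercising all expansion cases, a filter fixture with one violation per
# record, and a cached reference synthetic run shared across test files.

region_levels <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")
island_levels <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf")

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

tiny_expression_file <- function() {
  write_tsv_fixture(c(
    "gene\ts1\ts2\ts3",
    "G1\t1\t2\t3",
    "G2\t0\t0\t0",
    "G3\t5\tNA\t4"
  ))
}

# A raw annotation table (50 rows) covering multi-isoform duplication,
# overlapping genes, exact duplicate triples and open-sea probes.
constructed_annotation <- function() {
  probe_id <- sprintf("cg%08d", 1:50)
  gene_field <- character(50)
  region_field <- character(50)
  island_relation <- rep(NA_character_, 50)
  for (i in 1:40) {
    gene_field[i] <- sprintf("G%02d", (i - 1) %/% 2 + 1)
    region_field[i] <- region_levels[(i - 1) %% 6 + 1]
    island_relation[i] <- c(island_levels, NA_character_)[(i - 1) %% 6 + 1]
  }
  # multi-isoform: same gene, two regions (the dual-key case)
  gene_field[41] <- "ARMCX2;ARMCX2"
  region_field[41] <- "1stExon;5'UTR"
  island_relation[41] <- "N_Shore"
  # overlapping genes: two genes, two regions
  gene_field[42] <- "GA;GB"
  region_field[42] <- "TSS200;3'UTR"
  island_relation[42] <- "Island"
  # exact duplicate triple collapses to one record
  gene_field[43] <- "GC;GC"
  region_field[43] <- "Body;Body"
  island_relation[43] <- NA_character_
  # isoforms repeating one region plus a second region
  gene_field[44] <- "GD;GD;GD"
  region_field[44] <- "TSS1500;TSS1500;Body"
  island_relation[44] <- "S_Shelf"
  # open-sea promoter probe
  gene_field[45] <- "GE"
  region_field[45] <- "TSS200"
  # unannotated probes (no gene)
  gene_field[46:47] <- ""
  region_field[46:47] <- ""
  # gene symbol containing the key separator
  gene_field[48] <- "HLA_X"
  region_field[48] <- "5'UTR"
  island_relation[48] <- "N_Shelf"
  gene_field[49] <- "GF;GG"
  region_field[49] <- "Body;Body"
  island_relation[49] <- "S_Shore"
  gene_field[50] <- "GH"
  region_field[50] <- "3'UTR"
  suppressMessages(probe_annotation(probe_id, gene_field, region_field,
                                    island_relation = island_relation))
}

# One fully passing record in the unified column layout.
passing_record <- function(key = "cgP_Body_G1", gene = "G1") {
  data.frame(
    key = key, gene = gene, probe_id = "cgP", region = "Body",
    island = "Island", level = "probe", n_probes = 1L,
    median_up = 0.2, median_mid = 0.45, median_down = 0.8,
    mean_up = 0.22, mean_mid = 0.46, mean_down = 0.78,
    beta_diff_up_mid = -0.25, beta_diff_up_down = -0.6,
    beta_diff_mid_down = -0.35,
    ks_p_up_mid = 0.004, ks_p_up_down = 0.0001, ks_p_mid_down = 0.006,
    pearson_r = -0.9, pearson_p = 1e-6,
    expr_mean_up = 10, expr_mean_mid = 4, expr_mean_down = 2,
    fc_up_mid = 2.5, fc_up_down = 5, fc_mid_down = 2,
    ttest_p_up_mid = 0.002, ttest_p_up_down = 1e-5,
    ttest_p_mid_down = 0.008,
    stringsAsFactors = FALSE
  )
}

# Six records, each violating exactly one distinct filter at the default
# thresholds (pair selector up_down).
single_violation_fixture <- function() {
  recs <- do.call(rbind, lapply(1:6, function(i) {
    passing_record(key = sprintf("cg%02d_Body_G1", i))
  }))
  recs$median_mid[1] <- 0.9            # breaks monotone medians
  recs$beta_diff_up_down[2] <- -0.05   # breaks |beta-diff| >= 0.1
  recs$ks_p_up_down[3] <- 0.2          # breaks KS p <= 0.01
  recs$fc_up_down[4] <- 1.2            # breaks |FC| >= 2
  recs$ttest_p_up_down[5] <- 0.5       # breaks t-test p <= 0.01
  recs$pearson_p[6] <- 0.3             # breaks Pearson p <= 0.05
  recs
}

# Reference synthetic datasets and pipeline runs, computed once per session.
.fixture_cache <- new.env(parent = emptyenv())

reference_synth <- function() {
  if (is.null(.fixture_cache$synth)) {
    .fixture_cache$synth <- generate_synthetic(synth_spec(seed = 42))
  }
  .fixture_cache$synth
}

reference_run <- function() {
  if (is.null(.fixture_cache$run)) {
    d <- reference_synth()
    .fixture_cache$run <- methylink(d$expression, d$methylation,
                                    d$annotation)
  }
  .fixture_cache$run
}

null_synth <- function() {
  if (is.null(.fixture_cache$null_synth)) {
    # 500 genes x 6 probes: large enough that the Monte-Carlo error of the
    # null KS rate (SE ~ 0.003) is small against the calibration band
    .fixture_cache$null_synth <- generate_synthetic(
      synth_spec(n_genes = 500, effect_slope = 0, seed = 99))
  }
  .fixture_cache$null_synth
}

null_run <- function() {
  if (is.null(.fixture_cache$null_run)) {
    d <- null_synth()
    .fixture_cache$null_run <- methylink(d$expression, d$methylation,
                                         d$annotation)
  }
  .fixture_cache$null_run
}
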