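# Deterministic synthetic fixture generator: expression, methylation and
# annotation inputs with planted promoter/body correlation structure plus a
# truth table, so every pipeline stage is testable without external data.

#' Specification for the synthetic fixture generator
#'
#' Defaults describe the reference study condition used throughout the test
#' suite: 50 genes, 60 samples, one probe per region class (6 probes/gene),
#' 30% of genes with planted promoter anti-correlation, 20% with planted
#' gene-body positive correlation, logistic effect slope 3 per expression
#' z-score and Gaussian measurement noise with sd 0.05 on the beta scale.
#'
#' @param n_genes,n_samples Problem size.
#' @param probes_per_region Named integer vector: probes generated per gene
#'   for each region class.
#' @param fraction_regulated Fraction of genes whose promoter-class probes
#'   (TSS1500, TSS200, 5'UTR) anti-correlate with expression.
#' @param fraction_body_positive Fraction of genes whose Body probes
#'   correlate positively with expression.
#' @param effect_slope Beta-scale logistic slope per unit expression
#'   z-score; 0 makes every probe null.
#' @param noise_sd Gaussian noise sd added on the beta scale (then clipped
#'   to \[0,1\]).
#' @param is_log Whether the expression output is log2(x+1)-transformed.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(n_genes = 50, n_samples = 60,
                       probes_per_region = c("TSS1500" = 1, "TSS200" = 1,
                                             "5'UTR" = 1, "1stExon" = 1,
                                             "Body" = 1, "3'UTR" = 1),
                       fraction_regulated = 0.3,
                       fraction_body_positive = 0.2,
                       effect_slope = 3, noise_sd = 0.05,
                       is_log = FALSE, seed = 1) {
  stopifnot(n_genes >= 1, n_samples >= 1,
            all(names(probes_per_region) %in% REGION_LEVELS),
            all(probes_per_region >= 0),
            fraction_regulated >= 0, fraction_regulated <= 1,
            fraction_body_positive >= 0, fraction_body_positive <= 1,
            fraction_regulated + fraction_body_positive <= 1,
            effect_slope >= 0, noise_sd >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 probes_per_region = probes_per_region,
                 fraction_regulated = fraction_regulated,
                 fraction_body_positive = fraction_body_positive,
                 effect_slope = effect_slope, noise_sd = noise_sd,
                 is_log = is_log, seed = as.integer(seed)),
            class = "synth_spec")
}

# Island-relation sampling probabilities by region class: promoter-class
# probes sit mostly in or near CpG islands, body probes mostly in open sea.
ISLAND_PROBS <- list(
  "TSS1500" = c(Island = .45, N_Shore = .18, S_Shore = .18, N_Shelf = .04,
                S_Shelf = .04, OpenSea = .11),
  "TSS200"  = c(Island = .60, N_Shore = .15, S_Shore = .15, N_Shelf = .02,
                S_Shelf = .02, OpenSea = .06),
  "5'UTR"   = c(Island = .40, N_Shore = .15, S_Shore = .15, N_Shelf = .05,
                S_Shelf = .05, OpenSea = .20),
  "1stExon" = c(Island = .50, N_Shore = .15, S_Shore = .15, N_Shelf = .04,
                S_Shelf = .04, OpenSea = .12),
  "Body"    = c(Island = .08, N_Shore = .08, S_Shore = .08, N_Shelf = .13,
                S_Shelf = .13, OpenSea = .50),
  "3'UTR"   = c(Island = .08, N_Shore = .10, S_Shore = .10, N_Shelf = .11,
                S_Shelf = .11, OpenSea = .50)
)
PROMOTER_REGIONS <- c("TSS1500", "TSS200", "5'UTR")

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate a synthetic methylation-expression dataset
#'
#' Expression is drawn per gene from a log-normal distribution (gene-level
#' baseline and spread drawn once), optionally log2(x+1)-transformed. For
#' regulated genes the promoter-class probes follow
#' `beta = logistic(a - slope * z)` plus clipped Gaussian noise, where `z`
#' is the gene's standardized log-expression; body-positive genes use
#' `+slope` on their Body probes; all other probes are independent of
#' expression. Island relations are assigned per region class with fixed
#' proportions. A truth table records each probe's planted direction so
#' downstream checks never re-derive ground truth from generator internals.
#'
#' @param spec A [synth_spec()].
#' @return List with `expression` (an `expression_matrix`), `methylation`
#'   (a `methylation_matrix`), `annotation` (a `probe_annotation`), `truth`
#'   (data frame: `probe_id`, `gene`, `region`, `island`, `direction` in
#'   -1/0/+1) and `spec`.
#' @export
generate_synthetic <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  ns <- spec$n_samples
  genes <- sprintf("GENE%03d", seq_len(ng))
  samples <- sprintf("S%03d", seq_len(ns))

  # gene classes: planted promoter anti-correlation, planted body positive
  # correlation, or null
  n_reg <- round(spec$fraction_regulated * ng)
  n_body <- round(spec$fraction_body_positive * ng)
  gene_class <- rep("null", ng)
  if (n_reg > 0) gene_class[seq_len(n_reg)] <- "regulated"
  if (n_body > 0) gene_class[n_reg + seq_len(n_body)] <- "body_positive"

  meanlog <- stats::runif(ng, log(100), log(1000))
  sdlog <- stats::runif(ng, 0.4, 0.8)
  expr <- t(vapply(seq_len(ng),
                   function(i) stats::rlnorm(ns, meanlog[i], sdlog[i]),
                   numeric(ns)))
  dimnames(expr) <- list(genes, samples)

  regions <- rep(names(spec$probes_per_region), spec$probes_per_region)
  ppg <- length(regions)
  if (ppg == 0L) stop("spec generates no probes", call. = FALSE)
  n_probes <- ng * ppg
  probe_ids <- sprintf("cg%08d", seq_len(n_probes))

  truth <- data.frame(
    probe_id = probe_ids,
    gene = rep(genes, each = ppg),
    region = rep(regions, times = ng),
    island = NA_character_,
    direction = 0L,
    stringsAsFactors = FALSE
  )
  for (region in unique(regions)) {
    idx <- which(truth$region == region)
    p <- ISLAND_PROBS[[region]]
    truth$island[idx] <- sample(names(p), length(idx), replace = TRUE,
                                prob = p)
  }
  cls <- gene_class[match(truth$gene, genes)]
  truth$direction[cls == "regulated" &
                    truth$region %in% PROMOTER_REGIONS] <- -1L
  truth$direction[cls == "body_positive" & truth$region == "Body"] <- 1L
  # a zero slope plants nothing: every probe is null
  if (spec$effect_slope == 0) truth$direction[] <- 0L

  z <- t(scale(t(log2(expr + 1))))
  beta <- matrix(NA_real_, nrow = n_probes, ncol = ns,
                 dimnames = list(probe_ids, samples))
  intercept <- stats::qlogis(stats::runif(n_probes, 0.25, 0.75))
  for (i in seq_len(n_probes)) {
    zi <- z[truth$gene[i], ]
    core <- if (truth$direction[i] == 0L) {
      stats::plogis(intercept[i] + stats::rnorm(ns, 0, 0.7))
    } else {
      stats::plogis(intercept[i] + truth$direction[i] * spec$effect_slope * zi)
    }
    beta[i, ] <- clip01(core + stats::rnorm(ns, 0, spec$noise_sd))
  }

  ann <- probe_annotation(
    probe_id = truth$probe_id,
    gene_field = truth$gene,
    region_field = truth$region,
    island_name = ifelse(truth$island == OPEN_SEA, NA_character_,
                         paste0("chr1:", seq_len(n_probes))),
    island_relation = ifelse(truth$island == OPEN_SEA, NA_character_,
                             truth$island)
  )

  expr_out <- if (spec$is_log) log2(expr + 1) else expr
  list(expression = expression_matrix(expr_out, is_log = spec$is_log),
       methylation = methylation_matrix(beta),
       annotation = ann,
       truth = truth,
       spec = spec)
}

#' Write a synthetic dataset to disk
#'
#' Writes `expression.tsv`, `methylation.tsv`, `annotation.tsv` and
#' `truth.tsv` into `dir` in the dialects the readers accept.
#'
#' @param data Result of [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_synthetic <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_matrix(data$expression, file.path(dir, "expression.tsv"))
  write_methylation_matrix(data$methylation, file.path(dir, "methylation.tsv"))
  write_probe_annotation(data$annotation, file.path(dir, "annotation.tsv"))
  utils::write.table(data$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
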