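# Grouped methylation matrices per gene: by gene region, by CpG-island
# relation, and whole-gene, with group-level statistics.

new_grouped_matrix <- function(gene, label, member_keys, betas, level) {
  structure(list(gene = gene, label = label, member_keys = member_keys,
                 betas = betas, level = level),
            class = "grouped_matrix")
}

#' Group a gene's probes by gene region
#'
#' One grouped matrix per region class (TSS1500, TSS200, 5'UTR, 1stExon,
#' Body, 3'UTR) occupied by the gene's records. A probe annotated to two
#' regions of the same gene contributes to both region groups.
#'
#' @param pg Per-gene records with beta rows, from [probes_for_gene()].
#' @return Named list of `grouped_matrix` objects (possibly empty).
#' @export
group_by_region <- function(pg) {
  out <- list()
  for (region in REGION_LEVELS) {
    idx <- which(pg$records$region == region)
    if (!length(idx)) next
    out[[region]] <- new_grouped_matrix(
      gene = pg$records$gene[idx[1L]], label = region,
      member_keys = pg$records$key[idx],
      betas = pg$betas[idx, , drop = FALSE], level = "region_group")
  }
  out
}

#' Group a gene's probes by CpG-island relation
#'
#' One grouped matrix per island relation (Island, N_Shore, S_Shore,
#' N_Shelf, S_Shelf) occupied by the gene's records. A probe's island
#' relation is a probe property, so probes are deduplicated by probe id
#' within each relation; open-sea probes take part in no island group.
#'
#' @inheritParams group_by_region
#' @return Named list of `grouped_matrix` objects.
#' @export
group_by_island <- function(pg) {
  out <- list()
  for (rel in ISLAND_LEVELS) {
    idx <- which(pg$records$island == rel)
    idx <- idx[!duplicated(pg$records$probe_id[idx])]
    if (!length(idx)) next
    betas <- pg$betas[idx, , drop = FALSE]
    rownames(betas) <- pg$records$probe_id[idx]
    out[[rel]] <- new_grouped_matrix(
      gene = pg$records$gene[idx[1L]], label = rel,
      member_keys = pg$records$probe_id[idx],
      betas = betas, level = "island_group")
  }
  out
}

#' Group all probes of a gene
#'
#' Single grouped matrix over the gene's distinct probes (deduplicated by
#' probe id), labelled `"ALL"`, for whole-gene methylation analysis.
#'
#' @inheritParams group_by_region
#' @return A `grouped_matrix`, or `NULL` when the gene has no measured
#'   probes.
#' @export
group_all <- function(pg) {
  idx <- which(!duplicated(pg$records$probe_id))
  if (!length(idx)) return(NULL)
  betas <- pg$betas[idx, , drop = FALSE]
  rownames(betas) <- pg$records$probe_id[idx]
  new_grouped_matrix(gene = pg$records$gene[idx[1L]], label = "ALL",
                     member_keys = pg$records$probe_id[idx],
                     betas = betas, level = "gene_group")
}

#' Group-level methylation statistics
#'
#' The member probes' beta values are re-indexed to the gene's
#' descending-expression sample order, then pooled within each expression
#' tertile: medians, means and beta-differences are computed on the pooled
#' values, and the KS test contrasts pooled tertile value sets
#' (`ks_pooling = "pooled"`, the default) or the per-sample median profile
#' (`ks_pooling = "summary"`, for sensitivity analysis). The Pearson
#' correlation pairs each sample's expression with its median beta across
#' member probes, so the sample size is not inflated by pooling.
#'
#' @param gm A `grouped_matrix`.
#' @param strat The owning gene's `gene_stratification`.
#' @param expr_row Named numeric vector of the gene's expression values.
#' @param ks_pooling `"pooled"` or `"summary"`.
#' @return One-row data frame in the unified result-column layout; the key
#'   is `<gene>_<label>`.
#' @export
grouped_stats <- function(gm, strat, expr_row,
                          ks_pooling = c("pooled", "summary")) {
  ks_pooling <- match.arg(ks_pooling)
  ord <- strat$ordered_samples
  betas <- matrix(NA_real_, nrow = nrow(gm$betas), ncol = length(ord),
                  dimnames = list(rownames(gm$betas), ord))
  shared <- intersect(ord, colnames(gm$betas))
  betas[, shared] <- gm$betas[, shared]

  pools <- lapply(strat[c("up", "mid", "down")], function(ids) {
    v <- as.vector(betas[, ids, drop = FALSE])
    v[is.finite(v)]
  })
  medians <- vapply(pools, function(v) if (length(v)) stats::median(v)
                    else NA_real_, numeric(1))
  means <- vapply(pools, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1))

  if (ks_pooling == "pooled") {
    ks <- vapply(PAIRS, function(p) ks_test(pools[[p[1L]]], pools[[p[2L]]]),
                 numeric(1))
  } else {
    prof <- apply(betas, 2L, stats::median, na.rm = TRUE)
    grp <- lapply(strat[c("up", "mid", "down")], function(ids) prof[ids])
    ks <- vapply(PAIRS, function(p) ks_test(grp[[p[1L]]], grp[[p[2L]]]),
                 numeric(1))
  }

  profile <- apply(betas, 2L, function(col) {
    col <- col[is.finite(col)]
    if (length(col)) stats::median(col) else NA_real_
  })
  pe <- pearson_corr(unname(expr_row[ord]), unname(profile))

  n_probes <- length(unique(parse_key(gm$member_keys)$probe_id))
  if (gm$level != "region_group") n_probes <- length(gm$member_keys)
  make_stat_record(
    key = paste(gm$gene, gm$label, sep = "_"), gene = gm$gene,
    probe_id = NA_character_,
    region = if (gm$level == "region_group") gm$label else NA_character_,
    island = if (gm$level == "island_group") gm$label else NA_character_,
    level = gm$level, n_probes = n_probes,
    medians = medians, means = means, ks = ks, pearson = pe, strat = strat)
}
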