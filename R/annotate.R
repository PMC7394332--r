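# Expansion of raw 450k-style annotation into one-to-one
# probe-gene-region records and attachment of per-gene beta rows.

#' Build a composite record key
#'
#' Keys follow the `probeid_region_gene` layout (e.g.
#' `cg02626719_1stExon_ARMCX2`). Probe ids and the six region labels never
#' contain `"_"`, so [parse_key()] splits from the left at most twice and
#' gene symbols containing underscores survive a round trip.
#'
#' @param probe_id,region,gene Character vectors (recycled).
#' @return Character vector of keys.
#' @export
make_key <- function(probe_id, region, gene) {
  paste(probe_id, region, gene, sep = "_")
}

#' @rdname make_key
#' @param key Character vector of composite keys.
#' @return For `parse_key()`, a data frame with columns `probe_id`,
#'   `region`, `gene`.
#' @export
parse_key <- function(key) {
  parts <- strsplit(key, "_", fixed = TRUE)
  data.frame(
    probe_id = vapply(parts, `[`, character(1), 1L),
    region = vapply(parts, `[`, character(1), 2L),
    gene = vapply(parts, function(p) paste(p[-(1:2)], collapse = "_"),
                  character(1)),
    stringsAsFactors = FALSE
  )
}

#' Expand raw annotation into one-to-one probe-gene-region records
#'
#' Each raw row's positionally paired (gene, region) lists are exploded into
#' individual records, so probes annotated to several transcript isoforms or
#' overlapping genes appear once per distinct (probe, gene, region) triple;
#' exact duplicate triples collapse to a single record. The island relation
#' is copied to every derived record; probes with no relation are classed
#' `OpenSea`. Probes with an empty gene field yield no records.
#'
#' @param ann A `probe_annotation` data frame from
#'   [read_probe_annotation()] or [probe_annotation()].
#' @return A data frame of class `annotation_records` with columns `key`,
#'   `probe_id`, `gene`, `region`, `island`; `key` is unique.
#' @export
expand_annotation <- function(ann) {
  stopifnot(inherits(ann, "probe_annotation"))
  delim <- attr(ann, "delim")
  if (is.null(delim)) delim <- ";"
  ann <- ann[ann$annotated, , drop = FALSE]
  genes <- strsplit(ann$gene_field, delim, fixed = TRUE)
  regions <- strsplit(ann$region_field, delim, fixed = TRUE)
  n <- lengths(genes)
  rec <- data.frame(
    probe_id = rep(ann$probe_id, n),
    gene = unlist(genes, use.names = FALSE),
    region = unlist(regions, use.names = FALSE),
    island = rep(ifelse(is.na(ann$island_relation), OPEN_SEA,
                        ann$island_relation), n),
    stringsAsFactors = FALSE
  )
  rec <- rec[!duplicated(rec[c("probe_id", "gene", "region")]), , drop = FALSE]
  rec$key <- make_key(rec$probe_id, rec$region, rec$gene)
  rownames(rec) <- NULL
  rec <- rec[c("key", "probe_id", "gene", "region", "island")]
  class(rec) <- c("annotation_records", "data.frame")
  rec
}

#' Collect a gene's annotated probes with their beta rows
#'
#' Returns every expanded record of `gene` whose probe is present in the
#' methylation matrix, paired with that probe's beta row. Records whose
#' probe was not measured are dropped and counted.
#'
#' @param records Expanded records from [expand_annotation()].
#' @param gene Gene symbol.
#' @param meth Methylation matrix (probes x samples).
#' @return List with `records` (the matching rows), `betas` (numeric matrix,
#'   one row per record, rownames = record keys), and `n_dropped`.
#' @export
probes_for_gene <- function(records, gene, meth) {
  sub <- records[records$gene == gene, , drop = FALSE]
  measured <- sub$probe_id %in% rownames(meth)
  n_dropped <- sum(!measured)
  sub <- sub[measured, , drop = FALSE]
  betas <- unclass(meth)[sub$probe_id, , drop = FALSE]
  rownames(betas) <- sub$key
  list(records = sub, betas = betas, n_dropped = n_dropped)
}

#' Reorder a beta row to a gene's expression order
#'
#' Re-indexes a probe's beta values to the descending-expression sample
#' order of the owning gene. Samples missing from the beta row yield `NA`
#' in their slot.
#'
#' @param beta_row Named numeric vector of beta values.
#' @param ordered_samples Character vector of sample ids, or a
#'   `gene_stratification` whose order is used.
#' @return Named numeric vector aligned to `ordered_samples`.
#' @export
reorder_betas <- function(beta_row, ordered_samples) {
  if (inherits(ordered_samples, "gene_stratification")) {
    ordered_samples <- ordered_samples$ordered_samples
  }
  out <- beta_row[ordered_samples]
  names(out) <- ordered_samples
  out
}
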