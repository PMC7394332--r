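#' @keywords internal
"_PACKAGE"

# Controlled vocabularies of the Infinium 450k (GPL13534) annotation layout.
REGION_LEVELS <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")
ISLAND_LEVELS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf")
OPEN_SEA <- "OpenSea"

# Unified column set shared by the four result tables.
STAT_COLUMNS <- c(
  "key", "gene", "probe_id", "region", "island", "level", "n_probes",
  "median_up", "median_mid", "median_down",
  "mean_up", "mean_mid", "mean_down",
  "beta_diff_up_mid", "beta_diff_up_down", "beta_diff_mid_down",
  "ks_p_up_mid", "ks_p_up_down", "ks_p_mid_down",
  "pearson_r", "pearson_p",
  "expr_mean_up", "expr_mean_mid", "expr_mean_down",
  "fc_up_mid", "fc_up_down", "fc_mid_down",
  "ttest_p_up_mid", "ttest_p_up_down", "ttest_p_mid_down"
)

RESULT_FILES <- c(
  cg_individually = "CG_Individually.csv",
  cg_by_position  = "CG_by_position.csv",
  cg_island       = "CG_Island.csv",
  cg_of_genes     = "CG_of_genes.csv"
)

# Detect the field separator of a delimited text file: tab by default,
# falling back to comma when the header contains no tab.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, sep = detect_sep(path), header = TRUE,
                    quote = "\"", comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = c("NA", ""))
}

# Convert the character body of a just-read table to a numeric matrix,
# reporting the first offending cell on failure.
as_numeric_matrix <- function(df, id_label) {
  ids <- df[[1L]]
  body <- df[-1L]
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(body),
                dimnames = list(ids, colnames(body)))
  for (j in seq_along(body)) {
    raw <- body[[j]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad)) {
      stop(sprintf("non-numeric value %s at row %d (%s '%s'), column '%s'",
                   dQuote(raw[bad[1L]]), bad[1L], id_label, ids[bad[1L]],
                   colnames(body)[j]), call. = FALSE)
    }
    mat[, j] <- val
  }
  mat
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s id(s): %s (collapse input to unique ids first)",
                 what, paste(utils::head(dup, 10L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(ids)
}

#' Read a gene expression matrix
#'
#' Loads a delimited (TSV, falling back to CSV) genes-by-samples expression
#' table. The first column holds gene identifiers, the header holds sample
#' identifiers. Gene rows that are entirely missing or zero carry no signal
#' and are removed before analysis.
#'
#' @param path Path to the delimited file.
#' @param is_log Logical; `TRUE` declares the values are on the log2(x+1)
#'   scale, `FALSE` declares linear scale. The flag controls how fold
#'   changes are computed downstream (see [calc_fc()]).
#' @return An object of class `expression_matrix`: a list with `values`
#'   (numeric matrix, genes x samples), `is_log`, and `n_dropped` (count of
#'   all-null/all-zero rows removed).
#' @seealso [read_methylation_matrix()], [read_probe_annotation()]
#' @export
read_expression_matrix <- function(path, is_log = FALSE) {
  df <- read_delim_auto(path)
  check_unique_ids(df[[1L]], "gene")
  mat <- as_numeric_matrix(df, "gene")
  expression_matrix(mat, is_log = is_log)
}

#' Construct an expression matrix object from a numeric matrix
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @inheritParams read_expression_matrix
#' @return An `expression_matrix` object; see [read_expression_matrix()].
#' @export
expression_matrix <- function(values, is_log = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  check_unique_ids(rownames(values), "gene")
  empty <- apply(values, 1L, function(v) all(is.na(v) | v == 0))
  n_dropped <- sum(empty)
  if (n_dropped) {
    message(n_dropped, " gene row(s) removed: all values null or zero")
    values <- values[!empty, , drop = FALSE]
  }
  structure(list(values = values, is_log = is_log, n_dropped = n_dropped),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s scale, %d empty rows dropped)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_log) "log2(x+1)" else "linear", x$n_dropped))
  invisible(x)
}

#' Read a methylation beta-value matrix
#'
#' Loads a delimited probes-by-samples table of beta values. Beta values are
#' the ratio of methylated to total signal and must lie in \[0, 1\]. Missing
#' cells are kept as `NA` (never imputed); every downstream statistic drops
#' missing values pairwise.
#'
#' @param path Path to the delimited file; first column probe id, header
#'   sample ids.
#' @return A numeric matrix (probes x samples) of class `methylation_matrix`.
#' @export
read_methylation_matrix <- function(path) {
  df <- read_delim_auto(path)
  check_unique_ids(df[[1L]], "probe")
  mat <- as_numeric_matrix(df, "probe")
  methylation_matrix(mat)
}

#' Construct a methylation matrix object
#'
#' @param values Numeric matrix of beta values in \[0,1\] (NA allowed),
#'   probes in rows, samples in columns.
#' @return The validated matrix with class `methylation_matrix`.
#' @export
methylation_matrix <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  check_unique_ids(rownames(values), "probe")
  bad <- which(is.finite(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("beta value out of [0,1] for probe '%s' (value %g)",
                 rownames(values)[bad[1L, 1L]], values[bad[1L, , drop = FALSE]]),
         call. = FALSE)
  }
  structure(values, class = c("methylation_matrix", "matrix", "array"))
}

#' Read an Infinium 450k-style probe annotation table
#'
#' Parses a GPL13534-layout annotation table linking each CpG probe to its
#' gene symbol(s), gene region group(s) (TSS1500, TSS200, 5'UTR, 1stExon,
#' Body, 3'UTR) and CpG-island relation (Island, N/S_Shore, N/S_Shelf, or
#' empty for open sea). The gene and region fields are positionally paired
#' delimited lists, one entry per transcript isoform or overlapping gene.
#'
#' Column names are matched case-insensitively against both the canonical
#' platform names (`IlmnID`/`ID`, `UCSC_RefGene_Name`, `UCSC_RefGene_Group`,
#' `Relation_to_UCSC_CpG_Island`, `UCSC_CpG_Islands_Name`) and plain names
#' (`probe_id`, `gene`, `region`, `island_relation`, `island_name`).
#'
#' @param path Path to the delimited annotation file.
#' @param delim Delimiter separating entries inside the gene/region list
#'   fields (default `";"`).
#' @return A data frame of class `probe_annotation` with columns `probe_id`,
#'   `gene_field`, `region_field`, `island_name`, `island_relation`, and
#'   `annotated` (FALSE when the gene field is empty).
#' @export
read_probe_annotation <- function(path, delim = ";") {
  df <- read_delim_auto(path)
  nm <- tolower(colnames(df))
  pick <- function(cands, required = TRUE) {
    hit <- which(nm %in% tolower(cands))
    if (!length(hit)) {
      if (required)
        stop("annotation is missing a column for ", cands[1L], call. = FALSE)
      return(NULL)
    }
    df[[hit[1L]]]
  }
  ann <- data.frame(
    probe_id = pick(c("probe_id", "IlmnID", "ID", "ID_REF", "Name", "probe")),
    gene_field = pick(c("gene", "UCSC_RefGene_Name", "gene_symbol", "genes")),
    region_field = pick(c("region", "UCSC_RefGene_Group", "gene_region",
                          "regions")),
    stringsAsFactors = FALSE
  )
  isl_name <- pick(c("island_name", "UCSC_CpG_Islands_Name"), required = FALSE)
  isl_rel <- pick(c("island_relation", "Relation_to_UCSC_CpG_Island",
                    "island"), required = FALSE)
  ann$island_name <- if (is.null(isl_name)) NA_character_ else isl_name
  ann$island_relation <- if (is.null(isl_rel)) NA_character_ else isl_rel
  validate_annotation(ann, delim = delim)
}

# Vocabulary and pairing checks shared by the reader and in-memory input.
validate_annotation <- function(ann, delim = ";") {
  check_unique_ids(ann$probe_id, "annotation probe")
  ann$gene_field[is.na(ann$gene_field)] <- ""
  ann$region_field[is.na(ann$region_field)] <- ""
  ann$island_relation[!is.na(ann$island_relation) &
                        ann$island_relation == ""] <- NA_character_
  bad_rel <- setdiff(unique(ann$island_relation[!is.na(ann$island_relation)]),
                     ISLAND_LEVELS)
  if (length(bad_rel)) {
    stop("unknown island relation label(s): ",
         paste(bad_rel, collapse = ", "), call. = FALSE)
  }
  genes <- strsplit(ann$gene_field, delim, fixed = TRUE)
  regions <- strsplit(ann$region_field, delim, fixed = TRUE)
  n_g <- lengths(genes)
  n_r <- lengths(regions)
  ragged <- which(n_g != n_r)
  if (length(ragged)) {
    stop(sprintf("gene/region lists have different lengths for probe '%s' (%d vs %d)",
                 ann$probe_id[ragged[1L]], n_g[ragged[1L]], n_r[ragged[1L]]),
         call. = FALSE)
  }
  bad_reg <- setdiff(unique(unlist(regions)), REGION_LEVELS)
  if (length(bad_reg)) {
    stop("unknown gene region label(s): ", paste(bad_reg, collapse = ", "),
         call. = FALSE)
  }
  ann$annotated <- n_g > 0L
  if (any(!ann$annotated)) {
    message(sum(!ann$annotated), " probe(s) without gene annotation retained but flagged")
  }
  attr(ann, "delim") <- delim
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Construct a probe annotation table from vectors
#'
#' In-memory counterpart of [read_probe_annotation()]; used by the synthetic
#' generator and tests.
#'
#' @param probe_id,gene_field,region_field Character vectors; `gene_field`
#'   and `region_field` are `delim`-separated positionally paired lists.
#' @param island_name,island_relation Optional character vectors.
#' @param delim List-field delimiter.
#' @return A `probe_annotation` data frame.
#' @export
probe_annotation <- function(probe_id, gene_field, region_field,
                             island_name = NA_character_,
                             island_relation = NA_character_, delim = ";") {
  ann <- data.frame(probe_id = probe_id, gene_field = gene_field,
                    region_field = region_field,
                    island_name = island_name,
                    island_relation = island_relation,
                    stringsAsFactors = FALSE)
  validate_annotation(ann, delim = delim)
}

# Stable result-table ordering: gene id then key, lexicographic in the C
# locale so output bytes never depend on the session locale.
order_stat_table <- function(tab) {
  tab[order(tab$gene, tab$key, method = "radix"), , drop = FALSE]
}

empty_stat_table <- function() {
  tab <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(STAT_COLUMNS)),
                    STAT_COLUMNS), stringsAsFactors = FALSE)
  num <- setdiff(STAT_COLUMNS,
                 c("key", "gene", "probe_id", "region", "island", "level"))
  for (cn in num) tab[[cn]] <- numeric(0)
  tab$n_probes <- integer(0)
  tab
}

#' Write the four result tables
#'
#' Writes `CG_Individually.csv`, `CG_by_position.csv`, `CG_Island.csv` and
#' `CG_of_genes.csv` into `outdir`, comma-separated, with the documented
#' column set, rows ordered by gene id then key (C-locale lexicographic) and
#' missing statistics written as `"NA"`. Re-running on the same input
#' produces byte-identical files.
#'
#' @param results A [methylink()] result, or a named list with elements
#'   `cg_individually`, `cg_by_position`, `cg_island`, `cg_of_genes`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths of the four files written.
#' @export
write_result_tables <- function(results, outdir) {
  tabs <- if (inherits(results, "methylink")) results$tables else results
  stopifnot(all(names(RESULT_FILES) %in% names(tabs)))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(RESULT_FILES)) {
    tab <- order_stat_table(as.data.frame(tabs[[nm]]))
    path <- file.path(outdir, RESULT_FILES[[nm]])
    utils::write.csv(tab, path, row.names = FALSE, na = "NA", quote = TRUE,
                     eol = "\n")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read previously written result tables
#'
#' @param outdir Directory containing the four result CSVs.
#' @return A named list of the four data frames.
#' @export
read_result_tables <- function(outdir) {
  out <- list()
  for (nm in names(RESULT_FILES)) {
    path <- file.path(outdir, RESULT_FILES[[nm]])
    if (!file.exists(path)) stop("missing result table: ", path, call. = FALSE)
    out[[nm]] <- utils::read.csv(path, stringsAsFactors = FALSE,
                                 check.names = FALSE,
                                 colClasses = c(key = "character",
                                                gene = "character"))
  }
  out
}

# Writers for the three input formats (used by the generator and tests so
# that read(write(x)) round-trips exactly).

#' Write input matrices and annotation in the accepted dialects
#'
#' `write_expression_matrix()` and `write_methylation_matrix()` emit
#' tab-separated id + samples tables; `write_probe_annotation()` emits the
#' annotation layout [read_probe_annotation()] accepts.
#'
#' @param x Object to write.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path) {
  values <- if (inherits(x, "expression_matrix")) x$values else x
  write_id_matrix(values, "gene", path)
}

#' @rdname write_expression_matrix
#' @export
write_methylation_matrix <- function(x, path) {
  write_id_matrix(unclass(x), "probe_id", path)
}

write_id_matrix <- function(values, id_col, path) {
  # 17 significant digits guarantee an exact double round trip
  chr <- matrix(sprintf("%.17g", values), nrow = nrow(values),
                dimnames = dimnames(values))
  chr[is.na(values)] <- "NA"
  df <- data.frame(rownames(values), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(values))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
write_probe_annotation <- function(x, path) {
  df <- as.data.frame(x)[c("probe_id", "gene_field", "region_field",
                           "island_name", "island_relation")]
  colnames(df) <- c("probe_id", "gene", "region", "island_name",
                    "island_relation")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
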