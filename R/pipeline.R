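# End-to-end driver: stratify each gene, attach annotated probes, compute
# probe-level and grouped statistics, and assemble the four result tables.

as_expression <- function(x, is_log) {
  if (inherits(x, "expression_matrix")) return(x)
  expression_matrix(as.matrix(x), is_log = is_log)
}

as_methylation <- function(x) {
  if (inherits(x, "methylation_matrix")) return(x)
  methylation_matrix(as.matrix(x))
}

# Full analysis of one gene: returns the four per-gene table chunks.
analyze_gene <- function(gene, expr_row, records, meth, is_log, ks_pooling) {
  strat <- stratify_gene(expr_row, is_log = is_log, gene_id = gene)
  if (is.null(strat)) {
    return(list(skipped = "fewer than 3 finite expression values"))
  }
  pg <- probes_for_gene(records, gene, meth)
  if (!nrow(pg$records)) {
    return(list(skipped = "no measured annotated probes",
                probes_dropped = pg$n_dropped))
  }
  probe_rows <- lapply(seq_len(nrow(pg$records)), function(i) {
    probe_stats(pg$records[i, ], pg$betas[i, ], strat, expr_row)
  })
  region_rows <- lapply(group_by_region(pg), grouped_stats, strat = strat,
                        expr_row = expr_row, ks_pooling = ks_pooling)
  island_rows <- lapply(group_by_island(pg), grouped_stats, strat = strat,
                        expr_row = expr_row, ks_pooling = ks_pooling)
  all_gm <- group_all(pg)
  list(
    cg_individually = do.call(rbind, probe_rows),
    cg_by_position = if (length(region_rows)) do.call(rbind, region_rows),
    cg_island = if (length(island_rows)) do.call(rbind, island_rows),
    cg_of_genes = grouped_stats(all_gm, strat, expr_row,
                                ks_pooling = ks_pooling),
    probes_dropped = pg$n_dropped
  )
}

#' Integrated methylation-expression analysis
#'
#' Runs the full pipeline: the sample universe is restricted to samples
#' present in both matrices; each analyzable gene's samples are stratified
#' into Up/Medium/Down expression tertiles ([stratify_gene()]); the gene's
#' annotated probes are collected ([expand_annotation()],
#' [probes_for_gene()]) and per-probe statistics computed
#' ([probe_stats()]); probes are then grouped by gene region, island
#' relation and whole gene ([grouped_stats()]). Genes are processed in
#' batches (memory bound) and optionally in parallel; results are merged
#' and sorted deterministically, so output is identical for any worker
#' count or batch partition.
#'
#' @param expression An `expression_matrix` (or plain genes x samples
#'   matrix).
#' @param methylation A `methylation_matrix` (or plain probes x samples
#'   matrix of beta values).
#' @param annotation A `probe_annotation` table.
#' @param is_log Scale flag used when `expression` is a plain matrix.
#' @param genes Optional character vector restricting the analysis.
#' @param batch_size Genes per processing batch (default 1000).
#' @param workers Parallel workers (forked; >1 needs a unix-alike).
#' @param ks_pooling Group-level KS mode, see [grouped_stats()].
#' @return Object of class `methylink`: list with `tables` (the four result
#'   data frames `cg_individually`, `cg_by_position`, `cg_island`,
#'   `cg_of_genes`), `log` (genes analyzed/skipped with reasons, probes
#'   dropped, samples used) and `call`.
#' @examples
#' d <- generate_synthetic(synth_spec(n_genes = 5, n_samples = 30, seed = 7))
#' res <- methylink(d$expression, d$methylation, d$annotation)
#' res
#' head(summary(res))
#' @export
methylink <- function(expression, methylation, annotation, is_log = FALSE,
                      genes = NULL, batch_size = 1000, workers = 1,
                      ks_pooling = c("pooled", "summary")) {
  ks_pooling <- match.arg(ks_pooling)
  stopifnot(batch_size >= 1, workers >= 1)
  expression <- as_expression(expression, is_log)
  methylation <- as_methylation(methylation)
  stopifnot(inherits(annotation, "probe_annotation"))

  samples <- sort(intersect(colnames(expression$values),
                            colnames(methylation)), method = "radix")
  if (!length(samples)) {
    stop("expression and methylation share no sample ids", call. = FALSE)
  }
  expr <- expression$values[, samples, drop = FALSE]
  meth <- unclass(methylation)[, samples, drop = FALSE]

  records <- expand_annotation(annotation)
  unmatched <- setdiff(unique(records$gene), rownames(expr))
  gene_set <- intersect(rownames(expr), unique(records$gene))
  if (!is.null(genes)) gene_set <- intersect(gene_set, genes)
  gene_set <- sort(gene_set, method = "radix")
  if (!length(gene_set)) stop("no analyzable genes", call. = FALSE)

  batches <- split(gene_set, ceiling(seq_along(gene_set) / batch_size))
  run_batch <- function(batch_genes) {
    lapply(batch_genes, function(g) {
      analyze_gene(g, expr[g, ], records, meth, expression$is_log,
                   ks_pooling)
    })
  }
  per_gene <- if (workers > 1 && .Platform$OS.type == "unix") {
    unlist(parallel::mclapply(batches, run_batch, mc.cores = workers),
           recursive = FALSE, use.names = FALSE)
  } else {
    unlist(lapply(batches, run_batch), recursive = FALSE, use.names = FALSE)
  }
  names(per_gene) <- gene_set

  skipped <- vapply(per_gene, function(x) x$skipped %||% NA_character_,
                    character(1))
  analyzed <- is.na(skipped)
  probes_dropped <- sum(vapply(per_gene, function(x) {
    x$probes_dropped %||% 0L
  }, numeric(1)))

  bind_tab <- function(nm) {
    chunks <- Filter(Negate(is.null), lapply(per_gene[analyzed], `[[`, nm))
    if (!length(chunks)) return(empty_stat_table())
    tab <- do.call(rbind, chunks)
    rownames(tab) <- NULL
    order_stat_table(tab)
  }
  tables <- lapply(stats::setNames(names(RESULT_FILES),
                                   names(RESULT_FILES)), bind_tab)

  log <- list(
    n_samples = length(samples),
    samples = samples,
    n_genes_analyzed = sum(analyzed),
    genes_skipped = skipped[!analyzed],
    n_probes_dropped = probes_dropped,
    unmatched_annotation_genes = unmatched,
    n_unannotated_probes = sum(!annotation$annotated)
  )
  structure(list(tables = tables, log = log, call = match.call()),
            class = "methylink")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.methylink <- function(x, ...) {
  cat("methylink analysis\n")
  cat(sprintf("  samples: %d (expression/methylation intersection)\n",
              x$log$n_samples))
  cat(sprintf("  genes analyzed: %d (skipped: %d)\n",
              x$log$n_genes_analyzed, length(x$log$genes_skipped)))
  for (nm in names(x$tables)) {
    cat(sprintf("  %-16s %d record(s)\n", nm, nrow(x$tables[[nm]])))
  }
  invisible(x)
}

#' Summarize a methylink analysis
#'
#' @param object A `methylink` result.
#' @param alpha Significance level used to count nominally significant
#'   Pearson correlations.
#' @param ... Unused.
#' @return Data frame with one row per result table: record count, number
#'   and direction of nominally significant correlations.
#' @export
summary.methylink <- function(object, alpha = 0.05, ...) {
  rows <- lapply(names(object$tables), function(nm) {
    tab <- object$tables[[nm]]
    sig <- !is.na(tab$pearson_p) & tab$pearson_p <= alpha
    data.frame(table = nm, records = nrow(tab), significant = sum(sig),
               positive_r = sum(sig & tab$pearson_r > 0),
               negative_r = sum(sig & tab$pearson_r < 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pipeline run configuration
#'
#' Collects file paths and options for a file-to-file pipeline run; the
#' counterpart of the command-line interface. A YAML file with the same
#' field names can be loaded with [read_run_config()].
#'
#' @param expression,methylation,annotation Input file paths.
#' @param outdir Output directory.
#' @param is_log Expression scale flag.
#' @param genes,batch_size,workers,ks_pooling See [methylink()].
#' @param filter A [filter_config()] used by [run_filters()].
#' @param delim Annotation list-field delimiter.
#' @param seed Integer seed for any stochastic subroutine (the analysis
#'   itself is deterministic; the seed feeds the synthetic generator when
#'   used from the command line).
#' @return Object of class `run_config`.
#' @export
run_config <- function(expression, methylation, annotation, outdir,
                       is_log = FALSE, genes = NULL, batch_size = 1000,
                       workers = 1, ks_pooling = "pooled",
                       filter = filter_config(), delim = ";", seed = NULL) {
  structure(list(expression = expression, methylation = methylation,
                 annotation = annotation, outdir = outdir, is_log = is_log,
                 genes = genes, batch_size = batch_size, workers = workers,
                 ks_pooling = ks_pooling, filter = filter, delim = delim,
                 seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file; top-level fields mirror the [run_config()]
#'   arguments, with filter thresholds under a `filter:` mapping.
#' @param ... Overrides applied on top of the file's values.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  fcfg <- do.call(filter_config, y$filter %||% list())
  y$filter <- NULL
  overrides <- list(...)
  y[names(overrides)] <- overrides
  do.call(run_config, c(y, list(filter = fcfg)))
}

#' Run the pipeline from files to files
#'
#' Reads the three inputs, runs [methylink()], writes the four result
#' tables into `cfg$outdir` and a machine-readable `run_summary.json`
#' alongside them.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the `methylink` result.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  expression <- read_expression_matrix(cfg$expression, is_log = cfg$is_log)
  methylation <- read_methylation_matrix(cfg$methylation)
  annotation <- read_probe_annotation(cfg$annotation, delim = cfg$delim)
  res <- methylink(expression, methylation, annotation, genes = cfg$genes,
                   batch_size = cfg$batch_size, workers = cfg$workers,
                   ks_pooling = cfg$ks_pooling)
  write_result_tables(res, cfg$outdir)
  summary_path <- file.path(cfg$outdir, "run_summary.json")
  jsonlite::write_json(
    list(n_samples = res$log$n_samples,
         n_genes_analyzed = res$log$n_genes_analyzed,
         n_genes_skipped = length(res$log$genes_skipped),
         n_probes_dropped = res$log$n_probes_dropped,
         n_unannotated_probes = res$log$n_unannotated_probes,
         expression_rows_dropped = expression$n_dropped),
    summary_path, auto_unbox = TRUE)
  message("pipeline complete: ", res$log$n_genes_analyzed,
          " genes analyzed, tables written to ", cfg$outdir)
  invisible(res)
}

#' Run the filter cascade from files to files
#'
#' Reads the four result tables from `cfg$outdir`, applies
#' [filter_cascade()] with `cfg$filter`, and writes `*_filtered.csv` per
#' table plus `direction_summary.csv`, `top_positive.csv` and
#' `top_negative.csv` into `filtered_dir`.
#'
#' @param cfg A [run_config()] (only `outdir` and `filter` are used).
#' @param filtered_dir Output directory; defaults to
#'   `file.path(cfg$outdir, "filtered")`.
#' @return Invisibly, the `methylink_filtered` object.
#' @export
run_filters <- function(cfg, filtered_dir = file.path(cfg$outdir,
                                                      "filtered")) {
  tabs <- read_result_tables(cfg$outdir)
  fc <- filter_cascade(tabs, cfg$filter)
  if (!dir.exists(filtered_dir)) dir.create(filtered_dir, recursive = TRUE)
  for (nm in names(fc$tables)) {
    utils::write.csv(order_stat_table(fc$tables[[nm]]),
                     file.path(filtered_dir,
                               sub("\\.csv$", "_filtered.csv",
                                   RESULT_FILES[[nm]])),
                     row.names = FALSE, na = "NA", eol = "\n")
  }
  dir_rows <- list()
  for (nm in names(fc$directions)) {
    for (by in names(fc$directions[[nm]])) {
      d <- fc$directions[[nm]][[by]]
      if (!nrow(d)) next
      base <- data.frame(table = nm, by = by, region = NA_character_,
                         island = NA_character_, stringsAsFactors = FALSE)
      base <- base[rep(1L, nrow(d)), , drop = FALSE]
      if ("region" %in% colnames(d)) base$region <- d$region
      if ("island" %in% colnames(d)) base$island <- d$island
      dir_rows[[paste(nm, by)]] <- cbind(
        base, d[c("n_pos", "n_neg", "pct_pos", "pct_neg")])
    }
  }
  dir_tab <- do.call(rbind, dir_rows)
  rownames(dir_tab) <- NULL
  utils::write.csv(dir_tab, file.path(filtered_dir, "direction_summary.csv"),
                   row.names = FALSE, na = "NA", eol = "\n")
  for (side in c("positive", "negative")) {
    rows <- lapply(names(fc$top), function(nm) {
      t <- fc$top[[nm]][[side]]
      if (!nrow(t)) return(NULL)
      cbind(data.frame(table = nm, stringsAsFactors = FALSE), t)
    })
    tab <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(tab)) tab <- data.frame()
    utils::write.csv(tab, file.path(filtered_dir,
                                    paste0("top_", side, ".csv")),
                     row.names = FALSE, na = "NA", eol = "\n")
  }
  invisible(fc)
}
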