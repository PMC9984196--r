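#' Configuration for an end-to-end localization analysis run
#'
#' Collects the file paths, thresholds and seed of a run into a validated
#' list that is serialized verbatim (YAML) into every output directory for
#' provenance.
#'
#' @param out_dir output directory (created if needed).
#' @param counts_file,samples_file count matrix and sample sheet TSVs.
#' @param metric localization metric: \code{"CB"} (pulldown/input),
#'   \code{"AB"} (apical/basal) or \code{"LR"} (neurite/soma).
#' @param min_count minimum raw count filter (default 10).
#' @param fdr_level significance threshold reported in the summary;
#'   defaults to 0.01 for CB and 0.05 otherwise.
#' @param window,min_pyrimidines PRRE scanner parameters.
#' @param qc_min_spots,qc_max_spots smFISH per-cell QC bounds.
#' @param utr_file optional FASTA of 5' UTRs for motif annotation.
#' @param lr_matrix_file optional gene x dataset LR TSV for the LRz
#'   meta-analysis.
#' @param ortholog_file optional two-column TSV mapping bias gene ids to
#'   LR-matrix gene ids; required when the cross-compartment correlation
#'   is requested.
#' @param correlate whether the localization workflow should compute the
#'   cross-compartment correlation.
#' @param seed integer seed governing any randomness.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(out_dir, counts_file = NULL, samples_file = NULL,
                       metric = c("CB", "AB", "LR"), min_count = 10,
                       fdr_level = NULL, window = 10, min_pyrimidines = 9,
                       qc_min_spots = 100, qc_max_spots = 1000,
                       utr_file = NULL, lr_matrix_file = NULL,
                       ortholog_file = NULL, correlate = FALSE,
                       seed = 1L) {
  metric <- match.arg(metric)
  if (is.null(fdr_level)) fdr_level <- if (metric == "CB") 0.01 else 0.05
  if (fdr_level <= 0 || fdr_level >= 1) stop("fdr_level must be in (0, 1)")
  if (min_count < 0) stop("min_count must be non-negative")
  cfg <- list(schema_version = 1L, out_dir = out_dir,
              counts_file = counts_file, samples_file = samples_file,
              metric = metric, min_count = min_count,
              fdr_level = fdr_level, window = window,
              min_pyrimidines = min_pyrimidines,
              qc_min_spots = qc_min_spots, qc_max_spots = qc_max_spots,
              utr_file = utr_file, lr_matrix_file = lr_matrix_file,
              ortholog_file = ortholog_file, correlate = correlate,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

contrast_for_metric <- function(metric) {
  switch(metric,
         CB = c("pulldown", "input"),
         AB = c("apical", "basal"),
         LR = c("neurite", "soma"))
}

prepare_out_dir <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))
}

log_line <- function(config, ...) {
  cat(paste0(..., "\n"), file = file.path(config$out_dir, "run.log"),
      append = TRUE)
}

#' Run the fraction-enrichment workflow
#'
#' Reads the count matrix and sample sheet, computes the configured bias
#' metric with NB Wald testing and BH FDR, and writes the bias table
#' (\code{bias_<metric>.tsv}), a YAML copy of the configuration, a run log
#' with filtering counts, and a summary (\code{summary.yaml}) reporting
#' the number of genes significant at the configured FDR, split by sign.
#' Outputs are deterministic given fixed inputs and seed.
#'
#' @param config a \code{\link{run_config}} with \code{counts_file} and
#'   \code{samples_file} set.
#' @return the bias table, invisibly; side effect: files under
#'   \code{config$out_dir}.
#' @export
run_enrichment_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$counts_file) || is.null(config$samples_file))
    stop("config must provide counts_file and samples_file")
  for (f in c(config$counts_file, config$samples_file))
    if (!file.exists(f)) stop("input file not found: ", f)
  cm <- read_counts(config$counts_file, config$samples_file)
  if (nrow(cm$counts) == 0) stop("count file has no gene rows")
  prepare_out_dir(config)
  set.seed(config$seed)
  contrast <- contrast_for_metric(config$metric)
  bias <- compute_bias(cm, contrast[1], contrast[2],
                       min_count = config$min_count)
  log_line(config, "genes_in: ", nrow(cm$counts))
  log_line(config, "genes_tested: ", nrow(bias))
  log_line(config, "genes_filtered_min_count: ",
           nrow(cm$counts) - nrow(bias))
  write_bias_table(bias, file.path(config$out_dir,
                                   paste0("bias_", config$metric, ".tsv")))
  sig <- !is.na(bias$fdr) & bias$fdr < config$fdr_level
  summary <- list(metric = config$metric,
                  contrast = paste(contrast, collapse = "/"),
                  n_genes_tested = nrow(bias),
                  fdr_level = config$fdr_level,
                  n_significant = sum(sig),
                  n_significant_up = sum(sig & bias$bias > 0),
                  n_significant_down = sum(sig & bias$bias < 0))
  yaml::write_yaml(summary, file.path(config$out_dir, "summary.yaml"))
  invisible(bias)
}

#' Run the motif / cross-compartment localization workflow
#'
#' Starting from a bias table produced by
#' \code{\link{run_enrichment_workflow}} (or computed on the fly when
#' count files are configured), this workflow scans the configured 5' UTR
#' FASTA for PRREs, compares bias between TOP/PRTE classes and the
#' background, computes the LRz meta-statistic from the configured LR
#' matrix, and (when \code{correlate = TRUE}) correlates bias against LRz
#' through the ortholog table. Results are written under
#' \code{config$out_dir}: \code{prre_annotation.tsv}, \code{lrz.tsv},
#' \code{class_summary.tsv} and \code{report.json}.
#'
#' @param config a \code{\link{run_config}}.
#' @param bias optional precomputed \code{bias_table}; when \code{NULL}
#'   the enrichment workflow is run first.
#' @return list with the computed pieces (\code{annotation},
#'   \code{class_summary}, \code{lrz}, \code{correlation}), invisibly.
#' @export
run_localization_workflow <- function(config, bias = NULL) {
  stopifnot(inherits(config, "run_config"))
  prepare_out_dir(config)
  if (is.null(bias)) bias <- run_enrichment_workflow(config)
  out <- list()

  if (!is.null(config$utr_file)) {
    if (!file.exists(config$utr_file))
      stop("UTR FASTA not found: ", config$utr_file)
    utrs <- Biostrings::readDNAStringSet(config$utr_file)
    ann <- annotate_utrs(utrs, window = config$window,
                         min_pyrimidines = config$min_pyrimidines)
    utils::write.table(ann, file.path(config$out_dir, "prre_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line(config, "utrs_scanned: ", length(utrs))
    log_line(config, "genes_with_prre: ", sum(ann$has_prre))
    classes <- list()
    top <- ann$gene_id[ann$has_prre & ann$motif_class == "TOP"]
    prte <- ann$gene_id[ann$has_prre & ann$motif_class == "PRTE"]
    if (length(intersect(top, bias$gene_id)) >= 2) classes$TOP <- top
    if (length(intersect(prte, bias$gene_id)) >= 2) classes$PRTE <- prte
    if (length(classes)) {
      cls <- bias_by_motif_class(bias, classes)
      utils::write.table(cls, file.path(config$out_dir, "class_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$class_summary <- cls
    }
    out$annotation <- ann
  }

  if (!is.null(config$lr_matrix_file)) {
    if (!file.exists(config$lr_matrix_file))
      stop("LR matrix not found: ", config$lr_matrix_file)
    lrm <- read_lr_matrix(config$lr_matrix_file)
    lrz <- compute_lrz(lrm)
    utils::write.table(lrz, file.path(config$out_dir, "lrz.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line(config, "lrz_genes: ", sum(!is.na(lrz$lrz)))
    out$lrz <- lrz
    if (isTRUE(config$correlate)) {
      if (is.null(config$ortholog_file))
        stop("cross-compartment correlation requested but no ",
             "ortholog_file is configured; provide a two-column TSV ",
             "mapping bias gene ids to LR-matrix gene ids")
      if (!file.exists(config$ortholog_file))
        stop("ortholog file not found: ", config$ortholog_file)
      map <- utils::read.delim(config$ortholog_file,
                               stringsAsFactors = FALSE)
      out$correlation <- correlate_compartments(bias, lrz, map)
    }
  }

  report <- list(metric = config$metric,
                 n_genes = nrow(bias),
                 class_summary = out$class_summary,
                 correlation = out$correlation)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
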