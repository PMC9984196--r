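#' LRz: median within-dataset z-score of localization ratios
#'
#' Pools localization ratios (LR, log2 neurite/soma) from many independent
#' fractionation datasets. Within each dataset the LR values of the genes
#' measured there are z-normalized (mean 0, sd 1 with the n-1 denominator),
#' and a gene's LRz is the median of its available z-scores. Genes
#' quantified in fewer than \code{min_datasets} datasets get \code{NA}.
#' Because z-normalization removes any per-dataset location/scale
#' distortion, LRz is invariant to affine transformations of individual
#' datasets.
#'
#' @param lr_matrix numeric gene x dataset matrix of LR values, \code{NA}
#'   for genes not measured in a dataset; rownames are gene ids.
#' @param min_datasets minimum datasets per gene (default: half the
#'   datasets, rounded up).
#' @return data.frame per gene: \code{gene_id}, \code{lrz},
#'   \code{n_datasets}; the full z-score matrix is attached as attribute
#'   \code{"z"}.
#' @export
compute_lrz <- function(lr_matrix,
                        min_datasets = ceiling(ncol(lr_matrix) / 2)) {
  lr_matrix <- as.matrix(lr_matrix)
  if (is.null(rownames(lr_matrix)))
    rownames(lr_matrix) <- sprintf("gene_%05d", seq_len(nrow(lr_matrix)))
  if (is.null(colnames(lr_matrix)))
    colnames(lr_matrix) <- sprintf("dataset_%02d", seq_len(ncol(lr_matrix)))
  n_obs <- colSums(!is.na(lr_matrix))
  if (any(n_obs < 3))
    stop("dataset(s) with fewer than 3 measured genes: ",
         paste(colnames(lr_matrix)[n_obs < 3], collapse = ", "))
  sds <- apply(lr_matrix, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0))
    stop("dataset(s) with zero variance: ",
         paste(colnames(lr_matrix)[sds == 0], collapse = ", "))
  z <- scale(lr_matrix)          # column-wise (x - mean)/sd, NA-safe
  nd <- rowSums(!is.na(z))
  lrz <- apply(z, 1, stats::median, na.rm = TRUE)
  lrz[nd < min_datasets] <- NA_real_
  out <- data.frame(gene_id = rownames(lr_matrix), lrz = lrz,
                    n_datasets = nd, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "z") <- z
  out
}

#' Log2 localization ratio from a Taqman qPCR Ct table
#'
#' Delta-delta-Ct with an unlocalized reference transcript as internal
#' control: technical replicates are averaged first, then
#' \deqn{LR = \log_2(e)\,[(Ct_{ref,neurite} - Ct_{target,neurite}) -
#'             (Ct_{ref,soma} - Ct_{target,soma})]}
#' where \eqn{e} is the amplification efficiency (2 for perfect doubling,
#' giving the plain ddCt difference).
#'
#' @param ct data.frame with columns \code{target} (values
#'   \code{"target"}/\code{"reference"}), \code{fraction}
#'   (\code{"neurite"}/\code{"soma"}), \code{ct}, and optionally
#'   \code{replicate}.
#' @param efficiency amplification efficiency, must exceed 1 (default 2).
#' @return the log2 localization ratio (a single number).
#' @examples
#' qpcr_localization_ratio(generate_qpcr_ct(true_lr = 2))
#' @export
qpcr_localization_ratio <- function(ct, efficiency = 2) {
  if (efficiency <= 1) stop("efficiency must exceed 1")
  req <- c("target", "fraction", "ct")
  if (!all(req %in% names(ct)))
    stop("ct table needs columns: ", paste(req, collapse = ", "))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  means <- tapply(ct$ct, list(ct$target, ct$fraction), mean)
  need <- expand.grid(t = c("target", "reference"),
                      f = c("neurite", "soma"))
  have <- !is.na(means[cbind(match(need$t, rownames(means)),
                             match(need$f, colnames(means)))])
  if (anyNA(have) || !all(have))
    stop("ct table must cover target and reference in both fractions")
  dct_neu <- means["reference", "neurite"] - means["target", "neurite"]
  dct_som <- means["reference", "soma"] - means["target", "soma"]
  log2(efficiency) * (dct_neu - dct_som)
}

#' Correlate localization between two compartment systems
#'
#' Relates a per-gene bias from one cell type (e.g. epithelial Apical
#' Bias) to the LRz meta-statistic from another (e.g. neuronal cultures),
#' mapping gene ids through a two-column ortholog table. Only one-to-one
#' pairs are used; pairs involving a gene that appears more than once in
#' the mapping are dropped and counted. Association is summarized by
#' Spearman's rank correlation with the tie-corrected approximation for
#' the p-value.
#'
#' @param bias_a a \code{bias_table} (or data.frame with \code{gene_id}
#'   and \code{bias}) for compartment system A.
#' @param lrz output of \code{\link{compute_lrz}} (or data.frame with
#'   \code{gene_id} and \code{lrz}) for system B.
#' @param gene_map two-column data.frame mapping A ids (first column) to B
#'   ids (second column).
#' @param subset optional character vector of A-side gene ids restricting
#'   the correlation (e.g. ribosomal protein genes only).
#' @return list: \code{rho}, \code{p_value}, \code{n_genes},
#'   \code{n_dropped_multi} (pairs dropped as many-to-many).
#' @export
correlate_compartments <- function(bias_a, lrz, gene_map, subset = NULL) {
  if (!all(c("gene_id", "bias") %in% names(bias_a)))
    stop("bias_a needs gene_id and bias columns")
  if (!all(c("gene_id", "lrz") %in% names(lrz)))
    stop("lrz needs gene_id and lrz columns")
  gene_map <- as.data.frame(gene_map, stringsAsFactors = FALSE)
  if (ncol(gene_map) < 2) stop("gene_map must have two columns")
  names(gene_map)[1:2] <- c("id_a", "id_b")
  multi <- gene_map$id_a %in% gene_map$id_a[duplicated(gene_map$id_a)] |
           gene_map$id_b %in% gene_map$id_b[duplicated(gene_map$id_b)]
  n_multi <- sum(multi)
  if (n_multi)
    message("dropping ", n_multi, " many-to-many ortholog pair(s)")
  map <- gene_map[!multi, , drop = FALSE]
  if (!is.null(subset)) map <- map[map$id_a %in% subset, , drop = FALSE]
  a <- bias_a$bias[match(map$id_a, bias_a$gene_id)]
  b <- lrz$lrz[match(map$id_b, lrz$gene_id)]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 10)
    stop("fewer than 10 mapped genes with values on both sides")
  ht <- suppressWarnings(stats::cor.test(a[ok], b[ok], method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ht$estimate), p_value = unname(ht$p.value),
       n_genes = sum(ok), n_dropped_multi = n_multi)
}

#' Compare a gene class against the background on any per-gene metric
#'
#' Two-sided Wilcoxon rank-sum test of the metric values of a gene class
#' (e.g. ribosomal protein genes) against all remaining genes, with class
#' and background medians.
#'
#' @param values named numeric vector of the per-gene metric (names are
#'   gene ids).
#' @param gene_class character vector of gene ids forming the class.
#' @return list: \code{n_class}, \code{n_background},
#'   \code{class_median}, \code{background_median}, \code{p_value}.
#' @export
class_bias_summary <- function(values, gene_class) {
  if (is.null(names(values))) stop("values must be named by gene id")
  values <- values[!is.na(values)]
  in_class <- names(values) %in% gene_class
  if (sum(in_class) < 2) stop("class needs at least 2 genes with values")
  if (sum(!in_class) < 2) stop("background needs at least 2 genes")
  ht <- rank_sum_test(values[in_class], values[!in_class])
  list(n_class = sum(in_class), n_background = sum(!in_class),
       class_median = stats::median(values[in_class]),
       background_median = stats::median(values[!in_class]),
       p_value = ht$p_value)
}

#' Read / write a gene x dataset LR matrix as TSV
#'
#' Genes as rows (first column \code{gene_id}), datasets as columns,
#' \code{NA} for missing.
#'
#' @param file path.
#' @param lr_matrix numeric matrix with gene rownames.
#' @return \code{read_lr_matrix} returns the matrix; \code{write_lr_matrix}
#'   its input, invisibly.
#' @export
read_lr_matrix <- function(file) {
  tab <- utils::read.delim(file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_lr_matrix
#' @export
write_lr_matrix <- function(lr_matrix, file) {
  out <- data.frame(gene_id = rownames(lr_matrix), lr_matrix,
                    check.names = FALSE)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(lr_matrix)
}
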