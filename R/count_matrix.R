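#' Fraction-level RNA-seq count matrix
#'
#' Container for a gene x sample matrix of non-negative integer counts
#' together with per-sample metadata describing which subcellular fraction
#' each library was prepared from. Fractions come in contrast pairs:
#' \code{input}/\code{pulldown} for proximity-labeling enrichment,
#' \code{apical}/\code{basal} for epithelial polarity, and
#' \code{neurite}/\code{soma} for mechanically fractionated neuronal
#' cultures.
#'
#' @param counts numeric matrix of non-negative counts; rows are genes
#'   (rownames required and unique), columns are samples.
#' @param samples data.frame with one row per column of \code{counts},
#'   containing at least \code{sample} (matching \code{colnames(counts)}) and
#'   \code{fraction}; optional \code{replicate} and \code{dataset} columns
#'   are filled in when absent.
#'
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts} and \code{samples}.
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cm <- count_matrix(m, data.frame(sample = paste0("s", 1:4),
#'                                  fraction = rep(c("input", "pulldown"), each = 2)))
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique rownames (gene ids)")
  if (is.null(colnames(counts)))
    stop("counts must have colnames (sample ids)")
  if (any(counts < 0)) stop("counts must be non-negative")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample", "fraction")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(counts))
    stop("sample sheet has ", nrow(samples), " rows but counts has ",
         ncol(counts), " columns")
  if (!setequal(samples$sample, colnames(counts)))
    stop("sample sheet ids do not match count matrix columns")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  known <- c("input", "pulldown", "apical", "basal", "neurite", "soma")
  bad <- setdiff(unique(samples$fraction), known)
  if (length(bad))
    stop("unknown fraction label(s): ", paste(bad, collapse = ", "))
  if (anyNA(samples$fraction)) stop("every sample needs a fraction label")
  if (is.null(samples$replicate))
    samples$replicate <- stats::ave(seq_len(nrow(samples)), samples$fraction,
                                    FUN = seq_along)
  if (is.null(samples$dataset)) samples$dataset <- "dataset1"
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  tab <- table(x$samples$fraction)
  cat("fractions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix to the samples of two fractions
#'
#' @param x a \code{count_matrix}.
#' @param fractions character vector of fraction labels to keep.
#' @return a \code{count_matrix} restricted to the matching samples.
#' @keywords internal
subset_fractions <- function(x, fractions) {
  stopifnot(inherits(x, "count_matrix"))
  bad <- setdiff(fractions, unique(x$samples$fraction))
  if (length(bad))
    stop("fraction(s) not present in sample sheet: ", paste(bad, collapse = ", "))
  keep <- x$samples$fraction %in% fractions
  count_matrix(x$counts[, keep, drop = FALSE],
               x$samples[keep, , drop = FALSE])
}

#' Read counts and a sample sheet from TSV files
#'
#' The count file is TSV with gene ids in the first column and one column per
#' sample; the sample sheet is TSV with columns \code{sample},
#' \code{fraction} and optionally \code{replicate}, \code{dataset}.
#'
#' @param counts_file path to the count TSV.
#' @param samples_file path to the sample sheet TSV.
#' @return a \code{count_matrix}.
#' @export
read_counts <- function(counts_file, samples_file) {
  tab <- utils::read.delim(counts_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count file ", counts_file, " has no sample columns")
  if (nrow(tab) == 0) stop("count file ", counts_file, " has no gene rows")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  samples <- utils::read.delim(samples_file, stringsAsFactors = FALSE)
  count_matrix(m, samples)
}

#' Write counts and the sample sheet to TSV files
#'
#' @param x a \code{count_matrix}.
#' @param counts_file,samples_file output paths.
#' @return invisibly, the input object.
#' @export
write_counts <- function(x, counts_file, samples_file) {
  stopifnot(inherits(x, "count_matrix"))
  out <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE)
  utils::write.table(out, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, samples_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
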