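#' Scan a 5' UTR for pyrimidine-rich regulatory elements (PRREs)
#'
#' A PRRE is called wherever a sliding window of \code{window} nucleotides
#' contains at least \code{min_pyrimidines} pyrimidines (C or T; U is read
#' as T, N and other letters are rejected except N which counts as
#' non-pyrimidine). Overlapping or book-ended qualifying windows are merged
#' into a single element spanning from the first window's start to the last
#' window's end; the element position is the merged start. An element
#' starting at position 1 of the UTR is classified as a 5' TOP motif,
#' anything downstream as a PRTE.
#'
#' @param sequence a single nucleotide string (or \code{DNAString});
#'   case-insensitive alphabet A/C/G/T/U/N.
#' @param window window width (default 10).
#' @param min_pyrimidines minimum pyrimidines per qualifying window
#'   (default 9).
#' @return data.frame with zero or more rows: \code{start}, \code{end}
#'   (1-based inclusive), \code{n_qualifying_windows}, \code{motif_class}
#'   (\code{"TOP"} or \code{"PRTE"}). Hits are sorted and non-overlapping.
#' @examples
#' scan_prre("CCTCTTTTTCCGGCTGGAACC")   # one TOP element at position 1
#' scan_prre("AAGAGGGGGAAGGAGGGAAAA")   # no hits
#' @export
scan_prre <- function(sequence, window = 10, min_pyrimidines = 9) {
  if (window < 1) stop("window must be at least 1")
  if (min_pyrimidines > window)
    stop("min_pyrimidines cannot exceed the window width")
  s <- toupper(as.character(sequence))
  if (length(s) != 1) stop("sequence must be a single string")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "U", "N"))
  if (length(bad))
    stop("non-nucleotide character(s) in sequence: ",
         paste(bad, collapse = ", "))
  empty <- data.frame(start = integer(), end = integer(),
                      n_qualifying_windows = integer(),
                      motif_class = character(), stringsAsFactors = FALSE)
  n <- length(chars)
  if (n < window) return(empty)
  ispy <- as.integer(chars %in% c("C", "T", "U"))
  # pyrimidine count in each window via cumulative sums
  cs <- c(0L, cumsum(ispy))
  starts <- seq_len(n - window + 1L)
  counts <- cs[starts + window] - cs[starts]
  qual <- starts[counts >= min_pyrimidines]
  if (!length(qual)) return(empty)
  # merge overlapping or book-ended windows: a gap of more than `window`
  # between consecutive qualifying starts breaks the element
  brk <- c(TRUE, diff(qual) > window)
  grp <- cumsum(brk)
  first <- tapply(qual, grp, min)
  last <- tapply(qual, grp, max)
  nwin <- tapply(qual, grp, length)
  out <- data.frame(start = as.integer(first),
                    end = as.integer(last + window - 1L),
                    n_qualifying_windows = as.integer(nwin),
                    stringsAsFactors = FALSE)
  out$motif_class <- ifelse(out$start == 1L, "TOP", "PRTE")
  out[order(out$start), , drop = FALSE]
}

#' Swap every pyrimidine of a motif for a purine
#'
#' The mutagenesis rule used to kill a PRRE while preserving length and
#' purine content: C becomes A and T (or U) becomes G; purines and N are
#' unchanged. Case is preserved.
#'
#' @param sequence nucleotide string (alphabet A/C/G/T/U/N,
#'   case-insensitive).
#' @return the purine-swapped string.
#' @examples
#' mutate_prre("CCTCTTTTTCCGGCTGGAACC")
#' @export
mutate_prre <- function(sequence) {
  s <- as.character(sequence)
  if (length(s) != 1) stop("sequence must be a single string")
  bad <- setdiff(unique(strsplit(toupper(s), "", fixed = TRUE)[[1]]),
                 c("A", "C", "G", "T", "U", "N"))
  if (length(bad))
    stop("non-nucleotide character(s) in sequence: ",
         paste(bad, collapse = ", "))
  chartr("CTUctu", "AGGagg", s)
}

#' Annotate genes with their most 5' UTR pyrimidine-rich element
#'
#' When a gene has several annotated 5' UTRs, only its longest one is
#' scanned (ties broken by lexicographic transcript id). The reported
#' position is the start of the most 5' merged element in that UTR; the
#' class is TOP when that position is 1, PRTE otherwise.
#'
#' @param utrs named character vector or \code{Biostrings::DNAStringSet} of
#'   5' UTR sequences; names are transcript ids.
#' @param gene_ids character vector mapping each UTR to a gene (defaults to
#'   the UTR names, i.e. one UTR per gene).
#' @param window,min_pyrimidines passed to \code{\link{scan_prre}}.
#' @return data.frame with one row per gene: \code{gene_id},
#'   \code{utr_id}, \code{utr_length}, \code{has_prre},
#'   \code{most_5prime_position}, \code{motif_class} (\code{NA} for genes
#'   without a hit).
#' @export
annotate_utrs <- function(utrs, gene_ids = names(utrs), window = 10,
                          min_pyrimidines = 9) {
  ids <- names(utrs)
  seqs <- as.character(utrs)
  if (length(seqs) == 0) stop("empty UTR set")
  names(seqs) <- if (is.null(ids)) sprintf("utr_%d", seq_along(seqs)) else ids
  if (length(gene_ids) != length(seqs))
    stop("gene_ids must be parallel to utrs")
  # longest UTR per gene, ties by transcript id
  ord <- order(gene_ids, -nchar(seqs), names(seqs))
  pick <- !duplicated(gene_ids[ord])
  idx <- ord[pick]
  out <- do.call(rbind, lapply(idx, function(i) {
    hits <- scan_prre(seqs[[i]], window = window,
                      min_pyrimidines = min_pyrimidines)
    data.frame(gene_id = gene_ids[i], utr_id = names(seqs)[i],
               utr_length = nchar(seqs[[i]]),
               has_prre = nrow(hits) > 0,
               most_5prime_position = if (nrow(hits)) hits$start[1]
                                      else NA_integer_,
               motif_class = if (nrow(hits)) hits$motif_class[1]
                             else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare localization bias between motif classes and the background
#'
#' For each requested class of genes (e.g. TOP-containing,
#' PRTE-containing, or any user-supplied gene set) the distribution of the
#' bias metric is summarized by its median and compared with all remaining
#' genes by a two-sided Wilcoxon rank-sum test.
#'
#' @param bias a \code{bias_table} (or data.frame with \code{gene_id} and
#'   \code{bias}).
#' @param classes named list of character vectors of gene ids.
#' @return data.frame per class: \code{class}, \code{n},
#'   \code{class_median}, \code{background_median}, \code{p_value}.
#' @export
bias_by_motif_class <- function(bias, classes) {
  if (!all(c("gene_id", "bias") %in% names(bias)))
    stop("bias must contain gene_id and bias columns")
  if (!length(classes) || is.null(names(classes)))
    stop("classes must be a named list of gene id vectors")
  out <- do.call(rbind, lapply(names(classes), function(cl) {
    ids <- classes[[cl]]
    unknown <- setdiff(ids, bias$gene_id)
    in_class <- bias$gene_id %in% ids
    if (sum(in_class) < 2)
      stop("class '", cl, "' has fewer than 2 genes with bias values")
    cbs <- class_bias_summary(stats::setNames(bias$bias, bias$gene_id),
                              bias$gene_id[in_class])
    data.frame(class = cl, n = sum(in_class),
               n_unmatched = length(unknown),
               class_median = cbs$class_median,
               background_median = cbs$background_median,
               p_value = cbs$p_value, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write PRRE hits as TSV or BED
#'
#' BED output uses 0-based half-open UTR-local coordinates with the motif
#' class in the name column.
#'
#' @param hits data.frame of hits from \code{\link{scan_prre}} with an
#'   additional \code{sequence_id} column (added by callers scanning sets).
#' @param file output path.
#' @param format \code{"tsv"} or \code{"bed"}.
#' @return the input, invisibly.
#' @export
write_prre_hits <- function(hits, file, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!"sequence_id" %in% names(hits))
    stop("hits need a sequence_id column")
  if (format == "tsv") {
    utils::write.table(hits, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    bed <- data.frame(chrom = hits$sequence_id,
                      chromStart = hits$start - 1L,
                      chromEnd = hits$end,
                      name = hits$motif_class)
    utils::write.table(bed, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(hits)
}
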