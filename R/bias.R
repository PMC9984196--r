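#' Negative-binomial Wald test for differential fraction enrichment
#'
#' Tests, gene by gene, whether normalized abundance differs between a
#' numerator and a denominator group of samples under a negative-binomial
#' model with mean \eqn{\mu} and variance \eqn{\mu + \alpha\mu^2}. The
#' reported effect is the log2 ratio of pseudocounted group means of
#' normalized counts; its standard error comes from the delta method with
#' the NB variance plugged in.
#'
#' Dispersion \eqn{\alpha} is estimated by the method of moments on
#' normalized counts. With \code{dispersion = "pooled"} (default) a single
#' common dispersion is estimated across all genes, and the Wald statistic
#' is referred to a standard normal; with few replicates this borrows
#' enough information to keep the test calibrated without sacrificing
#' power. With \code{dispersion = "genewise"} each gene gets its own moment
#' estimate (floored at 1e-8 and capped at 10) and the statistic is
#' referred to a t distribution on the residual degrees of freedom, which
#' accounts for the estimation noise of a per-gene variance.
#'
#' @param num_counts,den_counts count matrices (genes x samples) for the
#'   numerator and denominator groups, with identical rownames.
#' @param sf positive size factors, numerator samples first then
#'   denominator; normalized counts are \code{counts/sf}. Default all 1.
#' @param dispersion \code{"pooled"} or \code{"genewise"}.
#' @param pseudocount added to each group mean before the log2 ratio.
#' @return data.frame with one row per gene: \code{gene_id},
#'   \code{base_mean}, \code{bias}, \code{se}, \code{wald_stat},
#'   \code{p_value}. Genes whose counts are zero in every sample get
#'   \code{NA} statistics.
#' @export
nb_wald_test <- function(num_counts, den_counts, sf = NULL,
                         dispersion = c("pooled", "genewise"),
                         pseudocount = 0.5) {
  dispersion <- match.arg(dispersion)
  num_counts <- as.matrix(num_counts)
  den_counts <- as.matrix(den_counts)
  if (!identical(rownames(num_counts), rownames(den_counts)))
    stop("numerator and denominator matrices must share gene rownames")
  n1 <- ncol(num_counts); n2 <- ncol(den_counts)
  if (n1 + n2 < 2) stop("need at least 2 samples in total")
  if (is.null(sf)) sf <- rep(1, n1 + n2)
  if (length(sf) != n1 + n2 || any(sf <= 0))
    stop("sf must be ", n1 + n2, " positive size factors")
  s1 <- sf[seq_len(n1)]; s2 <- sf[n1 + seq_len(n2)]
  y1 <- sweep(num_counts, 2, s1, "/")
  y2 <- sweep(den_counts, 2, s2, "/")
  m1 <- rowMeans(y1); m2 <- rowMeans(y2)

  # within-group residual variance pooled over both groups (df = n1+n2-2);
  # moment decomposition v ~ mean_j(mu/s_j) + alpha * mean(mu^2)
  df <- n1 + n2 - 2
  rss <- rowSums((y1 - m1)^2) + rowSums((y2 - m2)^2)
  v <- if (df > 0) rss / df else rep(NA_real_, length(m1))
  mpois <- (m1 * sum(1 / s1) + m2 * sum(1 / s2)) / (n1 + n2)
  msq <- (n1 * m1^2 + n2 * m2^2) / (n1 + n2)
  if (dispersion == "pooled") {
    use <- msq > 0 & is.finite(v)
    alpha <- if (any(use)) sum(v[use] - mpois[use]) / sum(msq[use]) else 0
    alpha <- min(max(alpha, 1e-8), 10)
    alpha <- rep(alpha, length(m1))
  } else {
    alpha <- ifelse(msq > 0 & is.finite(v), (v - mpois) / msq, NA_real_)
    alpha <- pmin(pmax(alpha, 1e-8), 10)
  }

  bias <- log2((m1 + pseudocount) / (m2 + pseudocount))
  var1 <- (m1 * sum(1 / s1) + n1 * alpha * m1^2) / n1^2
  var2 <- (m2 * sum(1 / s2) + n2 * alpha * m2^2) / n2^2
  se <- sqrt(var1 / pmax(m1, pseudocount)^2 +
             var2 / pmax(m2, pseudocount)^2) / log(2)
  wald <- bias / se
  p <- if (dispersion == "pooled") 2 * stats::pnorm(-abs(wald))
       else 2 * stats::pt(-abs(wald), df = max(df, 1))

  zero <- m1 == 0 & m2 == 0
  wald[zero] <- NA_real_; p[zero] <- NA_real_; se[zero] <- NA_real_
  data.frame(gene_id = rownames(num_counts),
             base_mean = (n1 * m1 + n2 * m2) / (n1 + n2),
             bias = bias, se = se, wald_stat = wald, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compute a per-gene localization bias table
#'
#' The workhorse for the three localization metrics: Cytoplasmic Bias
#' (pulldown over input), Apical Bias (apical over basal) and the neuronal
#' Localization Ratio (neurite over soma). Counts from the two requested
#' fractions are normalized to composition-scaled effective library sizes
#' (see \code{\link{estimate_size_factors}} for the related per-sample
#' factors), lowly covered genes are removed, and each remaining gene gets
#' a log2 bias, an NB Wald test and a Benjamini-Hochberg adjusted FDR.
#'
#' A gene is kept when at least one sample among the two fractions has at
#' least \code{min_count} raw counts.
#'
#' @param counts a \code{count_matrix}.
#' @param numerator_fraction,denominator_fraction fraction labels, e.g.
#'   \code{"pulldown"} and \code{"input"}.
#' @param min_count minimum raw count that must be reached in at least one
#'   sample for a gene to be tested (default 10).
#' @param pseudocount added to normalized fraction means before the log2
#'   ratio (default 0.5).
#' @param dispersion passed to \code{\link{nb_wald_test}}.
#' @return a \code{bias_table}: data.frame with columns \code{gene_id},
#'   \code{base_mean}, \code{bias}, \code{se}, \code{wald_stat},
#'   \code{p_value}, \code{fdr}.
#' @examples
#' sim <- generate_enrichment_counts(enrichment_sim_config(n_genes = 200, seed = 1))
#' head(compute_bias(sim$counts, "pulldown", "input"))
#' @export
compute_bias <- function(counts, numerator_fraction, denominator_fraction,
                         min_count = 10, pseudocount = 0.5,
                         dispersion = c("pooled", "genewise")) {
  dispersion <- match.arg(dispersion)
  if (identical(numerator_fraction, denominator_fraction))
    stop("numerator and denominator fractions must differ")
  sub <- subset_fractions(counts, c(numerator_fraction, denominator_fraction))
  is_num <- sub$samples$fraction == numerator_fraction
  if (!any(is_num) || !all(table(sub$samples$fraction) >= 1))
    stop("both fractions need at least one replicate")
  m <- sub$counts
  eff <- effective_lib_sizes(m)
  keep <- apply(m, 1, max) >= min_count
  if (!any(keep)) stop("no gene passes the min_count filter")
  m <- m[keep, , drop = FALSE]
  res <- nb_wald_test(m[, is_num, drop = FALSE],
                      m[, !is_num, drop = FALSE],
                      sf = c(eff[is_num], eff[!is_num]) / 1e6,
                      dispersion = dispersion, pseudocount = pseudocount)
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  class(res) <- c("bias_table", "data.frame")
  attr(res, "contrast") <- c(numerator_fraction, denominator_fraction)
  res
}

#' Write / read a bias table as TSV
#'
#' Fixed column order: gene_id, base_mean, bias, se, wald_stat, p_value, fdr.
#'
#' @param x a \code{bias_table}.
#' @param file path.
#' @return \code{write_bias_table} returns the input invisibly;
#'   \code{read_bias_table} returns a \code{bias_table}.
#' @export
write_bias_table <- function(x, file) {
  cols <- c("gene_id", "base_mean", "bias", "se", "wald_stat", "p_value", "fdr")
  utils::write.table(as.data.frame(x)[, cols], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname write_bias_table
#' @export
read_bias_table <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  class(x) <- c("bias_table", "data.frame")
  x
}
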