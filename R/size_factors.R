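#' Median-of-ratios size factors
#'
#' Estimates one normalization factor per sample by the median-of-ratios
#' method: each gene with strictly positive counts in every sample serves as
#' a reference, the per-sample ratio of its count to its geometric mean
#' across samples is formed, and the factor for a sample is the median of
#' these ratios. Factors are rescaled to have geometric mean 1 so they are
#' interpretable as relative library scalings.
#'
#' @param x a \code{count_matrix} or a plain numeric matrix of counts.
#' @return named numeric vector of positive size factors, one per sample,
#'   with geometric mean 1.
#' @examples
#' m <- matrix(c(10, 20, 30, 60), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("a", "b")))
#' estimate_size_factors(m)  # 1/sqrt(2), sqrt(2)
#' @export
estimate_size_factors <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (any(m < 0)) stop("counts must be non-negative")
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop("no gene has nonzero counts in every sample; ",
         "median-of-ratios needs at least one all-nonzero gene row ",
         "(a pseudo-reference fallback is not provided)")
  mm <- m[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(mm)))
  f <- apply(mm / geo, 2, stats::median)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  f
}

#' Composition-scaled effective library sizes
#'
#' Per-sample normalization used for bias computation: the library size
#' (column sum) multiplied by a composition factor obtained by
#' median-of-ratios on the count *proportions*. Because proportions are
#' unchanged when a whole column is rescaled, dividing counts by these
#' effective sizes (per million) yields normalized values that are exactly
#' invariant to rescaling any single library -- the effective-library-size
#' convention familiar from TMM-style normalization.
#'
#' @param m numeric matrix of counts (genes x samples).
#' @return named numeric vector of effective library sizes.
#' @keywords internal
effective_lib_sizes <- function(m) {
  libs <- colSums(m)
  if (any(libs <= 0)) stop("every sample needs at least one nonzero count")
  props <- sweep(m, 2, libs, "/")
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop("no gene has nonzero counts in every sample; ",
         "median-of-ratios needs at least one all-nonzero gene row ",
         "(a pseudo-reference fallback is not provided)")
  pp <- props[ref, , drop = FALSE]
  comp <- apply(pp / exp(rowMeans(log(pp))), 2, stats::median)
  comp <- comp / exp(mean(log(comp)))
  libs * comp
}

#' Normalized counts on the counts-per-million scale
#'
#' @param m counts matrix.
#' @param eff_lib effective library sizes from \code{effective_lib_sizes}.
#' @return matrix of normalized counts (per million effective library size).
#' @keywords internal
normalize_cpm <- function(m, eff_lib = effective_lib_sizes(m)) {
  sweep(m, 2, eff_lib / 1e6, "/")
}
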