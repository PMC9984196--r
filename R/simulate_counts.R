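#' Configuration for the fraction-enrichment count simulator
#'
#' Describes a two-fraction RNA-seq experiment with negative-binomial
#' counts: gene base means are log-normal, counts have variance
#' \eqn{\mu + \alpha\mu^2}, and a chosen proportion of genes carries a
#' planted log2 enrichment in the numerator fraction.
#'
#' @param n_genes number of genes.
#' @param n_replicates replicates per fraction.
#' @param mean_log_expression,sd_log_expression natural-log mean and sd of
#'   the log-normal gene base means. Defaults give a median base mean of
#'   about 500, a typical well-covered gene in a fractionation library.
#' @param dispersion NB dispersion \eqn{\alpha} (default 0.05, a mid-range
#'   biological coefficient of variation of ~22\% between replicates).
#' @param enriched_fraction proportion of genes carrying the planted effect.
#' @param effect_log2fc planted log2 fold change in the numerator fraction;
#'   positive effects label genes "enriched", negative "depleted".
#' @param size_factor_range interval from which per-sample library scale
#'   factors are drawn uniformly.
#' @param seed integer seed; all randomness flows from it.
#' @return a list of class \code{enrichment_sim_config}.
#' @export
enrichment_sim_config <- function(n_genes = 5000, n_replicates = 3,
                                  mean_log_expression = log(500),
                                  sd_log_expression = 1,
                                  dispersion = 0.05,
                                  enriched_fraction = 0.1,
                                  effect_log2fc = 2,
                                  size_factor_range = c(0.7, 1.4),
                                  seed = 1L) {
  if (n_genes < 1 || n_replicates < 1)
    stop("n_genes and n_replicates must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (sd_log_expression <= 0) stop("sd_log_expression must be positive")
  if (enriched_fraction < 0 || enriched_fraction > 1)
    stop("enriched_fraction must lie in [0, 1]")
  if (length(size_factor_range) != 2 || any(size_factor_range <= 0) ||
      diff(size_factor_range) < 0)
    stop("size_factor_range must be an increasing pair of positive reals")
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 mean_log_expression = mean_log_expression,
                 sd_log_expression = sd_log_expression,
                 dispersion = dispersion,
                 enriched_fraction = enriched_fraction,
                 effect_log2fc = effect_log2fc,
                 size_factor_range = size_factor_range,
                 seed = as.integer(seed)),
            class = "enrichment_sim_config")
}

#' Simulate a two-fraction count matrix with planted enrichment
#'
#' Generates \code{2 * n_replicates} libraries for a fraction pair. A
#' random subset of genes (proportion \code{enriched_fraction}) has its
#' expected abundance in the numerator fraction multiplied by
#' \code{2^effect_log2fc}; after size-factor correction the expected
#' numerator/denominator ratio of those genes is exactly
#' \code{2^effect_log2fc}.
#'
#' @param config an \code{\link{enrichment_sim_config}}.
#' @param design length-2 character: numerator then denominator fraction
#'   label (default \code{c("pulldown", "input")}).
#' @param gene_effects optional numeric vector of per-gene planted log2
#'   effects (length \code{n_genes}), overriding the config's
#'   subset-at-one-effect scheme; useful for planting continuous effect
#'   distributions.
#' @return list with \code{counts} (a \code{\link{count_matrix}}) and
#'   \code{truth} (data.frame \code{gene_id}, \code{effect_log2fc},
#'   \code{label} in \{enriched, depleted, null\}, \code{base_mean}).
#' @export
generate_enrichment_counts <- function(config,
                                       design = c("pulldown", "input"),
                                       gene_effects = NULL) {
  stopifnot(inherits(config, "enrichment_sim_config"))
  if (length(design) != 2 || design[1] == design[2])
    stop("design must name two distinct fractions")
  set.seed(config$seed)
  ng <- config$n_genes; nr <- config$n_replicates
  gene_ids <- sprintf("gene_%05d", seq_len(ng))
  mu <- exp(stats::rnorm(ng, config$mean_log_expression,
                         config$sd_log_expression))
  if (is.null(gene_effects)) {
    n_eff <- round(config$enriched_fraction * ng)
    hit <- sample.int(ng, n_eff)
    effect <- numeric(ng)
    effect[hit] <- config$effect_log2fc
  } else {
    if (length(gene_effects) != ng)
      stop("gene_effects must have length n_genes")
    effect <- gene_effects
  }
  label <- ifelse(effect > 0, "enriched",
                  ifelse(effect < 0, "depleted", "null"))
  sf <- stats::runif(2 * nr, config$size_factor_range[1],
                     config$size_factor_range[2])
  size <- 1 / config$dispersion
  cols <- lapply(seq_len(2 * nr), function(j) {
    m <- if (j <= nr) mu * 2^effect else mu
    stats::rnbinom(ng, mu = sf[j] * m, size = size)
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(gene_ids,
                      c(paste0(design[1], "_", seq_len(nr)),
                        paste0(design[2], "_", seq_len(nr))))
  samples <- data.frame(sample = colnames(m),
                        fraction = rep(design, each = nr),
                        replicate = rep(seq_len(nr), 2),
                        dataset = "sim", stringsAsFactors = FALSE)
  list(counts = count_matrix(m, samples),
       truth = data.frame(gene_id = gene_ids, effect_log2fc = effect,
                          label = label, base_mean = mu,
                          stringsAsFactors = FALSE))
}
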