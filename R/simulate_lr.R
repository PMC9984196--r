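#' Simulate localization-ratio matrices across many datasets
#'
#' Emulates pooling neurite/soma localization ratios (LR, log2 units) from
#' many independent fractionation experiments: each dataset reports the
#' same latent per-gene effect, distorted by a dataset-specific affine map
#' (location offset and positive scale) plus gaussian noise, with optional
#' missingness.
#'
#' @param n_genes,n_datasets dimensions.
#' @param gene_effects latent per-gene LR values; drawn N(0, 1) when NULL.
#' @param dataset_scales,dataset_offsets per-dataset affine distortion;
#'   scales must be positive. Recycled defaults: scales drawn
#'   log-uniform in [0.5, 2], offsets N(0, 0.5).
#' @param noise_sd sd of the per-entry gaussian noise.
#' @param missing_prob probability that an entry is missing at random.
#' @param seed integer seed.
#' @return list with \code{lr} (gene x dataset matrix, NA = missing) and
#'   \code{truth} (data.frame \code{gene_id}, \code{effect}).
#' @export
generate_multidataset_lr <- function(n_genes = 1000, n_datasets = 10,
                                     gene_effects = NULL,
                                     dataset_scales = NULL,
                                     dataset_offsets = NULL,
                                     noise_sd = 0.3, missing_prob = 0,
                                     seed = 1L) {
  set.seed(as.integer(seed))
  if (is.null(gene_effects)) gene_effects <- stats::rnorm(n_genes)
  if (length(gene_effects) != n_genes)
    stop("gene_effects must have length n_genes")
  if (is.null(dataset_scales))
    dataset_scales <- exp(stats::runif(n_datasets, log(0.5), log(2)))
  if (is.null(dataset_offsets))
    dataset_offsets <- stats::rnorm(n_datasets, 0, 0.5)
  if (length(dataset_scales) != n_datasets ||
      length(dataset_offsets) != n_datasets)
    stop("dataset_scales/offsets must have length n_datasets")
  if (any(dataset_scales <= 0)) stop("dataset scales must be positive")
  if (missing_prob < 0 || missing_prob >= 1)
    stop("missing_prob must lie in [0, 1)")
  lr <- vapply(seq_len(n_datasets), function(d) {
    dataset_offsets[d] + dataset_scales[d] *
      (gene_effects + stats::rnorm(n_genes, 0, noise_sd))
  }, numeric(n_genes))
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  dimnames(lr) <- list(gene_ids, sprintf("dataset_%02d", seq_len(n_datasets)))
  if (missing_prob > 0)
    lr[stats::runif(length(lr)) < missing_prob] <- NA_real_
  list(lr = lr,
       truth = data.frame(gene_id = gene_ids, effect = gene_effects,
                          stringsAsFactors = FALSE))
}

#' Simulate a Taqman qPCR Ct table with a known localization ratio
#'
#' Builds Ct values for a target and an unlocalized reference transcript in
#' neurite and soma fractions such that the expected
#' \eqn{\Delta\Delta}Ct-derived log2 localization ratio equals
#' \code{true_lr} (at amplification efficiency 2).
#'
#' @param true_lr planted log2 neurite/soma localization ratio.
#' @param base_ct baseline cycle threshold (default 20).
#' @param replicates technical replicates per well.
#' @param noise_sd gaussian Ct noise per replicate.
#' @param seed integer seed.
#' @return data.frame with columns \code{target} (\code{"target"} or
#'   \code{"reference"}), \code{fraction}, \code{replicate}, \code{ct}.
#' @export
generate_qpcr_ct <- function(true_lr, base_ct = 20, replicates = 3,
                             noise_sd = 0, seed = 1L) {
  if (replicates < 1) stop("replicates must be at least 1")
  if (base_ct <= 0) stop("base_ct must be positive")
  set.seed(as.integer(seed))
  grid <- expand.grid(target = c("target", "reference"),
                      fraction = c("neurite", "soma"),
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  # LR = (Ct_ref,neurite - Ct_target,neurite) - (Ct_ref,soma - Ct_target,soma)
  ct0 <- ifelse(grid$target == "target" & grid$fraction == "neurite",
                base_ct - true_lr, base_ct)
  grid$ct <- ct0 + stats::rnorm(nrow(grid), 0, noise_sd)
  grid[, c("target", "fraction", "replicate", "ct")]
}
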