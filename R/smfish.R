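#' QC-filter smFISH cells by spot count
#'
#' Keeps only spots belonging to (cell, target) groups whose total spot
#' count lies within \code{[min_spots, max_spots]} -- reporter experiments
#' expect roughly 100-1000 spots per expressing cell, so far fewer suggests
#' a silent cell and far more a segmentation failure. If the table carries
#' a logical \code{in_frame} column, cells not fully in frame are dropped
#' as well.
#'
#' @param spots data.frame with at least \code{cell_id} and \code{target}.
#' @param min_spots,max_spots inclusive bounds on spots per cell
#'   (defaults 100 and 1000; use \code{Inf} for endogenous targets with no
#'   upper bound).
#' @return the filtered spot table.
#' @export
qc_filter_cells <- function(spots, min_spots = 100, max_spots = 1000) {
  if (min_spots < 0 || max_spots < 0) stop("bounds must be non-negative")
  if (min_spots > max_spots) stop("min_spots must not exceed max_spots")
  if (!all(c("cell_id", "target") %in% names(spots)))
    stop("spots need cell_id and target columns")
  if ("in_frame" %in% names(spots))
    spots <- spots[as.logical(spots$in_frame), , drop = FALSE]
  if (!nrow(spots)) return(spots)
  key <- paste(spots$cell_id, spots$target, sep = "\r")
  n <- table(key)
  ok <- names(n)[n >= min_spots & n <= max_spots]
  out <- spots[key %in% ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-cell apicobasal spot positions normalized to a control transcript
#'
#' Computes the mean z position of each (cell, target) group and subtracts
#' the experiment-wide median z of all spots of the non-localized control
#' transcript. Control and target reporters are expressed in different
#' cells, so the reference is a property of the experiment, not of the
#' cell. Downstream tests treat the cell, not the spot, as the unit of
#' analysis.
#'
#' @param spots data.frame with \code{cell_id}, \code{target} and either a
#'   \code{z_um} column (micrometres) or a \code{z_slice} column of stack
#'   indices converted via \code{slice_spacing}.
#' @param control_target name of the control transcript (e.g. untagged
#'   Firefly luciferase).
#' @param slice_spacing micrometres between stack slices when \code{z_slice}
#'   is provided (default 0.2).
#' @return data.frame per (cell, target): \code{cell_id}, \code{target},
#'   \code{n_spots}, \code{mean_z}, \code{normalized_z}; the control
#'   reference median is attached as attribute \code{"reference_z"}.
#' @export
summarize_z <- function(spots, control_target = "control",
                        slice_spacing = 0.2) {
  if (!all(c("cell_id", "target") %in% names(spots)))
    stop("spots need cell_id and target columns")
  if (!"z_um" %in% names(spots)) {
    if (!"z_slice" %in% names(spots))
      stop("spots need a z_um (or z_slice) column")
    spots$z_um <- spots$z_slice * slice_spacing
  }
  if (!control_target %in% spots$target)
    stop("control target '", control_target, "' not present in the table")
  ref <- stats::median(spots$z_um[spots$target == control_target])
  agg <- stats::aggregate(z_um ~ cell_id + target, data = spots,
                          FUN = mean)
  nsp <- stats::aggregate(z_um ~ cell_id + target, data = spots,
                          FUN = length)
  out <- data.frame(cell_id = agg$cell_id, target = agg$target,
                    n_spots = nsp$z_um, mean_z = agg$z_um,
                    normalized_z = agg$z_um - ref,
                    stringsAsFactors = FALSE)
  out <- out[order(out$target, out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_z") <- ref
  out
}

#' Wilcoxon rank-sum comparison of per-cell positions
#'
#' Two-sided rank-sum test on per-cell \code{normalized_z} between two
#' targets: exact when the combined number of cells is at most 30 and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param summaries output of \code{\link{summarize_z}} (any data.frame
#'   with \code{target} and \code{normalized_z}).
#' @param target_a,target_b the two targets to compare.
#' @return list with \code{p_value}, \code{statistic} (rank-sum W for
#'   \code{target_a}), \code{n_a}, \code{n_b}, \code{exact}.
#' @export
compare_position <- function(summaries, target_a, target_b) {
  va <- summaries$normalized_z[summaries$target == target_a]
  vb <- summaries$normalized_z[summaries$target == target_b]
  res <- rank_sum_test(va, vb)
  res$n_a <- length(va); res$n_b <- length(vb)
  res
}

# shared rank-sum wrapper: exact for small untied samples, otherwise
# normal approximation with tie + continuity correction
rank_sum_test <- function(a, b, exact_max_n = 30) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 observations per group")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b)) <= exact_max_n && !ties
  ht <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = use_exact, correct = TRUE)
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
       exact = use_exact)
}

#' Per-cell neurite/soma puncta ratios
#'
#' For each cell the ratio of spot counts in the neurite compartment to
#' the soma compartment is computed; cells with no soma spots are excluded
#' with a warning (the ratio is undefined), cells with no neurite spots
#' get ratio 0 and are retained. When exactly two targets are present a
#' Wilcoxon rank-sum comparison of their per-cell ratios is attached.
#'
#' @param spots data.frame with \code{cell_id}, \code{target} and a
#'   \code{compartment} column with values \code{"neurite"}/\code{"soma"}.
#' @return data.frame per cell: \code{cell_id}, \code{target},
#'   \code{n_neurite}, \code{n_soma}, \code{ratio}; with attribute
#'   \code{"comparison"} (list with \code{p_value}) when two targets are
#'   present.
#' @export
neurite_soma_ratio <- function(spots) {
  req <- c("cell_id", "target", "compartment")
  if (!all(req %in% names(spots)))
    stop("spots need columns: ", paste(req, collapse = ", "))
  bad <- setdiff(unique(spots$compartment), c("neurite", "soma"))
  if (length(bad))
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "))
  cells <- unique(spots[, c("cell_id", "target")])
  cnt <- function(comp) {
    k <- spots$compartment == comp
    tab <- table(spots$cell_id[k])
    as.integer(tab[match(cells$cell_id, names(tab))])
  }
  out <- data.frame(cells,
                    n_neurite = cnt("neurite"), n_soma = cnt("soma"),
                    stringsAsFactors = FALSE)
  out$n_neurite[is.na(out$n_neurite)] <- 0L
  out$n_soma[is.na(out$n_soma)] <- 0L
  drop <- out$n_soma == 0
  if (any(drop)) {
    warning(sum(drop), " cell(s) with zero soma spots excluded")
    out <- out[!drop, , drop = FALSE]
  }
  out$ratio <- out$n_neurite / out$n_soma
  rownames(out) <- NULL
  tg <- unique(out$target)
  if (length(tg) == 2) {
    cmp <- rank_sum_test(out$ratio[out$target == tg[1]],
                         out$ratio[out$target == tg[2]])
    cmp$targets <- tg
    attr(out, "comparison") <- cmp
  }
  out
}

#' Read / write smFISH spot tables as CSV
#'
#' Schema: \code{spot_id,cell_id,target,x_um,y_um,z_um[,compartment]}.
#'
#' @param file path.
#' @param spots data.frame.
#' @return \code{read_spots} returns the data.frame; \code{write_spots}
#'   its input, invisibly.
#' @export
read_spots <- function(file) {
  sp <- utils::read.csv(file, stringsAsFactors = FALSE)
  req <- c("spot_id", "cell_id", "target", "x_um", "y_um", "z_um")
  miss <- setdiff(req, names(sp))
  if (length(miss))
    stop("spot table ", file, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(sp$z_um < 0)) stop("z coordinates must be non-negative")
  sp
}

#' @rdname read_spots
#' @export
write_spots <- function(spots, file) {
  utils::write.csv(spots, file, row.names = FALSE, quote = FALSE)
  invisible(spots)
}
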