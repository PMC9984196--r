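#' Configuration for the smFISH spot simulator
#'
#' Emulates spot-detection exports from 3D image stacks of an epithelial
#' monolayer: each cell is a slab of height \code{cell_height} (z = 0 at the
#' basal surface), a non-localized control transcript is uniform over the
#' slab, and localized targets are the same law translated along z.
#'
#' @param n_cells cells per target.
#' @param spots_per_cell spots per cell (the imaging QC window in the
#'   pipeline expects roughly 100-1000 for reporters).
#' @param cell_height slab height in micrometres (default 13.6, a typical
#'   monolayer stack depth).
#' @param spot_noise_sd gaussian localization noise in micrometres added to
#'   each z coordinate.
#' @param seed integer seed.
#' @return a list of class \code{spot_sim_config}.
#' @export
spot_sim_config <- function(n_cells = 20, spots_per_cell = 200,
                            cell_height = 13.6, spot_noise_sd = 0.5,
                            seed = 1L) {
  if (n_cells < 0 || spots_per_cell < 1) stop("invalid cell/spot counts")
  if (cell_height <= 0) stop("cell_height must be positive")
  if (spot_noise_sd < 0) stop("spot_noise_sd must be non-negative")
  structure(list(n_cells = as.integer(n_cells),
                 spots_per_cell = as.integer(spots_per_cell),
                 cell_height = cell_height,
                 spot_noise_sd = spot_noise_sd,
                 seed = as.integer(seed)),
            class = "spot_sim_config")
}

#' Simulate an smFISH spot table with planted apicobasal shifts
#'
#' Every target (and the uniform control named \code{"control"}) is imaged
#' in its own set of \code{n_cells} cells, mirroring reporter experiments
#' where each construct is expressed in different cells. Shifted targets
#' draw z from the control law translated by the target's shift plus
#' gaussian noise. The control law is uniform over the interior band of
#' the slab left after reserving room for the largest planted shift plus
#' three noise standard deviations on either side: translating a
#' full-height uniform would inevitably push mass outside the slab and
#' truncation would attenuate every planted shift, breaking the contract
#' that the planted shift is the expected displacement. Residual
#' out-of-slab draws (beyond three sigma) are rejected and resampled, so
#' no probability mass piles up at the boundaries.
#'
#' @param config a \code{\link{spot_sim_config}}.
#' @param targets data.frame with columns \code{target} and \code{shift_um}
#'   (negative = toward the basal surface). A control row is added
#'   automatically when absent.
#' @return list with \code{spots} (data.frame \code{spot_id},
#'   \code{cell_id}, \code{target}, \code{x_um}, \code{y_um}, \code{z_um})
#'   and \code{truth} (per-target planted shift).
#' @export
generate_spot_table <- function(config,
                                targets = data.frame(target = "target",
                                                     shift_um = -2)) {
  stopifnot(inherits(config, "spot_sim_config"))
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  if (!all(c("target", "shift_um") %in% names(targets)))
    stop("targets needs columns target and shift_um")
  if (!"control" %in% targets$target)
    targets <- rbind(data.frame(target = "control", shift_um = 0),
                     targets)
  H <- config$cell_height
  if (any(abs(targets$shift_um) >= H))
    stop("planted shift magnitude exceeds the cell height")
  if (any(abs(targets$shift_um) + 3 * config$spot_noise_sd >= H))
    stop("shift plus noise is not representable inside the slab")
  set.seed(config$seed)
  nc <- config$n_cells; ns <- config$spots_per_cell
  if (nc == 0) {
    empty <- data.frame(spot_id = character(), cell_id = character(),
                        target = character(), x_um = numeric(),
                        y_um = numeric(), z_um = numeric(),
                        stringsAsFactors = FALSE)
    return(list(spots = empty, truth = targets))
  }
  pad <- 3 * config$spot_noise_sd
  lo <- pad + max(0, -min(targets$shift_um))
  hi <- H - pad - max(0, max(targets$shift_um))
  if (hi <= lo)
    stop("planted shifts and noise leave no interior band inside the slab")
  draw_z <- function(n, shift) {
    out <- numeric(0)
    while (length(out) < n) {
      z <- stats::runif(n, lo, hi) + shift +
        stats::rnorm(n, 0, config$spot_noise_sd)
      out <- c(out, z[z >= 0 & z <= H])
    }
    out[seq_len(n)]
  }
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    tg <- targets$target[i]
    data.frame(cell_id = rep(sprintf("%s_cell%03d", tg, seq_len(nc)),
                             each = ns),
               target = tg,
               x_um = stats::runif(nc * ns, 0, 50),
               y_um = stats::runif(nc * ns, 0, 50),
               z_um = draw_z(nc * ns, targets$shift_um[i]),
               stringsAsFactors = FALSE)
  })
  spots <- do.call(rbind, rows)
  spots <- data.frame(spot_id = sprintf("spot%07d", seq_len(nrow(spots))),
                      spots, stringsAsFactors = FALSE)
  list(spots = spots, truth = targets)
}

#' Simulate neurite/soma spot counts per cell
#'
#' For neuronal geometry the informative quantity is the count of puncta in
#' the neurite versus the soma compartment. Per cell, soma counts are
#' Poisson with mean \code{soma_mean} and neurite counts Poisson with mean
#' \code{soma_mean * ratio}.
#'
#' @param n_cells number of cells per construct.
#' @param constructs data.frame with columns \code{target} and
#'   \code{ratio} (expected neurite/soma count ratio).
#' @param soma_mean expected soma spot count per cell.
#' @param seed integer seed.
#' @return data.frame of spots with columns \code{spot_id}, \code{cell_id},
#'   \code{target}, \code{x_um}, \code{y_um}, \code{z_um},
#'   \code{compartment}.
#' @export
generate_neurite_spots <- function(n_cells = 30,
                                   constructs = data.frame(
                                     target = c("wt", "mut"),
                                     ratio = c(0.2, 0.1)),
                                   soma_mean = 100, seed = 1L) {
  stopifnot(n_cells >= 1, soma_mean > 0, all(constructs$ratio >= 0))
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(constructs)), function(i) {
    tg <- constructs$target[i]
    n_soma <- stats::rpois(n_cells, soma_mean)
    n_soma <- pmax(n_soma, 1)      # fractionation always recovers some soma signal
    n_neur <- stats::rpois(n_cells, soma_mean * constructs$ratio[i])
    do.call(rbind, lapply(seq_len(n_cells), function(cc) {
      n <- n_soma[cc] + n_neur[cc]
      data.frame(cell_id = sprintf("%s_cell%03d", tg, cc), target = tg,
                 x_um = stats::runif(n, 0, 100),
                 y_um = stats::runif(n, 0, 100),
                 z_um = stats::runif(n, 0, 5),
                 compartment = rep(c("soma", "neurite"),
                                   c(n_soma[cc], n_neur[cc])),
                 stringsAsFactors = FALSE)
    }))
  })
  spots <- do.call(rbind, rows)
  data.frame(spot_id = sprintf("spot%07d", seq_len(nrow(spots))), spots,
             stringsAsFactors = FALSE)
}
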