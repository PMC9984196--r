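#' Configuration for the 5' UTR simulator
#'
#' Generates random-background 5' UTR sequences in which a subset carries a
#' planted run of pyrimidines detectable by \code{\link{scan_prre}}.
#'
#' @param n_sequences number of UTRs.
#' @param length_range integer pair: min and max UTR length.
#' @param planted_motif_length length of the planted pyrimidine run
#'   (default 10, the scanner's window).
#' @param planted_position_range integer pair: range of recorded element
#'   start positions for planted sequences.
#' @param background_pyrimidine_prob per-base probability that a background
#'   base is a pyrimidine; must be below 0.5 so that spurious qualifying
#'   windows are rare.
#' @param planted_fraction proportion of sequences that receive a motif.
#' @param seed integer seed.
#' @return a list of class \code{utr_sim_config}.
#' @export
utr_sim_config <- function(n_sequences = 100, length_range = c(60, 200),
                           planted_motif_length = 10,
                           planted_position_range = c(1, 40),
                           background_pyrimidine_prob = 0.25,
                           planted_fraction = 0.5, seed = 1L) {
  if (planted_motif_length < 10)
    stop("planted_motif_length must be at least 10")
  if (background_pyrimidine_prob >= 0.5 || background_pyrimidine_prob < 0)
    stop("background_pyrimidine_prob must lie in [0, 0.5)")
  if (length(length_range) != 2 || diff(length_range) < 0 ||
      length_range[1] < 1)
    stop("length_range must be an increasing pair of positive integers")
  if (length(planted_position_range) != 2 ||
      diff(planted_position_range) < 0 || planted_position_range[1] < 1)
    stop("planted_position_range must be an increasing pair of positions")
  # the motif is planted one base 3' of the recorded position (see
  # generate_utr_set), so it needs position + length + 1 bases of room
  if (planted_position_range[2] + planted_motif_length + 1 >
      length_range[1])
    stop("planted motif does not fit in the shortest sequence")
  if (planted_fraction < 0 || planted_fraction > 1)
    stop("planted_fraction must lie in [0, 1]")
  structure(list(n_sequences = as.integer(n_sequences),
                 length_range = as.integer(length_range),
                 planted_motif_length = as.integer(planted_motif_length),
                 planted_position_range = as.integer(planted_position_range),
                 background_pyrimidine_prob = background_pyrimidine_prob,
                 planted_fraction = planted_fraction,
                 seed = as.integer(seed)),
            class = "utr_sim_config")
}

#' Simulate 5' UTR sequences with planted pyrimidine-rich elements
#'
#' Background bases are pyrimidines (C/T, equal odds) with probability
#' \code{background_pyrimidine_prob} and purines (A/G) otherwise. Planted
#' sequences carry an uninterrupted pyrimidine run. Because any 10-nt
#' window holding 9 pyrimidines qualifies, a run starting at position p
#' would be reported from the window at p - 1; the generator therefore
#' places the run one base 3' of the recorded truth position and forces the
#' two bases 5' of the run to purines, so \code{\link{scan_prre}} reports
#' the merged element exactly at the recorded position. A truth position of
#' 1 places the run at the very 5' end (a 5' TOP configuration).
#'
#' @param config a \code{\link{utr_sim_config}}.
#' @return list with \code{utrs} (a \code{Biostrings::DNAStringSet}) and
#'   \code{truth} (data.frame \code{utr_id}, \code{planted},
#'   \code{planted_start} -- \code{NA} where nothing was planted).
#' @export
generate_utr_set <- function(config) {
  stopifnot(inherits(config, "utr_sim_config"))
  set.seed(config$seed)
  n <- config$n_sequences
  ids <- sprintf("utr_%04d", seq_len(n))
  lens <- sample(seq(config$length_range[1], config$length_range[2]),
                 n, replace = TRUE)
  n_planted <- round(config$planted_fraction * n)
  planted <- seq_len(n) <= n_planted      # ids are anonymous; no need to randomize
  p_py <- config$background_pyrimidine_prob
  draw_bg <- function(k) {
    py <- stats::runif(k) < p_py
    ifelse(py, sample(c("C", "T"), k, replace = TRUE),
           sample(c("A", "G"), k, replace = TRUE))
  }
  starts <- rep(NA_integer_, n)
  seqs <- vapply(seq_len(n), function(i) {
    s <- draw_bg(lens[i])
    if (planted[i]) {
      p <- sample(seq(config$planted_position_range[1],
                      config$planted_position_range[2]), 1)
      run <- sample(c("C", "T"), config$planted_motif_length, replace = TRUE)
      if (p == 1) {
        s[seq_along(run)] <- run
      } else {
        # purines at p-1 (if present) and p insulate the 5' flank; the run
        # starts at p+1 so the first qualifying window starts at p
        if (p > 1) s[p - 1] <- sample(c("A", "G"), 1)
        s[p] <- sample(c("A", "G"), 1)
        s[p + seq_along(run)] <- run
      }
      starts[i] <<- p
    }
    paste(s, collapse = "")
  }, character(1))
  utrs <- Biostrings::DNAStringSet(seqs)
  names(utrs) <- ids
  list(utrs = utrs,
       truth = data.frame(utr_id = ids, planted = planted,
                          planted_start = starts,
                          stringsAsFactors = FALSE))
}
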