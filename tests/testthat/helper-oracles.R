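# Independent brute-force oracles used across tests. These deliberately do
# not share code with the package implementation.

# enumerate every window, test it, then merge qualifying windows whose
# starts are within `window` of each other
brute_prre <- function(seq, window = 10, min_pyr = 9) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  qual <- integer(0)
  if (n >= window) {
    for (s in 1:(n - window + 1)) {
      w <- chars[s:(s + window - 1)]
      if (sum(w %in% c("C", "T", "U")) >= min_pyr) qual <- c(qual, s)
    }
  }
  if (!length(qual))
    return(data.frame(start = integer(), end = integer(),
                      n_qualifying_windows = integer(),
                      motif_class = character()))
  groups <- list(); cur <- qual[1]
  if (length(qual) > 1) {
    for (i in 2:length(qual)) {
      if (qual[i] - cur[length(cur)] <= window) cur <- c(cur, qual[i])
      else { groups[[length(groups) + 1]] <- cur; cur <- qual[i] }
    }
  }
  groups[[length(groups) + 1]] <- cur
  out <- do.call(rbind, lapply(groups, function(g)
    data.frame(start = min(g), end = max(g) + window - 1,
               n_qualifying_windows = length(g))))
  out$motif_class <- ifelse(out$start == 1, "TOP", "PRTE")
  out
}

# exact two-sided rank-sum p-value by full enumeration of rank assignments
brute_ranksum_p <- function(a, b) {
  n <- length(a) + length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_along(a)])
  all_w <- apply(utils::combn(n, length(a)), 2,
                 function(idx) sum(rank(seq_len(n))[idx]))
  mu <- length(a) * (n + 1) / 2
  mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-12)
}

# random nucleotide sequence
random_seq <- function(len, py_prob = 0.4) {
  paste(ifelse(runif(len) < py_prob,
               sample(c("C", "T"), len, replace = TRUE),
               sample(c("A", "G"), len, replace = TRUE)),
        collapse = "")
}

# Benjamini-Hochberg step-up written from the definition
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# spreadsheet-style bias recomputation on a tiny matrix: effective library
# sizes, CPM, pseudocounted log2 ratio of fraction means
brute_bias <- function(m, is_num, pseudocount = 0.5) {
  libs <- colSums(m)
  props <- sweep(m, 2, libs, "/")
  ref <- which(apply(m, 1, function(r) all(r > 0)))
  rat <- sapply(seq_len(ncol(m)), function(j) {
    r <- sapply(ref, function(g)
      props[g, j] / exp(mean(log(props[g, ]))))
    median(r)
  })
  rat <- rat / exp(mean(log(rat)))
  eff <- libs * rat
  cpm <- sweep(m, 2, eff / 1e6, "/")
  m1 <- rowMeans(cpm[, is_num, drop = FALSE])
  m2 <- rowMeans(cpm[, !is_num, drop = FALSE])
  log2((m1 + pseudocount) / (m2 + pseudocount))
}
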