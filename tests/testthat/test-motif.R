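# printed wildtype/mutant PRRE pairs used as fixed reference sequences
RPL7_WT  <- "CCTCTTTTTCCGGCTGGAACC"
RPL7_MUT <- "AAGAGGGGGAAGGAGGGAAAA"
RPS28_WT <- "ACTCCTCTCCGCCAGACCGCCGCCGCGCCGCCATC"
RPS28_MUT <- "AAGAAGAGAAGAAAGAAAGAAGAAGAGAAGAAAGA"

test_that("purine swap maps the reference PRREs to their printed mutants", {
  expect_identical(mutate_prre(RPL7_WT), RPL7_MUT)
  expect_identical(mutate_prre(RPS28_WT), RPS28_MUT)
  expect_identical(mutate_prre("AAAA"), "AAAA")
  expect_identical(mutate_prre("acgu"), "aagg")
  expect_identical(mutate_prre("NCN"), "NAN")
  expect_error(mutate_prre("ACGX"), "X")
})

test_that("scanner finds single 5' elements in the reference PRREs", {
  h1 <- scan_prre(RPL7_WT)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$start, 1L)
  expect_equal(h1$motif_class, "TOP")
  expect_equal(h1$n_qualifying_windows, 3L)

  h2 <- scan_prre(RPS28_WT)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$start, 1L)
  expect_equal(h2$n_qualifying_windows, 4L)

  expect_equal(nrow(scan_prre(RPL7_MUT)), 0)
  expect_equal(nrow(scan_prre(RPS28_MUT)), 0)
})

test_that("scanner equals the brute-force window oracle on random sequences", {
  set.seed(101)
  for (i in 1:300) {
    s <- random_seq(sample(0:200, 1), py_prob = runif(1, 0.2, 0.6))
    got <- scan_prre(s)
    want <- brute_prre(s)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_qualifying_windows, want$n_qualifying_windows)
    expect_equal(got$motif_class, want$motif_class)
  }
})

test_that("mutated sequences never contain an element", {
  set.seed(5)
  for (i in 1:100) {
    s <- random_seq(sample(10:150, 1), py_prob = 0.6)
    expect_equal(nrow(scan_prre(mutate_prre(s))), 0)
  }
})

test_that("prepending purines shifts interior hits by exactly k", {
  set.seed(6)
  for (i in 1:20) {
    # two leading purines make the 5'-most hit an interior one, so no
    # prepended window can reach 9 pyrimidines before the existing start
    s <- paste0("GG", random_seq(12, py_prob = 1),
                random_seq(30, py_prob = 0.3))
    base <- scan_prre(s)
    expect_gt(base$start[1], 1L)
    for (k in c(1, 5)) {
      shifted <- scan_prre(paste0(strrep("A", k), s))
      expect_equal(shifted$start, base$start + k)
      expect_equal(shifted$end, base$end + k)
      expect_identical(shifted$motif_class, base$motif_class)
    }
  }
})

test_that("a TOP element tolerates one leading purine but not two", {
  # the 9-of-10 rule absorbs a single prepended purine into the leading
  # window, so the element still starts at 1 and stays TOP; from two
  # prepended purines on, the first qualifying window starts at k
  s <- paste0(strrep("CT", 7), strrep("G", 30))
  expect_equal(scan_prre(s)$motif_class[1], "TOP")
  one <- scan_prre(paste0("A", s))
  expect_equal(one$start[1], 1L)
  expect_equal(one$motif_class[1], "TOP")
  for (k in 2:4) {
    sh <- scan_prre(paste0(strrep("A", k), s))
    expect_equal(sh$start[1], k)
    expect_equal(sh$motif_class[1], "PRTE")
  }
})

test_that("window-count and ordering invariants hold", {
  set.seed(7)
  for (i in 1:100) {
    h <- scan_prre(random_seq(sample(20:200, 1), py_prob = 0.55))
    if (!nrow(h)) next
    expect_true(all(h$n_qualifying_windows <= h$end - h$start - 10 + 2))
    expect_true(all(h$end - h$start + 1 >= 10))
    expect_true(all(diff(h$start) > 0))
    if (nrow(h) > 1) expect_true(all(h$start[-1] > h$end[-nrow(h)]))
  }
})

test_that("scanner validates parameters and alphabet", {
  expect_error(scan_prre("ACGT", window = 0), "window")
  expect_error(scan_prre("ACGT", min_pyrimidines = 11), "exceed")
  expect_error(scan_prre("ACGTB"), "B")
  # U and case-insensitivity; N is a non-pyrimidine
  expect_equal(scan_prre("ucuccuuuuu")$motif_class, "TOP")
  expect_equal(nrow(scan_prre(paste0("CCTCTTTT", strrep("N", 10)))), 0)
  expect_equal(nrow(scan_prre("")), 0)
  expect_equal(nrow(scan_prre("CCTCTTT")), 0)  # shorter than one window
})

test_that("annotate_utrs picks the longest UTR and the most 5' element", {
  utrs <- c(tx_short = random_seq(50, py_prob = 0),
            tx_long = paste0(strrep("A", 11), strrep("CT", 5),
                             strrep("G", 59)))
  ann <- annotate_utrs(utrs, gene_ids = c("geneA", "geneA"))
  expect_equal(nrow(ann), 1)
  expect_equal(ann$utr_id, "tx_long")
  expect_equal(ann$most_5prime_position, 11L)  # purine at 11 + 9 pyrimidines
  expect_equal(ann$motif_class, "PRTE")

  two <- paste0(strrep("CT", 6), strrep("A", 28),
                strrep("T", 10), strrep("G", 20))
  ann2 <- annotate_utrs(c(tx = two))
  expect_equal(ann2$most_5prime_position, 1L)
  expect_equal(ann2$motif_class, "TOP")

  # tie on length broken lexicographically by transcript id
  utrs3 <- c(tx_b = strrep("A", 30), tx_a = strrep("A", 30))
  ann3 <- annotate_utrs(utrs3, gene_ids = c("g", "g"))
  expect_equal(ann3$utr_id, "tx_a")
  expect_false(ann3$has_prre)
  expect_error(annotate_utrs(character(0)), "empty")
})

test_that("planted UTR sets round-trip through the scanner", {
  # clean background: annotations must equal the truth table exactly
  cfg0 <- utr_sim_config(n_sequences = 60, background_pyrimidine_prob = 0,
                         seed = 42)
  sim0 <- generate_utr_set(cfg0)
  ann0 <- annotate_utrs(sim0$utrs)
  expect_equal(ann0$has_prre, sim0$truth$planted)
  planted <- sim0$truth$planted
  expect_equal(ann0$most_5prime_position[planted],
               sim0$truth$planted_start[planted])
  expect_equal(ann0$motif_class[planted],
               ifelse(sim0$truth$planted_start[planted] == 1, "TOP", "PRTE"))

  # default background: every planted element found at its position, and
  # spurious background hits are rare
  cfg <- utr_sim_config(n_sequences = 200, seed = 9)
  sim <- generate_utr_set(cfg)
  ann <- annotate_utrs(sim$utrs)
  pl <- sim$truth$planted
  expect_true(all(ann$has_prre[pl]))
  expect_gte(mean(ann$most_5prime_position[pl] ==
                  sim$truth$planted_start[pl]), 0.95)
  expect_lt(mean(ann$has_prre[!pl]), 0.05)
})

test_that("background composition alone rarely produces a hit", {
  cfg <- utr_sim_config(n_sequences = 400, planted_fraction = 0, seed = 23)
  sim <- generate_utr_set(cfg)
  ann <- annotate_utrs(sim$utrs)
  expect_lt(mean(ann$has_prre), 0.05)
})

test_that("bias class comparison detects shifted classes", {
  set.seed(12)
  ids <- sprintf("g%04d", 1:2000)
  bias <- data.frame(gene_id = ids, bias = rnorm(2000))
  shifted <- ids[1:50]
  bias$bias[1:50] <- bias$bias[1:50] - 1
  res <- bias_by_motif_class(bias, list(down = shifted))
  expect_lt(res$p_value, 1e-6)
  expect_lt(res$class_median, res$background_median)
  expect_equal(res$n, 50)
  # identical machinery as class_bias_summary
  cbs <- class_bias_summary(setNames(bias$bias, bias$gene_id), shifted)
  expect_equal(res$p_value, cbs$p_value, tolerance = 1e-12)
  expect_error(bias_by_motif_class(bias, list(tiny = ids[1])), "fewer than 2")
})

test_that("hit tables serialize as TSV and BED", {
  hits <- cbind(sequence_id = "utr1", scan_prre(RPL7_WT))
  tf <- tempfile(fileext = ".tsv")
  write_prre_hits(hits, tf)
  expect_equal(utils::read.delim(tf)$start, 1L)
  bf <- tempfile(fileext = ".bed")
  write_prre_hits(hits, bf, format = "bed")
  bed <- utils::read.delim(bf, header = FALSE)
  expect_equal(bed$V2, 0L)   # 0-based start
  expect_equal(bed$V3, 12L)  # half-open end
  expect_equal(bed$V4, "TOP")
})
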