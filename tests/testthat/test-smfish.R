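spot_df <- function(cell_id, target, z, compartment = NULL) {
  df <- data.frame(spot_id = sprintf("s%05d", seq_along(z)),
                   cell_id = cell_id, target = target,
                   x_um = 0, y_um = 0, z_um = z,
                   stringsAsFactors = FALSE)
  if (!is.null(compartment)) df$compartment <- compartment
  df
}

test_that("QC filter applies inclusive per-cell spot-count bounds", {
  counts <- c(99, 100, 1000, 1001)
  sp <- spot_df(rep(sprintf("c%d", 1:4), counts), "r",
                z = runif(sum(counts), 0, 10))
  kept <- qc_filter_cells(sp, 100, 1000)
  expect_setequal(unique(kept$cell_id), c("c2", "c3"))
  expect_equal(nrow(qc_filter_cells(sp, 0, Inf)), nrow(sp))
  small <- spot_df(rep("c1", 50), "r", runif(50, 0, 10))
  expect_equal(nrow(qc_filter_cells(small, 100, 1000)), 0)
  expect_error(qc_filter_cells(sp, -1, 10), "non-negative")
  expect_error(qc_filter_cells(sp, 10, 5), "min_spots")
})

test_that("QC filter honours an in_frame flag", {
  sp <- spot_df(rep(c("c1", "c2"), each = 150), "r", runif(300, 0, 10))
  sp$in_frame <- sp$cell_id == "c1"
  kept <- qc_filter_cells(sp, 100, 1000)
  expect_setequal(unique(kept$cell_id), "c1")
})

test_that("per-cell z positions are normalized to the control median", {
  sp <- rbind(spot_df(rep("ctrl1", 3), "firefly", c(5, 5, 5)),
              spot_df(rep("cellA", 2), "reporter", c(2.0, 4.4)))
  sz <- summarize_z(sp, control_target = "firefly")
  a <- sz[sz$target == "reporter", ]
  expect_equal(a$mean_z, 3.2, tolerance = 1e-12)
  expect_equal(a$normalized_z, -1.8, tolerance = 1e-12)
  expect_equal(attr(sz, "reference_z"), 5)
  expect_error(summarize_z(sp, control_target = "nope"), "not present")
})

test_that("slice indices convert to micrometres through the slice spacing", {
  sp <- spot_df(rep(c("c1", "c2"), each = 2), c("ctl", "ctl", "r", "r"), 0)
  sp$z_um <- NULL
  sp$z_slice <- c(10, 20, 30, 40)
  sz <- summarize_z(sp, control_target = "ctl")
  expect_equal(sz$mean_z[sz$target == "ctl"], 3)     # 15 slices * 0.2
  expect_equal(sz$mean_z[sz$target == "r"], 7)
  sz5 <- summarize_z(sp, control_target = "ctl", slice_spacing = 0.5)
  expect_equal(sz5$mean_z[sz5$target == "r"], 17.5)
})

test_that("normalized positions are invariant to a global z translation", {
  set.seed(44)
  sp <- rbind(
    spot_df(rep(sprintf("c%d", 1:5), each = 40), "control",
            runif(200, 0, 10)),
    spot_df(rep(sprintf("t%d", 1:5), each = 40), "reporter",
            runif(200, 0, 10)))
  a <- summarize_z(sp, "control")
  sp2 <- sp; sp2$z_um <- sp2$z_um + 3.7
  b <- summarize_z(sp2, "control")
  expect_equal(a$normalized_z, b$normalized_z, tolerance = 1e-12)
})

test_that("cells, not spots, are the unit of aggregation", {
  set.seed(45)
  sp <- rbind(
    spot_df(rep("ctl", 30), "control", runif(30, 0, 10)),
    spot_df(rep(c("c1", "c2"), c(10, 200)), "reporter",
            c(runif(10, 8, 10), runif(200, 0, 2))))
  a <- summarize_z(sp, "control")
  dup <- rbind(sp, transform(sp, spot_id = paste0(spot_id, "_d")))
  b <- summarize_z(dup, "control")
  expect_equal(a$mean_z, b$mean_z, tolerance = 1e-12)
  expect_equal(b$n_spots, 2L * a$n_spots)
})

test_that("rank-sum p-values equal brute-force enumeration for small n", {
  s <- data.frame(target = rep(c("a", "b"), each = 3),
                  normalized_z = c(1, 2, 3, 10, 11, 12))
  expect_equal(compare_position(s, "a", "b")$p_value, 0.1)
  set.seed(46)
  for (i in 1:25) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    va <- rnorm(na); vb <- rnorm(nb)
    s <- data.frame(target = rep(c("a", "b"), c(na, nb)),
                    normalized_z = c(va, vb))
    got <- compare_position(s, "a", "b")
    expect_true(got$exact)
    expect_equal(got$p_value, brute_ranksum_p(va, vb), tolerance = 1e-12)
  }
})

test_that("identical groups compare with p = 1", {
  s <- data.frame(target = rep(c("a", "b"), each = 4),
                  normalized_z = rep(c(1, 2, 3, 4), 2))
  expect_equal(compare_position(s, "a", "b")$p_value, 1)
})

test_that("spot simulator respects slab bounds, seeds and empty input", {
  cfg <- spot_sim_config(n_cells = 5, spots_per_cell = 50, seed = 2)
  sim <- generate_spot_table(cfg, data.frame(target = "t", shift_um = -2))
  expect_true(all(sim$spots$z_um >= 0 & sim$spots$z_um <= 13.6))
  expect_true(all(c("control", "t") %in% sim$spots$target))
  expect_identical(sim$spots,
                   generate_spot_table(cfg, data.frame(target = "t",
                                                       shift_um = -2))$spots)
  empty <- generate_spot_table(spot_sim_config(n_cells = 0, seed = 1))
  expect_equal(nrow(empty$spots), 0)
  expect_error(generate_spot_table(cfg, data.frame(target = "t",
                                                   shift_um = -20)),
               "exceeds the cell height")
})

test_that("a planted shift is the mean displacement in the no-noise case", {
  cfg <- spot_sim_config(n_cells = 10, spots_per_cell = 400,
                         spot_noise_sd = 0, seed = 8)
  sim <- generate_spot_table(cfg, data.frame(target = "t", shift_um = -2))
  mz <- tapply(sim$spots$z_um, sim$spots$target, mean)
  expect_lt(abs(unname(mz["t"] - mz["control"]) + 2), 0.2)
})

test_that("null-shift targets match the control closely", {
  cfg <- spot_sim_config(n_cells = 10, spots_per_cell = 200, seed = 21)
  sim <- generate_spot_table(cfg, data.frame(target = "t", shift_um = 0))
  mz <- tapply(sim$spots$z_um, sim$spots$target, mean)
  expect_lt(abs(mz["t"] - mz["control"]), 0.2)
})

test_that("neurite/soma ratios are per cell with zero-soma cells dropped", {
  sp <- rbind(
    spot_df(rep("c1", 110), "wt", runif(110),
            compartment = rep(c("neurite", "soma"), c(10, 100))),
    spot_df(rep("c2", 40), "wt", runif(40),
            compartment = rep("soma", 40)),
    spot_df(rep("c3", 25), "wt", runif(25),
            compartment = rep("neurite", 25)))
  expect_warning(out <- neurite_soma_ratio(sp), "zero soma")
  expect_setequal(out$cell_id, c("c1", "c2"))
  expect_equal(out$ratio[out$cell_id == "c1"], 0.1)
  expect_equal(out$ratio[out$cell_id == "c2"], 0)  # no neurite spots: kept
  expect_error(neurite_soma_ratio(transform(sp, compartment = "axon")),
               "unknown compartment")
})

test_that("a doubled neurite export ratio is detected between constructs", {
  sp <- generate_neurite_spots(n_cells = 30,
                               constructs = data.frame(
                                 target = c("wt", "mut"),
                                 ratio = c(0.2, 0.1)),
                               soma_mean = 100, seed = 17)
  out <- neurite_soma_ratio(sp)
  cmp <- attr(out, "comparison")
  expect_lt(cmp$p_value, 0.01)
  med <- tapply(out$ratio, out$target, median)
  expect_gt(med["wt"], med["mut"])
})

test_that("spot tables round-trip through CSV", {
  sim <- generate_spot_table(spot_sim_config(n_cells = 2, spots_per_cell = 5,
                                             seed = 3))
  f <- tempfile(fileext = ".csv")
  write_spots(sim$spots, f)
  back <- read_spots(f)
  expect_equal(back$z_um, sim$spots$z_um, tolerance = 1e-6)
  expect_equal(back$cell_id, sim$spots$cell_id)
})
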