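test_that("a uniform cell has zero midcell-minus-quarter intensity", {
  px <- 0.065
  m <- capsule_mask(3.0 / px, 1.0 / px)
  img <- matrix(0, nrow(m), ncol(m)); img[m == 1L] <- 50
  axis <- extract_cell_axis(m, 1L)
  mid <- midcell_intensity(img, m, 1L, axis)
  expect_equal(mid$value, 0, tolerance = 0.5)
  expect_equal(mid$midcell_raw, 50, tolerance = 1)
})

test_that("a planted septal band yields the planted enrichment ratio", {
  sim <- simulate_cells(cell_sim_params(
    n_cells = 6, enrichment = 2, septal_sigma_um = 0.2,
    poisson_noise = FALSE, read_noise_sd = 0, background = 0, seed = 9))
  res <- analyze_cells(sim$gfp, sim$mask)
  # band centre is ~2x the cytoplasmic level; 3-px averaging lowers it a little
  expect_equal(mean(res$cells$midcell_raw / res$cells$quarter_raw), 2,
               tolerance = 0.1)
  # value ~ (enrichment - 1) * cytoplasmic level
  expect_equal(mean(res$cells$value), 200, tolerance = 0.15 * 200)
})

test_that("group means order correctly for enriched vs flat cells", {
  for (s in 1:3) {
    enr <- analyze_cells_of(seed = 100 + s, enrichment = 2, n = 15)
    flat <- analyze_cells_of(seed = 200 + s, enrichment = 1, n = 15)
    expect_gt(mean(enr$value), mean(flat$value))
  }
})

test_that("control-median normalization yields relative midcell intensities", {
  df <- tibble::tibble(
    cell_id = 1:8,
    group = c("WT", "WT", "WT", "mut", rep("WT", 3), "mut"),
    replicate = c(rep("r1", 4), rep("r2", 4)),
    value = c(2, 4, 6, 8, 10, 20, 30, 5))
  out <- normalize_by_control(df, control_group = "WT")
  expect_equal(out$relative_value[1:3], c(0.5, 1.0, 1.5))
  expect_equal(out$relative_value[4], 2.0)          # 8 / median(2,4,6)
  # per-replicate median of normalised control values is 1
  for (r in unique(out$replicate)) {
    ctrl <- out$relative_value[out$replicate == r & out$group == "WT"]
    expect_equal(median(ctrl), 1)
  }
  # a replicate without controls is an error naming the replicate
  df2 <- df
  df2$group[df2$replicate == "r2"] <- "mut"
  expect_error(normalize_by_control(df2, "WT"), "r2")
})

test_that("intensity rescaling cancels in relative values", {
  df <- tibble::tibble(group = rep(c("WT", "mut"), each = 4),
                       replicate = "r1", value = c(1:4, 3:6))
  a <- normalize_by_control(df, "WT")$relative_value
  df$value <- df$value * 37.5   # e.g. different exposure
  b <- normalize_by_control(df, "WT")$relative_value
  expect_equal(a, b)
})

test_that("the Mann-Whitney comparison behaves at its boundaries", {
  same <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.9)

  sep <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)          # complete separation, smaller-rank group
  expect_lt(sep$p_value, 0.1)

  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})
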