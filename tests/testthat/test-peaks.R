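two_frag_panel <- function() list(
  `GlcNAc-MurNAcAnh` = glycan_fragment(c("GlcNAc", "anhMurNAc")),
  `GlcN-MurNAcAnh` = glycan_fragment(c("GlcN", "anhMurNAc"))
)

test_that("assign_peaks matches peaks within ppm tolerance and flags the best", {
  peaks <- tibble::tibble(mz = c(437.1766, 437.30), intensity = c(10, 5))
  asg <- assign_peaks(peaks, two_frag_panel(), tolerance_ppm = 10)
  expect_equal(nrow(asg), 1L)
  expect_identical(asg$fragment, "GlcN-MurNAcAnh")
  expect_lt(abs(asg$error_ppm), 0.5)
  expect_true(asg$best)
  expect_identical(attr(asg, "unassigned"), 2L)   # 437.30 is ~280 ppm away

  expect_error(assign_peaks(peaks, list(), 10), "empty")
  expect_error(assign_peaks(tibble::tibble(mz = -1), two_frag_panel(), 10),
               "positive")
})

test_that("vanishing tolerance keeps only exact matches", {
  exact <- mz_value(monoisotopic_mass(glycan_fragment(c("GlcN", "anhMurNAc"))))
  peaks <- tibble::tibble(mz = c(exact, exact * (1 + 2e-6)))
  asg <- assign_peaks(peaks, two_frag_panel(), tolerance_ppm = 1e-6)
  expect_identical(asg$peak, 1L)
  expect_identical(attr(asg, "unassigned"), 2L)
})

test_that("simulated peak panels are recovered through assignment", {
  panel <- default_fragment_panel(20)
  # panel masses must be pairwise distinct by a wide margin
  masses <- vapply(panel, monoisotopic_mass, numeric(1))
  expect_gt(min(diff(sort(masses))), 1)

  # no noise: every identity recovered at any positive tolerance
  sim0 <- simulate_peaks(panel, ppm_sigma = 0, seed = 5)
  asg0 <- assign_peaks(sim0$peaks, panel, tolerance_ppm = 0.01)
  best0 <- asg0[asg0$best, ]
  expect_identical(best0$fragment[order(best0$peak)],
                   sim0$truth$assignments$fragment)

  # 5 ppm Gaussian noise, 10 ppm tolerance: every best assignment correct
  sim <- simulate_peaks(panel, ppm_sigma = 5, seed = 6)
  asg <- assign_peaks(sim$peaks, panel, tolerance_ppm = 10)
  best <- asg[asg$best, ]
  truth <- sim$truth$assignments$fragment[best$peak]
  expect_identical(best$fragment, truth)
})

test_that("deacetylation pairs are detected by the 42.0106 Da shift", {
  mzs <- c(mz_value(monoisotopic_mass(glycan_fragment(c("GlcN", "anhMurNAc")))),
           mz_value(monoisotopic_mass(glycan_fragment(c("GlcNAc", "anhMurNAc")))))
  pairs <- find_deacetylation_pairs(tibble::tibble(mz = mzs), tolerance_ppm = 10)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$delta_mz, mass_constants()$acetyl_delta, tolerance = 1e-6)
  expect_equal(pairs$deacetylated_candidate, min(mzs))

  none <- find_deacetylation_pairs(tibble::tibble(mz = c(437.1766, 480.0)),
                                   tolerance_ppm = 10)
  expect_equal(nrow(none), 0L)
  expect_error(find_deacetylation_pairs(tibble::tibble(mz = 437.2)), "two peaks")
})

test_that("relative peak areas scale against the control contract", {
  ctrl <- c(p1 = 100, p2 = 250, p3 = 40)
  # identity: sample == control -> 100% everywhere
  out <- relative_peak_areas(ctrl, ctrl)
  expect_equal(out$percent, rep(100, 3))

  # half the control -> 50%
  out <- relative_peak_areas(ctrl / 2, ctrl)
  expect_equal(out$percent, rep(50, 3))

  # peak absent from the sample -> 0%
  out <- relative_peak_areas(ctrl[c("p1", "p3")], ctrl)
  expect_equal(out$percent[out$peak_id == "p2"], 0)

  # sample-only peak flagged, not scaled
  expect_warning(out <- relative_peak_areas(c(ctrl, pX = 7), ctrl),
                 "not scaled")
  expect_identical(attr(out, "unmatched_sample_peaks"), "pX")
  expect_false("pX" %in% out$peak_id)

  expect_error(relative_peak_areas(ctrl, c(p1 = 0, p2 = 1, p3 = 1)),
               "positive")
})

test_that("planted assay inhibition factors are recovered from simulated areas", {
  ctrl <- setNames(runif(6, 50, 500), paste0("pk", 1:6))

  # factor 1, no noise: exactly 100%
  sim1 <- simulate_assay(ctrl, inhibition_factor = 1, noise_cv = 0,
                         n_replicates = 1, seed = 3)
  out1 <- relative_peak_areas(
    setNames(sim1$sample$area, sim1$sample$peak_id), ctrl)
  expect_equal(out1$percent, rep(100, 6), tolerance = 1e-12)

  # planted factor 0.4 with 10% CV over 3 replicates: mean near 40%
  sim <- simulate_assay(ctrl, inhibition_factor = 0.4, noise_cv = 0.1,
                        n_replicates = 3, seed = 8)
  pct <- vapply(split(sim$sample, sim$sample$replicate), function(rep)
    mean(relative_peak_areas(setNames(rep$area, rep$peak_id), ctrl)$percent),
    numeric(1))
  expect_lt(abs(mean(pct) - 100 * sim$truth$inhibition_factor), 10)
})
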