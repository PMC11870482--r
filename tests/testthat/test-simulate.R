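test_that("genome simulation is seed-deterministic and respects forced limits", {
  p <- genome_sim_params(n_genomes = 25, seed = 123)
  a <- simulate_genomes(p)
  b <- simulate_genomes(p)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$truth$genomes, b$truth$genomes)

  rules <- builtin_rules()
  # forced limit: everything linked on the same strand
  forced <- simulate_genomes(genome_sim_params(
    n_genomes = 40, p_both = 1, p_a_only = 0, p_b_only = 0, p_linked = 1,
    p_same_strand_linked = 1, seed = 5))
  s <- linkage_survey(forced$genomes, rules$SddA, rules$EnvC)
  expect_identical(s$fraction_same_strand, 1.0)
  expect_identical(s$n_with_pair, 40L)

  none <- simulate_genomes(genome_sim_params(
    n_genomes = 30, p_both = 0, p_a_only = 0.5, p_b_only = 0.5, seed = 5))
  s0 <- linkage_survey(none$genomes, rules$SddA, rules$EnvC)
  expect_identical(s0$n_with_both, 0L)

  expect_error(genome_sim_params(p_both = 1.5), "\\[0, 1\\]")
  expect_error(genome_sim_params(p_both = 0.8, p_a_only = 0.2, p_b_only = 0.2),
               "exceed 1")
})

test_that("linked pairs sit at their planted gap and the generated tables validate", {
  sg <- simulate_genomes(genome_sim_params(n_genomes = 40, seed = 88))
  expect_silent(as_gene_table(sg$genomes))
  rules <- builtin_rules()
  pairs <- linkage_survey(sg$genomes, rules$SddA, rules$EnvC)$pairs
  tr <- sg$truth$genomes
  linked <- tr[tr$linked, ]
  got <- pairs[match(linked$genome_id, pairs$genome_id), ]
  expect_identical(got$distance_bp, linked$planted_gap_bp)
  expect_identical(got$same_strand, linked$planted_same_strand)
})

test_that("cell simulation is byte-identical under a fixed seed", {
  p <- cell_sim_params(n_cells = 6, seed = 404)
  a <- simulate_cells(p)
  b <- simulate_cells(p)
  expect_identical(a$mask, b$mask)
  expect_identical(a$gfp, b$gfp)
  expect_identical(a$membrane, b$membrane)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_cell_tiffs(a, d1); f2 <- write_cell_tiffs(b, d2)
  expect_identical(unname(tools::md5sum(f1[["gfp"]])),
                   unname(tools::md5sum(f2[["gfp"]])))
  expect_identical(unname(tools::md5sum(f1[["mask"]])),
                   unname(tools::md5sum(f2[["mask"]])))

  back <- read_cell_tiffs(d1)
  expect_identical(back$mask, a$mask)
})

test_that("no simulated cell touches the border and labels are complete", {
  sim <- simulate_cells(cell_sim_params(n_cells = 30, seed = 7))
  expect_identical(sort(unique(as.vector(sim$mask))), c(0:30))
  border <- c(sim$mask[1, ], sim$mask[nrow(sim$mask), ],
              sim$mask[, 1], sim$mask[, ncol(sim$mask)])
  expect_true(all(border == 0L))
})

test_that("a flat (enrichment 1) noiseless cell has zero midcell statistic", {
  sim <- simulate_cells(cell_sim_params(
    n_cells = 5, enrichment = 1, poisson_noise = FALSE, read_noise_sd = 0,
    background = 0, seed = 2))
  res <- analyze_cells(sim$gfp, sim$mask)
  # exact zero up to bilinear blending at the cell edge (< 2% of the level)
  expect_lt(max(abs(res$cells$value)), 0.02 * 200)
})

test_that("peak and assay simulators honour their zero-noise contracts", {
  panel <- default_fragment_panel(8)
  sim <- simulate_peaks(panel, ppm_sigma = 0, seed = 1)
  theo <- vapply(panel, function(f) mz_value(monoisotopic_mass(f)), numeric(1))
  expect_equal(sim$peaks$mz, unname(theo))

  ctrl <- c(a = 10, b = 20)
  asy <- simulate_assay(ctrl, inhibition_factor = 1, noise_cv = 0,
                        n_replicates = 2, seed = 1)
  expect_equal(asy$sample$area, rep(unname(ctrl), 2))
  expect_error(simulate_assay(c(a = -1), seed = 1), "positive")
})
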