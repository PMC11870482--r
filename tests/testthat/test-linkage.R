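make_pair_genome <- function(start_b = 501L, end_b = 900L, strand_b = "+",
                             contig_b = "c1") {
  tibble::tibble(
    genome_id = "g1",
    gene_id = c("geneA", "geneB"),
    contig_id = c("c1", contig_b),
    start = c(100L, start_b), end = c(400L, end_b),
    strand = c("+", strand_b),
    annotations = list("PFAM:PF04748", "KEGG:K22719")
  )
}

rules <- builtin_rules()

test_that("closest_pair measures strictly intervening bases", {
  cp <- closest_pair(make_pair_genome(), rules$SddA, rules$EnvC)
  expect_equal(cp$distance_bp, 100L)   # 501 - 400 - 1
  expect_true(cp$same_strand)

  # overlapping genes clamp to zero
  cp <- closest_pair(make_pair_genome(start_b = 350L, end_b = 600L),
                     rules$SddA, rules$EnvC)
  expect_equal(cp$distance_bp, 0L)

  # abutting genes too
  cp <- closest_pair(make_pair_genome(start_b = 401L), rules$SddA, rules$EnvC)
  expect_equal(cp$distance_bp, 0L)

  # opposite strand is recorded, not filtered
  cp <- closest_pair(make_pair_genome(strand_b = "-"), rules$SddA, rules$EnvC)
  expect_false(cp$same_strand)

  # different contigs -> no same-chromosome pair
  expect_null(closest_pair(make_pair_genome(contig_b = "c2"),
                           rules$SddA, rules$EnvC))

  # one family absent -> absent result
  g <- make_pair_genome()
  g$annotations[[2]] <- "PFAM:PF00001"
  expect_null(closest_pair(g, rules$SddA, rules$EnvC))
})

test_that("closest_pair breaks ties lexicographically and never self-pairs", {
  g <- tibble::tibble(
    genome_id = "g1",
    gene_id = c("a2", "a1", "b1"),
    contig_id = "c1",
    start = c(100L, 700L, 401L), end = c(300L, 900L, 600L),
    strand = "+",
    annotations = list("PFAM:PF04748", "PFAM:PF04748", "KEGG:K22719")
  )
  # both a-genes are 100 bp from b1; lexicographic tie-break picks a1
  cp <- closest_pair(g, rules$SddA, rules$EnvC)
  expect_equal(cp$gene_a_id, "a1")
  expect_equal(cp$gene_b_id, "b1")

  # a single gene matching both rules must not pair with itself
  solo <- tibble::tibble(
    genome_id = "g1", gene_id = "dual", contig_id = "c1",
    start = 1L, end = 500L, strand = "+",
    annotations = list(c("PFAM:PF04748", "KEGG:K22719")))
  expect_null(closest_pair(solo, rules$SddA, rules$EnvC))
})

test_that("closest_pair agrees with the exhaustive brute-force oracle", {
  withr::with_seed(4001, {
    n_checked <- 0L
    for (i in 1:300) {
      g <- random_oracle_genome(sprintf("g%03d", i))
      got <- closest_pair(g, rules$SddA, rules$EnvC)
      want <- brute_closest_pair(g, rules$SddA, rules$EnvC)
      if (is.null(want)) {
        expect_null(got)
      } else {
        n_checked <- n_checked + 1L
        expect_equal(got$distance_bp, want$distance_bp)
        expect_equal(got$same_strand, want$same_strand)
        expect_equal(got$gene_a_id, want$gene_a_id)
        expect_equal(got$gene_b_id, want$gene_b_id)
      }
    }
    expect_gt(n_checked, 50L)   # the comparison actually exercised pairs
  })
})

test_that("count_per_genome counts matches and reports all-zero genomes", {
  g <- tibble::tibble(
    genome_id = "g1",
    gene_id = c("x1", "x2", "x3"),
    contig_id = "c1",
    start = c(1L, 1000L, 2000L), end = c(500L, 1500L, 2500L),
    strand = "+",
    annotations = list("PFAM:PF04748", "PFAM:PF04748", "KEGG:K22719"))
  cnt <- count_per_genome(g, builtin_rules(), genome_ids = c("g1", "gEmpty"))
  expect_equal(cnt$SddA, c(2L, 0L))
  expect_equal(cnt$EnvC, c(1L, 0L))
  expect_equal(cnt$GpmM, c(0L, 0L))
  expect_error(count_per_genome(g, genome_ids = c("g1", "g1")), "duplicate")
})

test_that("per-genome counts recover the generator's planted truth exactly", {
  sg <- simulate_genomes(genome_sim_params(n_genomes = 60, seed = 202))
  cnt <- count_per_genome(sg$genomes, builtin_rules(),
                          genome_ids = sg$truth$genomes$genome_id)
  expect_identical(cnt$SddA, sg$truth$genomes$count_SddA)
  expect_identical(cnt$EnvC, sg$truth$genomes$count_EnvC)
})

test_that("linkage_survey aggregates pair observations coherently", {
  s <- linkage_survey(make_pair_genome(), rules$SddA, rules$EnvC)
  expect_equal(s$n_with_pair, 1L)
  expect_equal(s$fraction_same_strand, 1.0)
  expect_equal(s$fraction_within_threshold, 1.0)

  # family B absent everywhere: no pairs, fractions undefined
  g <- make_pair_genome()
  g$annotations[[2]] <- "PFAM:PF00001"
  s <- linkage_survey(g, rules$SddA, rules$EnvC)
  expect_equal(s$n_with_both, 0L)
  expect_true(is.na(s$fraction_same_strand))
  expect_true(is.na(s$fraction_within_threshold))

  # both families present but never on one contig
  s <- linkage_survey(make_pair_genome(contig_b = "c2"),
                      rules$SddA, rules$EnvC)
  expect_equal(s$n_with_both, 1L)
  expect_equal(s$n_with_pair, 0L)

  expect_error(linkage_survey(make_pair_genome()[0, ], rules$SddA,
                              rules$EnvC), "at least one")
})

test_that("survey counts obey their ordering invariant on simulated data", {
  sg <- simulate_genomes(genome_sim_params(n_genomes = 80, seed = 17))
  s <- linkage_survey(sg$genomes, rules$SddA, rules$EnvC,
                      genome_ids = sg$truth$genomes$genome_id)
  expect_lte(s$n_same_strand, s$n_with_pair)
  expect_lte(s$n_with_pair, s$n_with_both)
  expect_lte(s$n_with_both, min(s$n_with_a, s$n_with_b))
  expect_lte(s$n_with_a, s$n_genomes)
  expect_equal(length(s$distance_values), s$n_with_pair)
})

test_that("permuting gene order within genomes changes no survey output", {
  sg <- simulate_genomes(genome_sim_params(n_genomes = 30, seed = 55))
  s1 <- linkage_survey(sg$genomes, rules$SddA, rules$EnvC)
  shuffled <- withr::with_seed(99, sg$genomes[sample.int(nrow(sg$genomes)), ])
  s2 <- linkage_survey(shuffled, rules$SddA, rules$EnvC,
                       genome_ids = unique(sg$genomes$genome_id))
  expect_equal(s1$n_with_pair, s2$n_with_pair)
  expect_equal(s1$fraction_same_strand, s2$fraction_same_strand)
  expect_equal(sort(s1$distance_values), sort(s2$distance_values))
  expect_equal(s1$pairs[order(s1$pairs$genome_id), ],
               s2$pairs[order(s2$pairs$genome_id), ])
})
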