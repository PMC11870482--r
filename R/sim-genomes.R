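#' Parameters for the synthetic genome generator
#'
#' Defines the study conditions the genome simulator emulates: per-genome
#' gene counts, gene/intergenic length distributions, the probabilities of
#' carrying the two surveyed families, of the carried pair being an operon
#' pair (adjacent, short gap), and the strand-concordance probabilities of
#' linked and unlinked pairs.
#'
#' @param n_genomes Number of genomes (default 500).
#' @param genes_per_genome_mean,genes_per_genome_min Poisson mean and lower
#'   bound of genes per genome (defaults 40, 10).
#' @param gene_length_mean,gene_length_min Gene length distribution in bp
#'   (gamma with shape 4, defaults mean 900, min 150).
#' @param gap_mean,gap_min Background intergenic gap distribution in bp
#'   (exponential, defaults mean 150, min 1).
#' @param linked_gap_mean Mean of the short-gap distribution separating a
#'   linked (operon) pair (exponential, default 300 bp; essentially always
#'   below 2 kb).
#' @param p_both Probability a genome carries both families (default 0.8).
#' @param p_a_only,p_b_only Probabilities of carrying only family A / B
#'   (defaults 0.1 each).
#' @param p_linked Probability that a both-carrying genome has the pair as
#'   adjacent operon neighbours (default 0.8).
#' @param p_same_strand_linked,p_same_strand_unlinked Strand-concordance
#'   probabilities for linked and unlinked pairs (defaults 0.9, 0.5).
#' @param decoy_rate Fraction of background genes given decoy annotations,
#'   including the LytM-activator exclusion IDs and near-miss combinations,
#'   so the rule logic is exercised (default 0.03).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `genome_sim_params`.
#' @export
genome_sim_params <- function(n_genomes = 500L,
                              genes_per_genome_mean = 40,
                              genes_per_genome_min = 10L,
                              gene_length_mean = 900,
                              gene_length_min = 150L,
                              gap_mean = 150, gap_min = 1L,
                              linked_gap_mean = 300,
                              p_both = 0.8, p_a_only = 0.1, p_b_only = 0.1,
                              p_linked = 0.8,
                              p_same_strand_linked = 0.9,
                              p_same_strand_unlinked = 0.5,
                              decoy_rate = 0.03,
                              seed = 1L) {
  p <- as.list(environment())
  probs <- c(p$p_both, p$p_a_only, p$p_b_only, p$p_linked,
             p$p_same_strand_linked, p$p_same_strand_unlinked, p$decoy_rate)
  if (any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (p$p_both + p$p_a_only + p$p_b_only > 1)
    stop("p_both + p_a_only + p_b_only must not exceed 1")
  if (p$genes_per_genome_min < 4L)
    stop("need at least 4 genes per genome")
  structure(p, class = "genome_sim_params")
}

## Decoy annotation sets: exclusion IDs and near-miss combinations that
## must never satisfy any builtin rule.
.DECOY_SETS <- list(
  c("KEGG:K19304"), c("KEGG:K06194"), c("KEGG:K12943"),
  c("KEGG:K22719", "KEGG:K06194"),   # EnvC include + exclusion -> no match
  c("KEGG:K22719", "KEGG:K19304"),
  c("PFAM:PF01520"),                 # AmiC include without AMIN domain
  c("KEGG:K01448"),
  c("PFAM:PF11741")                  # AMIN domain without amidase
)

#' Simulate annotated genomes with planted family linkage
#'
#' Lays each genome out left-to-right on a single linear contig with drawn
#' gene lengths and intergenic gaps. With probability `p_both` a genome
#' carries one gene of family A (divergent-deacetylase annotations) and one
#' of family B (murein-hydrolase-activator annotation); a carried pair is,
#' with probability `p_linked`, placed as adjacent operon neighbours
#' separated by a short drawn gap (strand concordance
#' `p_same_strand_linked`), and otherwise at independent random loci
#' (concordance `p_same_strand_unlinked`). Background genes carry junk
#' annotations, a fraction of them decoys that include the exclusion IDs,
#' so family rules with exclusions are exercised.
#'
#' @param params A [genome_sim_params()] object.
#' @return A list with `genomes` (a gene table, see [as_gene_table()]) and
#'   `truth` (list: `params`, `seed`, and a per-genome tibble `genomes`
#'   with planted carriage, linkage, gap, strand concordance and family
#'   counts).
#' @export
simulate_genomes <- function(params = genome_sim_params()) {
  stopifnot(inherits(params, "genome_sim_params"))
  withr::with_seed(params$seed, simulate_genomes_impl(params))
}

#' @noRd
simulate_genomes_impl <- function(p) {
  n <- p$n_genomes
  gid <- sprintf("g%04d", seq_len(n))
  carriage <- runif(n)
  has_a <- carriage < p$p_both + p$p_a_only
  has_b <- carriage < p$p_both | (carriage >= p$p_both + p$p_a_only &
                                    carriage < p$p_both + p$p_a_only + p$p_b_only)
  linked <- has_a & has_b & runif(n) < p$p_linked
  linked_gap <- ifelse(linked,
                       pmax(1L, round(rexp(n, 1 / p$linked_gap_mean))), NA)
  same_strand_planted <- ifelse(
    linked, runif(n) < p$p_same_strand_linked,
    ifelse(has_a & has_b, runif(n) < p$p_same_strand_unlinked, NA))

  tables <- vector("list", n)
  for (i in seq_len(n)) {
    ng <- max(p$genes_per_genome_min, rpois(1L, p$genes_per_genome_mean))
    lens <- pmax(p$gene_length_min,
                 round(rgamma(ng, shape = 4, scale = p$gene_length_mean / 4)))
    gaps <- pmax(p$gap_min, round(rexp(ng, 1 / p$gap_mean)))
    strands <- sample(c("+", "-"), ng, replace = TRUE)
    ann <- replicate(ng, sprintf("PFAM:PF9%04d", sample.int(9999L, 1L)),
                     simplify = FALSE)
    decoy <- runif(ng) < p$decoy_rate
    ann[decoy] <- sample(.DECOY_SETS, sum(decoy), replace = TRUE)

    slot_a <- slot_b <- NA_integer_
    if (linked[i]) {
      slot_a <- sample.int(ng - 1L, 1L)
      slot_b <- slot_a + 1L
      gaps[slot_b] <- linked_gap[i]           # gap *before* gene slot_b
      strands[slot_a] <- sample(c("+", "-"), 1L)
      strands[slot_b] <- if (same_strand_planted[i]) strands[slot_a] else
        setdiff(c("+", "-"), strands[slot_a])
    } else {
      if (has_a[i]) slot_a <- sample.int(ng, 1L)
      if (has_b[i]) {
        avail <- setdiff(seq_len(ng), slot_a)
        slot_b <- avail[sample.int(length(avail), 1L)]
      }
      if (has_a[i] && has_b[i]) {
        strands[slot_a] <- sample(c("+", "-"), 1L)
        strands[slot_b] <- if (same_strand_planted[i]) strands[slot_a] else
          setdiff(c("+", "-"), strands[slot_a])
      }
    }
    if (!is.na(slot_a))
      ann[[slot_a]] <- sample(c("PFAM:PF04748", "KEGG:K09798"), 1L)
    if (!is.na(slot_b)) ann[[slot_b]] <- "KEGG:K22719"

    starts <- cumsum(gaps) + cumsum(c(0, lens[-ng])) + 1L
    ends <- starts + lens - 1L
    tables[[i]] <- tibble(
      genome_id = gid[i],
      gene_id = sprintf("%s_%03d", gid[i], seq_len(ng)),
      contig_id = "chr1",
      start = as.integer(starts), end = as.integer(ends),
      strand = strands, annotations = ann
    )
  }
  genomes <- as_gene_table(dplyr::bind_rows(tables))
  truth <- list(
    params = unclass(p), seed = p$seed,
    genomes = tibble(
      genome_id = gid, has_a = has_a, has_b = has_b, linked = linked,
      planted_gap_bp = as.integer(linked_gap),
      planted_same_strand = same_strand_planted,
      count_SddA = as.integer(has_a), count_EnvC = as.integer(has_b)
    )
  )
  list(genomes = genomes, truth = truth)
}
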