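# Independent oracles and ad-hoc fixture builders used across tests.

# Exhaustive brute-force closest-pair oracle: enumerates every ordered
# cross-family pair and keeps the minimum with explicit comparison logic,
# independent of the vectorised selection in closest_pair().
brute_closest_pair <- function(genome, rule_a, rule_b) {
  g <- as_gene_table(genome)
  ia <- which(matches_rule(g$annotations, rule_a))
  ib <- which(matches_rule(g$annotations, rule_b))
  best <- NULL
  for (i in ia) for (j in ib) {
    if (i == j) next
    if (g$contig_id[i] != g$contig_id[j]) next
    gap <- max(g$start[i], g$start[j]) - min(g$end[i], g$end[j]) - 1L
    if (gap < 0L) gap <- 0L
    cand <- list(distance_bp = gap, gene_a_id = g$gene_id[i],
                 gene_b_id = g$gene_id[j],
                 same_strand = g$strand[i] == g$strand[j])
    if (is.null(best) ||
        cand$distance_bp < best$distance_bp ||
        (cand$distance_bp == best$distance_bp &&
         (cand$gene_a_id < best$gene_a_id ||
          (cand$gene_a_id == best$gene_a_id &&
           cand$gene_b_id < best$gene_b_id))))
      best <- cand
  }
  best
}

# Random genome tables for oracle comparison: arbitrary coordinates
# (overlaps allowed), 1-2 contigs, annotations drawn from a pool that
# includes both family IDs at moderate rates.
random_oracle_genome <- function(genome_id, max_genes = 50L) {
  ng <- sample.int(max_genes, 1L)
  pool <- c("PFAM:PF04748", "KEGG:K09798", "KEGG:K22719", "KEGG:K06194",
            "PFAM:PF00001", "PFAM:PF00002", "TIGRFAM:TIGR99999")
  starts <- sample.int(50000L, ng, replace = TRUE)
  tibble::tibble(
    genome_id = genome_id,
    gene_id = sprintf("%s_%02d", genome_id, seq_len(ng)),
    contig_id = sample(c("c1", "c2"), ng, replace = TRUE),
    start = starts,
    end = starts + sample.int(3000L, ng, replace = TRUE),
    strand = sample(c("+", "-"), ng, replace = TRUE),
    annotations = replicate(ng, sample(pool, sample.int(2L, 1L)),
                            simplify = FALSE)
  )
}

# Axis-aligned capsule (spherocylinder) label mask: total length len_px,
# width wid_px, horizontal, centred in an image with margin.
capsule_mask <- function(len_px, wid_px, margin = 6L, label = 1L) {
  h <- 2L * margin + ceiling(wid_px) + 2L
  w <- 2L * margin + ceiling(len_px) + 2L
  m <- matrix(0L, h, w)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r <- wid_px / 2
  half <- max(0, (len_px - wid_px) / 2)
  for (row in seq_len(h)) for (col in seq_len(w)) {
    du <- max(abs(col - cx) - half, 0)
    if (sqrt(du^2 + (row - cy)^2) <= r) m[row, col] <- label
  }
  m
}
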