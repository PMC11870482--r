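#' Count family members per genome
#'
#' Applies each annotation rule to every gene and counts matches per genome.
#' Genomes listed in `genome_ids` but absent from the table (no annotated
#' genes) get all-zero rows.
#'
#' @param genomes A gene table ([as_gene_table()]) covering one or more
#'   genomes.
#' @param rules A named list of [family_rule()] objects (default
#'   [builtin_rules()]).
#' @param genome_ids Optional character vector fixing the set and order of
#'   genomes reported; defaults to the genomes present in the table.
#' @return A tibble with `genome_id` and one integer count column per rule.
#' @export
count_per_genome <- function(genomes, rules = builtin_rules(),
                             genome_ids = NULL) {
  g <- as_gene_table(genomes)
  if (is.null(names(rules)) || any(!nzchar(names(rules))))
    names(rules) <- vapply(rules, function(r) r$name, character(1L))
  if (anyDuplicated(names(rules)))
    stop("rule names must be unique")
  if (is.null(genome_ids)) genome_ids <- unique(g$genome_id)
  if (anyDuplicated(genome_ids)) stop("duplicate genome_id in `genome_ids`")
  out <- tibble(genome_id = as.character(genome_ids))
  gid <- factor(g$genome_id, levels = genome_ids)
  for (nm in names(rules)) {
    hit <- matches_rule(g$annotations, rules[[nm]])
    cnt <- tapply(hit, gid, sum, default = 0L)
    out[[nm]] <- as.integer(cnt[out$genome_id])
    out[[nm]][is.na(out[[nm]])] <- 0L
  }
  out
}

#' Intervening bases between two gene intervals
#'
#' Number of strictly intervening base pairs between two 1-based inclusive
#' intervals on the same contig; 0 if the intervals overlap or abut.
#' @noRd
interval_gap_bp <- function(start_a, end_a, start_b, end_b) {
  pmax(0L, pmax(start_a, start_b) - pmin(end_a, end_b) - 1L)
}

#' Closest cross-family gene pair within one genome
#'
#' Over all gene pairs (a, b) with a matching `rule_a`, b matching `rule_b`,
#' a and b distinct and on the same contig, returns the pair minimising the
#' intergenic distance, defined as the count of strictly intervening base
#' pairs (0 when the intervals overlap or abut). Contigs are treated as
#' linear; pairs spanning different contigs are never considered. Ties are
#' broken lexicographically by `(gene_a_id, gene_b_id)`, so the result is
#' deterministic and independent of gene order in the table.
#'
#' @param genome A gene table containing a single genome.
#' @param rule_a,rule_b [family_rule()] objects for the two families.
#' @return A one-row tibble with columns `genome_id`, `contig_id`,
#'   `gene_a_id`, `gene_b_id`, `distance_bp`, `same_strand`, or `NULL` when
#'   no same-contig cross-family pair exists.
#' @export
closest_pair <- function(genome, rule_a, rule_b) {
  g <- as_gene_table(genome)
  if (length(unique(g$genome_id)) > 1L)
    stop("closest_pair() expects a table for a single genome")
  ia <- which(matches_rule(g$annotations, rule_a))
  ib <- which(matches_rule(g$annotations, rule_b))
  if (!length(ia) || !length(ib)) return(NULL)
  cand <- expand.grid(a = ia, b = ib)
  keep <- cand$a != cand$b & g$contig_id[cand$a] == g$contig_id[cand$b]
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  d <- interval_gap_bp(g$start[cand$a], g$end[cand$a],
                       g$start[cand$b], g$end[cand$b])
  k <- order(d, g$gene_id[cand$a], g$gene_id[cand$b])[1L]
  a <- cand$a[k]; b <- cand$b[k]
  tibble(
    genome_id = g$genome_id[1L],
    contig_id = g$contig_id[a],
    gene_a_id = g$gene_id[a],
    gene_b_id = g$gene_id[b],
    distance_bp = as.integer(d[k]),
    same_strand = g$strand[a] == g$strand[b]
  )
}

#' Cross-genome linkage survey of two gene families
#'
#' Aggregates [closest_pair()] over every genome: how many genomes carry
#' each family, both families, a same-contig cross-family pair, and of those
#' pairs how many are strand-concordant and how many lie within
#' `threshold_bp` intervening bases (default 2 kb, the operon-scale
#' threshold). Genomes carrying both families only on different contigs
#' count in `n_with_both` but not `n_with_pair`. Fractions are relative to
#' `n_with_pair` and are `NA` when no genome has a pair.
#'
#' @inheritParams count_per_genome
#' @param rule_a,rule_b [family_rule()] objects for the two families.
#' @param threshold_bp Distance threshold in base pairs (default 2000).
#' @return An object of class `linkage_summary`: a list with counts
#'   (`n_genomes`, `n_with_a`, `n_with_b`, `n_with_both`, `n_with_pair`,
#'   `n_same_strand`), `fraction_same_strand`, `distance_values`,
#'   `fraction_within_threshold`, `threshold_bp`, and `pairs` (a tibble of
#'   per-genome [closest_pair()] observations).
#' @export
linkage_survey <- function(genomes, rule_a, rule_b, threshold_bp = 2000L,
                           genome_ids = NULL) {
  g <- as_gene_table(genomes)
  if (is.null(genome_ids)) genome_ids <- unique(g$genome_id)
  if (!length(genome_ids)) stop("linkage_survey() needs at least one genome")
  if (anyDuplicated(genome_ids)) stop("duplicate genome_id in `genome_ids`")
  per <- split(seq_len(nrow(g)), factor(g$genome_id, levels = genome_ids))
  has_a <- has_b <- logical(length(genome_ids))
  pair_rows <- vector("list", length(genome_ids))
  for (i in seq_along(genome_ids)) {
    idx <- per[[i]]
    if (!length(idx)) next
    gi <- g[idx, ]
    ma <- matches_rule(gi$annotations, rule_a)
    mb <- matches_rule(gi$annotations, rule_b)
    has_a[i] <- any(ma)
    has_b[i] <- any(mb)
    if (has_a[i] && has_b[i]) pair_rows[[i]] <- closest_pair(gi, rule_a, rule_b)
  }
  pairs <- dplyr::bind_rows(pair_rows)
  n_with_pair <- nrow(pairs)
  n_same_strand <- if (n_with_pair) sum(pairs$same_strand) else 0L
  n_within <- if (n_with_pair) sum(pairs$distance_bp <= threshold_bp) else 0L
  structure(list(
    n_genomes = length(genome_ids),
    n_with_a = sum(has_a),
    n_with_b = sum(has_b),
    n_with_both = sum(has_a & has_b),
    n_with_pair = n_with_pair,
    n_same_strand = n_same_strand,
    fraction_same_strand = if (n_with_pair) n_same_strand / n_with_pair else NA_real_,
    distance_values = if (n_with_pair) pairs$distance_bp else integer(),
    fraction_within_threshold = if (n_with_pair) n_within / n_with_pair else NA_real_,
    threshold_bp = as.integer(threshold_bp),
    rule_a = rule_a$name, rule_b = rule_b$name,
    pairs = pairs
  ), class = "linkage_summary")
}

#' @export
print.linkage_summary <- function(x, ...) {
  cat(sprintf("<linkage_summary> %s vs %s over %d genomes\n",
              x$rule_a, x$rule_b, x$n_genomes))
  cat(sprintf("  with %s: %d   with %s: %d   with both: %d   with same-contig pair: %d\n",
              x$rule_a, x$n_with_a, x$rule_b, x$n_with_b, x$n_with_both,
              x$n_with_pair))
  if (x$n_with_pair) {
    cat(sprintf("  same strand: %d (%.1f%%)   within %d bp: %.1f%%   median distance: %d bp\n",
                x$n_same_strand, 100 * x$fraction_same_strand, x$threshold_bp,
                100 * x$fraction_within_threshold,
                as.integer(median(x$distance_values))))
  } else {
    cat("  no same-contig cross-family pairs\n")
  }
  invisible(x)
}

#' Serialise a linkage summary to JSON
#'
#' @param x A `linkage_summary`.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_linkage_json <- function(x, path) {
  stopifnot(inherits(x, "linkage_summary"))
  out <- x[c("rule_a", "rule_b", "n_genomes", "n_with_a", "n_with_b",
             "n_with_both", "n_with_pair", "n_same_strand",
             "fraction_same_strand", "fraction_within_threshold",
             "threshold_bp", "distance_values")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
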