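#' Export per-genome family counts as iTOL datasets
#'
#' Writes one plain-text iTOL `DATASET_SIMPLEBAR` file per family so the
#' counts can be displayed along a phylogenetic tree whose leaf labels are
#' genome IDs. Data rows appear in the order of the counts table and only
#' for genomes present in the tree; genomes missing from the tree, and tree
#' leaves missing from the table, are returned (and raised) as warnings.
#'
#' @param counts A counts table from [count_per_genome()] (`genome_id` plus
#'   one numeric column per family).
#' @param tree A `phylo` object, a Newick string, or a path to a Newick file.
#' @param rule_names Families (column names) to export; defaults to all
#'   count columns.
#' @param dir Output directory (created if needed).
#' @param colors Optional named vector of hex colours per family.
#' @return Invisibly, a list with `files` (named vector of paths),
#'   `missing_from_tree` (genomes in the table without a leaf) and
#'   `leaves_without_counts` (tree leaves absent from the table).
#' @export
export_itol <- function(counts, tree, rule_names = NULL, dir = ".",
                        colors = NULL) {
  counts <- as_tibble(counts)
  if (!"genome_id" %in% names(counts))
    stop("`counts` must have a genome_id column")
  if (is.null(rule_names)) rule_names <- setdiff(names(counts), "genome_id")
  miss <- setdiff(rule_names, names(counts))
  if (length(miss)) stop("counts table lacks column(s): ",
                         paste(miss, collapse = ", "))
  tree <- read_tree_input(tree)
  leaves <- tree$tip.label
  missing_from_tree <- setdiff(counts$genome_id, leaves)
  leaves_without_counts <- setdiff(leaves, counts$genome_id)
  if (length(missing_from_tree))
    warning(length(missing_from_tree),
            " genome(s) in the counts table have no tree leaf: ",
            paste(head(missing_from_tree, 5L), collapse = ", "),
            if (length(missing_from_tree) > 5L) ", ..." else "")
  if (length(leaves_without_counts))
    warning(length(leaves_without_counts),
            " tree leaf/leaves have no counts row and were omitted")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  palette <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
               "#8c564b")
  files <- character(0)
  keep <- counts$genome_id %in% leaves
  for (i in seq_along(rule_names)) {
    nm <- rule_names[i]
    col <- if (!is.null(colors) && nm %in% names(colors)) colors[[nm]] else
      palette[(i - 1L) %% length(palette) + 1L]
    path <- file.path(dir, paste0("itol_", nm, ".txt"))
    lines <- c(
      "DATASET_SIMPLEBAR",
      "SEPARATOR COMMA",
      paste0("DATASET_LABEL,", nm),
      paste0("COLOR,", col),
      "DATA",
      paste(counts$genome_id[keep], counts[[nm]][keep], sep = ",")
    )
    writeLines(lines, path)
    files[nm] <- path
  }
  invisible(list(files = files, missing_from_tree = missing_from_tree,
                 leaves_without_counts = leaves_without_counts))
}

#' Read back the DATA section of an iTOL simple-bar dataset
#'
#' Parses a file written by [export_itol()] (or any iTOL
#' `DATASET_SIMPLEBAR` with comma separator) into a tibble of leaf labels
#' and values, preserving row order.
#'
#' @param path Path to an iTOL dataset file.
#' @return A tibble with columns `genome_id` and `value`.
#' @export
read_itol_dataset <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1L], "DATASET_SIMPLEBAR"))
    stop("not an iTOL DATASET_SIMPLEBAR file: ", path)
  i <- match("DATA", lines)
  if (is.na(i)) stop("no DATA section in ", path)
  rows <- lines[seq.int(i + 1L, length.out = length(lines) - i)]
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, ",", fixed = TRUE)
  tibble(genome_id = vapply(parts, `[[`, character(1L), 1L),
         value = as.numeric(vapply(parts, `[[`, character(1L), 2L)))
}

#' @noRd
read_tree_input <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  stopifnot(is.character(tree), length(tree) == 1L)
  out <- suppressWarnings(
    if (grepl("\\(", tree)) try(ape::read.tree(text = tree), silent = TRUE)
    else try(ape::read.tree(tree), silent = TRUE))
  if (inherits(out, "try-error") || is.null(out))
    stop("could not parse Newick tree input")
  out
}
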