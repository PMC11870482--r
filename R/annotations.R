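#' Validate and normalise a gene annotation table
#'
#' The package-wide container for multi-genome gene annotations is a tidy
#' table with one row per gene and columns:
#'
#' * `genome_id`, `gene_id`, `contig_id` — character;
#' * `start`, `end` — integer, 1-based inclusive (GFF3 convention);
#' * `strand` — `"+"` or `"-"`;
#' * `annotations` — list-column of character vectors of namespaced IDs
#'   (`"PFAM:..."`, `"KEGG:..."`, `"TIGRFAM:..."`), or a character column of
#'   `;`- or `,`-separated IDs which is split on normalisation.
#'
#' Invariants checked: `start >= 1`, `end >= start`, valid strand, gene IDs
#' unique within each genome, annotation IDs namespaced and non-empty.
#'
#' @param x A data frame as above.
#' @return A validated tibble with `annotations` as a list-column.
#' @export
as_gene_table <- function(x) {
  x <- as_tibble(x)
  need <- c("genome_id", "gene_id", "contig_id", "start", "end", "strand",
            "annotations")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
  x$genome_id <- as.character(x$genome_id)
  x$gene_id <- as.character(x$gene_id)
  x$contig_id <- as.character(x$contig_id)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$strand <- as.character(x$strand)
  if (!is.list(x$annotations))
    x$annotations <- strsplit(as.character(x$annotations), "[;,]\\s*")
  x$annotations <- lapply(x$annotations, function(a) {
    a <- as.character(a)
    a[nzchar(a)]
  })
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop("`start`/`end` must be integer coordinates")
  if (any(x$start < 1L)) stop("`start` must be >= 1 (1-based coordinates)")
  if (any(x$end < x$start)) stop("`end` must be >= `start`")
  if (!all(x$strand %in% c("+", "-")))
    stop("`strand` must be '+' or '-'")
  dup <- tapply(x$gene_id, x$genome_id, anyDuplicated)
  if (any(dup > 0))
    stop("duplicated gene_id within genome(s): ",
         paste(names(dup)[dup > 0], collapse = ", "))
  ids <- unlist(x$annotations, use.names = FALSE)
  if (length(ids) && !all(grepl("^[A-Za-z0-9]+:.+", ids)))
    stop("annotation IDs must be namespaced, e.g. 'PFAM:PF04748'")
  x
}

#' Read a gene annotation table from a flat TSV file
#'
#' Columns `genome_id`, `gene_id`, `contig_id`, `start`, `end`, `strand`,
#' `annotations` (IDs separated by `;` or `,`). Coordinates are 1-based
#' inclusive.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A validated gene table (see [as_gene_table()]).
#' @export
read_gene_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_gene_table(df)
}

#' Write a gene annotation table to a flat TSV file
#'
#' Inverse of [read_gene_tsv()]; the `annotations` list-column is serialised
#' as `;`-separated IDs.
#'
#' @param x A gene table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_tsv <- function(x, path) {
  x <- as_gene_table(x)
  x$annotations <- vapply(x$annotations, paste, character(1L), collapse = ";")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read one genome's annotations from GFF3
#'
#' Parses a GFF3 file (via \pkg{rtracklayer}) whose gene/CDS attributes carry
#' `pfam=`, `kegg=` and/or `tigrfam=` comma-separated lists, and returns the
#' package's flat gene table for a single genome.
#'
#' @param path Path to a GFF3 file.
#' @param genome_id Genome identifier to assign (single string).
#' @param feature_types GFF3 `type` values to keep (default `gene` and `CDS`).
#' @return A validated gene table.
#' @export
read_gene_gff3 <- function(path, genome_id, feature_types = c("gene", "CDS")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the 'rtracklayer' package")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  mc <- as.data.frame(gr)
  pick <- function(field, ns) {
    if (!field %in% names(mc)) return(rep(list(character()), nrow(mc)))
    v <- mc[[field]]
    if (!is.list(v)) v <- strsplit(ifelse(is.na(v), "", as.character(v)), ",\\s*")
    lapply(v, function(a) {
      a <- as.character(a)
      a <- a[nzchar(a)]
      if (length(a)) paste0(ns, ":", sub(paste0("^", ns, ":"), "", a)) else character()
    })
  }
  ann <- Map(c, pick("pfam", "PFAM"), pick("kegg", "KEGG"), pick("tigrfam", "TIGRFAM"))
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    paste0(genome_id, "_g", seq_len(nrow(mc)))
  as_gene_table(tibble(
    genome_id = genome_id,
    gene_id = ids,
    contig_id = as.character(mc$seqnames),
    start = mc$start,
    end = mc$end,
    strand = as.character(mc$strand),
    annotations = ann
  ))
}
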