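#' Define a gene-family annotation rule
#'
#' A family rule classifies genes into a family from their functional
#' annotations alone (no sequence comparison). A gene matches when it carries
#' at least one ID from `include_any`, carries every ID in `require_all`, and
#' carries no ID from `exclude_any`. Annotation IDs are namespaced strings
#' such as `"PFAM:PF04748"`, `"KEGG:K22719"` or `"TIGRFAM:TIGR01307"`.
#'
#' @param name Family name (single string).
#' @param include_any Character vector of IDs, at least one of which must be
#'   present. Must be non-empty.
#' @param require_all Character vector of IDs that must all be present
#'   (default none).
#' @param exclude_any Character vector of IDs, none of which may be present
#'   (default none).
#' @return An object of class `family_rule`.
#' @seealso [builtin_rules()], [matches_rule()]
#' @examples
#' envc <- family_rule("EnvC", include_any = "KEGG:K22719",
#'                     exclude_any = c("KEGG:K19304", "KEGG:K06194", "KEGG:K12943"))
#' matches_rule("KEGG:K22719", envc)
#' matches_rule(c("KEGG:K22719", "KEGG:K06194"), envc)
#' @export
family_rule <- function(name, include_any, require_all = character(),
                        exclude_any = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  include_any <- unique(as.character(include_any))
  require_all <- unique(as.character(require_all))
  exclude_any <- unique(as.character(exclude_any))
  if (length(include_any) == 0L)
    stop("`include_any` must contain at least one annotation ID")
  ids <- c(include_any, require_all, exclude_any)
  if (any(is.na(ids)) || any(!nzchar(ids)))
    stop("annotation IDs must be non-empty strings")
  if (!all(grepl("^[A-Za-z0-9]+:.+", ids)))
    stop("annotation IDs must be namespaced, e.g. 'PFAM:PF04748' or 'KEGG:K22719'")
  if (length(intersect(include_any, require_all)) ||
      length(intersect(include_any, exclude_any)) ||
      length(intersect(require_all, exclude_any)))
    stop("`include_any`, `require_all` and `exclude_any` must be pairwise disjoint")
  structure(list(name = name, include_any = include_any,
                 require_all = require_all, exclude_any = exclude_any),
            class = "family_rule")
}

#' @export
print.family_rule <- function(x, ...) {
  cat("<family_rule> ", x$name, "\n", sep = "")
  cat("  include any of: ", paste(x$include_any, collapse = ", "), "\n", sep = "")
  if (length(x$require_all))
    cat("  require all of: ", paste(x$require_all, collapse = ", "), "\n", sep = "")
  if (length(x$exclude_any))
    cat("  exclude any of: ", paste(x$exclude_any, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Test gene annotations against a family rule
#'
#' Pure predicate deciding family membership. Matching requires a non-empty
#' intersection with `include_any`, containment of `require_all`, and an
#' empty intersection with `exclude_any`. For rules with no exclusions the
#' predicate is monotone: adding annotations can never turn a match into a
#' non-match.
#'
#' @param annotations A character vector of namespaced annotation IDs for one
#'   gene, or a list of such vectors (one element per gene).
#' @param rule A [family_rule()].
#' @return Logical vector, one element per gene.
#' @export
matches_rule <- function(annotations, rule) {
  stopifnot(inherits(rule, "family_rule"))
  if (!is.list(annotations)) annotations <- list(annotations)
  vapply(annotations, function(a) {
    a <- as.character(a)
    any(a %in% rule$include_any) &&
      all(rule$require_all %in% a) &&
      !any(a %in% rule$exclude_any)
  }, logical(1L))
}

#' Built-in family rules for the envC-sddA operon survey
#'
#' The four annotation-defined families used to survey the genetic linkage
#' of the septal deacetylase gene to the amidase-activator gene across
#' bacterial genomes:
#'
#' * `SddA`: divergent polysaccharide deacetylase, `PFAM:PF04748` or
#'   `KEGG:K09798` (YibQ-like).
#' * `EnvC`: murein hydrolase activator `KEGG:K22719`, excluding genes also
#'   annotated with the KEGG numbers of the other LytM-domain activators
#'   (`KEGG:K19304` MepM, `KEGG:K06194` NlpD, `KEGG:K12943` YgeR).
#' * `GpmM`: cofactor-independent phosphoglycerate mutase,
#'   `TIGRFAM:TIGR01307` (third gene of the operon).
#' * `AmiC`: N-acetylmuramoyl-L-alanine amidase, `KEGG:K01448` or
#'   `PFAM:PF01520`, additionally requiring the AMIN targeting domain
#'   `PFAM:PF11741`.
#'
#' @return Named list of [family_rule()] objects.
#' @export
builtin_rules <- function() {
  list(
    SddA = family_rule("SddA", include_any = c("PFAM:PF04748", "KEGG:K09798")),
    EnvC = family_rule("EnvC", include_any = "KEGG:K22719",
                       exclude_any = c("KEGG:K19304", "KEGG:K06194", "KEGG:K12943")),
    GpmM = family_rule("GpmM", include_any = "TIGRFAM:TIGR01307"),
    AmiC = family_rule("AmiC", include_any = c("KEGG:K01448", "PFAM:PF01520"),
                       require_all = "PFAM:PF11741")
  )
}
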