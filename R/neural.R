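# Neural-related gene classification: substring matching of GO term names
# against a fixed pattern vocabulary.  Matching is case-insensitive and
# deliberately plain-substring (no word boundaries), so "neuro" matches
# "neurotransmitter"; the known side effect that "dendritic cell" (immune)
# matches "dendritic" is accepted and documented.

#' Default neural pattern vocabulary
#'
#' The 13 substrings used to flag GO term names as neural-related.
#' @return Character vector of 13 patterns.
#' @export
neural_patterns <- function() {
  c("neuro", "neuron", "neuronal", "neural", "nervous", "axon",
    "dendritic", "synaptic", "synapse", "learning", "memory", "brain",
    "hippocampus")
}

#' Identify neural-related GO terms
#'
#' A term is flagged iff its lower-cased name contains at least one
#' lower-cased pattern as a plain substring.
#'
#' @param go A [go_annotation()].
#' @param patterns Non-empty character vector; default [neural_patterns()].
#' @return Character vector of flagged `term_id`s (unique, sorted).
#' @export
neural_terms <- function(go, patterns = neural_patterns()) {
  stopifnot(inherits(go, "go_annotation"), length(patterns) > 0)
  terms <- unique(go[, c("term_id", "term_name")])
  nm <- tolower(terms$term_name)
  hit <- rep(FALSE, nrow(terms))
  for (p in tolower(patterns)) hit <- hit | grepl(p, nm, fixed = TRUE)
  sort(unique(terms$term_id[hit]))
}

#' Flag neural-related genes
#'
#' A gene is neural-related iff it is annotated to at least one flagged
#' term.  Genes with no GO records are unflagged.  Witnesses record, for
#' each flagged gene, the term(s) and pattern(s) that triggered the flag.
#'
#' @param go A [go_annotation()].
#' @param patterns Pattern vocabulary passed to [neural_terms()].
#' @param universe Optional character vector of gene ids to report flags
#'   for (genes absent from `go` are reported unflagged); default: all
#'   genes in `go`.
#' @return Object of class `neural_flags`: list with `flags` (named
#'   logical), `witnesses` (`data.frame` gene_id/term_id/pattern) and
#'   `patterns`.
#' @export
flag_genes <- function(go, patterns = neural_patterns(), universe = NULL) {
  stopifnot(inherits(go, "go_annotation"))
  terms <- unique(go[, c("term_id", "term_name")])
  nm <- tolower(terms$term_name)
  wit <- do.call(rbind, lapply(tolower(patterns), function(p) {
    hit <- grepl(p, nm, fixed = TRUE)
    if (!any(hit)) return(NULL)
    data.frame(term_id = terms$term_id[hit], pattern = p,
               stringsAsFactors = FALSE)
  }))
  flagged_terms <- unique(wit$term_id)
  rec <- go[go$term_id %in% flagged_terms, c("gene_id", "term_id")]
  witnesses <- if (is.null(wit) || nrow(rec) == 0L) {
    data.frame(gene_id = character(), term_id = character(),
               pattern = character(), stringsAsFactors = FALSE)
  } else {
    merge(rec, wit, by = "term_id")[, c("gene_id", "term_id", "pattern")]
  }
  witnesses <- witnesses[order(witnesses$gene_id, witnesses$term_id,
                               witnesses$pattern), , drop = FALSE]
  rownames(witnesses) <- NULL
  if (is.null(universe)) universe <- sort(unique(go$gene_id))
  flags <- setNames(universe %in% witnesses$gene_id, universe)
  structure(list(flags = flags, witnesses = witnesses,
                 patterns = patterns),
            class = "neural_flags")
}

#' Genes flagged as neural-related
#' @param flags A `neural_flags` object.
#' @return Character vector of flagged gene ids.
#' @export
neural_gene_ids <- function(flags) {
  stopifnot(inherits(flags, "neural_flags"))
  names(flags$flags)[flags$flags]
}

#' Fraction of a gene universe flagged as neural-related
#'
#' The array-background rate: `|flagged genes in universe| / |universe|`.
#'
#' @param flags A `neural_flags` object.
#' @param universe Non-empty character vector of gene ids.
#' @return Fraction in \[0,1\].
#' @export
background_fraction <- function(flags, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  mean(universe %in% neural_gene_ids(flags))
}

#' @export
print.neural_flags <- function(x, ...) {
  cat(sprintf("neural_flags: %d of %d genes flagged (%d patterns)\n",
              sum(x$flags), length(x$flags), length(x$patterns)))
  invisible(x)
}
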