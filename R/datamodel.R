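# Domain containers.  Lightweight S3: each constructor validates and tags a
# plain list / data.frame, mirroring how limma's EList-style objects work.

#' Declared vocabulary of probe-to-gene region labels
#'
#' Region labels follow Illumina 450k manifest conventions.  Promoter probes
#' are those labelled `TSS200`, `TSS1500` or `1stExon` for a gene.
#' @return Character vector of admissible region labels.
#' @export
probe_regions <- function() {
  c("TSS200", "TSS1500", "1stExon", "5'UTR", "Body", "3'UTR", "ExonBnd")
}

#' Promoter region labels used for gene aggregation
#' @return Character vector, subset of [probe_regions()].
#' @export
promoter_regions <- function() c("TSS200", "TSS1500", "1stExon")

sample_groups <- function() c("normal", "tumor", "premalignant")

#' Construct a methylation dataset
#'
#' Bundles a beta-value matrix (probes x samples, fractions in \[0,1\]) with
#' its sample sheet.  Column order of `beta` is aligned to the sheet.
#'
#' @param beta Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).  Values in \[0,1\] or `NA`.
#' @param samples `data.frame` with columns `sample_id`, `group` (one of
#'   `normal`, `tumor`, `premalignant`) and optionally `cancer_type`,
#'   `purity` (fraction in \[0,1\] or `NA`), `age`, `sex`.
#' @return Object of class `methylation_dataset` with elements `beta`,
#'   `samples`.
#' @export
methylation_dataset <- function(beta, samples) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("'beta' must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("'beta' must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(beta)))
    stop("duplicated probe ids in beta matrix")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ex <- bad[1L, , drop = TRUE]
    stop(sprintf(
      "beta values outside [0,1]: %d cell(s), first at probe '%s', sample '%s' (value %g)",
      nrow(bad), rownames(beta)[ex[1L]], colnames(beta)[ex[2L]],
      beta[ex[1L], ex[2L]]))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "group")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0)
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample sheet: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  only_beta <- setdiff(colnames(beta), samples$sample_id)
  if (length(only_beta) > 0)
    stop("beta columns without a sample-sheet row: ",
         paste(only_beta, collapse = ", "))
  only_sheet <- setdiff(samples$sample_id, colnames(beta))
  if (length(only_sheet) > 0)
    stop("sample-sheet rows without a beta column: ",
         paste(only_sheet, collapse = ", "))
  badg <- setdiff(unique(samples$group), sample_groups())
  if (length(badg) > 0)
    stop("unknown group label(s): ", paste(badg, collapse = ", "),
         " (expected ", paste(sample_groups(), collapse = "/"), ")")
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!"purity" %in% names(samples)) samples$purity <- NA_real_
  pp <- samples$purity
  if (any(!is.na(pp) & (pp < 0 | pp > 1)))
    stop("purity values outside [0,1]")
  structure(list(beta = beta, samples = samples),
            class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("methylation_dataset: %d probes x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  print(table(x$samples$group))
  invisible(x)
}

#' Construct a probe annotation
#'
#' Probe-to-gene mapping with per-(probe, gene) region labels and a
#' per-probe CpG-island flag.  Genomic coordinates are deliberately not
#' modelled: gene assignment comes solely from this table.
#'
#' @param probes `data.frame` with columns `probe_id` (unique), `island`
#'   (logical).
#' @param map `data.frame` with columns `probe_id`, `gene_id`, `region`
#'   (one row per probe-gene-region assignment; a probe may map to 0..n
#'   genes).
#' @return Object of class `probe_annotation`.
#' @export
probe_annotation <- function(probes, map) {
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "island") %in% names(probes)))
    stop("'probes' needs columns probe_id, island")
  if (!all(c("probe_id", "gene_id", "region") %in% names(map)))
    stop("'map' needs columns probe_id, gene_id, region")
  if (anyDuplicated(probes$probe_id))
    stop("duplicated probe ids in annotation")
  if (!is.logical(probes$island)) stop("'island' must be logical")
  orphan <- setdiff(map$probe_id, probes$probe_id)
  if (length(orphan) > 0)
    stop("map rows for unknown probes: ",
         paste(head(orphan, 5), collapse = ", "))
  badr <- setdiff(unique(map$region), probe_regions())
  if (length(badr) > 0)
    stop("region label(s) outside declared vocabulary: ",
         paste(badr, collapse = ", "))
  rownames(probes) <- NULL
  rownames(map) <- NULL
  structure(list(probes = probes, map = map), class = "probe_annotation")
}

#' @export
print.probe_annotation <- function(x, ...) {
  cat(sprintf("probe_annotation: %d probes, %d probe-gene assignments, %d genes\n",
              nrow(x$probes), nrow(x$map), length(unique(x$map$gene_id))))
  invisible(x)
}

#' Construct a GO annotation table
#'
#' @param records `data.frame` with columns `gene_id`, `term_id`,
#'   `term_name` (non-empty), `namespace` (`BP`, `CC` or `MF`).
#'   `(gene_id, term_id)` pairs must be unique.
#' @return Object of class `go_annotation` (a validated `data.frame`).
#' @export
go_annotation <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  req <- c("gene_id", "term_id", "term_name", "namespace")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0)
    stop("GO annotation missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(records$term_name) | !nzchar(records$term_name)))
    stop("empty term_name in GO annotation")
  badns <- setdiff(unique(records$namespace), c("BP", "CC", "MF"))
  if (length(badns) > 0)
    stop("unknown GO namespace: ", paste(badns, collapse = ", "))
  key <- paste(records$gene_id, records$term_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (gene_id, term_id) pair(s) in GO annotation")
  rownames(records) <- NULL
  class(records) <- c("go_annotation", "data.frame")
  records
}

#' Construct a named gene-set collection
#'
#' @param sets Named list of character vectors (set name -> gene ids).
#'   Names must be unique and every set non-empty.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list")
  if (anyDuplicated(names(sets)))
    stop("duplicated gene-set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  empty <- names(sets)[vapply(sets, length, 1L) == 0L]
  if (length(empty) > 0)
    stop("empty gene set(s): ", paste(empty, collapse = ", "))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(sets, class = "gene_set_collection")
}

#' Construct an expression dataset
#'
#' @param log_expr Numeric matrix of log2-scale expression, genes in rows
#'   (unique rownames), samples in columns.
#' @param samples `data.frame` with columns `sample_id`, `condition`
#'   (at least 2 levels) and optionally `age`, `sex`.
#' @param is_counts Logical; `TRUE` when values are log-scaled counts whose
#'   mean-variance trend should be absorbed by precision weights.
#' @return Object of class `expression_dataset`.
#' @export
expression_dataset <- function(log_expr, samples, is_counts = FALSE) {
  if (!is.matrix(log_expr) || !is.numeric(log_expr))
    stop("'log_expr' must be a numeric matrix")
  if (is.null(rownames(log_expr)) || anyDuplicated(rownames(log_expr)))
    stop("'log_expr' needs unique gene rownames")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(samples)))
    stop("sample table needs columns sample_id, condition")
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample_id")
  if (!setequal(colnames(log_expr), samples$sample_id))
    stop("expression columns and sample table disagree")
  if (length(unique(samples$condition)) < 2L)
    stop("'condition' needs at least 2 levels")
  samples <- samples[match(colnames(log_expr), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  structure(list(log_expr = log_expr, samples = samples,
                 is_counts = isTRUE(is_counts)),
            class = "expression_dataset")
}

#' Construct a gene call set
#'
#' The unit of all enrichment tests: hyper- and hypomethylated gene sets
#' plus the tested background (genes with at least one tested promoter
#' probe).  A gene with both hyper- and hypomethylated promoter probes is a
#' member of both sets.
#'
#' @param hyper,hypo,tested Character vectors of gene ids;
#'   `hyper` and `hypo` must be subsets of `tested`.
#' @return Object of class `gene_call_set`.
#' @export
gene_call_set <- function(hyper, hypo, tested) {
  hyper <- unique(as.character(hyper))
  hypo <- unique(as.character(hypo))
  tested <- unique(as.character(tested))
  out <- setdiff(c(hyper, hypo), tested)
  if (length(out) > 0)
    stop("called genes outside the tested background: ",
         paste(head(out, 5), collapse = ", "))
  structure(list(hyper = hyper, hypo = hypo, tested = tested),
            class = "gene_call_set")
}

#' @export
print.gene_call_set <- function(x, ...) {
  cat(sprintf("gene_call_set: %d hyper, %d hypo, %d tested (background)\n",
              length(x$hyper), length(x$hypo), length(x$tested)))
  invisible(x)
}
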