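# Readers/writers for the tabular interchange formats: TSV matrices and
# sheets, semicolon-list probe annotation, GMT gene sets.  All outputs are
# TSV with a header and deterministic row order so reruns are byte-stable.

#' Read a methylation dataset from TSV files
#'
#' @param beta_path TSV with probe ids in the first column and one column
#'   per sample; values are beta fractions in \[0,1\] (missing allowed).
#' @param samplesheet_path TSV sample sheet with columns `sample_id`,
#'   `group`, and optionally `cancer_type`, `purity`, `age`, `sex`.
#' @return A [methylation_dataset()].
#' @export
read_methylation <- function(beta_path, samplesheet_path) {
  tab <- read.delim(beta_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("beta table needs a probe-id column plus samples")
  beta <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(beta) <- "double"
  rownames(beta) <- as.character(tab[[1L]])
  sheet <- read.delim(samplesheet_path, check.names = FALSE,
                      stringsAsFactors = FALSE)
  methylation_dataset(beta, sheet)
}

#' Read a probe annotation table
#'
#' Expects columns `probe_id`, `gene_ids` (semicolon-joined), `region_labels`
#' (semicolon-joined, aligned with `gene_ids`) and `island_flag` (0/1 or
#' TRUE/FALSE).  A probe with an empty `gene_ids` field is retained but maps
#' to no gene.
#'
#' @param path TSV file.
#' @return A [probe_annotation()].
#' @export
read_probe_annotation <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  req <- c("probe_id", "gene_ids", "region_labels", "island_flag")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("probe annotation missing column(s): ", paste(miss, collapse = ", "))
  genes <- strsplit(tab$gene_ids, ";", fixed = TRUE)
  labels <- strsplit(tab$region_labels, ";", fixed = TRUE)
  ng <- lengths(genes)
  nl <- lengths(labels)
  bad <- which(ng != nl)
  if (length(bad) > 0)
    stop(sprintf(
      "gene_ids/region_labels length mismatch for probe(s): %s",
      paste(tab$probe_id[head(bad, 5)], collapse = ", ")))
  island <- tab$island_flag %in% c("1", "TRUE", "True", "true")
  bad_flag <- !(tab$island_flag %in%
                  c("0", "1", "TRUE", "FALSE", "True", "False",
                    "true", "false"))
  if (any(bad_flag))
    stop("unparseable island_flag for probe(s): ",
         paste(tab$probe_id[head(which(bad_flag), 5)], collapse = ", "))
  map <- data.frame(
    probe_id = rep(tab$probe_id, ng),
    gene_id = unlist(genes, use.names = FALSE),
    region = unlist(labels, use.names = FALSE),
    stringsAsFactors = FALSE)
  probe_annotation(
    probes = data.frame(probe_id = tab$probe_id, island = island,
                        stringsAsFactors = FALSE),
    map = map)
}

#' Read a GO annotation table
#'
#' @param path TSV with columns `gene_id`, `term_id`, `term_name`,
#'   `namespace`.
#' @return A [go_annotation()].
#' @export
read_go_annotation <- function(path) {
  go_annotation(read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character"))
}

#' Read gene sets from a GMT file
#'
#' GMT lines are `name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate set names and empty sets are rejected.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short))
    stop("GMT line(s) with no members (need name, description, members): line ",
         paste(head(which(short), 5), collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  sets <- lapply(fields, function(f) f[-c(1L, 2L)])
  names(sets) <- nm
  gene_set_collection(sets)
}

#' Write a gene-set collection to a GMT file
#' @param sets A [gene_set_collection()].
#' @param path Output file.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression dataset from TSV files
#' @param expr_path TSV with gene ids in the first column, one column per
#'   sample, log2-scale values.
#' @param samplesheet_path TSV with columns `sample_id`, `condition` and
#'   optionally `age`, `sex`.
#' @param is_counts Whether values are log-scaled counts (see
#'   [expression_dataset()]).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(expr_path, samplesheet_path, is_counts = FALSE) {
  tab <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(tab[[1L]])
  sheet <- read.delim(samplesheet_path, check.names = FALSE,
                      stringsAsFactors = FALSE)
  expression_dataset(mat, sheet, is_counts = is_counts)
}

#' Write a result table as TSV with deterministic row order
#'
#' Rows are sorted by `sort_by` (first column by default) so identical
#' inputs always produce byte-identical files.  Numeric columns keep full
#' double precision (15 significant digits).
#'
#' @param x `data.frame`.
#' @param path Output file.
#' @param sort_by Column name(s) to sort rows by; `NULL` keeps input order.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path, sort_by = names(x)[1L]) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.null(sort_by)) {
    miss <- setdiff(sort_by, names(x))
    if (length(miss) > 0)
      stop("sort_by column(s) not in table: ", paste(miss, collapse = ", "))
    x <- x[do.call(order, x[sort_by]), , drop = FALSE]
  }
  num <- vapply(x, is.numeric, TRUE)
  for (j in which(num)) {
    x[[j]] <- vapply(x[[j]], function(v) {
      if (is.na(v)) "NA" else format(v, digits = 15, scientific = NA,
                                     trim = TRUE)
    }, "")
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read back a TSV written by [write_table_tsv()]
#' @param path TSV file.
#' @return `data.frame`.
#' @export
read_table_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write run metadata (parameters, seed, versions) as JSON
#'
#' Captures the audit trail for a run: every threshold, the exact pattern
#' list, the seed and the RNG algorithm.  No timestamps, so reruns are
#' byte-identical.
#'
#' @param path Output JSON file.
#' @param params Named list of parameters to record.
#' @param seed Integer seed used for the run (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, params = list(), seed = NULL) {
  meta <- list(
    package = "neuromethyl",
    version = as.character(packageVersion("neuromethyl")),
    rng = list(kind = "Mersenne-Twister", normal_kind = "Inversion"),
    seed = seed,
    params = params)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
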