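# End-to-end orchestration: simulate -> diffmeth -> annotate -> enrich ->
# confound -> diffexpr -> overlap, with a consolidated report directory.
# All randomness flows from one seed; reruns with the same config are
# byte-identical.

pipeline_stages <- function() {
  c("diffmeth", "annotate", "enrich", "confound", "diffexpr", "overlap")
}

#' Build a validated pipeline run configuration
#'
#' @param out_dir Output directory for the run.
#' @param seed Integer master seed (all stage seeds derive from it).
#' @param n_genes Universe size; default 2000.
#' @param probes_per_gene Promoter probes per gene; default 2.
#' @param neural_fraction Planted neural gene fraction; default 0.186.
#' @param bivalent_fraction Planted bivalent fraction; default 0.15.
#' @param cancers List of per-cancer simulation settings, each a list with
#'   `name`, `n_hyper`, `n_hypo`, `neural_enrichment` (or NULL),
#'   `n_normal`, `n_tumor`, `purity_model` (or NULL).
#' @param alpha,lfc,dbeta Probe-call thresholds; defaults 0.05, 1, 0.1.
#' @param patterns Neural pattern list; default [neural_patterns()].
#' @param promoter_labels Promoter region labels.
#' @param island_only Restrict gene aggregation to CpG-island probes.
#' @param stages Enabled stages, subset of
#'   `diffmeth, annotate, enrich, confound, diffexpr, overlap`.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, n_genes = 2000,
                       probes_per_gene = 2, neural_fraction = 0.186,
                       bivalent_fraction = 0.15,
                       cancers = list(
                         list(name = "SIM-A", n_hyper = 260, n_hypo = 150,
                              neural_enrichment = 0.385, n_normal = 15,
                              n_tumor = 15,
                              purity_model = c(0.2, 0.9)),
                         list(name = "SIM-B", n_hyper = 200, n_hypo = 120,
                              neural_enrichment = 0.30, n_normal = 15,
                              n_tumor = 15, purity_model = NULL)),
                       alpha = 0.05, lfc = 1, dbeta = 0.1,
                       patterns = neural_patterns(),
                       promoter_labels = promoter_regions(),
                       island_only = FALSE,
                       stages = pipeline_stages()) {
  if (alpha <= 0 || lfc <= 0 || dbeta <= 0)
    stop("thresholds must be positive")
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad) > 0)
    stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_genes = n_genes, probes_per_gene = probes_per_gene,
                 neural_fraction = neural_fraction,
                 bivalent_fraction = bivalent_fraction, cancers = cancers,
                 alpha = alpha, lfc = lfc, dbeta = dbeta,
                 patterns = patterns, promoter_labels = promoter_labels,
                 island_only = island_only, stages = stages),
            class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Simulates a gene universe and per-"cancer-type" methylation datasets,
#' runs every enabled stage, and writes per-stage TSVs, a Table-1-style
#' enrichment summary, truth-vs-estimate recovery metrics, a run-metadata
#' JSON and a MANIFEST into `config$out_dir`.  Deterministic given the
#' seed.  On a stage error, partial outputs are kept and the MANIFEST
#' names the failing stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(x, name, sort_by = names(x)[1L]) {
    write_table_tsv(x, file.path(out_dir, name), sort_by = sort_by)
    written <<- c(written, name)
  }
  res <- list()
  stage <- "simulate"
  on_fail <- function(e) {
    writeLines(c("status\tINCOMPLETE",
                 paste0("failed_stage\t", stage),
                 paste0("error\t", conditionMessage(e)),
                 paste0("file\t", sort(written))),
               file.path(out_dir, "MANIFEST"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    uni <- generate_universe(
      n_genes = config$n_genes, probes_per_gene = config$probes_per_gene,
      neural_fraction = config$neural_fraction,
      bivalent_fraction = config$bivalent_fraction, seed = config$seed)
    res$universe <- uni
    truth_all <- list(universe = uni$truth)

    sims <- list()
    for (i in seq_along(config$cancers)) {
      cc <- config$cancers[[i]]
      sims[[cc$name]] <- generate_methylation(
        uni$annotation, neural_genes = uni$truth$neural_genes,
        n_hyper = cc$n_hyper, n_hypo = cc$n_hypo,
        neural_enrichment = cc$neural_enrichment,
        n_normal = cc$n_normal, n_tumor = cc$n_tumor,
        purity_model = cc$purity_model, cancer_type = cc$name,
        seed = config$seed + 100L + i)
      truth_all[[cc$name]] <- sims[[cc$name]]$truth[
        c("hyper_genes", "hypo_genes", "neural_enrichment", "seed")]
    }
    res$sims <- sims

    flags <- NULL
    if ("annotate" %in% config$stages) {
      stage <- "annotate"
      flags <- flag_genes(uni$go, patterns = config$patterns,
                          universe = uni$truth$genes)
      emit(data.frame(gene_id = names(flags$flags),
                      neural = unname(flags$flags)), "neural_flags.tsv")
      emit(flags$witnesses, "neural_witnesses.tsv")
      res$flags <- flags
    }

    calls <- list(); dms <- list()
    if ("diffmeth" %in% config$stages) {
      stage <- "diffmeth"
      for (nm in names(sims)) {
        dm <- diff_methylation(sims[[nm]]$dataset,
                               alpha = config$alpha, lfc = config$lfc,
                               dbeta = config$dbeta)
        dms[[nm]] <- dm
        calls[[nm]] <- aggregate_genes(
          dm, uni$annotation, promoter_labels = config$promoter_labels,
          island_only = config$island_only)
        emit(as.data.frame(dm), paste0("probes_", nm, ".tsv"))
        gc_df <- data.frame(
          gene_id = calls[[nm]]$tested,
          hyper = calls[[nm]]$tested %in% calls[[nm]]$hyper,
          hypo = calls[[nm]]$tested %in% calls[[nm]]$hypo)
        emit(gc_df, paste0("genes_", nm, ".tsv"))
      }
      res$diffmeth <- dms
      res$calls <- calls
    }

    if ("enrich" %in% config$stages) {
      stage <- "enrich"
      if (is.null(flags) || length(calls) == 0L)
        stop("enrich requires the annotate and diffmeth stages")
      rows <- do.call(rbind, unlist(lapply(names(calls), function(nm) {
        lapply(c("hyper", "hypo"), function(dir)
          neural_enrichment_test(calls[[nm]], flags, direction = dir,
                                 cancer_type = nm))
      }), recursive = FALSE))
      rows <- fdr_across_cancers(rows)
      emit(rows, "enrichment.tsv", sort_by = c("direction", "cancer_type"))
      res$enrichment <- rows
    }

    if ("confound" %in% config$stages) {
      stage <- "confound"
      if (is.null(flags) || length(calls) == 0L)
        stop("confound requires the annotate and diffmeth stages")
      nm <- NULL
      for (cn in names(sims))
        if (any(!is.na(sims[[cn]]$truth$purity))) { nm <- cn; break }
      if (!is.null(nm)) {
        pr <- purity_regression(sims[[nm]]$dataset, calls[[nm]], flags,
                                uni$annotation)
        emit(pr, "purity_regression.tsv")
        res$purity <- pr
      }
      nm1 <- names(calls)[1L]
      bc <- bivalency_crosstab(calls[[nm1]], flags,
                               uni$sets$bivalent)
      bc_df <- do.call(rbind, lapply(names(bc), function(s) {
        data.frame(stratum = s,
                   a = bc[[s]]$table[1, 1], b = bc[[s]]$table[1, 2],
                   c = bc[[s]]$table[2, 1], d = bc[[s]]$table[2, 2],
                   chi2 = bc[[s]]$chi2, p = bc[[s]]$p, or = bc[[s]]$or,
                   stringsAsFactors = FALSE)
      }))
      emit(bc_df, "bivalency.tsv")
      res$bivalency <- bc
      hm <- hallmark_enrichment(
        calls[[nm1]], flags,
        gene_set_collection(unclass(uni$sets)[cancer_hallmark_names()]))
      emit(hm, "hallmarks.tsv")
      res$hallmarks <- hm
      md <- methylation_degree_compare(sims[[nm1]]$dataset, calls[[nm1]],
                                       flags, uni$annotation)
      emit(md$summary, "methylation_degree.tsv")
      res$degree <- md
    }

    diff_assoc <- NULL
    if ("diffexpr" %in% config$stages) {
      stage <- "diffexpr"
      genes <- uni$truth$genes
      neural <- uni$truth$neural_genes
      n_da <- max(20L, round(config$n_genes * 0.05))
      set_generator_seed(config$seed + 200L)
      planted_da <- c(sample(neural, round(n_da * 0.4)),
                      sample(setdiff(genes, neural),
                             n_da - round(n_da * 0.4)))
      ex <- generate_expression(
        genes, diff_assoc = planted_da, n_per_condition = 10, shift = 2,
        age_effect_genes = sample(setdiff(genes, planted_da), 50),
        sex_effect_genes = sample(setdiff(genes, planted_da), 50),
        seed = config$seed + 201L)
      de <- de_expression(ex$dataset)
      diff_assoc <- classify_differentiation(de)
      emit(as.data.frame(de), "de_differentiation.tsv")
      truth_all$expression <- ex$truth
      res$de <- de
      res$diff_assoc <- diff_assoc
    }

    if ("overlap" %in% config$stages) {
      stage <- "overlap"
      if (is.null(diff_assoc) || length(calls) == 0L || is.null(flags))
        stop("overlap requires the diffmeth, annotate and diffexpr stages")
      nm1 <- names(calls)[1L]
      # cancer expression contrast: a planted subset of hyper genes is
      # downregulated in tumors
      set_generator_seed(config$seed + 300L)
      dr_planted <- sample(calls[[nm1]]$hyper,
                           round(length(calls[[nm1]]$hyper) * 0.4))
      exc <- generate_expression(
        uni$truth$genes, diff_assoc = dr_planted, shift = -2,
        age_confounded = FALSE, conditions = c("normal", "tumor"),
        seed = config$seed + 301L)
      de_cancer <- de_expression(exc$dataset,
                                 contrast = c("tumor", "normal"))
      ov <- overlap_stats(calls[[nm1]], diff_assoc, flags,
                          de_cancer = de_cancer)
      emit(ov$shares, "overlap_shares.tsv")
      emit(ov$expression, "overlap_expression.tsv")
      res$overlap <- ov
    }

    stage <- "report"
    if (length(calls) > 0L) {
      rec <- do.call(rbind, lapply(names(calls), function(nm) {
        planted <- sims[[nm]]$truth$hyper_genes
        called <- calls[[nm]]$hyper
        neural <- uni$truth$neural_genes
        data.frame(
          cancer_type = nm,
          n_planted_hyper = length(planted),
          n_called_hyper = length(called),
          jaccard_hyper = length(intersect(planted, called)) /
            length(union(planted, called)),
          planted_neural_share =
            if (is.null(sims[[nm]]$truth$neural_enrichment)) NA_real_
            else sims[[nm]]$truth$neural_enrichment,
          est_neural_share = mean(called %in% neural),
          stringsAsFactors = FALSE)
      }))
      emit(rec, "recovery.tsv")
      res$recovery <- rec
    }
    write_truth_json(truth_all, file.path(out_dir, "truth.json"))
    written <- c(written, "truth.json")
    write_run_metadata(
      file.path(out_dir, "run_metadata.json"),
      params = config[setdiff(names(config), "out_dir")],
      seed = config$seed)
    written <- c(written, "run_metadata.json")
    writeLines(c("status\tCOMPLETE",
                 paste0("file\t", sort(written))),
               file.path(out_dir, "MANIFEST"))
  }, error = on_fail)
  invisible(res)
}

#' Run the bundled demonstration pipeline
#'
#' A complete end-to-end run on a 2000-gene universe with two simulated
#' cancer types; finishes in well under two minutes on one CPU and reruns
#' byte-identically under a fixed seed.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed; default 1.
#' @return Invisibly, the [run_pipeline()] result list.
#' @export
run_demo <- function(out_dir, seed = 1) {
  run_pipeline(run_config(out_dir = out_dir, seed = seed))
}

#' Export probe calls for external upstream-regulator tools
#'
#' Promoter DNA methylation is an expression-silencing mark, so for
#' regulator tools that expect expression direction, hypermethylated loci
#' are exported as "down" and hypomethylated loci as "up".  No regulator
#' inference is performed here.
#'
#' @param dm A `diffmeth_table` from [diff_methylation()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
export_ipa <- function(dm, path) {
  stopifnot(inherits(dm, "diffmeth_table"))
  keep <- dm$call != "ns"
  out <- data.frame(
    probe_id = dm$probe_id[keep],
    direction = ifelse(dm$call[keep] == "hyper", "down", "up"),
    logFC_m = dm$logFC_m[keep],
    p_adj = dm$p_adj[keep],
    stringsAsFactors = FALSE)
  write_table_tsv(out, path)
}
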