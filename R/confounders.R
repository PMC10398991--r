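# Confounder analyses: tumor-purity robust regression, methylation-degree
# comparison, bivalent-chromatin cross-tabulation, and hallmark-wise
# neural enrichment.

# the four gene groups used by the purity analysis
purity_groups <- function(calls, flags) {
  neural <- neural_gene_ids(flags)
  hmg <- calls$hyper
  nondm <- setdiff(calls$tested, union(calls$hyper, calls$hypo))
  list(
    neural_hmg = intersect(hmg, neural),
    non_neural_hmg = setdiff(hmg, neural),
    neural_nondm = intersect(nondm, neural),
    non_neural_nondm = setdiff(nondm, neural))
}

#' Per-sample mean methylation by gene group
#'
#' For each tumor sample, the mean beta over the promoter probes of genes
#' in each of four groups: neural-related HMGs, non-neural HMGs,
#' neural-related non-differentially-methylated genes, and non-neural
#' non-DM genes.  Empty groups are omitted with a warning.
#'
#' @param dataset A [methylation_dataset()].
#' @param calls A [gene_call_set()].
#' @param flags A `neural_flags` object.
#' @param annotation A [probe_annotation()].
#' @param promoter_labels Promoter region labels.
#' @return Long `data.frame`: `sample_id`, `purity`, `group`, `mean_beta`.
#' @export
sample_group_means <- function(dataset, calls, flags, annotation,
                               promoter_labels = promoter_regions()) {
  stopifnot(inherits(dataset, "methylation_dataset"))
  groups <- purity_groups(calls, flags)
  map <- annotation$map
  map <- map[map$region %in% promoter_labels, , drop = FALSE]
  tum <- dataset$samples$group == "tumor"
  beta_t <- dataset$beta[, tum, drop = FALSE]
  sheet <- dataset$samples[tum, , drop = FALSE]
  rows <- lapply(names(groups), function(gn) {
    probes <- intersect(unique(map$probe_id[map$gene_id %in% groups[[gn]]]),
                        rownames(beta_t))
    if (length(probes) == 0L) {
      warning("empty gene group omitted: ", gn)
      return(NULL)
    }
    data.frame(sample_id = sheet$sample_id, purity = sheet$purity,
               group = gn,
               mean_beta = colMeans(beta_t[probes, , drop = FALSE],
                                    na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Huber robust regression of methylation on purity
#'
#' M-estimation with the Huber psi (tuning constant 1.345), MAD scale and
#' iteratively reweighted least squares, via `MASS::rlm`.  On clean data
#' (all residuals below the tuning threshold) the fit equals ordinary least
#' squares.
#'
#' @param y Response (e.g. per-sample mean beta).
#' @param x Covariate (tumor purity); needs >= 5 complete pairs and
#'   non-constant `x`.
#' @param k Huber tuning constant; default 1.345.
#' @param maxit Maximum IRLS iterations; default 200.
#' @param acc Convergence tolerance on coefficient change; default 1e-8.
#' @return List of class `purity_model_fit`: `slope`, `intercept`, `scale`,
#'   `iterations`, `converged`, `n`.
#' @export
robust_fit <- function(y, x, k = 1.345, maxit = 200, acc = 1e-8) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5L) stop("need >= 5 complete (x, y) pairs")
  if (sd(x) == 0) stop("design rank-deficient: 'x' is constant")
  ols <- stats::lm.fit(cbind(1, x), y)
  if (max(abs(ols$residuals)) <= 1e-12 * max(1, max(abs(y)))) {
    # perfect linear fit: the MAD scale is 0 and IRLS is undefined, but
    # Huber equals OLS by construction
    return(structure(list(slope = unname(ols$coefficients[2L]),
                          intercept = unname(ols$coefficients[1L]),
                          scale = 0, iterations = 0L, converged = TRUE,
                          n = length(x)),
                     class = "purity_model_fit"))
  }
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = k, maxit = maxit,
                   acc = acc, scale.est = "MAD")
  if (!fit$converged)
    stop(sprintf(
      "Huber IRLS did not converge in %d iterations (criterion trace: %s)",
      maxit, paste(format(utils::tail(fit$conv, 5), digits = 3),
                   collapse = ", ")))
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 scale = fit$s, iterations = length(fit$conv),
                 converged = fit$converged, n = length(x)),
            class = "purity_model_fit")
}

#' Purity regression per gene group
#'
#' Runs [sample_group_means()] and fits [robust_fit()] of the per-sample
#' group mean on tumor purity, separately for each of the four gene groups
#' (no interaction model).
#'
#' @inheritParams sample_group_means
#' @return `data.frame`: `group`, `slope`, `intercept`, `scale`,
#'   `iterations`, `n`.
#' @export
purity_regression <- function(dataset, calls, flags, annotation,
                              promoter_labels = promoter_regions()) {
  gm <- sample_group_means(dataset, calls, flags, annotation,
                           promoter_labels)
  rows <- lapply(split(gm, gm$group), function(g) {
    fit <- robust_fit(g$mean_beta, g$purity)
    data.frame(group = g$group[1L], slope = fit$slope,
               intercept = fit$intercept, scale = fit$scale,
               iterations = fit$iterations, n = fit$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare tumor methylation degrees of neural vs non-neural hyper genes
#'
#' Per-gene mean tumor beta over promoter probes, compared between
#' neural-related and non-neural hypermethylated genes with a two-sided
#' Wilcoxon rank-sum test.
#'
#' @inheritParams sample_group_means
#' @return List: `p`, `direction` (sign of neural median minus non-neural
#'   median), `n_neural`, `n_non_neural`, `summary` (`data.frame` of
#'   per-gene means), `degenerate` (TRUE when either set has a single
#'   gene, where the rank-sum test is uninformative).
#' @export
methylation_degree_compare <- function(dataset, calls, flags, annotation,
                                       promoter_labels =
                                         promoter_regions()) {
  neural <- neural_gene_ids(flags)
  sets <- list(neural = intersect(calls$hyper, neural),
               non_neural = setdiff(calls$hyper, neural))
  if (any(lengths(sets) == 0L))
    stop("both neural and non-neural hyper sets must be non-empty")
  map <- annotation$map
  map <- map[map$region %in% promoter_labels &
               map$probe_id %in% rownames(dataset$beta), , drop = FALSE]
  tum <- dataset$samples$group == "tumor"
  probe_mean <- rowMeans(dataset$beta[, tum, drop = FALSE], na.rm = TRUE)
  per_gene <- function(gs) {
    m <- map[map$gene_id %in% gs, , drop = FALSE]
    vapply(split(m$probe_id, m$gene_id),
           function(p) mean(probe_mean[p]), 0)
  }
  v1 <- per_gene(sets$neural)
  v2 <- per_gene(sets$non_neural)
  degenerate <- length(v1) < 2L || length(v2) < 2L
  wt <- suppressWarnings(wilcox.test(v1, v2))
  list(p = wt$p.value,
       direction = sign(median(v1) - median(v2)),
       n_neural = length(v1), n_non_neural = length(v2),
       summary = data.frame(
         gene_id = c(names(v1), names(v2)),
         set = rep(c("neural", "non_neural"), c(length(v1), length(v2))),
         mean_tumor_beta = c(v1, v2), stringsAsFactors = FALSE),
       degenerate = degenerate)
}

#' Cross-tabulate hypermethylation against bivalency and neural status
#'
#' Emits (i) the overall 2x2 table of hypermethylation x bivalency over
#' the universe, and (ii) within-bivalent and within-non-bivalent 2x2
#' tables of hypermethylation x neural status, each with a Pearson
#' chi-squared p-value (no continuity correction) and an odds ratio.
#' Bivalent genes outside the universe are dropped with a warning; empty
#' strata are skipped with a warning.
#'
#' @param calls A [gene_call_set()].
#' @param flags A `neural_flags` object.
#' @param bivalent Character vector of bivalent gene ids.
#' @param universe Background gene ids; default `calls$tested`.
#' @return Named list of strata (`overall`, `bivalent`, `non_bivalent`),
#'   each a list with `table`, `chi2`, `p`, `or`, `or_corrected`.
#' @export
bivalency_crosstab <- function(calls, flags, bivalent,
                               universe = calls$tested) {
  universe <- unique(as.character(universe))
  drop <- setdiff(bivalent, universe)
  if (length(drop) > 0) {
    warning(length(drop), " bivalent gene(s) outside the universe dropped")
    bivalent <- intersect(bivalent, universe)
  }
  hyper <- universe %in% calls$hyper
  biv <- universe %in% bivalent
  neural <- universe %in% neural_gene_ids(flags)
  one <- function(i_rows, f1, f2, n1, n2) {
    tab <- matrix(c(sum(f1[i_rows] & f2[i_rows]),
                    sum(f1[i_rows] & !f2[i_rows]),
                    sum(!f1[i_rows] & f2[i_rows]),
                    sum(!f1[i_rows] & !f2[i_rows])),
                  nrow = 2L, byrow = TRUE,
                  dimnames = list(c(n1, paste0("non_", n1)),
                                  c(n2, paste0("non_", n2))))
    ts <- chisq_2x2(tab)
    orr <- tryCatch(
      odds_ratio(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
      error = function(e) list(or = NA_real_, corrected = NA))
    list(table = tab, chi2 = ts$chi2, p = ts$p, or = orr$or,
         or_corrected = orr$corrected)
  }
  out <- list(overall = one(rep(TRUE, length(universe)), hyper, biv,
                            "hyper", "bivalent"))
  for (stratum in c("bivalent", "non_bivalent")) {
    rows <- if (stratum == "bivalent") biv else !biv
    if (sum(rows) == 0L) {
      warning("empty stratum skipped: ", stratum)
      next
    }
    out[[stratum]] <- one(rows, hyper, neural, "hyper", "neural")
  }
  out
}

#' Neural enrichment within each cancer-hallmark gene set
#'
#' For every hallmark set, restricts to the set's intersection with the
#' tested background and tests the 2x2 association (HMG vs non-HMG) x
#' (neural vs not) with a Pearson chi-squared test, BH-adjusted across
#' hallmarks.  Hallmarks with empty intersections yield an `NA` row with a
#' warning.
#'
#' @param calls A [gene_call_set()].
#' @param flags A `neural_flags` object.
#' @param hallmarks A [gene_set_collection()].
#' @return `data.frame`: `set_name`, `n`, `n_hmg`, `pct_neural_hmg`,
#'   `pct_neural_non_hmg`, `chi2`, `p`, `p_adj`.
#' @export
hallmark_enrichment <- function(calls, flags, hallmarks) {
  stopifnot(inherits(hallmarks, "gene_set_collection"))
  neural <- neural_gene_ids(flags)
  rows <- lapply(names(hallmarks), function(nm) {
    g <- intersect(hallmarks[[nm]], calls$tested)
    if (length(g) == 0L) {
      warning("hallmark set with empty tested intersection: ", nm)
      return(data.frame(set_name = nm, n = 0L, n_hmg = 0L,
                        pct_neural_hmg = NA_real_,
                        pct_neural_non_hmg = NA_real_,
                        chi2 = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    hmg <- g %in% calls$hyper
    neu <- g %in% neural
    tab <- matrix(c(sum(hmg & neu), sum(hmg & !neu),
                    sum(!hmg & neu), sum(!hmg & !neu)),
                  nrow = 2L, byrow = TRUE)
    ts <- if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
      list(chi2 = NA_real_, p = NA_real_) else chisq_2x2(tab)
    data.frame(set_name = nm, n = length(g), n_hmg = sum(hmg),
               pct_neural_hmg = 100 * sum(hmg & neu) / max(sum(hmg), 1L),
               pct_neural_non_hmg =
                 100 * sum(!hmg & neu) / max(sum(!hmg), 1L),
               chi2 = ts$chi2, p = ts$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- bh_adjust(out$p[ok])
  rownames(out) <- NULL
  out
}
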