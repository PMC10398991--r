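# Differential expression with optional precision weights, for identifying
# neural differentiation-associated genes, and the overlap statistics
# linking them to promoter hypermethylation and downregulation.
#
# The moderated-t machinery is shared with the methylation stage: with
# precision weights off and no covariates, de_expression reduces exactly to
# the two-group moderated t on the expression matrix.

# voom-style per-observation precision weights: lowess trend of
# sqrt(residual sd) on mean log-expression, evaluated at the fitted values;
# weights are predicted sd^-4.
voom_weights <- function(y, design, span = 0.5) {
  fit <- lm.fit(design, t(y))
  dfr <- nrow(design) - fit$rank
  res <- t(fit$residuals)
  sigma <- sqrt(rowSums(res^2) / dfr)
  sx <- rowMeans(y)
  sy <- sqrt(sigma)
  lo <- lowess(sx, sy, f = span)
  fitted_vals <- t(design %*% fit$coefficients)
  pred <- approx(lo$x, lo$y, xout = as.vector(fitted_vals), rule = 2,
                 ties = "ordered")$y
  pred <- pmax(pred, 1e-4)
  w <- matrix(pred^-4, nrow = nrow(y))
  dimnames(w) <- dimnames(y)
  w
}

#' Differential expression with moderated t and optional precision weights
#'
#' Fits a linear model per gene (condition plus optional age/sex
#' covariates), moderates residual variances with the same empirical-Bayes
#' machinery as the methylation stage, and calls genes `UR` (logFC > `lfc`
#' and BH-adjusted p < `alpha`), `DR` (mirrored) or `nonDE`.  With
#' `use_precision_weights`, per-observation weights from a lowess
#' mean-variance trend (predicted sd^-4 at the fitted values) absorb the
#' count-driven heteroscedasticity of log-scaled counts before moderation.
#'
#' @param dataset An [expression_dataset()].
#' @param contrast Length-2 character: conditions compared as
#'   `contrast[1] - contrast[2]`; default `c("neuron", "progenitor")`.
#' @param covariates Character subset of `c("age", "sex")` to adjust for;
#'   default: whichever are present in the sample table.
#' @param use_precision_weights Default `dataset$is_counts`.
#' @param alpha,lfc Call thresholds; defaults 0.05 and 1 (strict
#'   inequalities).
#' @param d0 Optional forced prior degrees of freedom.
#' @param span Lowess span of the mean-variance trend; default 0.5.
#' @return `data.frame` of class `de_table`: `gene_id`, `logFC`, `t_mod`,
#'   `df_total`, `p`, `p_adj`, `status`.
#' @export
de_expression <- function(dataset, contrast = c("neuron", "progenitor"),
                          covariates = NULL,
                          use_precision_weights = dataset$is_counts,
                          alpha = 0.05, lfc = 1, d0 = NULL, span = 0.5) {
  stopifnot(inherits(dataset, "expression_dataset"), length(contrast) == 2L)
  sheet <- dataset$samples
  keep <- sheet$condition %in% contrast
  if (sum(sheet$condition[keep] == contrast[1L]) < 3L ||
      sum(sheet$condition[keep] == contrast[2L]) < 3L)
    stop("need >= 3 samples per condition")
  y <- dataset$log_expr[, keep, drop = FALSE]
  sheet <- sheet[keep, , drop = FALSE]
  if (is.null(covariates))
    covariates <- intersect(c("age", "sex"), names(sheet))
  dat <- data.frame(
    cond = factor(sheet$condition, levels = rev(contrast)))
  for (cv in covariates) {
    v <- sheet[[cv]]
    if (is.null(v)) stop("covariate not in sample table: ", cv)
    dat[[cv]] <- if (cv == "sex") factor(v) else as.numeric(v)
  }
  design <- model.matrix(~ ., data = dat)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    aliased <- colnames(design)[qr_d$pivot[-seq_len(qr_d$rank)]]
    stop("design matrix rank-deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  coef_name <- paste0("cond", contrast[1L])
  ci <- match(coef_name, colnames(design))
  G <- nrow(y)
  p_des <- ncol(design)
  dfr <- nrow(design) - p_des
  if (use_precision_weights) {
    w <- voom_weights(y, design, span = span)
    coefs <- numeric(G); s2 <- numeric(G); seu <- numeric(G)
    for (g in seq_len(G)) {
      fg <- lm.wfit(design, y[g, ], w[g, ])
      coefs[g] <- fg$coefficients[ci]
      s2[g] <- sum(fg$residuals^2 * w[g, ]) / dfr
      xtwx_inv <- chol2inv(chol(crossprod(design * sqrt(w[g, ]))))
      seu[g] <- sqrt(xtwx_inv[ci, ci])
    }
  } else {
    fit <- lm.fit(design, t(y))
    coefs <- fit$coefficients[ci, ]
    res <- t(fit$residuals)
    s2 <- rowSums(res^2) / dfr
    xtx_inv <- chol2inv(chol(crossprod(design)))
    seu <- rep(sqrt(xtx_inv[ci, ci]), G)
  }
  eb <- ebayes_moderate(s2, dfr, coef = coefs, stderr_unit = seu, d0 = d0)
  p_adj <- bh_adjust(eb$p)
  status <- rep("nonDE", G)
  status[which(coefs > lfc & p_adj < alpha)] <- "UR"
  status[which(coefs < -lfc & p_adj < alpha)] <- "DR"
  out <- data.frame(gene_id = rownames(y), logFC = unname(coefs),
                    t_mod = unname(eb$t_mod),
                    df_total = unname(eb$df_total), p = unname(eb$p),
                    p_adj = p_adj, status = status,
                    stringsAsFactors = FALSE)
  attr(out, "ebayes") <- list(d0 = eb$d0, s0_sq = eb$s0_sq)
  attr(out, "contrast") <- contrast
  class(out) <- c("de_table", "data.frame")
  out
}

#' Extract differentiation-associated genes from a DE table
#'
#' Genes significantly overexpressed in the neuron-vs-progenitor contrast
#' (`status == "UR"`).
#'
#' @param de A `de_table` from [de_expression()].
#' @return Character vector of gene ids (warning when empty).
#' @export
classify_differentiation <- function(de) {
  stopifnot(inherits(de, "de_table"))
  out <- de$gene_id[de$status == "UR"]
  if (length(out) == 0L)
    warning("no differentiation-associated (UR) genes found")
  out
}

#' Overlap statistics linking hypermethylation, differentiation and
#' downregulation
#'
#' Emits (i) the hypermethylated share within the
#' differentiation-associated set and within its neural-related subset,
#' each with the 2x2 odds ratio and chi-squared test against the rest of
#' the universe; and (ii), when a cancer DE table is given, the
#' DR/UR/nonDE composition of hypermethylated neural genes that are vs.
#' are not differentiation-associated, with the odds ratio for
#' downregulation.
#'
#' @param calls A [gene_call_set()] (cancer methylation calls).
#' @param diff_assoc Character vector of differentiation-associated genes.
#' @param flags A `neural_flags` object.
#' @param de_cancer Optional `de_table` of cancer-vs-normal expression.
#' @param universe Background gene ids; default `calls$tested`.
#' @return List with `shares` (`data.frame`: `set`, `n`, `n_hyper`,
#'   `pct_hyper`, `or`, `chi2`, `p`) and, when `de_cancer` given,
#'   `expression` (`data.frame`: `group`, `n`, `frac_DR`, `frac_UR`,
#'   `frac_nonDE`) and `dr_or` (odds ratio for DR membership).
#' @export
overlap_stats <- function(calls, diff_assoc, flags, de_cancer = NULL,
                          universe = calls$tested) {
  universe <- unique(as.character(universe))
  diff_assoc <- intersect(unique(as.character(diff_assoc)), universe)
  neural <- neural_gene_ids(flags)
  hyper <- intersect(calls$hyper, universe)
  share_row <- function(nm, set) {
    if (length(set) == 0L) {
      warning("empty gene set in overlap: ", nm)
      return(data.frame(set = nm, n = 0L, n_hyper = NA_integer_,
                        pct_hyper = NA_real_, or = NA_real_,
                        chi2 = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    k <- sum(set %in% hyper)
    rest <- setdiff(universe, set)
    tab <- matrix(c(k, length(set) - k,
                    sum(rest %in% hyper),
                    length(rest) - sum(rest %in% hyper)),
                  nrow = 2L, byrow = TRUE)
    ts <- chisq_2x2(tab)
    orr <- tryCatch(
      odds_ratio(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$or,
      error = function(e) NA_real_)
    data.frame(set = nm, n = length(set), n_hyper = k,
               pct_hyper = 100 * k / length(set), or = orr,
               chi2 = ts$chi2, p = ts$p, stringsAsFactors = FALSE)
  }
  shares <- rbind(
    share_row("diff_assoc", diff_assoc),
    share_row("diff_assoc_neural", intersect(diff_assoc, neural)))
  out <- list(shares = shares)
  if (!is.null(de_cancer)) {
    stopifnot(inherits(de_cancer, "de_table"))
    grp <- list(
      hyper_neural_diff = intersect(intersect(hyper, neural), diff_assoc),
      hyper_neural_nondiff = setdiff(intersect(hyper, neural), diff_assoc))
    status <- setNames(de_cancer$status, de_cancer$gene_id)
    comp <- lapply(names(grp), function(nm) {
      g <- intersect(grp[[nm]], names(status))
      if (length(g) == 0L) {
        warning("empty expression-overlap group: ", nm)
        return(data.frame(group = nm, n = 0L, frac_DR = NA_real_,
                          frac_UR = NA_real_, frac_nonDE = NA_real_,
                          stringsAsFactors = FALSE))
      }
      st <- status[g]
      data.frame(group = nm, n = length(g),
                 frac_DR = mean(st == "DR"),
                 frac_UR = mean(st == "UR"),
                 frac_nonDE = mean(st == "nonDE"),
                 stringsAsFactors = FALSE)
    })
    out$expression <- do.call(rbind, comp)
    g1 <- intersect(grp$hyper_neural_diff, names(status))
    g2 <- intersect(grp$hyper_neural_nondiff, names(status))
    out$dr_or <- if (length(g1) > 0 && length(g2) > 0) {
      tryCatch(odds_ratio(sum(status[g1] == "DR"),
                          sum(status[g1] != "DR"),
                          sum(status[g2] == "DR"),
                          sum(status[g2] != "DR"))$or,
               error = function(e) NA_real_)
    } else NA_real_
  }
  out
}
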