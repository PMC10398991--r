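# Per-probe differential methylation: M-value transform, two-group fit,
# empirical-Bayes variance moderation (moment matching on log s^2), BH
# adjustment, three-threshold hyper/hypo calls, promoter gene aggregation.
#
# Contrast orientation is tumor - normal throughout: hyper <=> logFC_m > +1.

#' Convert beta-values to M-values
#'
#' `m = log2((beta + offset) / (1 - beta + offset))`.  The offset guards
#' exact 0/1 beta values; it is strictly increasing in beta.
#'
#' @param beta Numeric vector/matrix of fractions in \[0,1\] (`NA` allowed).
#' @param offset Small positive constant; default `1e-6`.
#' @return M-values, same shape as `beta`.
#' @export
beta_to_m <- function(beta, offset = 1e-6) {
  if (any(!is.na(beta) & (beta < 0 | beta > 1)))
    stop("beta values outside [0,1]")
  log2((beta + offset) / (1 - beta + offset))
}

#' Inverse of [beta_to_m()] at offset 0
#' @param m M-values.
#' @return Beta fractions in (0,1).
#' @export
m_to_beta <- function(m) {
  e <- 2^m
  e / (1 + e)
}

#' Per-probe two-group fit on M-values
#'
#' For every probe, the difference of group means of M (tumor minus normal),
#' the pooled residual variance and its degrees of freedom, computed
#' complete-case per probe.  Probes with fewer than 2 non-missing samples in
#' either group are excluded (a message reports the count).  The mean
#' beta-value difference is computed on the raw beta scale.
#'
#' @param dataset A [methylation_dataset()].
#' @param contrast Length-2 character: groups compared as
#'   `contrast[1] - contrast[2]`; default `c("tumor", "normal")`.
#' @param offset Beta-to-M offset.
#' @return `data.frame` with columns `probe_id`, `logFC_m`, `mean_dbeta`,
#'   `s2`, `df`, `stderr_unit` (`sqrt(1/n1 + 1/n2)`), `n1`, `n2`.
#' @export
fit_probewise <- function(dataset, contrast = c("tumor", "normal"),
                          offset = 1e-6) {
  stopifnot(inherits(dataset, "methylation_dataset"), length(contrast) == 2L)
  g <- dataset$samples$group
  i1 <- which(g == contrast[1L])
  i2 <- which(g == contrast[2L])
  if (length(i1) < 2L || length(i2) < 2L)
    stop(sprintf("need >=2 samples per group ('%s': %d, '%s': %d)",
                 contrast[1L], length(i1), contrast[2L], length(i2)))
  m <- beta_to_m(dataset$beta, offset = offset)
  b1 <- dataset$beta[, i1, drop = FALSE]
  b2 <- dataset$beta[, i2, drop = FALSE]
  m1 <- m[, i1, drop = FALSE]
  m2 <- m[, i2, drop = FALSE]
  n1 <- rowSums(!is.na(m1))
  n2 <- rowSums(!is.na(m2))
  keep <- n1 >= 2L & n2 >= 2L
  if (any(!keep))
    message(sprintf("%d probe(s) excluded: <2 non-missing samples per group",
                    sum(!keep)))
  mu1 <- rowMeans(m1, na.rm = TRUE)
  mu2 <- rowMeans(m2, na.rm = TRUE)
  ss1 <- rowSums((m1 - mu1)^2, na.rm = TRUE)
  ss2 <- rowSums((m2 - mu2)^2, na.rm = TRUE)
  d <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / pmax(d, 1L)
  out <- data.frame(
    probe_id = rownames(dataset$beta),
    logFC_m = mu1 - mu2,
    mean_dbeta = rowMeans(b1, na.rm = TRUE) - rowMeans(b2, na.rm = TRUE),
    s2 = s2,
    df = as.numeric(d),
    stderr_unit = sqrt(1 / n1 + 1 / n2),
    n1 = n1, n2 = n2,
    stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Newton inversion of the trigamma function (solve trigamma(x) = y), used by
# the moment estimator of the prior degrees of freedom.
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(NA_real_)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, 0)
}

#' Empirical-Bayes moderation of probewise variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq`
#' by matching the moments of `log(s2)` to its theoretical scaled-F
#' distribution (digamma/trigamma inversion), then shrinks each probe's
#' variance to the posterior
#' `s_post_sq = (d0 * s0_sq + df * s2) / (d0 + df)`.
#' When `coef` and `stderr_unit` are supplied, moderated t-statistics and
#' two-sided p-values on `d0 + df` degrees of freedom are returned.
#'
#' Degenerate cases follow the usual conventions: if the observed `log(s2)`
#' dispersion is no larger than expected under equal true variances,
#' `d0 = Inf` and every posterior variance equals `s0_sq`; with fewer than
#' 10 probes the estimator is unreliable, so the function warns and falls
#' back to ordinary t (`d0 = 0`).  `d0` may also be forced (e.g. `d0 = 0`
#' reproduces the ordinary two-sample t exactly).
#'
#' @param s2 Vector of residual variances (>= 0).
#' @param df Residual degrees of freedom (scalar or vector, >= 1).
#' @param coef Optional vector of effect estimates.
#' @param stderr_unit Optional unit standard errors (stderr = s * stderr_unit).
#' @param d0 Optional forced prior degrees of freedom.
#' @return List of class `ebayes_fit`: `d0`, `s0_sq`, `s_post_sq`, `df`,
#'   and, when `coef` given, `t_mod`, `df_total`, `p`.
#' @export
ebayes_moderate <- function(s2, df, coef = NULL, stderr_unit = NULL,
                            d0 = NULL) {
  n <- length(s2)
  if (length(df) == 1L) df <- rep(as.numeric(df), n)
  stopifnot(length(df) == n, all(df >= 1), all(s2 >= 0, na.rm = TRUE))
  if (is.null(d0)) {
    if (n < 10L) {
      warning("fewer than 10 probes: falling back to ordinary t (d0 = 0)")
      d0 <- 0
      s0_sq <- NA_real_
    } else {
      ok <- is.finite(s2) & s2 > 0
      z <- log(s2[ok])
      e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
      emean <- mean(e)
      evar <- var(e) - mean(trigamma(df[ok] / 2))
      if (is.na(evar) || evar <= 0) {
        # under-dispersed log-variances: no evidence of variance
        # heterogeneity, so shrink completely to the geometric mean of the
        # observed s2 (equal to the common value when all s2 are identical)
        d0 <- Inf
        s0_sq <- exp(mean(z))
      } else {
        d0 <- 2 * trigamma_inverse(evar)
        s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
      }
    }
  } else {
    stopifnot(length(d0) == 1L, d0 >= 0)
    s0_sq <- if (d0 == 0) NA_real_ else {
      ok <- is.finite(s2) & s2 > 0
      e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
      if (is.finite(d0)) exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      else exp(mean(log(s2[ok])))
    }
  }
  s_post_sq <- if (is.infinite(d0)) {
    rep(s0_sq, n)
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_sq + df * s2) / (d0 + df)
  }
  fit <- list(d0 = d0, s0_sq = s0_sq, s_post_sq = s_post_sq, df = df)
  if (!is.null(coef)) {
    stopifnot(length(coef) == n, length(stderr_unit) %in% c(1L, n))
    df_total <- d0 + df
    t_mod <- coef / (sqrt(s_post_sq) * stderr_unit)
    p <- 2 * pt(-abs(t_mod), df = df_total)
    fit$t_mod <- t_mod
    fit$df_total <- df_total
    fit$p <- p
  }
  class(fit) <- "ebayes_fit"
  fit
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotone enforcement; `p_adj` lies in `[p, 1]`.
#' @param p Vector of p-values in \[0,1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values outside [0,1]")
  p.adjust(p, method = "BH")
}

#' Three-threshold hyper/hypo probe calls
#'
#' `hyper` iff `p_adj < alpha` and `logFC_m > lfc` and `mean_dbeta > dbeta`;
#' `hypo` with the mirrored cut-offs; all inequalities strict, so boundary
#' values are `ns`.
#'
#' @param p_adj,logFC_m,mean_dbeta Per-probe vectors.
#' @param alpha,lfc,dbeta Positive thresholds; defaults 0.05, 1, 0.1.
#' @return Character vector with values `hyper`, `hypo`, `ns`.
#' @export
call_probes <- function(p_adj, logFC_m, mean_dbeta,
                        alpha = 0.05, lfc = 1, dbeta = 0.1) {
  stopifnot(alpha > 0, lfc > 0, dbeta > 0)
  call <- rep("ns", length(p_adj))
  call[which(p_adj < alpha & logFC_m > lfc & mean_dbeta > dbeta)] <- "hyper"
  call[which(p_adj < alpha & logFC_m < -lfc & mean_dbeta < -dbeta)] <- "hypo"
  call
}

#' Full per-probe differential methylation table
#'
#' Runs [fit_probewise()], [ebayes_moderate()], [bh_adjust()] and
#' [call_probes()] in sequence.
#'
#' @inheritParams fit_probewise
#' @inheritParams call_probes
#' @param d0 Optional forced prior degrees of freedom (see
#'   [ebayes_moderate()]).
#' @return `data.frame` of class `diffmeth_table` with columns `probe_id`,
#'   `logFC_m`, `mean_dbeta`, `t_mod`, `df_total`, `p`, `p_adj`, `call`.
#' @export
diff_methylation <- function(dataset, contrast = c("tumor", "normal"),
                             offset = 1e-6, alpha = 0.05, lfc = 1,
                             dbeta = 0.1, d0 = NULL) {
  fw <- fit_probewise(dataset, contrast = contrast, offset = offset)
  eb <- ebayes_moderate(fw$s2, fw$df, coef = fw$logFC_m,
                        stderr_unit = fw$stderr_unit, d0 = d0)
  out <- data.frame(
    probe_id = fw$probe_id,
    logFC_m = fw$logFC_m,
    mean_dbeta = fw$mean_dbeta,
    t_mod = eb$t_mod,
    df_total = eb$df_total,
    p = eb$p,
    p_adj = bh_adjust(eb$p),
    stringsAsFactors = FALSE)
  out$call <- call_probes(out$p_adj, out$logFC_m, out$mean_dbeta,
                          alpha = alpha, lfc = lfc, dbeta = dbeta)
  attr(out, "ebayes") <- list(d0 = eb$d0, s0_sq = eb$s0_sq)
  attr(out, "thresholds") <- list(alpha = alpha, lfc = lfc, dbeta = dbeta,
                                  offset = offset)
  class(out) <- c("diffmeth_table", "data.frame")
  out
}

#' Aggregate probe calls to promoter-level gene calls
#'
#' A gene is hypermethylated iff at least one of its promoter probes
#' (labels in `promoter_labels`; restricted to CpG-island probes when
#' `island_only`) is called hyper; hypomethylation is defined analogously,
#' and a gene with probes in both directions belongs to both sets.  The
#' tested background is every gene with at least one tested promoter probe.
#'
#' @param dm A `diffmeth_table` from [diff_methylation()] (or any
#'   `data.frame` with `probe_id` and `call`).
#' @param annotation A [probe_annotation()].
#' @param promoter_labels Region labels that define a promoter probe.
#' @param island_only Restrict to probes with the CpG-island flag.
#' @return A [gene_call_set()].
#' @export
aggregate_genes <- function(dm, annotation,
                            promoter_labels = promoter_regions(),
                            island_only = FALSE) {
  stopifnot(inherits(annotation, "probe_annotation"))
  map <- annotation$map
  map <- map[map$region %in% promoter_labels, , drop = FALSE]
  if (island_only) {
    isl <- annotation$probes$probe_id[annotation$probes$island]
    map <- map[map$probe_id %in% isl, , drop = FALSE]
  }
  map <- map[map$probe_id %in% dm$probe_id, , drop = FALSE]
  call <- dm$call[match(map$probe_id, dm$probe_id)]
  gene_call_set(
    hyper = unique(map$gene_id[call == "hyper"]),
    hypo = unique(map$gene_id[call == "hypo"]),
    tested = unique(map$gene_id))
}
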