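# Core enrichment statistics: 2x2 chi-squared for neural enrichment against
# the tested-gene background, BH across cancer types, hyper-vs-hypo paired
# t-test, generic hypergeometric overrepresentation, two-proportion
# comparison, odds ratios.  No continuity corrections anywhere by default.

# Pearson chi-squared on a 2x2 table without continuity correction, with an
# exact (Fisher) fallback when any expected cell is below `min_expected`.
chisq_2x2 <- function(tab, min_expected = 1) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  method <- "chisq"
  p <- ct$p.value
  if (any(ct$expected < min_expected)) {
    warning("expected cell count < ", min_expected,
            ": reporting exact (Fisher) p-value instead")
    p <- fisher.test(tab)$p.value
    method <- "fisher"
  }
  list(chi2 = unname(ct$statistic), p = unname(p), method = method,
       expected = ct$expected)
}

#' Test neural enrichment of a called gene set against the array background
#'
#' Builds the 2x2 table (gene in the hyper/hypo set vs. rest of the tested
#' background) x (neural-related vs. not) and applies the Pearson
#' chi-squared test (1 df, no continuity correction).  When any expected
#' cell count is below 1, an exact Fisher p-value is reported instead and
#' the row is flagged.  Alternatively (`test = "goodness_of_fit"`) a 1-df
#' goodness-of-fit test of the observed neural count against the background
#' fraction is available.
#'
#' @param calls A [gene_call_set()] with at least 10 tested genes.
#' @param flags A `neural_flags` object (see [flag_genes()]).
#' @param direction `"hyper"` or `"hypo"`.
#' @param cancer_type Label copied into the output row.
#' @param test `"background"` (2x2 against the rest of the tested
#'   background, the default) or `"goodness_of_fit"`.
#' @return One-row `data.frame`: `cancer_type`, `direction`, `n_genes`,
#'   `n_neural`, `pct_neural` (0-100), `background_pct`, `effect`
#'   (`enriched`/`depleted`/`none`), `chi2`, `p`, `method`.
#' @export
neural_enrichment_test <- function(calls, flags,
                                   direction = c("hyper", "hypo"),
                                   cancer_type = NA_character_,
                                   test = c("background",
                                            "goodness_of_fit")) {
  direction <- match.arg(direction)
  test <- match.arg(test)
  stopifnot(inherits(calls, "gene_call_set"),
            inherits(flags, "neural_flags"))
  if (length(calls$tested) < 10L)
    stop("tested background has fewer than 10 genes")
  set <- calls[[direction]]
  if (length(set) == 0L) stop("empty ", direction, " gene set")
  neural <- neural_gene_ids(flags)
  rest <- setdiff(calls$tested, set)
  a <- sum(set %in% neural)
  b <- length(set) - a
  cc <- sum(rest %in% neural)
  dd <- length(rest) - cc
  bg_pct <- 100 * sum(calls$tested %in% neural) / length(calls$tested)
  if (test == "background") {
    tab <- matrix(c(a, b, cc, dd), nrow = 2L, byrow = TRUE,
                  dimnames = list(c("set", "rest"),
                                  c("neural", "non_neural")))
    ts <- chisq_2x2(tab)
  } else {
    f <- sum(calls$tested %in% neural) / length(calls$tested)
    ct <- suppressWarnings(chisq.test(c(a, b), p = c(f, 1 - f)))
    ts <- list(chi2 = unname(ct$statistic), p = unname(ct$p.value),
               method = "goodness_of_fit")
  }
  pct <- 100 * a / length(set)
  effect <- if (pct > bg_pct) "enriched" else if (pct < bg_pct)
    "depleted" else "none"
  data.frame(cancer_type = cancer_type, direction = direction,
             n_genes = length(set), n_neural = a, pct_neural = pct,
             background_pct = bg_pct, effect = effect,
             chi2 = ts$chi2, p = ts$p, method = ts$method,
             stringsAsFactors = FALSE)
}

#' BH adjustment of enrichment rows across cancer types
#'
#' Applies Benjamini-Hochberg within each direction (hyper/hypo) across the
#' cancer types present.
#'
#' @param rows `data.frame` of rows from [neural_enrichment_test()].
#' @return The same rows with an `fdr` column.
#' @export
fdr_across_cancers <- function(rows) {
  stopifnot(all(c("direction", "p") %in% names(rows)))
  rows$fdr <- NA_real_
  for (d in unique(rows$direction)) {
    i <- rows$direction == d
    rows$fdr[i] <- bh_adjust(rows$p[i])
  }
  rows
}

#' Paired two-tailed t-test on per-cancer percentages
#'
#' One-sample t on the paired differences (`df = n - 1`), as used to compare
#' the percentages of neural-related hyper- vs hypomethylated genes across
#' cancer types.
#'
#' @param pct_hyper,pct_hypo Equal-length numeric vectors (n >= 3), paired
#'   by cancer type.
#' @return List with `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
paired_t_test <- function(pct_hyper, pct_hypo) {
  stopifnot(length(pct_hyper) == length(pct_hypo))
  if (length(pct_hyper) < 3L) stop("need at least 3 pairs")
  d <- pct_hyper - pct_hypo
  if (sd(d) == 0)
    stop("zero-variance paired differences: t undefined")
  ht <- t.test(pct_hyper, pct_hypo, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d))
}

#' Hypergeometric overrepresentation analysis
#'
#' For every set in `collection`, the upper-tail hypergeometric probability
#' `P(X >= k)` of observing `k` = |query ∩ set| successes when drawing
#' `n` = |query| genes from a universe of `N` containing `K` = |set| set
#' members, with BH adjustment across sets.  Query genes outside the
#' universe are dropped with a warning.
#'
#' @param query Character vector of gene ids.
#' @param collection A [gene_set_collection()].
#' @param universe Non-empty character vector of background gene ids.
#' @param alpha Significance threshold recorded in the `significant` column
#'   (`p_adj < alpha`); default 0.05.
#' @return `data.frame` with columns `set_name`, `k`, `K`, `n`, `N`, `p`,
#'   `p_adj`, `significant`, sorted by `p`.
#' @export
ora <- function(query, collection, universe, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  query <- unique(as.character(query))
  out <- setdiff(query, universe)
  if (length(out) > 0) {
    warning(length(out), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < alpha
  res <- res[order(res$p, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare two proportions
#'
#' Two-sample proportion chi-squared test (1 df, no continuity correction),
#' two-sided.
#'
#' @param x1,n1 Successes and trials in the first sample.
#' @param x2,n2 Successes and trials in the second sample.
#' @return List with `p`, `estimate` (difference p1 - p2), `chi2`.
#' @export
compare_proportions <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  if (x1 > n1 || x2 > n2 || x1 < 0 || x2 < 0)
    stop("inconsistent counts")
  pt_ <- suppressWarnings(
    prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
  list(p = pt_$p.value, estimate = x1 / n1 - x2 / n2,
       chi2 = unname(pt_$statistic))
}

#' Odds ratio of a 2x2 table
#'
#' `OR = (a d) / (b c)`, with the Haldane +0.5 correction applied to every
#' cell iff any cell is zero.  Undefined tables (a zero row or column)
#' raise an error.
#'
#' @param a,b,c,d Non-negative counts laid out row-wise:
#'   `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return List with `or`, `corrected` (logical), `table`.
#' @export
odds_ratio <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0)) stop("negative counts")
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0))
    stop("odds ratio undefined: zero row or column")
  corrected <- any(cnt == 0)
  if (corrected) cnt <- cnt + 0.5
  or <- (cnt[1] * cnt[4]) / (cnt[2] * cnt[3])
  list(or = or, corrected = corrected,
       table = matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE))
}
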