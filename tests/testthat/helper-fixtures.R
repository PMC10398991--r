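# Fixture builders shared across test files.  Everything is constructed in
# code; no data files.

# tiny 3-probe x 4-sample dataset with known group means
tiny_meth <- function() {
  beta <- matrix(c(0.1, 0.1, 0.8, 0.8,
                   0.5, 0.5, 0.5, 0.5,
                   0.7, 0.6, 0.2, 0.3),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("cg01", "cg02", "cg03"),
                                 c("N1", "N2", "T1", "T2")))
  samples <- data.frame(sample_id = c("N1", "N2", "T1", "T2"),
                        group = c("normal", "normal", "tumor", "tumor"),
                        stringsAsFactors = FALSE)
  methylation_dataset(beta, samples)
}

# minimal neural_flags object with a given flagged subset
fake_flags <- function(neural, universe) {
  structure(list(
    flags = stats::setNames(universe %in% neural, universe),
    witnesses = data.frame(gene_id = as.character(neural),
                           term_id = rep("T:1", length(neural)),
                           pattern = rep("neuro", length(neural)),
                           stringsAsFactors = FALSE),
    patterns = neural_patterns()),
    class = "neural_flags")
}

# small GO annotation from parallel vectors
make_go <- function(gene_id, term_name,
                    term_id = paste0("T:", as.integer(factor(term_name))),
                    namespace = "BP") {
  go_annotation(data.frame(gene_id = gene_id, term_id = term_id,
                           term_name = term_name, namespace = namespace,
                           stringsAsFactors = FALSE))
}

# write a methylation dataset out as the TSV pair read_methylation expects
write_meth_tsv <- function(ds, dir = withr::local_tempdir(.local_envir =
                                                            parent.frame())) {
  beta_path <- file.path(dir, "beta.tsv")
  sheet_path <- file.path(dir, "samples.tsv")
  tab <- data.frame(probe_id = rownames(ds$beta), ds$beta,
                    check.names = FALSE)
  utils::write.table(tab, beta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$samples, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(beta = beta_path, samples = sheet_path)
}

# independent pooled two-sample t oracle (textbook formulas)
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  coef <- mean(x) - mean(y)
  s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  t <- coef / sqrt(s2 * (1 / n1 + 1 / n2))
  list(coef = coef, s2 = s2, t = t,
       p = 2 * stats::pt(-abs(t), df = n1 + n2 - 2))
}

# quadratic-time Benjamini-Hochberg reference
bh_reference <- function(p) {
  m <- length(p)
  r <- vapply(p, function(x) sum(p <= x), 0)
  ratio <- m * p / r
  vapply(p, function(x) min(1, min(ratio[p >= x])), 0)
}
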