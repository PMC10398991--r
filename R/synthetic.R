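# Seeded synthetic-data generators.  These define the study conditions the
# test suite runs under: a gene universe with GO names whose neural status
# is decidable by construction, logit-normal methylation noise with
# heterogeneous probe variances (so the empirical-Bayes machinery has
# something to shrink), hypermethylation planted preferentially in a
# designated neural subset, beta-scale purity mixing, and an expression
# contrast with age/sex covariates.
#
# All randomness is Mersenne-Twister with inversion normals, set from the
# `seed` argument at entry, so equal seeds give byte-identical output.

set_generator_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
}

# GO name vocabularies.  Every neural name contains >=1 default pattern as
# a substring; no non-neural name contains any (asserted at generation), so
# classifier correctness is decidable by construction.
neural_term_names <- function() {
  c("axon guidance", "regulation of nervous system development",
    "synaptic transmission", "neuron differentiation",
    "brain morphogenesis", "memory consolidation",
    "dendritic spine organization", "hippocampus development",
    "neural crest cell migration", "learning behavior",
    "neurotransmitter secretion", "synapse assembly",
    "neuronal action potential")
}

non_neural_term_names <- function() {
  c("cell cycle arrest", "lipid metabolic process", "DNA repair",
    "response to oxidative stress", "protein folding",
    "potassium ion transport", "apoptotic process",
    "cytoskeleton organization", "translation initiation",
    "oxidative phosphorylation", "cell adhesion",
    "glycolysis regulation", "chromatin remodeling", "vesicle docking",
    "RNA splicing", "mitochondrion organization")
}

cancer_hallmark_names <- function() {
  c("proliferative_signaling", "growth_suppressor_evasion",
    "cell_death_resistance", "replicative_immortality",
    "angiogenesis_induction", "invasion_metastasis",
    "genome_instability", "tumor_promoting_inflammation",
    "energy_metabolism_deregulation", "immune_evasion")
}

#' Generate a synthetic gene/probe/GO universe with planted neural labels
#'
#' Every gene receives at least one promoter probe (`TSS200`, `TSS1500` or
#' `1stExon`) and optionally a gene-body probe.  Exactly
#' `round(n_genes * neural_fraction)` genes are neural: each is annotated
#' to at least one GO term whose name contains a default neural pattern,
#' while non-neural genes receive only names containing none, so the
#' substring classifier recovers the planted labels exactly.
#'
#' @param n_genes Number of genes (>= 10).
#' @param probes_per_gene Promoter probes per gene (>= 1); default 2.
#' @param neural_fraction Fraction of genes planted neural; default 0.2.
#' @param bivalent_fraction Fraction of genes in the bivalent set;
#'   default 0.15.
#' @param body_prob Probability a gene also gets one Body probe;
#'   default 0.3.
#' @param island_prob Per-probe CpG-island probability; default 0.7.
#' @param hallmark_fraction Fraction of genes sampled into each of the 10
#'   hallmark sets; default 0.05.
#' @param seed Integer seed.
#' @return List with `annotation` ([probe_annotation()]), `go`
#'   ([go_annotation()]), `sets` ([gene_set_collection()]: `bivalent` plus
#'   10 hallmark sets) and `truth` (planted labels and parameters).
#' @export
generate_universe <- function(n_genes, probes_per_gene = 2,
                              neural_fraction = 0.2,
                              bivalent_fraction = 0.15,
                              body_prob = 0.3, island_prob = 0.7,
                              hallmark_fraction = 0.05, seed = 1) {
  stopifnot(n_genes >= 10, probes_per_gene >= 1,
            neural_fraction >= 0, neural_fraction <= 1,
            bivalent_fraction >= 0, bivalent_fraction <= 1)
  set_generator_seed(seed)
  pat <- tolower(neural_patterns())
  bad <- Filter(function(nm) any(vapply(pat, grepl, TRUE, tolower(nm),
                                        fixed = TRUE)),
                non_neural_term_names())
  stopifnot(length(bad) == 0L)

  genes <- sprintf("G%05d", seq_len(n_genes))
  n_neural <- round(n_genes * neural_fraction)
  neural_genes <- sort(sample(genes, n_neural))
  bivalent_genes <- sort(sample(genes, round(n_genes * bivalent_fraction)))

  # term table: ids and namespaces fixed per distinct name
  all_names <- c(neural_term_names(), non_neural_term_names())
  term_tab <- data.frame(
    term_id = sprintf("T:%07d", seq_along(all_names)),
    term_name = all_names,
    namespace = sample(c("BP", "CC", "MF"), length(all_names),
                       replace = TRUE),
    stringsAsFactors = FALSE)
  n_neu_terms <- length(neural_term_names())
  is_neural_gene <- genes %in% neural_genes

  n_other_terms <- nrow(term_tab) - n_neu_terms
  idx_list <- lapply(seq_len(n_genes), function(i) {
    if (is_neural_gene[i]) {
      unique(c(sample.int(n_neu_terms, sample(1:2, 1L)),
               if (runif(1) < 0.5)
                 n_neu_terms + sample.int(n_other_terms, sample(1:2, 1L))))
    } else {
      n_neu_terms + sample.int(n_other_terms, sample(1:3, 1L))
    }
  })
  idx <- unlist(idx_list, use.names = FALSE)
  go <- go_annotation(data.frame(
    gene_id = rep(genes, lengths(idx_list)),
    term_id = term_tab$term_id[idx],
    term_name = term_tab$term_name[idx],
    namespace = term_tab$namespace[idx],
    stringsAsFactors = FALSE))

  # probes: promoter probes for every gene, optional body probe
  prom_labels <- promoter_regions()
  n_prom <- n_genes * probes_per_gene
  has_body <- runif(n_genes) < body_prob
  gene_of_probe <- c(rep(genes, each = probes_per_gene), genes[has_body])
  region <- c(sample(prom_labels, n_prom, replace = TRUE),
              rep("Body", sum(has_body)))
  probe_ids <- sprintf("cg%07d", seq_along(gene_of_probe))
  annotation <- probe_annotation(
    probes = data.frame(probe_id = probe_ids,
                        island = runif(length(probe_ids)) < island_prob,
                        stringsAsFactors = FALSE),
    map = data.frame(probe_id = probe_ids, gene_id = gene_of_probe,
                     region = region, stringsAsFactors = FALSE))

  hm <- lapply(cancer_hallmark_names(), function(nm)
    sort(sample(genes, max(1L, round(n_genes * hallmark_fraction)))))
  names(hm) <- cancer_hallmark_names()
  sets <- gene_set_collection(c(list(bivalent = bivalent_genes), hm))

  truth <- list(genes = genes, neural_genes = neural_genes,
                bivalent_genes = bivalent_genes,
                neural_fraction = neural_fraction, seed = seed)
  list(annotation = annotation, go = go, sets = sets, truth = truth)
}

#' Generate a two-group methylation dataset with planted differential genes
#'
#' Probe baselines are drawn on the M scale (`m0 ~ N(baseline_mean,
#' baseline_sd^2)`), per-probe noise variances from a scaled
#' inverse-chi-squared prior (`sigma^2 ~ var_prior_df * var_prior_scale /
#' chisq(var_prior_df)`), and sample M-values as `m0 + eps`.  Every
#' promoter probe of a planted hyper gene is shifted by `+effect_m` in the
#' pure tumor signal (hypo genes by `-effect_m`); M-values are mapped to
#' beta through the logistic, so all beta values lie strictly in (0,1).
#' With a purity model, the observed tumor beta is the cell-fraction
#' mixture `purity * beta_tumor + (1 - purity) * beta_normal` on the beta
#' scale.
#'
#' When `neural_enrichment` is given, the planted hyper set contains
#' exactly `round(n_hyper * neural_enrichment)` neural genes; when `NULL`,
#' hyper genes are sampled irrespective of neural status (optionally biased
#' by `hyper_weight`).
#'
#' @param annotation A [probe_annotation()] (e.g. from
#'   [generate_universe()]).
#' @param neural_genes Character vector of neural gene ids (used for
#'   enrichment planting).
#' @param n_hyper,n_hypo Numbers of planted hyper-/hypomethylated genes.
#' @param neural_enrichment Target fraction of planted hyper genes that are
#'   neural, or `NULL`.
#' @param effect_m Mean M-scale shift (> 0) for planted probes; default 3.
#' @param n_normal,n_tumor Samples per group (>= 3 each).
#' @param purity_model `NULL` (pure tumors, purity recorded as `NA`) or
#'   `c(a, b)` for per-sample purity ~ Uniform(a, b).
#' @param cancer_type Label written into the sample sheet.
#' @param baseline_mean,baseline_sd Baseline M distribution; defaults -1
#'   and 1.5 (promoter probes skew unmethylated).
#' @param var_prior_df,var_prior_scale Prior df and scale (s0^2) of the
#'   probe variance distribution; defaults 4 and 0.04.
#' @param hyper_weight Optional named per-gene sampling weight used when
#'   `neural_enrichment` is `NULL` (e.g. to give bivalent genes higher
#'   hyper odds).
#' @param seed Integer seed.
#' @return List with `dataset` ([methylation_dataset()]) and `truth`
#'   (planted hyper/hypo genes, purity, parameters).
#' @export
generate_methylation <- function(annotation, neural_genes = character(),
                                 n_hyper, n_hypo = 0,
                                 neural_enrichment = NULL, effect_m = 3,
                                 n_normal = 20, n_tumor = 20,
                                 purity_model = NULL,
                                 cancer_type = "SIM",
                                 baseline_mean = -1, baseline_sd = 1.5,
                                 var_prior_df = 4, var_prior_scale = 0.04,
                                 hyper_weight = NULL, seed = 1) {
  stopifnot(inherits(annotation, "probe_annotation"),
            n_normal >= 3, n_tumor >= 3, effect_m >= 0,
            n_hyper >= 0, n_hypo >= 0)
  set_generator_seed(seed)
  map <- annotation$map
  prom <- map[map$region %in% promoter_regions(), , drop = FALSE]
  eligible <- unique(prom$gene_id)
  if (n_hyper + n_hypo > length(eligible))
    stop("more planted genes than genes with promoter probes")

  if (!is.null(neural_enrichment)) {
    stopifnot(neural_enrichment >= 0, neural_enrichment <= 1)
    n_neu <- round(n_hyper * neural_enrichment)
    n_non <- n_hyper - n_neu
    pool_neu <- intersect(eligible, neural_genes)
    pool_non <- setdiff(eligible, neural_genes)
    if (n_neu > length(pool_neu))
      stop(sprintf(
        paste0("neural_enrichment %.3f unreachable: needs %d neural genes ",
               "but only %d available (max enrichment %.3f)"),
        neural_enrichment, n_neu, length(pool_neu),
        length(pool_neu) / n_hyper))
    if (n_non > length(pool_non))
      stop(sprintf(
        paste0("neural_enrichment %.3f unreachable: needs %d non-neural ",
               "genes but only %d available (min enrichment %.3f)"),
        neural_enrichment, n_non, length(pool_non),
        1 - length(pool_non) / n_hyper))
    hyper_genes <- c(sample(pool_neu, n_neu), sample(pool_non, n_non))
  } else {
    w <- if (is.null(hyper_weight)) NULL else {
      ww <- hyper_weight[eligible]
      ww[is.na(ww)] <- 1
      ww
    }
    hyper_genes <- sample(eligible, n_hyper, prob = w)
  }
  hypo_genes <- sample(setdiff(eligible, hyper_genes), n_hypo)

  probes <- annotation$probes$probe_id
  P <- length(probes)
  m0 <- rnorm(P, baseline_mean, baseline_sd)
  sigma <- sqrt(var_prior_df * var_prior_scale / rchisq(P, var_prior_df))
  delta <- numeric(P)
  i_hyper <- probes %in% prom$probe_id[prom$gene_id %in% hyper_genes]
  i_hypo <- probes %in% prom$probe_id[prom$gene_id %in% hypo_genes]
  delta[i_hyper] <- effect_m
  delta[i_hypo] <- -effect_m

  noise <- function(ncol) matrix(rnorm(P * ncol, 0, sigma), nrow = P)
  beta_normal <- m_to_beta(m0 + noise(n_normal))
  beta_pure <- m_to_beta(m0 + delta + noise(n_tumor))
  if (is.null(purity_model)) {
    purity <- rep(NA_real_, n_tumor)
    beta_tumor <- beta_pure
  } else {
    stopifnot(length(purity_model) == 2L,
              purity_model[1] >= 0, purity_model[2] <= 1,
              purity_model[1] <= purity_model[2])
    purity <- runif(n_tumor, purity_model[1], purity_model[2])
    beta_contam <- m_to_beta(m0 + noise(n_tumor))
    beta_tumor <- sweep(beta_pure, 2L, purity, `*`) +
      sweep(beta_contam, 2L, 1 - purity, `*`)
  }
  beta <- cbind(beta_normal, beta_tumor)
  rownames(beta) <- probes
  ids <- c(sprintf("N%03d", seq_len(n_normal)),
           sprintf("T%03d", seq_len(n_tumor)))
  colnames(beta) <- ids
  samples <- data.frame(
    sample_id = ids,
    group = rep(c("normal", "tumor"), c(n_normal, n_tumor)),
    cancer_type = cancer_type,
    purity = c(rep(NA_real_, n_normal), purity),
    stringsAsFactors = FALSE)
  truth <- list(hyper_genes = sort(hyper_genes),
                hypo_genes = sort(hypo_genes),
                neural_genes = neural_genes,
                effect_m = effect_m,
                neural_enrichment = neural_enrichment,
                purity = setNames(purity, ids[samples$group == "tumor"]),
                baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                var_prior_df = var_prior_df,
                var_prior_scale = var_prior_scale, seed = seed)
  list(dataset = methylation_dataset(beta, samples), truth = truth)
}

#' Generate a two-condition expression dataset with planted differentiation
#' genes
#'
#' Planted `diff_assoc` genes get a `+shift` log2 shift in the `neuron`
#' condition.  Age is confounded with condition by default (+10 years in
#' neurons) and drives a subset of genes at `age_beta` log2-units per year,
#' so covariate adjustment is genuinely exercised: an unadjusted analysis
#' sees age-driven genes as differentially expressed, an adjusted one does
#' not.  Sex is a balanced two-level factor with additive effects on its
#' own gene subset.
#'
#' @param genes Character vector: the gene universe.
#' @param diff_assoc Subset of `genes` planted as
#'   differentiation-associated.
#' @param n_per_condition Samples per condition (>= 3); default 10.
#' @param shift Log2 shift for `diff_assoc` genes in neurons; default 2.
#' @param age_effect_genes,sex_effect_genes Optional gene subsets driven by
#'   the covariates.
#' @param age_beta Log2-units per year of age for age-driven genes;
#'   default 0.15.
#' @param sex_beta Additive log2 effect of male sex; default 1.
#' @param age_confounded Add +10 years to neuron-condition ages;
#'   default TRUE.
#' @param noise_sd Residual log2 SD; default 0.5.
#' @param is_counts Generate a mean-variance trend (higher noise at low
#'   expression) and mark the dataset for precision weighting.
#' @param conditions Length-2 character condition labels (reference first);
#'   the shift and the age confound apply to the second; default
#'   `c("progenitor", "neuron")`.
#' @param seed Integer seed.
#' @return List with `dataset` ([expression_dataset()]) and `truth`.
#' @export
generate_expression <- function(genes, diff_assoc,
                                n_per_condition = 10, shift = 2,
                                age_effect_genes = NULL, age_beta = 0.15,
                                sex_effect_genes = NULL, sex_beta = 1,
                                age_confounded = TRUE, noise_sd = 0.5,
                                is_counts = FALSE,
                                conditions = c("progenitor", "neuron"),
                                seed = 1) {
  stopifnot(n_per_condition >= 3, all(diff_assoc %in% genes),
            length(conditions) == 2L)
  set_generator_seed(seed)
  G <- length(genes)
  n <- 2L * n_per_condition
  condition <- rep(conditions, each = n_per_condition)
  age <- rnorm(n, 50, 8) + if (age_confounded)
    10 * (condition == conditions[2L]) else 0
  sex <- sample(c("F", "M"), n, replace = TRUE)
  base <- rnorm(G, 6, 2)
  mu <- matrix(base, nrow = G, ncol = n)
  mu[genes %in% diff_assoc, condition == conditions[2L]] <-
    mu[genes %in% diff_assoc, condition == conditions[2L]] + shift
  if (length(age_effect_genes) > 0) {
    ia <- genes %in% age_effect_genes
    mu[ia, ] <- mu[ia, ] + rep(age_beta * (age - 50), each = sum(ia))
  }
  if (length(sex_effect_genes) > 0) {
    is_ <- genes %in% sex_effect_genes
    mu[is_, ] <- mu[is_, ] + rep(sex_beta * (sex == "M"), each = sum(is_))
  }
  sd_g <- if (is_counts) noise_sd * (1 + 3 * 2^(-base / 2)) else
    rep(noise_sd, G)
  y <- mu + matrix(rnorm(G * n, 0, sd_g), nrow = G)
  rownames(y) <- genes
  ids <- sprintf("E%03d", seq_len(n))
  colnames(y) <- ids
  samples <- data.frame(sample_id = ids, condition = condition,
                        age = age, sex = sex, stringsAsFactors = FALSE)
  truth <- list(diff_assoc = sort(diff_assoc),
                age_effect_genes = sort(as.character(age_effect_genes)),
                sex_effect_genes = sort(as.character(sex_effect_genes)),
                shift = shift, age_beta = age_beta, sex_beta = sex_beta,
                noise_sd = noise_sd, seed = seed)
  list(dataset = expression_dataset(y, samples, is_counts = is_counts),
       truth = truth)
}

#' Write planted truth to a JSON file
#' @param truth Truth list from a generator.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
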