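---
title: "Methods: detecting the neural hypermethylation fingerprint"
author: "neuromethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting the neural hypermethylation fingerprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromethyl)
```

# The problem and the model

Solid tumors accumulate promoter DNA hypermethylation, and a
disproportionate share of the affected genes have nervous-system
functions — a *neural hypermethylation fingerprint* interpretable as
cancer cells silencing neural differentiation programs to preserve a
stem-like state.  `neuromethyl` implements the complete analytical chain
needed to detect and scrutinise this fingerprint from array-style
methylation data, together with a synthetic-data generator that plants
known truth so that every stage can be validated by recovery.

The pipeline has five statistical components, described below:
probe-level differential methylation, gene aggregation, neural
classification, enrichment testing, and the confounder/overlap analyses.

## Differential methylation on the M scale

Testing is performed on M-values, $M = \log_2\frac{\beta + \epsilon}
{1 - \beta + \epsilon}$, because beta fractions are heteroscedastic near
their boundaries while M-values are approximately Gaussian with
probe-specific variances.  The offset $\epsilon$ (default $10^{-6}$,
configurable) guards exact 0/1 values; it was left small so that the
transform is effectively the canonical logit on the interior of the unit
interval.

Per probe, the tumor-minus-normal mean difference of M is computed
complete-case (probes with fewer than two non-missing samples in either
group are excluded and counted).  Pooled residual variances $s_g^2$ on
$d_g$ degrees of freedom are then moderated with the standard
empirical-Bayes construction: hyperparameters $(d_0, s_0^2)$ are obtained
by matching the mean and variance of $\log s_g^2$ to its theoretical
scaled-F distribution, inverting the trigamma function by Newton
iteration, and each probe's variance is shrunk to the posterior
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$.  The moderated
$t = \hat\beta_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$ is referred to a t
distribution on $d_0 + d_g$ degrees of freedom.

Numerical conventions for the edges of the estimator:

* If the observed $\log s^2$ dispersion is no larger than expected under
  equal true variances, $d_0 = \infty$ and every posterior variance is
  set to the geometric mean of the observed $s_g^2$ — equal to the
  common value when all variances are identical, in which case the
  statistic coincides with the ordinary t.
* With fewer than 10 probes the moment estimator is unreliable, so the
  function warns and falls back to the ordinary t ($d_0 = 0$).
* $d_0$ can be forced; $d_0 = 0$ reproduces the pooled two-sample t
  exactly, which is how the engine is validated against an independent
  textbook oracle (and against the limma implementation, used in the test
  suite purely as a cross-check).
* Zero sample variances are admissible: they are excluded from the
  log-moment estimation but shrink to a positive posterior whenever
  $d_0 > 0$.

## Calls and gene aggregation

A probe is called hypermethylated when **all three** of: BH-adjusted
$p < 0.05$, $\mathrm{logFC}(M) > 1$, and mean beta difference $> 0.1$;
hypomethylated with the mirrored cut-offs.  All inequalities are strict
(boundary values are not significant), the contrast is oriented
tumor − normal throughout, and the beta difference is computed on the raw
beta scale (a biological-effect filter), not back-transformed from M.

A gene is hypermethylated iff at least one of its promoter probes —
region labels TSS200, TSS1500 or 1stExon, optionally restricted to
CpG-island probes — is called hyper.  Genes with probes in both
directions belong to both sets; the background for every enrichment
statistic is the set of genes with at least one *tested* promoter probe.
Genomic coordinates are deliberately not modelled: probe-to-gene
assignment comes solely from the annotation table, and region labels are
resolved per (probe, gene) pair, so a probe that is promoter for one gene
and gene-body for another counts only toward the former.

## Neural classification

A GO term is neural-related iff its lower-cased name contains one of 13
substrings (neuro, neuron, neuronal, neural, nervous, axon, dendritic,
synaptic, synapse, learning, memory, brain, hippocampus); a gene is
neural-related iff annotated to at least one such term.  Matching is
plain substring, not word-boundary: that is required for "neuro" to match
"neurotransmitter", and has the known side effect that immune "dendritic
cell" terms match "dendritic".  Matching applies to term names only, with
no ancestor propagation over the GO graph; the pattern list is
configurable but defaults are frozen.  Note the patterns are partly
redundant under substring semantics ("neuro" subsumes "neuron" and
"neuronal"); the flag set is invariant to removing the subsumed patterns,
which is asserted by a regression test.

## Enrichment statistics

The headline test conditions on the data actually tested: a 2×2 table of
(hyper set vs rest of tested background) × (neural vs not), Pearson
chi-squared with 1 df and no continuity correction.  When any expected
cell is below 1 the exact (Fisher) p-value is reported and flagged.  A
1-df goodness-of-fit variant against a fixed background fraction is
available as an option, since "compared to the expected amount on the
array" is ambiguous between the two constructions; the 2×2 form is the
default because it propagates the uncertainty of the background estimate.
Depletion ("derichment") is reported as the sign of observed minus
expected share; the test itself is two-sided.  P-values are BH-adjusted
across cancer types within each direction.

Supporting statistics are deliberately plain: a paired two-tailed t on
per-cancer percentages (hyper vs hypo), upper-tail hypergeometric ORA
over GMT gene-set collections with BH across sets, two-proportion
chi-squared comparisons, and cross-product odds ratios with the Haldane
+0.5 correction applied only when a cell is zero (a zero row or column is
an error, not a number).

## Confounder analyses

*Tumor purity.*  Per tumor sample, mean promoter-probe beta is computed
for four gene groups (neural/non-neural × HMG/non-DM) and regressed on
the sample's consensus purity estimate with Huber M-estimation (tuning
constant 1.345, MAD scale, IRLS; coefficient tolerance $10^{-8}$).  The
iteration cap is 200: with the tight tolerance, IRLS on realistic noise
routinely needs more than a few dozen sweeps, and a cap that routinely
truncates would silently change the estimator.  Perfect linear fits are
short-circuited to OLS (the MAD scale is zero there and IRLS is
undefined; Huber equals OLS by construction).  If hypermethylation
originates in the cancer cells, HMG-group slopes are positive — purer
tumors look more hypermethylated — while non-DM groups stay flat, which
is exactly the planted behaviour the generator reproduces and the tests
assert.

*Methylation degree.*  Per-gene mean tumor beta, neural vs non-neural
HMGs, compared with a two-sided Wilcoxon rank-sum test — a distributional
claim, so a rank test is the conservative choice (the package's own; no
specific test is canonical here).  Single-gene sets are flagged as
degenerate rather than rejected.

*Bivalency.*  Three cross-tables: hypermethylation × bivalency overall,
and hypermethylation × neural status within bivalent and non-bivalent
strata, each with chi-squared and odds ratio.  Marginals always sum to
the stratum size (asserted in tests); empty strata are skipped with a
warning.

*Hallmarks.*  Per hallmark gene set, the 2×2 (HMG vs non-HMG) × (neural
vs not) restricted to the set's intersection with the tested background,
BH across hallmarks.

## Differentiation expression stage

The expression stage shares the moderation engine with the methylation
stage: a per-gene linear model with condition plus optional age (linear)
and sex (two-level factor) covariates, empirical-Bayes moderation of
residual variances, and the UR/DR/nonDE trichotomy at logFC > 1 and BH
p < 0.05 (strict).  With precision weights enabled (the default for
log-scaled counts), a lowess trend (span 0.5) of the square-root residual
standard deviation on mean log-expression is evaluated at the fitted
values and each observation is weighted by the predicted
$\mathrm{sd}^{-4}$ — absorbing the count-driven mean-variance
relationship before moderation.  Without covariates and weights, the
stage reduces *exactly* to the two-group moderated t, which is asserted
to $10^{-10}$ in the tests.  Differentiation-associated genes are the UR
genes of the neuron-vs-progenitor contrast, and the overlap module
reports their hypermethylated share (with odds ratio and chi-squared
against the rest of the universe) and the DR/UR/nonDE composition of
hypermethylated neural genes split by differentiation association.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions of the test suite.

*Universe.*  Each gene receives `probes_per_gene` promoter probes (labels
uniform over TSS200/TSS1500/1stExon) and a gene-body probe with
probability 0.3; CpG-island flags are independent Bernoulli(0.7).
Exactly `round(n_genes * neural_fraction)` genes are neural, annotated to
GO names drawn from a vocabulary that contains at least one default
pattern; non-neural genes draw only from a vocabulary containing none
(checked at generation), so classifier correctness is decidable by
construction.

*Methylation.*  Probe baselines are $m_0 \sim N(-1, 1.5^2)$ on the M
scale — promoter probes skew unmethylated, and this range keeps the
beta-scale effect of a planted M-shift of 3 above the 0.1 call threshold
for essentially all probes.  Probe noise variances follow a scaled
inverse-chi-squared prior with $d_0 = 4$, $s_0^2 = 0.04$, giving the
empirical-Bayes estimator genuine heterogeneity to shrink.  Planted hyper
genes have *all* their promoter probes shifted by $+\,$`effect_m`
(default 3) in the pure tumor signal; the M-to-beta map is the logistic,
so all beta values are strictly inside (0, 1).  Tumor purity, when
enabled, is per-sample Uniform(0.2, 0.9) and mixing happens on the beta
scale — a cell-fraction mixture of methylation proportions, which is the
biology — not on the M scale.  The planted hyper set contains exactly
`round(n_hyper * neural_enrichment)` neural genes (an unreachable target
raises an error stating the attainable bound), or is sampled irrespective
of neural status when the enrichment is `NULL` (optionally with per-gene
odds weights, used to plant bivalency effects).

*Expression.*  Differentiation-associated genes get a +2 log2 shift in
the neuron condition (noise sd 0.5, n = 10 + 10 by default: a planted
effect of 4 residual sds, so near-complete recovery is expected by
design).  Age is confounded with condition (+10 years in neurons) and
drives its own gene subset at 0.15 log2-units/year, so covariate
adjustment is genuinely exercised rather than decorative; sex is a
balanced factor with additive effects.  In counts mode the noise sd
decreases with baseline expression, producing the mean-variance trend the
precision weights are built to absorb.

All randomness is Mersenne-Twister with inversion normals, seeded at
generator entry; equal seeds give byte-identical objects, and the RNG
identity is recorded in every run's metadata.

*What the generator does not emulate* — and hence what passing tests do
not certify about real data: probe-type (Infinium I/II) chemistry and
normalization, batch effects, copy-number interference, correlated probes
within a CpG island, realistic GO topology (terms here are flat labels),
and cell-type composition beyond the single purity mixture.  Recovery
results on synthetic data bound the pipeline's correctness, not the
biology's cooperativeness.

# Problem sizes and calibration checks

The validation suite runs, among others: the moderated-t engine against a
pooled-t oracle (50 probes, agreement to $10^{-10}$ with $d_0$ forced to
0) and a hyperparameter-recovery simulation (50 seeds × 1000 probes,
d = 10, true $d_0 = 4$: median estimate within ±1, $s_0^2$ within 10%);
BH against a quadratic-time reference on 1000 random vectors; the full
enrichment pipeline on a 20,000-gene universe (18.6% neural background,
2,600 planted hyper genes at 38.5% neural share, effect 3, 30 + 30
samples), recovering the planted share within 3 percentage points at
FDR $< 10^{-6}$; a 200-seed null calibration (hyper genes planted
irrespective of neural status on a 4,000-gene universe, 400 planted
genes — sized so expected cell counts ≈ 75 keep the chi-squared p
effectively continuous) tested for uniformity by Kolmogorov–Smirnov at
$\alpha = 0.01$; exact hypergeometric enumeration for universes up to 30
genes; purity-slope sign recovery; differentiation-stage sensitivity
≥ 95% at shift 2; and byte-identical demo reruns.  These sizes were
chosen as the smallest at which the binomial/continuity arguments above
hold cleanly.

# Known limitations

* Substring matching over-captures non-neural terms containing pattern
  words (e.g. immune "dendritic cell" biology); this is inherent to the
  stated procedure and documented rather than patched.
* Raw GO annotation only: no ancestor closure, so real-data neural
  fractions depend on the annotation release used.
* The 2×2-vs-goodness-of-fit choice for the background comparison changes
  p-values slightly at small backgrounds; both are exposed.
* No probe-type normalization, paired designs, or cell-type
  deconvolution; purity is an input covariate, never estimated.
* The expression stage consumes any log-scale matrix; count-level
  (negative binomial) modelling is out of scope.
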