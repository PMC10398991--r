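# neuromethyl

Promoter hypermethylation in solid tumors preferentially hits genes with
functions in the nervous system.  `neuromethyl` is an R package for
detecting and characterising this *neural hypermethylation fingerprint* in
Illumina 450k-style DNA methylation data: it calls promoter hyper- and
hypomethylated genes from beta-value matrices, flags neural-related genes
from GO annotation, quantifies the enrichment of neural-related genes among
hypermethylated genes against the array background, and runs the
accompanying confounder and expression-overlap analyses.  It is aimed at
cancer epigenomics analysts who have probe-level beta matrices, sample
sheets and annotation tables and want the whole pipeline — or any single
stage — as tested, scriptable functions.

A seeded synthetic-data generator with planted ground truth makes every
stage testable end to end without any external data.

## The statistics at the core

**Probe-level differential methylation.**  Beta-values (methylation
fractions β ∈ [0,1]) are transformed to M-values,
M = log2((β + ε)/(1 − β + ε)), and each probe is tested for a
tumor-vs-normal difference with an empirical-Bayes moderated t-statistic:
per-probe pooled variances s² on d degrees of freedom are shrunk toward a
prior (d₀, s₀²), estimated by matching the moments of log s² to its
theoretical scaled-F distribution, giving

    s̃² = (d₀·s₀² + d·s²) / (d₀ + d),   t = (M̄_tumor − M̄_normal) / (s̃·√(1/n₁+1/n₂))

on d₀ + d degrees of freedom.  A probe is called **hyper** when the
BH-adjusted p < 0.05, logFC(M) > 1 and the mean beta difference > 0.1
(all strict; hypo mirrored), and a gene is a hypermethylated gene (HMG)
when ≥ 1 of its promoter probes (TSS200/TSS1500/1stExon) is hyper.

**Neural classification.**  A gene is *neural-related* iff it is annotated
to ≥ 1 GO term whose name contains (case-insensitive substring) one of 13
patterns: neuro, neuron, neuronal, neural, nervous, axon, dendritic,
synaptic, synapse, learning, memory, brain, hippocampus.

**Enrichment.**  The neural share of the HMG set is tested against the
tested-gene array background with a Pearson 2×2 chi-squared test (1 df, no
continuity correction; exact fallback for tiny expected counts), BH-adjusted
across cancer types.  Supporting statistics: paired t across cancer types
(hyper vs hypo percentages), hypergeometric over-representation for
arbitrary GMT gene sets, two-proportion comparisons and odds ratios
(Haldane-corrected at zero cells).

**Confounders.**  Tumor purity (Huber robust regression of per-sample mean
methylation on the consensus purity estimate, per gene group), methylation
degree (Wilcoxon rank-sum, neural vs non-neural HMGs), chromatin bivalency
(stratified 2×2 cross-tables) and the ten cancer hallmarks (per-set 2×2
with BH).

**Differentiation overlap.**  A moderated-t differential-expression stage
(age/sex-adjusted, optional voom-style precision weights) identifies
neural differentiation-associated genes (logFC > 1, BH p < 0.05 in a
neuron-vs-progenitor contrast), and overlap statistics link them to
promoter hypermethylation and downregulation in cancer.

## Worked example

```r
library(neuromethyl)

res <- run_demo("demo_run", seed = 1)   # ~2 s, fully synthetic
res$enrichment[, c("cancer_type", "direction", "n_genes", "pct_neural",
                   "background_pct", "fdr")]
#>   cancer_type direction n_genes pct_neural background_pct          fdr
#> 1       SIM-A     hyper     259   38.61004           18.6 1.457260e-18
#> 2       SIM-A      hypo     142   12.67606           18.6 1.196027e-01
#> 3       SIM-B     hyper     200   30.00000           18.6 1.256941e-05
#> 4       SIM-B      hypo     119   15.12605           18.6 3.152502e-01
```

The demo plants hypermethylation in 260 genes of a 2000-gene universe for
"SIM-A", with 38.5% of the planted genes neural-related against an 18.6%
array background.  The pipeline recovers 259 of the 260 genes and estimates
the neural share at 38.6% — a strong enrichment (FDR ≈ 1e−18), while
hypomethylated genes sit at/below background.  The purity analysis on the
same run shows why this is not a tumor-purity artifact: per-sample mean
methylation of hypermethylated groups rises steeply with purity while
non-differentially-methylated groups stay flat,

```r
res$purity
#>              group         slope  intercept ...
#> 1       neural_hmg  0.3915218330 0.3574188
#> 2     neural_nondm -0.0019743069 0.3631148
#> 3   non_neural_hmg  0.3894561220 0.3657621
#> 4 non_neural_nondm -0.0006926685 0.3558078
```

i.e. more tumor cells mean more observed hypermethylation — for neural and
non-neural genes alike — so the signal originates in the cancer cells.
Every output is also written to `demo_run/` as TSV, with `truth.json`
(planted truth), `run_metadata.json` (thresholds, pattern list, seed, RNG)
and a `MANIFEST`.

A thin CLI wrapper over the same functions ships at
`inst/cli/neuromethyl.R` (`demo`, `diffmeth`, `annotate`, `export-ipa`
subcommands).

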