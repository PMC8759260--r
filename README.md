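# clockdissect

Epigenetic clocks predict a person's chronological age from the DNA
methylation (beta values) of a fixed CpG set, usually via a penalized
linear model

```
age = intercept + sum_i w_i * beta_i        (optionally transformed)
```

yet *why* they work has long been unclear. `clockdissect` implements a
functional-genomics dissection of blood-based clocks built around one
hypothesis: clock CpGs read out the age-related shift from naive towards
activated T and NK cells. The package is aimed at methylation
researchers who want to probe what a clock measures, and at method
developers who need a fully specified synthetic testbed.

It provides, end to end:

- **Clock application** — linear CpG clocks with the identity,
  piecewise log-linear (multi-tissue style), and per-sample
  standardization (blood/saliva style) transforms; missing-CpG
  accounting and imputation; error summaries (MAE, Pearson r),
  cross-clock error concordance, and directed overlap of extreme
  (≥ 10 y) deviations.
- **Clock redundancy** — shared-CpG overlap matrices, correlated-proxy
  fractions at |r| ≥ 0.5/0.7/0.9, and genomic-feature enrichment
  (CpG islands, 2 kb shores, histone peaks, chromatin states) with
  Fisher exact tests and a Bonferroni family of 9.
- **The trans-association core** — for every clock CpG, OLS of each
  gene's rank-inverse-normal log2-CPM expression on the CpG's beta plus
  cohort, age, sex, cell percentages, technical batches, and 5 latent
  factors; per-CpG empirical-null correction of the t statistics
  (3-component Gaussian mixture); cis (≤ 100 kb) and trans (> 5 Mb or
  different chromosome) domains Bonferroni-corrected separately; a core
  set of genes associated with ≥ 5 % of any clock's CpGs and CpGs
  associated with ≥ 10 trans genes; a sample-label permutation null.
- **Cell-type interpretation** — 2-way hierarchical clustering
  (Euclidean) of the core t matrix, min-max normalized sorted-cell
  profiles, Welch tests of naive versus activated compartments, and
  paired naive-vs-activated clock-age differences per donor.
- **Genetics cross-check** — intersection of trans pairs with
  cis-meQTL / trans-eQTL catalogs (and the mirrored direction).
- **A synthetic whole-blood cohort generator** with full ground truth:
  age-dependent naive/activated T and NK proportions (logistic in age),
  nine-compartment composition with the neutrophil–lymphocyte
  anticorrelation, mixture methylomes, negative-binomial counts whose
  marker genes follow the matching compartment fraction, batch shifts,
  latent confounders, technical replicates, and optional QTL effects.

## Worked example

```r
library(clockdissect)

run <- run_pipeline(pipeline_config(seed = 1), run_permutation = TRUE)
run
#> <pipeline_run> seed 1, n = 500
#>   clock MAE (y): true 3.14, refit 2.72, horvath_like 2.74, subset_a 2.91, subset_b 2.79
#>   significant: 1 cis, 7617 trans pairs; core set 100 genes x 120 CpGs (ARI vs truth 1.00)
#>   median per-CpG inflation 1.15; permutation p 0.009901
```

Reading the output: the five synthetic clocks predict age with a 2.7–3.1
year mean absolute error (the published blood clocks span 2.7–4.5 y on
real cohorts). The association stage finds essentially no cis signal but
thousands of Bonferroni-significant trans pairs; the core set recovers
exactly the 100 planted marker genes and 120 cluster CpGs, and the 2-way
clustering of the core t matrix matches the planted naive/activated
cluster labels perfectly (adjusted Rand index 1.00). All 100 methylation
sample-label permutations find zero significant trans associations
(empirical p = 1/101 ≈ 0.0099), confirming the signal is carried by the
sample linkage, not by the analysis machinery.

Individual stages are plain functions:

```r
sim  <- simulate_cohort(simulation_config(seed = 1))
expr <- preprocess_expression(sim$cohort$counts, sim$cohort$gene_coords)
des  <- association_design(sim$cohort$covariates)
res  <- run_association(sim$cohort$beta, expr, des, sim$cohort$cpg_coords)
core <- select_core_set(res, list(clock = names(sim$truth$true_clock$coefficients)))
```

A thin command-line wrapper lives in `inst/cli/clockdissect.R`
(`simulate`, `predict`, `run-all`).

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — simulating the default cohort, applying the clocks, running
the full association/clustering/permutation pipeline — and writes a JSON
summary file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
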