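---
title: "Dissecting blood epigenetic clocks with clockdissect"
author: "clockdissect maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting blood epigenetic clocks with clockdissect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Blood epigenetic clocks are linear predictors of chronological age from
the methylation (beta values, in [0, 1]) of a few dozen to a few hundred
CpGs. They predict age remarkably well across cohorts, but the model
coefficients say nothing about *what* biological quantity they read out.
`clockdissect` implements one dissection strategy: associate each clock
CpG's methylation with genome-wide gene expression, separate local (cis)
from distal (trans) associations, and interpret the recurring trans gene
sets through sorted immune-cell reference profiles. The working model is
that clock CpGs largely track the age-related replacement of naive T and
NK cells by activated/memory phenotypes, so that a clock is - at least
in blood - substantially a cell-ratio meter.

This vignette documents the package's models and procedures, the
synthetic-data world used to test them, the numerical choices, and the
design decisions made where the design was genuinely open. Every
quantitative claim here is computed by the test suite or the acceptance
script; none is asserted from memory.

## Clock application

A `clock_model` carries an intercept, a named coefficient vector, and a
transform kind:

- `identity`: the linear score is the age in years.
- `horvath`: the score lives on a piecewise log-linear transformed-age
  scale, `f(age) = log(age + 1) - log(A + 1)` below the maturity
  constant `A` (default 20 years, exposed as a parameter) and
  `(age - A) / (A + 1)` above it; predictions are mapped back through
  the exact inverse.
- `zhang`: beta values are standardized per *sample* to mean 0, SD 1
  across **all** supplied CpGs (population SD, divisor n) before the
  linear score; this makes predictions invariant to per-sample shifts
  of the whole methylome.

Missing clock CpGs are a fact of life (probes fail QC). `predict_age()`
imputes an absent value from the clock's stored training means when the
coefficient file carries them, otherwise from the cohort mean of that
CpG, and errors when neither exists or when more than 20 % (tunable) of
the clock is absent. The per-sample count of imputed CpGs is always
reported: degradation is accounted, never silent.

Error summaries report the MAE and Pearson r (flagged `NA`, not silently
propagated, for constant inputs). Cross-clock redundancy is quantified
three ways: shared-CpG counts (percentages relative to the smaller clock
of a pair), the fraction of a clock's CpGs with at least one methylation
proxy at |r| >= 0.5 / 0.7 / 0.9 in another clock (a CpG shared by both
clocks counts as a perfect proxy; within one clock the self-correlation
is excluded), and the directed overlap of extreme age deviations
(>= 10 years): the percentage of one clock's extreme samples that are
extreme under another clock, with `NaN` flagging an empty extreme set.

## The association model

For clock CpG *y* and gene *x* the package fits, by OLS,

```
expression_x = beta_y + cohort + age + sex + basophil% + eosinophil% +
               lymphocyte% + monocyte% + plate + array position +
               flowcell + LF1..LF5 + error
```

Expression enters as rank-inverse-normal transformed log2-CPM
(`log2((count + 0.5) / (lib + 1) * 1e6)`; the offset avoids log 0 and is
a documented choice, as is the RIN convention `qnorm((rank - 0.5)/n)`
with average ranks for ties) over protein-coding genes with median raw
count strictly above 1. Neutrophil percentage is excluded by
construction: it is almost perfectly anticorrelated with lymphocyte
percentage and would make the design collinear. Only autosomal CpGs and
genes are analyzed. All genes for one CpG share a single design
factorization; the full CpG x gene t matrix is computed by
residualizing both data blocks on the design once.

**Latent factors.** Five factors are estimated as the top left singular
vectors of the expression residual after the known covariates, with each
factor's sign fixed so its largest-magnitude loading is positive. A
plain residual SVD, however, will absorb *any* strong expression axis -
including the axis shared with methylation, i.e. the signal under
study; dedicated confounder-adjustment methods are built to avoid
exactly this. `estimate_latent_factors()` therefore accepts `protect`
directions that the factors are kept orthogonal to. Two caveats
discovered during development are worth recording. First, protection is
only needed when the signal axis would otherwise rank among the top-k
expression axes; in realistic data (ours included, after the generator
below was finished) the unmodelled confounders dominate and protection
is unnecessary, so `run_association(k_protect = 0)` is the default.
Second, protecting with the *same-run* methylation PCs makes the factors
a function of both data blocks, and conditioning on such a factor
induces collider-style partial correlations under sample-label
permutation - permutation tests are only clean when factors are a
function of expression alone. Use protection deliberately and interpret
permutations with care when it is on.

**Empirical-null correction.** Residual confounding inflates or biases
a CpG's whole row of t statistics. Following the empirical-null idea,
each row's z-converted statistics are modelled as a 3-component Gaussian
mixture fitted by EM (central null component initialized at the
median/MAD, up to 500 iterations, relative tolerance 1e-8, median/MAD
fallback when the EM does not converge to a null weight of at least
0.5). Two light regularizations keep the fit honest at both extremes: a
Dirichlet pseudo-count on the null weight (the flanks must not nibble a
pure null's tails) and flank components constrained to be at least as
wide as, and at least 2.5 null SDs away from, the null (the flanks model
diffuse signal, never the null's shoulders). Corrected statistics are
`z' = (z - bias) / inflation`. Following the genomic-control convention
an inflation estimate below 1 is reported but never used to scale
statistics *up*: underdispersion - common for short, correlated rows -
is not converted into significance. The whole correction is vectorized
across CpGs, so an association run on the default synthetic cohort takes
about two seconds.

**Domains and multiplicity.** A pair is cis when the CpG lies within
100 kb of the gene interval (distance 0 inside the gene, else the gap to
the nearest edge - the gene body, not the TSS, since only a "distance"
is specified by the underlying method; the windows are parameters),
trans when more than 5 Mb away or on a different chromosome, excluded
otherwise; the three classes partition every pair. Bonferroni correction
runs separately within the cis and the trans domain, over the tested
pair count of that domain. Boundary conventions: a gap of exactly
100 kb is cis; exactly 5 Mb is excluded; 5 Mb + 1 bp is trans.

**Core set and permutation null.** A gene enters the core set when it is
significantly associated with at least `ceiling(0.05 * clock size)` CpGs
of any single clock (for published clock sizes 71/353/391/514 these
thresholds are 4/18/20/26); a CpG enters with >= 10 significant trans
genes. The permutation test shuffles the methylation sample identifiers
only - expression stays linked to its covariates - and reruns the
identical trans analysis, reporting the count of Bonferroni-significant
trans pairs per permutation and the add-one-smoothed empirical p value.

## Cell-type interpretation

The core CpG x gene matrix of corrected t statistics (non-significant
entries set to 0, matching the convention that absent signal is blank)
is clustered hierarchically on Euclidean distance, rows and columns cut
at k = 2. The linkage is complete by default - the underlying method
states only the distance - with ward/average exposed as alternatives.
Sorted-cell profiles are min-max normalized per feature across cell
types (`(x - min) / (max - min)`; constant profiles are emitted as
missing), and cluster membership is tested between naive and activated
compartments with Welch two-sample t tests computed in closed form (so
perfectly separated near-constant groups give t = Inf, p = 0 rather
than an error). Clock ages predicted on paired sorted-cell methylomes
give per-donor activated-minus-naive differences, summarized as the
median difference with a paired t test per clock and lineage.

The QTL cross-check intersects observed trans pairs with cis-meQTL and
trans-eQTL catalogs by SNP identity (string match, mirroring a catalog
lookup): a trans association could be genetic only if one SNP is
simultaneously a cis-QTL for one member and a trans-QTL for the other.
Catalogs are taken as already thresholded.

## The synthetic world

The generator emulates a whole-blood cohort in which both clock-CpG
methylation and marker-gene expression are driven by latent
naive/activated cell proportions. It is a stated world: the defaults
below were chosen once, for clear signal at desk scale (n = 500 versus
the thousands of samples of real cohorts), and the test thresholds were
never adjusted to meet them.

- **Composition.** Nine compartments (naive/activated T, canonical/
  adaptive NK, B, monocytes, neutrophils, eosinophils, basophils). The
  granulocyte/lymphoid balance is drawn per sample, which makes
  neutrophil and lymphocyte percentages strongly anticorrelated
  (r < -0.9, as observed in differentials); the activated share of T
  cells is logistic in age (slope 0.045 logit/year centred at 50 years,
  NK at 0.8x) with a per-person logit SD of 0.5.
- **Methylation.** Cluster-1 CpGs are high (0.85) in naive and low
  (0.25) in activated compartments, cluster-2 reversed, other
  compartments intermediate (0.55), all with small per-CpG jitter;
  neutral CpGs are identical across compartments. Observed betas are
  the fraction-weighted mixture plus batch shifts and N(0, 0.01) array
  noise, truncated to [0, 1].
- **Age.** A latent target age drives the activation trend; the *true
  clock* is the naive-to-activated methylation contrast over the
  cluster CpGs, linearly calibrated against the target; recorded
  chronological age is the clock's noise-free prediction plus a
  N(0, 4 y) deviation. Two consequences are deliberate. With every
  noise SD at zero, age is exactly linear in the betas, so the true
  clock reproduces it to machine precision - the strongest possible
  oracle for the clock engine. At the defaults, the deviation keeps a
  naive/activated signal in the methylome that chronological age does
  not explain, which is precisely the proposed interpretation of
  age-prediction deviations, and it is what makes the trans
  associations detectable *after* adjusting for age. (An earlier
  design that emitted age as the exact clock score made age a perfect
  composition proxy and silently destroyed the trans signal - a useful
  cautionary tale for simulation design.)
- **Expression.** Marker genes follow an affine function of the
  matching compartment fraction (12 natural-log units per unit
  fraction, centred so baselines stay put; roughly a 3x expression
  change per 10-point shift in the naive share). Marker genes are made
  less abundant than the bulk (as subset-restricted transcripts are)
  with a tight abundance spread, which also keeps them a small share
  of the library: otherwise CPM normalization couples *every* gene to
  the marker swings through the denominator - negligible in a
  14370-gene transcriptome, dominant in a 300-gene one. Counts are
  negative-binomial (dispersion 0.08) around per-sample log-normal
  library sizes. Four latent expression-only confounders load on every
  gene; together with the compositional CPM axis they are exactly the
  five structured axes the five latent factors absorb.
- **Extras.** Technical batches shift both modalities per level;
  technical replicates re-draw measurement noise only; optional QTL
  effects add Hardy-Weinberg genotypes with additive per-allele shifts
  on one CpG (cis-meQTL) and one gene's log expression (trans-eQTL).

What a green test does and does not establish: the generator produces
clean, dense, low-dimensional signal; real methylomes have hundreds of
thousands of CpGs, milder effect sizes, LD-like local correlation, cell
types beyond nine compartments, and array artefacts none of which are
emulated (no IDAT-level simulation, no realistic LD). Green tests
establish correctness of the machinery and recoverability of the stated
world, not field performance.

## Numerical choices and degenerate inputs

- t-to-z conversion uses log-space tail probabilities, stable for
  |t| far beyond 8.
- OLS is computed through one QR per design; rank deficiency is an
  error that names the collinear columns; a perfect fit is flagged
  rather than reported as a huge finite t.
- Constant beta rows make per-sample standardization impossible and
  name the offending sample; constant vectors make Pearson r undefined
  and are flagged `NA`.
- Fisher odds ratios use the Haldane-Anscombe 0.5 correction when a
  cell is zero (flagged; the p value stays exact); features annotating
  nothing (or everything) are degenerate and leave the Bonferroni
  family.
- The min-norm SVD solution is used when fitting clocks on
  rank-deficient mixture betas, spreading weight over all CpGs instead
  of piling it on pivot columns (pivoted-QR solutions amplify noise by
  orders of magnitude there).
- Seeds: one global seed; each pipeline stage derives its own stream
  via a string hash kept below 2^31.

## Known limitations

- The latent-factor estimator is a residual SVD, not the full robust
  factor machinery of dedicated confounder-adjustment packages; the
  signal-protection option approximates, and the generator's
  axis-separation property substitutes for, that robustness.
- The empirical-null EM assumes a dominant central component; rows
  where genuine signal exceeds half the statistics will fall back to
  median/MAD and under-correct.
- Cis associations are classified and tested but the generator plants
  no cis effects, so cis recovery is untested beyond the null.
- The sorted-cell module models three lineages with one naive and one
  activated phenotype each; finer taxonomies are accepted as input but
  not simulated.
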