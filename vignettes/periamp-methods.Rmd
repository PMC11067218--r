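---
title: "Methods: plasma amino-acid profiling of periampullary disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasma amino-acid profiling of periampullary disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periamp)
```

`periamp` analyzes targeted plasma amino-acid panels from cohorts in which
every patient was resected for suspected periampullary cancer and the
definite benign/malignant diagnosis comes from pathology afterwards. This
vignette documents the statistical procedures, the tunable parameters and
their defaults, the design decisions taken where the methodology is
genuinely open, and what the synthetic cohort generator does and does not
emulate.

## Batch integration by bridge samples

Concentrations arrive as two measurement batches sharing a set of bridge
samples (nine by default) measured in both. For batch $b$ and metabolite
$m$, the reference is the arithmetic mean of the raw bridge-sample
concentrations, $r_{bm}$, and every value is divided by it:
$\tilde{x}_{ibm} = x_{ibm} / r_{bm}$. If batch effects are multiplicative
per metabolite — the model assumed here, typical of run-to-run response
drift in LC-MS/MS — they cancel exactly: scaling batch 2 by any factor
$f_m > 0$ leaves $\tilde{x}$ unchanged, because $r_{2m}$ scales by the same
factor. The test suite asserts this invariance to 1e-12 relative.

Bridge samples measured twice contribute the elementwise mean of their two
normalized rows as a single data point, *before* the log transform,
matching the stated order of operations of the integration procedure. The
integrated table is then log2-transformed and mean-centered per metabolite.
Centering is pooled over all samples (benign and malignant together):
group-wise centering would erase exactly the group differences the
downstream tests are meant to detect. Values must be strictly positive;
a missing or non-positive concentration is an ingestion error, not an
imputation case — targeted panels of this kind report complete
quantifications, and silently imputing would bias the rank-based tests.

## Differential testing

Each metabolite is compared between groups with a two-sided Wilcoxon
rank-sum test on mid-ranks. Two p-value paths exist:

* **exact** — full enumeration of the permutation distribution of the rank
  sum, which handles ties exactly; used automatically when both groups have
  at most 8 observations (enumeration is $\binom{n}{n_1}$), forceable via
  `exact = TRUE`;
* **approximate** (default for cohort-sized groups) — the tie-corrected
  normal approximation with continuity correction, delegated to
  `stats::wilcox.test`.

Multiplicity over the 28-metabolite panel is controlled by
Benjamini–Hochberg; results carry star labels (`*` q ≤ 0.05 through
`****` q ≤ 0.0001) and the direction of the median difference. Fisher's
exact test (used for the cluster–disease association) defines the
two-sided p as the total probability of margin-fixed tables no more likely
than the observed one — the common convention, stated here because a
"double one tail" alternative exists — while the reported odds ratio is
the sample odds ratio $ad/bc$ ($\infty$ allowed when $bc = 0$), not the
conditional-MLE estimate. Clinical percentages round half away from zero
to one decimal with missing values excluded from the denominator,
reproducing the arithmetic style of clinical characteristics tables.

## Correlation profiles

Group-wise Spearman matrices use mid-ranks with the t-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df for the two-sided p. The
pairwise p-values are deliberately *not* multiplicity-adjusted — the
correlation display reads significance at P < 0.05 per pair — and the
differential contrast is $\Delta\rho = \rho_{malignant} - \rho_{benign}$
(the direction convention is recorded in output metadata), masked at
$|\Delta\rho| > 0.25$ by default.

## Consensus clustering

For each $k \in \{2,\dots,5\}$ the resampling loop runs 1000 iterations;
each draws $\lfloor 0.8\,n \rfloor$ samples and
$\lfloor 0.8\,p \rfloor$ metabolites without replacement, clusters the
subsample, and accumulates co-clustering and co-sampling counts; the
consensus entry of a sample pair is their ratio (0, with a warning, for
pairs never co-sampled — vanishingly rare at these settings). Iteration
randomness comes from a counter-based stream keyed by (seed, k, iteration)
and draws are made over *sorted* sample/metabolite identifiers, so results
are independent of execution order and of the row/column order of the
input.

Two design points deserve explanation:

* **Inner clustering linkage.** The final clustering of the consensus
  matrix uses Pearson correlation distance with *complete* linkage. For
  the inner, per-iteration step the package defaults to *average* linkage
  instead (configurable via `inner_linkage`). The reason is structural:
  complete linkage's outermost split tends to peel single outlying samples
  off the root, so at k = 2 the cut oscillates between "group vs group"
  and "outlier vs rest" across resamples, smearing the consensus matrix
  even when two clean clusters exist. Average linkage dilutes single-point
  effects and yields stable small-k partitions; it is also the customary
  inner setting of the consensus-clustering methodology.
* **Selecting k.** The per-k CDF of consensus values, its area (exact step
  integral over [0, 1]), and the relative area change versus k−1 (for the
  smallest k, the total area) are all computed and reported. The selected
  k, however, minimizes PAC — the proportion of pairs with consensus
  strictly between 0.1 and 0.9 — with ties to the smaller k. The
  delta-area elbow (threshold 0.1, configurable; reported as `elbow_k`)
  has a structural failure mode: splitting a genuinely stable cluster
  moves pairs from consensus 1 into the ambiguous mid-range, which
  *increases* CDF area, so even a perfectly crisp two-cluster consensus
  produces delta-area values above any small threshold at k = 3 and the
  elbow rule overshoots. PAC measures exactly the ambiguity the elbow rule
  mistakes for structure, and selects the crisp partition.

At k = 2 the cluster with the larger benign share is named the "Benign
cluster" (ties fall back to cluster size, with a warning).

## Centroid classifier

The benign centroid is the per-metabolite mean over benign samples inside
the Benign cluster; the malignant centroid over malignant samples inside
the Malignant cluster. "Overall correlation to the means" is read as
Pearson correlation across the 28 centered log2 values (Spearman is
available as an option); the continuous score is
$r_{malignant} - r_{benign}$ — the minimal monotone reduction of the two
correlations — with "malignant-like" called at score > 0 (ties are called
benign-like and logged). Classification is resubstitution: the same
samples that define the centroids are scored, which is the procedure being
mirrored; a leave-one-out variant would estimate generalization but is a
different quantity. The ROC is computed over the continuous score and the
AUC equals the Mann–Whitney probability with ties counted one half (the
test suite asserts this equivalence exactly).

## Survival analysis

Overall survival runs from surgery to death from any cause; relapse-free
survival to confirmed relapse. Patients with neoadjuvant chemotherapy,
metastasis at diagnosis, or a non-standard treatment regime are excluded
before any survival computation. Kaplan–Meier estimation and Cox fitting
delegate to the `survival` package; ties use the Breslow approximation
(configurable to Efron), confidence intervals are normal on the log-hazard
scale, and continuous metabolite covariates enter on the centered log2
analysis scale. Categorical covariates use reference-level coding with an
alphabetical reference by default (for blood type this makes A the
reference, the contrast conventionally reported as "O versus A").

Backwards elimination starts from the full model and repeatedly removes
the variable with the largest Wald p-value while that p exceeds 0.05,
refitting after each removal; a boundary p equal to 0.05 retains the
variable. Multi-coefficient terms (factors) are eliminated as whole terms
using a joint Wald test. The full trace — step, variable removed, its p —
is returned, and the trace invariants (each removal was the maximum and
exceeded 0.05; every retained variable ends at or below 0.05) are asserted
in the tests on every run. Note a statistical property of the procedure
itself: each pure-noise covariate independently retains roughly an
$\alpha = 5\%$ chance of ending significant, so with three noise
covariates the probability that *all* are eliminated is about
$0.95^3 \approx 0.86$ per dataset; per-covariate removal rates, not the
joint event, are the calibrated quantity.

## The synthetic cohort generator

The generator's defaults are the study conditions the pipeline assumes:

* 117 patients (72 malignant / 45 benign); 6 neoadjuvant and 7
  post-surgery samples (one overlapping), whose metabolite profiles are
  drawn from the benign distribution — emulating the observed migration of
  those samples toward the benign cluster; 1 metastatic-at-diagnosis and 1
  non-standard-treatment patient, so the survival filter keeps 64.
* Per-metabolite log-normal concentrations (concentrations are positive
  and the analysis is on the log2 scale, making log-normality the natural
  choice) with heterogeneous spreads — Cysteine narrowest (0.15 log2
  units), Cystathionine widest (1.10) — and plausible micromolar
  locations. Correlation is induced by a Gaussian copula on the log2
  scale with block-diagonal structure: a BCAA block (Valine, Leucine,
  Isoleucine, pairwise 0.7) and a 3-carbon amino-acid block (Alanine,
  Glycine, Serine, 0.6), both configurable.
* 16 planted group effects: 15 metabolites shifted down and Glutamic acid
  shifted up in malignant patients by `effect_size` = 1.0 log2 units (a
  two-fold median difference). The magnitude is a generator choice — the
  emulated regime is one where roughly this panel fraction reaches
  FDR ≤ 0.05 at n = 45 vs 72 and the two diagnosis groups form crisp
  consensus clusters; materially smaller shifts leave the two-cluster
  structure unrecoverable by any resampled clustering of 28 features.
* Two batches share 9 bridge samples; batch 2 is scaled per metabolite by
  configurable factors (defaults spanning 0.7–1.4).
* Survival: Weibull proportional hazards (shape 1.2; scale 27 months
  malignant, 130 benign — medians near 20 and 95 months) with uniform
  censoring windows (40–110 months malignant, 24–135 benign). The
  malignant log hazard depends on centered log2 Phenylalanine with
  coefficient −1.0, derived from the reported two-year survival contrast
  of the mean-dichotomized groups (a between-group hazard ratio near 2).
  RFS is OS minus a positive log-normal relapse-to-death lag (median 6.9
  months) whose spread is scaled to
  $\sigma_{lag} = \sigma_{OS}\sqrt{1/r^2 - 1}$ for the target RFS–OS
  correlation $r = 0.94$ (independence approximation), clipped so
  $0 < RFS \le OS$. Benign patients never relapse.
* Demographics (sex 64/117 male, age, BMI, nutrition, diabetes, blood
  type, CA19-9) follow the cohort's clinical characteristics table;
  missingness in BMI, nutrition, handling and CA19-9 is completely at
  random with configurable rates matching that table's NA counts. The
  source table prints a male share of 57.3% alongside counts implying
  64/117 = 54.7%; the generator uses the counts and the discrepancy is
  noted here rather than resolved.

What the generator does *not* emulate: real assay units or per-metabolite
absolute concentrations, LC-MS/MS peak-level error structure, informative
missingness, non-proportional hazards, or heavy-tailed outlier patients.
Consequences for interpretation: passing recovery tests shows the
pipeline's statistics behave correctly under the assumed structure
(multiplicative batch effects, log-normal noise, proportional hazards),
not that real cohorts will yield the same effect sizes or cluster
crispness.

```{r example, eval = FALSE}
report <- run_pipeline(synthetic_config(seed = 42))
print(report)
```

## Numerical choices and degenerate inputs

* Zero-variance rows have undefined Pearson correlation; their correlation
  distance is defined as 1 (warning logged). Zero-variance sample profiles
  get `NA` classifier correlations and are excluded from the ROC.
* Exact ties in the classifier score are called benign-like; a tie in
  benign share when naming clusters falls back to cluster size.
* Percentages round half away from zero; BH q-values cap at 1; |ρ| = 1
  yields p = 0 under the t-approximation.
* Column means after centering are asserted to 1e-9; batch-factor
  cancellation to 1e-12 relative.
* Counter-based iteration seeds are kept below $2^{31}$ and derived
  arithmetically from (seed, k, iteration), so consensus runs are
  reproducible and order-independent.

## Problem sizes used by the test suite

The standing suite runs the full study conditions (117 × 28, 1000
iterations, k = 2–5) across 20 seeds for cluster-recovery calibration, 20
seeds each for differential and classifier calibration (the classifier
check uses 150 consensus iterations at k = 2, where assignments are already
stable), 20 seeds of Cox recovery at n = 500 and elimination at n = 300,
and 50-seed calibration of the RFS–OS correlation — sizes chosen to make
Monte-Carlo rates stable while keeping a full run of the suite inside a
couple of minutes on one core.

## Known limitations

* The inner clusterer is pluggable only across hierarchical linkages;
  partitioning algorithms would need a new `inner_cluster`.
* No confidence intervals or effect sizes beyond median direction for the
  rank-sum comparisons; no proportionality diagnostics, time-varying
  covariates, or competing risks in the survival stage.
* The initial covariate set for backwards elimination is a configuration
  choice (`survival_covariates`); the package does not automate selection
  from univariable screens.
* Resubstitution AUC is optimistic by construction; it mirrors the
  procedure, it does not estimate out-of-sample performance.
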