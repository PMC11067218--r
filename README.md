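# periamp

Plasma amino-acid profiling of periampullary disease: an R pipeline for
targeted-metabolomics cohorts that compare patients resected for suspected
periampullary cancer with patients who turn out to have benign disease.

Distinguishing periampullary cancer from benign pancreatic disease before
surgery is hard — a relevant fraction of pancreatic resections end with a
benign diagnosis — and plasma amino acids shift systematically with
malignancy (most panel metabolites fall; Glutamic acid rises). `periamp`
implements the complete analysis such a cohort needs, end to end, plus a
synthetic cohort generator with the same statistical structure so every
stage can be exercised and tested without access to patient data.

## What the pipeline computes

Given two LC-MS/MS measurement batches that share a set of bridge samples,
and a clinical table:

1. **Bridge-sample integration.** For each batch, each metabolite is
   divided by its mean over that batch's bridge samples, so that purely
   multiplicative batch effects cancel exactly; bridge samples measured
   twice are averaged to one data point; the integrated table is
   log2-transformed and mean-centered per metabolite.
2. **Differential profiling.** Per-metabolite two-sided Wilcoxon rank-sum
   tests between benign and malignant samples, Benjamini–Hochberg FDR
   across the 28-metabolite panel, with direction-of-median and star labels
   (`*` q ≤ 0.05 … `****` q ≤ 0.0001).
3. **Correlation contrast.** Group-wise Spearman correlation matrices
   (ρ and two-sided p per metabolite pair) and their difference
   Δρ = ρ(malignant) − ρ(benign), masked at |Δρ| > 0.25.
4. **Consensus clustering.** 1000 iterations per k ∈ {2,…,5}, each
   resampling 80% of samples and 80% of metabolites without replacement and
   clustering with Pearson correlation distance; the consensus matrix M
   holds co-clustering frequencies; per-k CDF and delta-area curves are
   reported and the cluster count is selected by minimal PAC (proportion of
   ambiguous pairs). The consensus matrix itself is then clustered
   (Pearson distance, complete linkage) and, at k = 2, the clusters are
   named "Benign cluster" / "Malignant cluster" by benign share.
5. **Centroid classifier.** Per-metabolite means over the benign samples of
   the Benign cluster and the malignant samples of the Malignant cluster;
   each sample is scored by r(malignant centroid) − r(benign centroid)
   (Pearson) and called benign-like/malignant-like; ROC and AUC (equal to
   the Mann–Whitney probability) evaluate the resubstitution
   classification.
6. **Survival.** Exclusion filtering (neoadjuvant, metastatic at diagnosis,
   non-standard treatment), Kaplan–Meier estimation, RFS–OS Pearson
   correlation, mean-dichotomized Phenylalanine with a log-rank contrast,
   univariable Cox, and multivariable Cox with backwards elimination: fit
   all covariates, repeatedly drop the variable with the largest Wald p
   while that p exceeds 0.05, refit, and record the full elimination trace.

The synthetic generator (`synthetic_config()`, `generate_cohort()`)
emulates the study conditions: 117 patients (72 malignant / 45 benign), 28
metabolites with 16 planted effects (15 reduced in malignancy, Glutamic
acid elevated), six neoadjuvant and seven post-surgery samples with
benign-like profiles, two batches sharing nine bridge samples with
per-metabolite batch factors, and Weibull proportional-hazards survival
with a protective Phenylalanine effect and RFS–OS correlation near 0.94.

## Worked example

```r
library(periamp)
report <- run_pipeline(synthetic_config(seed = 42))
print(report)
```

```
Cohort analysis run report
  samples: 117 (45 benign / 72 malignant), seed 42
  metabolites at FDR <= 0.05: 16 of 28
  PCA variance explained (PC1, PC2): 38.3%, 10.9%
  consensus clustering: selected k = 2
           labels
            Benign cluster Malignant cluster
  benign                45                 0
  malignant             11                61
  cluster-disease Fisher p = 2.75e-22
  centroid classifier AUC = 0.911
  survival: n = 64 included, RFS-OS r = 0.964, log-rank p (Phe split) = 6.35e-07
  Phenylalanine univariable HR = 0.20 (95% CI 0.11-0.37, p = 3.44e-07)
  elimination retained: phenylalanine
```

Reading this: the 16 planted group effects are exactly the metabolites at
FDR ≤ 0.05; consensus clustering selects two clusters whose association
with diagnosis is overwhelming (the 11 malignant samples in the Benign
cluster are the neoadjuvant/post-surgery patients, whose profiles are
benign-like by construction); the centroid classifier separates the groups
with AUC 0.91 on resubstitution; and in the survival stage the 64 eligible
cancer patients show the planted protective Phenylalanine effect (HR per
log2 unit 0.20), which is the only covariate surviving backwards
elimination. `run_pipeline(..., outdir = "...")` additionally writes every
stage table as CSV and the summary as JSON.

The top of the differential table for the same run:

```
              metabolite statistic  p_value  q_value direction stars
           Glutamic acid       283 7.01e-14 1.96e-12        -1  ****
              Asparagine      2906 5.94e-13 8.31e-12         1  ****
                 Proline      2864 3.25e-12 2.27e-11         1  ****
```

(`direction` is the sign of median(benign) − median(malignant): positive
for metabolites reduced in cancer, negative for the elevated Glutamic
acid.)

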