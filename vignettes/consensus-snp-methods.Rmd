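---
title: "Consensus SNP selection with gradient-boosted model ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus SNP selection with gradient-boosted model ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Categorical plant phenotypes such as seed colour are often governed by a
handful of loci acting jointly, in panels where the number of genotyped
variants (millions) dwarfs the number of accessions (a few hundred).
Classical univariate GWAS tests one variant at a time against a binary
contrast, pays a heavy multiple-testing price, and cannot model
multi-class traits directly. `consensusSNP` implements the alternative
this package is built around: train many multi-class extreme
gradient-boosted (XGBoost-style) classifiers on random stratified
train/test resamples of the 0/1/2 genotype matrix, extract each model's
gain importances, and call a variant *consensus-selected* when it carries
positive gain in at least `minModels` of the replicates. The consensus
set is then expanded with collinear variants (|Pearson r| at or above
0.97 against a selected anchor, a proxy for linkage disequilibrium),
validated by retraining the same ensemble on the selected columns alone,
visualized with PCA/LDA, and benchmarked against a univariate
linear-mixed-model GWAS.

## The model and its assumptions

**Boosted classifier.** Each replicate trains a multi-class softmax
gradient-boosted tree model. Class imbalance is countered with balanced
per-sample weights `w_c = n / (k n_c)`, so every class carries the same
total weight. Missing genotype codes are passed to the tree learner as
missing values and routed by its learned default directions — no
imputation happens in the classifier path. Six hyperparameters
(max depth, min child weight, gamma, column subsample, row subsample,
learning rate) are tuned per replicate by seeded random search over
conventional ranges (`searchSpace()`), scored by mean one-vs-rest AUC
over stratified k-fold cross-validation with early stopping (35 rounds)
inside each fold. The best configuration is refit deterministically with
the mean early-stopped round count. Multi-class AUC is not uniquely
defined; the package uses one-vs-rest averaging, macro by default and
support-weighted as an option.

**Splits.** Test-set size is a count, not a fraction. A 95-sample
three-class panel with counts (45, 27, 23) and 24 held out yields test
supports (11, 7, 6) under largest-remainder allocation — the package's
`stratifiedSplit()` reproduces exactly this arithmetic, with ties in the
fractional parts broken by class-set order for determinism.

**Consensus.** "Important in a model" is operationalized as strictly
positive gain in that model's importance map. The threshold `minModels`
trades stability against sensitivity; it is a free parameter (9 of 100
at full panel scale, 3 of 25 in the package demo). Selection is
monotone in the threshold by construction.

**Collinear expansion.** Correlation is computed over pairwise-complete
non-missing codes; pairs sharing fewer than 10 called samples are
skipped, and zero-variance columns never match. The absolute value is
used by default because allele coding makes the sign arbitrary; a signed
mode is available. Additions are matched against *selected* anchors only,
never transitively, so expansion is idempotent.

**LMM GWAS baseline.** For each unordered class pair, each variant is
tested in `y = α + xβ + u + ε` with `cov(u) = σ_g² K` and K the centered
relatedness matrix `K = (1/p) Σ c_j c_jᵀ`. The kinship eigendecomposition
is done once per contrast; the variance ratio `δ = σ_e²/σ_g²` is
estimated per site by REML over a 60-point log-spaced grid on
[1e-5, 1e5] with golden-section refinement (the standard spectral-trick
formulation). Wald statistics `(β/se)²` are referred to χ²(1).
Significance uses a fixed genome-wide threshold (1e-8 by default, the
conventional genome-wide cutoff for panels with millions of tests)
rather than a recomputed α/m. Kinship is recomputed on each pair's samples by default; subsetting a
panel-wide K is equally defensible and available as an option.

**Ordination.** PCA imputes missing codes by site means, centers, and
projects by SVD; axis signs are fixed by making each axis's
largest-magnitude loading positive, so plots and tests are reproducible.
LDA maximizes between- over within-class scatter; because genotype
panels have p ≫ n, the data are first reduced to the PCA subspace of
rank ≤ n−1 and the within-class scatter receives a ridge of
`1e-6 · trace(Sw)/dim` — the solver behaviour of common LDA libraries in
the singular regime is unspecified, so the package makes its
regularization explicit and configurable. Class separation is quantified
by the mean silhouette width (singletons and degenerate zero-distance
configurations contribute 0).

**Structure confounding check.** The top 10 PC coordinates are appended
as pseudo-features and the ensemble is rerun; if any PC feature reaches
the consensus threshold, phenotype and population structure are
entangled and the run is flagged `confounded`. The check only needs
enough replicates to see whether PC features recur, so the pipeline
allows a reduced replicate count for it (8 in the demo).

**Annotation.** Variants are mapped to gene bodies and 1000-bp flanks
from GFF3 gene features. Flank boundaries are closed intervals: a SNP
exactly 1000 bp from a gene edge is a hit. Upstream/downstream labels
are strand-aware. The interval query runs through standard genomic-range
overlap machinery and is tested against an exhaustive (site, gene) scan.

## The synthetic data generator

The generator is first-class, tested code; it defines the conditions
under which the package's claims are verified.

* **Allele frequencies.** Ancestral frequencies are
  Uniform(0.1, 0.9); subpopulation frequencies follow the
  Balding–Nichols model `Beta(p(1−F)/F, (1−p)(1−F)/F)` at FST `F`
  (default 0.05, three subpopulations — mild structure typical of a
  diversity panel). Genotypes are Binomial(2, freq).
* **Linkage disequilibrium.** Within consecutive blocks of 5 sites,
  sites 2..5 copy the block template entry-wise, each entry keeping its
  own independent draw with probability 0.1. This produces strongly
  correlated columns — all the collinear-expansion stage needs — without
  simulating recombination maps.
* **Phenotype.** A multinomial-logit liability over 8 causal SNPs
  placed on distinct block templates, each pushing one of three classes
  with effect 2 per dosage unit. Intercepts default to the log target
  proportions 45:27:23 *minus* each class's expected causal score
  (`effects · E[dosage]`, `E[dosage] = freqLo + freqHi`), so realized
  class frequencies track that imbalance on average. Labels are drawn
  from the softmax (default) or taken as the argmax. Missing dosages
  count as zero in the score so missingness cannot leak label
  information.
* **Scale.** The default demo is 300 samples × 5000 sites with 2%
  missingness — a desk-scale stand-in for resequencing designs six
  orders of magnitude larger. What passing tests show is that the procedure
  recovers planted signal under structure, LD, imbalance and
  missingness; they cannot show robustness to sequencing artefacts,
  allele-calling error or real LD decay, which the generator does not
  emulate.

## Numerical and design choices

* Boosting uses the histogram tree method with 16 bins (dosages take
  only three values), a single thread, and an explicit seed, making
  every fit bit-reproducible.
* Replicate r derives its split seed as `baseSeed + r` and its tuning
  seed as `baseSeed + 100000 + r`; every stage is re-runnable in
  isolation from those seeds.
* The demo tunes 4 random-search trials per replicate over 4 CV folds
  with a 60-round budget. These are deliberately small desk-scale
  budgets: 8 strong causal signals need few boosting rounds, and a
  tight round budget keeps each model's positive-gain feature set sparse
  — at 5000 sites, consensus counting only discriminates signal from
  noise when individual models do not each touch hundreds of columns.
  The tuning machinery is identical at any budget; the non-demo defaults
  (250 trials, 500 rounds) suit full-scale panels.
* The retraining comparison reuses the full run's replicate seeds so
  full-vs-subset deltas are paired.
* `read012`/`write012` are bit-compatible with the vcftools `--012`
  dialect (`-1` missing sentinel, 0-based leading row index,
  chrom/pos site lines).
* VCF hard filters apply a criterion only when its INFO key is present;
  synthetic files need not fabricate caller annotations. The depth
  bounds apply to the record-level (site-total) DP field as emitted by
  the caller.
* Degenerate inputs: monomorphic sites are skipped in the LMM (recorded
  reason), removed by the MAF filter, and never matched by collinear
  expansion; identical samples produce zero PCA projections and a zero
  kinship matrix; silhouette conventions assign 0 to singletons and
  all-identical coordinates.

## Known limitations

* Gain importances are biased towards high-variance features; the
  consensus-over-resamples construction mitigates but does not remove
  this.
* The ensemble replicates are trained on overlapping data, so the
  model-count distribution has no closed-form null; `minModels` is a
  stability heuristic, not an error-controlled procedure. Concretely:
  when labels carry no genotype signal at all, the sites most spuriously
  correlated with the (fixed) label vector are rediscovered by most
  replicates, so the consensus set is not empty under the null at
  desk-scale site counts. Only at very large panels (millions of sites)
  are near-tied spurious correlates numerous enough that no single one
  recurs. Consensus counts must therefore be read as a ranking of
  stability, not as significance.
* The PC-feature confounding check is conservative at desk scale: the
  10 PC pseudo-features compete with only thousands of SNP columns, and
  under Balding–Nichols structure the causal SNPs are themselves
  differentiated between subpopulations, so PCs can carry genuine class
  signal even when the phenotype is SNP-driven. A `confounded` flag
  means structure and phenotype are entangled, not that the consensus
  SNPs are artefacts; the subpopulation-driven positive control is the
  sharper diagnostic.
* The LMM uses a single variance component and an intercept-only null;
  covariates beyond kinship are out of scope.
* With softmax label noise the ceiling accuracy of the demo is below 1
  by design; headline metrics from the full-scale study (AUC 0.82,
  accuracy 0.88) are properties of that cohort and are not reproduced
  at desk scale — the package's acceptance checks verify directions and
  invariants instead (subset retraining improves the ensemble, planted
  causal sites are recovered, null calibrations hold).

## Problem sizes used by the test suite

Unit tests run on panels of 40–200 samples and 20–400 sites; the
acceptance-style checks run the full default demo (300 × 5000, 25
replicates), a no-signal calibration at 150 × 2000 with 10-replicate
ensembles, and an LMM oracle comparison at n = 8 against brute-force
full-covariance likelihood maximization.
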