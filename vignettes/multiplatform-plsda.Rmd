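---
title: "Multi-platform metabolomics fusion and double cross-validated PLS-DA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-platform metabolomics fusion and double cross-validated PLS-DA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Grain metabolomics studies routinely profile the same samples on several
complementary analytical platforms — headspace GC-MS for volatiles,
¹H-NMR and direct-infusion electrospray MS (both ionisation modes) for
polar and semi-polar metabolites, GC-TOF-MS for derivatised primary
metabolites, and ICP-MS for micronutrient elements. Each platform yields
a samples × variables intensity table on its own measurement scale. Two
questions follow: do the sample groups (e.g. fragrant basmati versus
jasmine rice varieties, fresh versus stored grain) differ in their
metabolome, and *which* variables carry the difference?

`metabofuse` implements that workflow end to end: platform-specific
feature-table preprocessing, fusion of the blocks into one autoscaled
matrix, unsupervised exploration (PCA with cross-validated rank, Ward
clustering), and a double cross-validated PLS-DA with a permutation test
on the misclassification count and rank-product ranking of the
regression coefficients. Because the archetypal six-platform rice data
set was never deposited, the package carries a first-class synthetic
generator that emulates the study design with known ground truth, so
every stage is testable.

## Platform preprocessing

Each rule acts on a "raw-ish" precursor and yields a complete
`feature_block` (no missing values):

* **Mass-signal tables (GC-MS)** — cells with signal-to-noise strictly
  below 3 are replaced by a uniform draw in [2.4, 3.0) × the signal's
  noise estimate (`snr_filter_randomize()`): sub-noise cells are
  placeholders just under the detection limit, not measurements, which
  keeps them from becoming informative zeros after autoscaling. Signals
  detected (s/n ≥ 3) in 6 or fewer samples are discarded
  (`prevalence_filter()`). The replacement draws land strictly below the
  detection threshold, so the two steps commute.
* **Spectra (NMR, DI-MS)** — `bucket_spectrum()` integrates a spectrum
  into equal-width buckets (0.01 ppm for NMR; 1 m/z over 50–1000 for
  DI-MS). Buckets are half-open, left-closed intervals, the final bucket
  closed, so the grid partitions the range and total intensity is
  conserved exactly. NMR buckets are scaled to the TSP-d₄ reference
  region (δ 0.05 to −0.05); DI-MS buckets to total spectrum intensity.
  Both scalings are invariant to any positive rescaling of the input.
  Buckets empty in every sample are dropped, which is why a nominal
  950-bucket DI-MS grid yields a few hundred variables in practice.
* **Element panels (ICP-MS)** — the limit of detection is 3 × the sample
  SD of at least 7 blank replicates (`compute_lod()`; fewer blanks is an
  error). Values not strictly above the LOD are below the detection
  limit, and an element with any such value in any sample is dropped
  entirely (`apply_lod_filter()`), so the fused matrix stays complete —
  the multivariate models assume complete data and imputation would be
  an additional, uncited modelling step. Measured means deviating by
  10% or more from certified reference means fail
  `validate_reference_material()` (the boundary is strict: exactly 10%
  fails).

## Fusion

`align_samples()` restricts all blocks to their common samples in one
canonical order; `concatenate_blocks()` autoscales every variable
(mean 0, SD 1, sample SD with the n − 1 denominator, the chemometrics
convention) and column-concatenates the blocks, recording each column's
platform. Autoscaling gives every variable equal a priori weight, so no
platform dominates through its intensity scale. Zero-variance columns
are undefined under autoscaling and are removed with a warning rather
than kept as zeros. At the archetypal dimensions (518 + 95 + 634 + 367 +
82 + 13) the fused matrix has 1709 columns for 44 samples.

Full-matrix autoscaling serves the *unsupervised* analyses only. Inside
any cross-validation, scaling parameters are recomputed on each training
portion and applied to its held-out sample — otherwise the held-out
sample would leak into the model through the column means and SDs.

## Unsupervised exploration

`pca_fit()` is a singular-value decomposition of the scaled matrix;
component k explains σₖ²/Σσ² of the variance. Sign indeterminacy is
resolved by making each loading vector's largest-magnitude entry
positive, so output is reproducible across linear-algebra backends.

`select_significant_pcs()` picks the rank by element-wise 7-fold
cross-validation: matrix cells are randomly split into folds, each fold
in turn is set missing and reconstructed by an EM-style iterative SVD
fitted to the remaining cells, and component a is accepted while
Q²ₐ = 1 − PRESSₐ/PRESSₐ₋₁ exceeds 0.05. The source this rule descends
from is a software manual without formulas, so both the fold count and
the threshold are arguments; 0.05 is a conventional acceptance limit.
On simulated pure-noise matrices the rule returns 0 components in ≳90%
of runs, and it recovers a planted rank-2 structure exactly.

`hierarchical_cluster()` delegates to `stats::hclust` with Euclidean
distances and Ward's criterion in its "ward.D2" form (squared distances
in the objective, merge heights on the distance scale) — the textbook
Ward variant; the linkage is an argument because software packages
differ. `cut_first_split()` returns the two subtrees of the root, the
"first cluster break" used to read group structure off a dendrogram,
and `dendrogram_to_newick()` serialises the tree ultrametrically (leaf
depth = root height / 2) for exchange with phylogenetics tools.

## Double cross-validated PLS-DA

PLS-DA regresses a 0/1 class-indicator matrix **Y** on the scaled
feature matrix **X** through latent variables. `pls_fit()` implements
NIPALS PLS2: each component extracts weights **w** ∝ **X**ᵀ**u**, scores
**t** = **Xw**, Y-loadings **q** = **Y**ᵀ**t**/**t**ᵀ**t**; **X** is
deflated by **t p**ᵀ, **Y** is not. Regression coefficients are
recovered in closed form, **B** = **W**(**P**ᵀ**W**)⁻¹**Q**ᵀ; the
per-component inner iteration runs to a 1e-12 relative tolerance (cap
500 iterations — with a two-class complementary indicator the loop
converges in a handful of steps). At full rank **B** equals the
least-squares solution, which the tests assert against the normal
equations. Classification is argmax over the predicted indicators, ties
broken by the earliest class in the class order — the simplest rule
consistent with 0/1 coding.

The inference engine is a two-nested leave-one-out scheme
(`double_cv()`). The outer loop sets one sample aside; the inner loop,
on the remaining n − 1 samples, selects the number of latent variables
by a second leave-one-out pass, choosing the count (up to
min(n − 3, p, 10); 10 is a conventional chemometrics cap) that
minimises the inner misclassification total, ties going to the smaller
model. A model with the selected complexity is then fitted on all n − 1
training samples and classifies the held-out sample, using training-fold
scaling throughout. The result is one honest prediction and one model
per sample; the misclassification count M over all n outer folds is the
unbiased error estimate. A mutation test asserts the leakage guard:
corrupting a sample never changes the model fitted without it.

`permutation_test()` re-runs the *complete* procedure — inner selection
included — on labels shuffled among the samples (class sizes preserved),
and reports p = (1 + #{null M ≤ observed M}) / (1 + B), the add-one
correction that keeps p > 0. The default B is 1000 for analyses; the
package's own simulations use 99, which is sufficient to resolve
p ≤ 0.05 and keeps 200-repetition calibration runs around eight minutes
on one core.

`rank_products()` summarises the n per-sample models: within each model
variables are ranked by descending |B| (rank 1 = largest; ties receive
average ranks, which makes the result invariant to variable order), and
ranks are multiplied across models. The product is computed as a sum of
logs — monotone-equivalent and immune to overflow at any realistic n
and p (the tests check it against direct integer products) — and
reported alongside the geometric-mean rank exp(mean log rank).
Consistently important variables have low rank products;
`summarize_discriminators()` tabulates the top k with per-class raw
means, SDs, and higher/lower flags, mirroring the usual red/blue
discriminant tables.

## The synthetic generator

`sim_config()` fixes the simulated study design. Choices and rationale:

* **Dimensions** default to the six-platform archetype (1709 variables,
  44 samples as 2 × 22), preserving the fused-shape check.
* **Intensities are log-normal**: log-intensity is Gaussian with
  within-class SD `noise_sd` (default 0.5, i.e. ~50% CV — typical
  between-variety variation for metabolite intensities). Positivity is
  required by the total-intensity and reference-region normalisations.
* **Class structure is mean shifts only**: a seeded subset of variables
  per platform (default ~5% of each block) receives class-mean offsets
  of `effect_size × noise_sd` on the log scale between adjacent classes,
  i.e. a standardized shift of `effect_size` (default 2 — a strong but
  realistic single-metabolite group difference). No covariance structure
  is injected: independent noise is the simplest structure the
  PLS-DA/rank-product machinery must detect, and also the *least*
  favourable for classification at fixed per-variable effect.
* **Raw-ish precursors** (`generate_raw_*`) exercise each preprocessing
  rule: signal tables with controllable sub-noise fractions and rare
  signals, spectra on a ≤0.001-ppm axis with a TSP reference peak,
  m/z–intensity pairs within 50–1000, element panels with (by default) 7
  blank replicates of SD `blank_sd`.

Because the effect is defined on the log scale, the supervised recovery
analyses in the tests and the acceptance script run on log-intensities
(a standard variance-stabilising choice for log-normal data); on the raw
scale the lognormal skew attenuates the nominal standardized shift. The
structural analyses (fusion, autoscaling, PCA/HCA of the full study
shape) run on the raw intensities.

What the generator does *not* emulate: chromatographic peak shapes,
retention-time drift, isotope patterns, within-class biological
replication structure, and between-variable correlation. Passing tests
therefore demonstrate that the machinery detects mean-shift structure of
known size in independent noise — they do not certify performance on
correlated real-world blocks.

## Calibration and limits, as measured by the package's own suite

The test suite and `scripts/acceptance.R` compute (not assume) the
following, at problem sizes chosen to keep the full run in minutes:
the permutation test's type-I error at α = 0.05 over 200 effect-free
studies (n = 20, p = 100, 99 permutations each); the per-run
misclassification counts of those null studies against the binomial 99%
band around chance — per run, not pooled, because balanced leave-one-out
has a known pessimistic finite-sample bias (the training fold is always
9-vs-10 against the held-out sample's class), a property of the
procedure rather than of this implementation; and signal recovery at
n = 20, p = 200 with five variables shifted by 3 SD, where the five
truths are expected in the rank-product top ten and the permutation p at
or below 0.05. At that signal-to-dimension ratio an *error-free* outer
classification is beyond what (non-sparse) PLS-DA can deliver — the
weight vector's accumulated noise weights give an irreducible
per-sample error on the order of 15% — so a residual misclassification
count of a few samples out of 20 is the expected behaviour, and
independent PLS-DA implementations reproduce it on identical data.

## Degenerate inputs and tie-breaks, in one place

* Zero-variance columns: removed before autoscaling (warning); inside
  cross-validation folds a constant column gets scale 1, so it is
  centred to zero and attracts no weight, keeping every fold's variable
  set identical (rank products require a shared variable set).
* Component count exceeding the achievable rank: fitted up to the rank
  with a warning (`pls_fit()`); inner folds reuse the deepest
  achievable model's prediction for larger candidate counts.
* Argmax ties in classification: earliest class in `class_order`.
  Inner-loop ties in the error count: fewest latent variables.
  Rank ties in |B|: average ranks.
* A training fold losing an entire class is an error naming the fold;
  a permutation that fails is redrawn once, then errors.
* Empty sample intersection in `align_samples()`, all-zero spectra,
  non-positive reference regions, certified values of zero, and fewer
  than 7 blanks are all errors, not silent repairs.

## Reproducibility

Every stochastic routine takes a seed and restores the caller's RNG
state. `run_pipeline()` writes blocks and the fused matrix at 17
significant digits (read-back is bit-exact) and result tables at 12,
plus a DCF manifest recording seed, dimensions and headline results;
two runs from the same configuration produce byte-identical artifacts.
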