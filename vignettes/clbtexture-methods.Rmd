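---
title: "Methods: masked-ROI texture classification of breast-cancer subtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masked-ROI texture classification of breast-cancer subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clbtexture)
```

This vignette documents the scientific and numerical choices behind the
package: the texture model, every tunable parameter and its default, what
the synthetic phantoms do and do not emulate, and the places where the
design was genuinely open and a decision had to be made.

## The problem

Invasive ductal carcinoma (IDC) and invasive lobular carcinoma (ILC) are
the two dominant histological subtypes of invasive breast cancer. ILC's
diffuse, single-file growth makes it notoriously inconspicuous on
conventional imaging. The pipeline implemented here asks whether texture
of the *glandular tissue of the contralateral (unaffected) breast* on
T1-weighted pre-contrast MRI carries enough subtype signal to classify
IDC vs ILC — a non-invasive, contrast-free signal that does not depend on
visualizing the tumor at all. The classification unit is a 2-D slice with
a binary glandular mask; slices nest within patients, and the clinical
class frequencies are strongly imbalanced (1890 IDC : 554 ILC slices,
i.e. 77.3% vs 22.7%).

## Masked-ROI statistics: list, not product

Applying a mask by elementwise multiplication, as is often described,
floods the image with zeros wherever the mask is off. All statistics in
this package are therefore computed over the **masked pixel list** (the
intensities where the mask is 1, in row-major order); the multiplied grid
is produced by `apply_mask()` only for visualization. Histogram features
over the product grid would otherwise be dominated by an artifactual
zero bin. Users who want product-grid semantics can pass the `grid`
element of `apply_mask()` through a full mask.

Slices whose ROI is degenerate are excluded before extraction by
`qc_exclude()`: masked area below `min_area = 64` pixels, or largest
8-connected component holding less than `min_largest_component_share =
0.9` of the masked area. No published rule exists for "ROI
discontinuity", so both thresholds are explicit, configurable arguments
rather than constants. Exclusion happens **before** feature extraction;
the alternative (extract, then drop) differs only for the excluded rows.

## The 12 features and their tunables

First-order moments use the population divisor `N` throughout, matching
the defining formulas. Two printed-formula issues were resolved as
follows:

* **Kurtosis.** A squared-deviation "kurtosis" variant that circulates in
  print evaluates to exactly −2 for *any* image, because the mean squared
  standardized deviation is 1 by construction. The package implements the
  standard excess kurtosis (fourth power, minus 3) and retains the
  degenerate variant internally with a unit test documenting the −2
  identity.
* **Entropy.** Histogram entropies use 256 equal-width bins spanning the
  full bit-depth range `[0, 2^bit_depth − 1]` and base-2 logarithms
  (bits), with `0·log 0 ≡ 0`. For 8-bit data this is one bin per gray
  level.

Local features are computed per masked pixel over the intersection of a
square window with the mask; pixels whose window retains fewer than two
masked pixels are skipped, and the per-slice scalar is the mean of the
map over contributing pixels. Window sizes — 9×9 for local entropy, 3×3
for local range and local standard deviation — are the long-standing
defaults of the MATLAB functions (`entropyfilt`, `rangefilt`,
`stdfilt`) this feature family descends from; all are arguments of
`feature_params()`.

The GLCM is computed on 8 gray levels after min–max quantization *within
the mask* (equal-width bins over `[min, max]` of the masked intensities,
maximum mapping to the top level, constant regions to level 0), offset
(0,1), symmetric accumulation, normalized to sum 1. These four settings
are unstated in most clinical texture papers; the defaults here are the
common defaults of the MATLAB/scikit-image lineage and are all
configurable and recorded in the returned `glcm` object. Correlation is
reported missing when a marginal SD is zero; a mask admitting no valid
pixel pair raises a dedicated `glcm_undefined` condition, which
`extract_features()` converts to four missing values.

## Cleaning, normalization, ranking

Rows with any missing feature are removed by `drop_missing()`, which
emits a per-column missingness report (a textual replacement for the
usual heat-map inspection). Normalization implements the min–max formula
`Xn = (X − Xmin)/(Xmax − Xmin)`; the accompanying prose convention
("zero mean and unit variance") contradicts that formula, and the formula
wins — a z-score option (`method = "zscore"`) exists for users who want
the prose behavior. By default normalization parameters are fitted on
training rows only and reused on test rows (values outside [0, 1] are
then legitimate); fitting on all rows is what the original protocol did
and remains available by simply not passing `fit_rows`.

Feature relevance uses the two-group one-way ANOVA F-test, `F =
MS_between/MS_within` with df (1, n−2) — equal to the squared pooled
two-sample t statistic, which the test suite verifies on random
instances. `sequential_elimination()` removes features from least to
most significant F; since the test is univariate, the removal order is
fixed by the initial ranking. Each ladder row reports the accuracy of
the model trained on the features *still present* before that removal,
so the first row is the all-features baseline. F-scores are computed on
training rows by default; `mode = "full-table"` ranks on the full table, as
the original selection protocol appears to have done. One stratified
split (fixed by `seed`) serves all rungs.

## Imbalance handling and the order of operations

`smote()` is implemented from first principles: synthetic minority rows
are `x + λ(x_nn − x)` with `x` a uniformly resampled minority row,
`x_nn` one of its `k_neighbors = 5` nearest minority neighbors
(Euclidean distance in normalized space, distance ties broken by lowest
row index), `λ ~ U[0, 1]`. Synthetic rows are flagged in a provenance
column and never reuse real slice ids. `undersample()` subsamples the
majority class to the minority count without replacement.

The order of operations matters. The default (`order = "split-first"` in
`run_once()`) splits 80/20 first and balances **only the training side**,
so no synthetic point interpolated from a test row can reach the
classifier. The original protocol balanced the full table and then split
(`order = "balance-first"`); both are first-class so the leakage effect itself
can be measured. At the clinical scale the package's stratified 20%
split reproduces test supports of 378 IDC + 111 ILC = 489 rows exactly
(`round(0.2·1890)`, `round(0.2·554)`); the alternative 383/106 support
sometimes quoted for the unbalanced protocol is not recoverable from a
stratified split of 2444 rows and is treated as an unexplained artifact
of the original split procedure.

## Modeling

The experiment protocol (stratified splits, fold plans, benchmark loop,
grid search, tie-breaking) is authored here; tree/kernel induction is
delegated to standard backends: `class::knn`, `stats::glm`, `ranger`
(random forest), `rpart`, `e1071::naiveBayes`, `e1071::svm`. AdaBoost is
a compact SAMME-style boosting loop over depth-1 `rpart` stumps (50
rounds), since no boosting package is part of the package's dependency
footprint. Scores returned by `predict_model()` are class-1
probabilities (or probability-scaled margins for AdaBoost), so ROC
construction is uniform across learners.

The random-forest grid mirrors the sklearn-style search:
`n_estimators ∈ {50,100,200,300}`, `max_depth ∈ {∞,10,20,30,40}`,
`min_samples_split ∈ {2,5,10}`, `min_samples_leaf ∈ {1,2,4}`,
`bootstrap ∈ {TRUE,FALSE}` — 360 configurations, mapped onto ranger's
`num.trees`, `max.depth`, `min.node.size`, `min.bucket`,
`replace`/`sample.fraction = 1`. Although the source protocol says
"random grid search", it reports a fixed grid and winners that lie on
it, so exhaustive search over the printed ranges is the default. Ties
are broken by higher mean CV accuracy, then lower fold SD, then first
position in lexicographic grid order. `random_state`-style determinism
is honored by fixing the model seed at 42 wherever the protocol states
it. Cross-validation runs on the training subset (the standard
protocol); scoring is accuracy, matching the benchmark convention.

## Evaluation

Confusion counts are one-vs-rest for both classes (class 0 = IDC,
class 1 = ILC); accuracy, precision, recall and F1 follow the four
standard formulas with missing values (never errors) on zero
denominators. Report rounding follows the clinical convention: two
decimals for precision/recall/F1, integer percent for accuracy
(`format_metrics()`). ROC/AUC is computed twice — threshold sweep with
trapezoidal integration, and the rank (Mann–Whitney) formulation with
midranked ties — and the two must agree, which the suite checks against
`pROC` as a third, external implementation.

`compare_runs()` performs the paired analysis of two accuracy series:
paired t-test (`stats::t.test`), Wilcoxon signed-rank (`stats::wilcox.test`
with zero differences dropped; exact for ≤ 25 nonzero pairs, normal
approximation with continuity correction beyond — the reported `W` is
the smaller of the two signed-rank sums), and a percentile bootstrap CI
of the mean difference (10000 resamples by default). The "bootstrap
analysis" of the source figure is under-specified; the percentile CI of
the mean paired difference is the simplest inference consistent with it.

## The synthetic phantoms

`generate_texture_field()` produces white Gaussian noise convolved with
a Gaussian kernel of scale `smoothing_length`, empirically standardized
and mapped to `mean_intensity ± noise_sd`, then quantized and clipped.
This family was chosen because the smoothing scale gives *monotone,
analyzable* control over GLCM statistics: larger `smoothing_length`
lowers contrast and raises homogeneity, which the test suite verifies
over seed batches. Masks are unions of disjoint axis-aligned ellipses
(`make_glandular_mask()`); fragmentation — for exercising the QC rule —
is modeled by asking for several components.

`generate_cohort()` adds the cohort structure that matters statistically:
patients with several slices each, per-patient random offsets (mean
shift ~ N(0, 4) gray levels, smoothing multiplier ~ exp N(0, 0.08)) drawn
once per patient so within-patient slices are correlated, and a
class-imbalance dial defaulting to the clinical 1890:554 ratio. Seed
discipline is a documented counter scheme (`derive_seed()`): one master
seed, with per-patient, per-slice and per-run seeds derived from counter
paths, so every artifact is a pure function of its configuration. The
number of slices per patient is not reported for the clinical cohort, so
it is a free parameter (default 6).

What the phantoms deliberately do **not** emulate: anatomy, bias fields,
3-D continuity between slices, scanner noise spectra, or any
biologically grounded link between subtype and texture. Passing tests on
phantoms therefore demonstrate that the *pipeline machinery* is correct
and that its statistical behavior (imbalance effects, leakage effects,
selection behavior) is as theory predicts — not that contralateral
texture classifies real IDC/ILC. The clinical headline numbers depend on
the original imaging collection and manual segmentations and are out of
scope here; only their internally consistent report arithmetic is
recomputed.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately small
instances chosen to make every stochastic check stable at fixed seeds:
48×48 phantoms with ~30% mask coverage, cohorts of 56–124 slices,
10-fold CV, 100-run paired experiments, and an exhaustive 360-point grid
at 5-fold CV in the acceptance script. The acceptance experiment uses
partially overlapping classes (smoothing 2 vs 3, mean 120 vs 130, noise
SD 35): fully separated classes saturate every classifier at accuracy
1.0, where the imbalance machinery has nothing to show; the overlapping
regime reproduces the qualitative clinical findings — SMOTE raises
minority-class recall while slightly lowering overall accuracy.

Other numerical details: population SDs throughout the texture formulas
and for fold-accuracy SDs; GLCM normalization tolerance 1e−12 enforced
structurally (counts divided by their sum); feature-vs-oracle agreement
asserted at 1e−9; flood-fill component labeling by iterative minimum-
label propagation (converges in at most the mask diameter iterations);
min–max quantization maps the masked maximum into the top level by
clamping rather than an ε-widened bin.

## Interfaces

The package's users drive it from R: the exported functions compose the
full pipeline, and this vignette plus the README's worked example are
the canonical entry points (there is no shell executable; the
`scripts/acceptance.R` script shows a complete scripted run). Cohorts
round-trip to disk as 8-bit PNG (or 16-bit TIFF) image/mask pairs plus a
manifest CSV (`write_cohort()`/`read_cohort()`), so external images
segmented elsewhere can be fed in through the same manifest format.

## Known limitations

* Slice-level splitting (the default `group_mode = "slice"`) lets slices
  of one patient appear on both sides of a split, which inflates
  accuracy when within-patient correlation is strong; `group_mode =
  "patient"` is provided and recommended for honest generalization
  estimates, but the slice mode remains the default for comparability
  with the original protocol.
* The GLCM uses a single offset by default; rotation-averaged multi-
  offset matrices are supported via `feature_params(offsets = ...)` but
  not studied here.
* AdaBoost stops early if no stump beats chance, returning a constant
  0.5 score — correct but uninformative on degenerate folds.
* 16-bit output uses TIFF because PNG writing in R is 8-bit only;
  16-bit PNG *reading* is supported.
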