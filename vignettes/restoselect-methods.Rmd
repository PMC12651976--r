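---
title: "Methods: texture-based restoration classification with hybrid wrapper selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture-based restoration classification with hybrid wrapper selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Panoramic dental radiographs routinely contain restorations — fillings,
implants, root-canal treatments, fixed partial dentures (bridges) and crowns —
whose automatic identification supports reporting, treatment planning and
record management. `restoselect` implements an image-level, single-label
formulation of that task: each radiograph carries one dominant restoration
label out of the five classes, and classification rests on global texture
statistics rather than end-to-end representation learning, a deliberate choice
for small, single-center datasets where handcrafted features remain
competitive and interpretable.

The pipeline has three stages: (i) enhancement and global GLCM texture
description, classified by conventional models; (ii) hybrid grey-wolf /
particle-swarm (HGWO-PSO) wrapper feature selection feeding an RBF-SVM; and
(iii) a CNN architecture defined for baseline comparison. Everything is
exercised on a synthetic phantom generator, so no clinical data ships with or
is required by the package.

# Enhancement chain

Images pass through a centered crop (default 1700 x 880, applied only when the
source is larger — panoramic margins are non-diagnostic and peripheral, so a
centered anchor is the natural choice), then global histogram equalization,
then CLAHE (clip limit 2.0, 8 x 8 tile grid).

Two numerical conventions matter here:

* **HE mapping.** We use the classic full-range map
  `T(v) = round((cdf(v) - cdf_min) / (N - cdf_min) * (L - 1))`, which sends
  the darkest occupied bin to 0 and the brightest to `L - 1`. A constant
  image is returned unchanged. The map is monotone (rank-preserving) and
  idempotent up to one gray level of quantization.
* **CLAHE clip limit.** The limit is a *multiple of the uniform tile
  histogram height* (`clip * n_tile_pixels / n_bins`), the convention used by
  the common OpenCV-style implementations; clipped mass is redistributed
  uniformly. Tiles use the same full-range CDF map as global HE and are
  blended by bilinear interpolation between tile centers, so a single tile
  with an unbounded clip limit reproduces global HE exactly. Bins equal the
  full intensity range of the bit depth, which keeps 8-bit behavior exact.

# GLCM texture features

Each (enhanced) image is min-max rescaled to [0, 1] and quantized to 64 gray
levels; a constant image maps to level 0. One co-occurrence matrix is built
per angle (0, 45, 90, 135 degrees) at displacement d = 1, counting ordered
pixel pairs truncated at the borders (no padding or wraparound), symmetrized
by adding the transpose, and normalized to sum 1.

From each matrix five descriptors are computed: contrast
`sum p (i-j)^2`, correlation (from the marginal means and SDs), energy / ASM
`sum p^2`, homogeneity `sum p / (1 + |i-j|)`, and entropy `-sum p log2 p`
(bits; any other base only rescales). Two conventions are documented and
tested: correlation of a zero-variance (constant) texture is defined as 1 —
constant texture is perfectly predictable — and entropy sums over nonzero
cells only.

The 25-feature vector is descriptor-major: for each of Contrast, Correlation,
ASM, Homogeneity, Entropy come the four per-angle values followed by the
across-angle arithmetic mean, named by the bare descriptor (`Contrast0`,
`Contrast45`, `Contrast90`, `Contrast135`, `Contrast`, ...). This published
ordering is the package's canonical index map; alternative index schemes
seen in the field are ambiguous between blocks of four and five, so we do
not attempt to match any of them. The quantization note above also resolves
an apparent tension between "normalize pixels to [0, 1]" and "z-score" in
the field's descriptions: min-max feeds the *pixel* quantization, while
z-score standardization applies to the extracted *feature columns*, fitted
on training rows only (`zscore_fit()` / `zscore_apply()`; a zero-variance
column maps to 0).

# HGWO-PSO wrapper selection

Each wolf carries a continuous score vector `X`, a velocity `V`, and a binary
inclusion mask over the 25 features. The wrapper fitness of a mask is

```
F = 0.9 * Acc + 0.1 * (1 - Fr)
```

where `Acc` is the seeded stratified internal-CV accuracy of the RBF-SVM on
the selected columns and `Fr = |mask| / d` the fraction selected, so
equal-accuracy smaller subsets always win by exactly 0.1/d per feature.
`Fr` is the fraction *selected* (not reduced): read literally as a
"reduction ratio" the parsimony term would reward keeping everything, which
contradicts its purpose. An empty mask is never evaluated (fitness 0,
flagged invalid).

Per iteration the three fittest wolves form the elitist alpha/beta/delta
hierarchy; they are frozen within the iteration and replaced only by strictly
better agents, which makes the best-so-far fitness non-decreasing by
construction. All remaining wolves update with the inertia-weighted velocity
rule toward their personal best and the global best (the alpha wolf by
default; the mean of the three leader encodings via
`leader_combine = "mean3"`), with `c1 = c2 = 2` and the inertia weight
annealed linearly from 0.8 to 0.4. As printed in the field the update rule
assigns the velocity expression directly to the next position; we read it as
the standard PSO velocity update with `X(t+1) = X(t) + V(t+1)`, since a pure
assignment would discard position history.

Three numerical choices were genuinely open and are worth recording:

* **Attractor encoding.** Personal and global bests are stored as masks; in
  the velocity update they act as attractors through a finite logit encoding
  (selected = +2, dropped = -2, matching `sigmoid(2) ~ 0.88`), which is also
  the initialization of `X` from the Bernoulli(0.5) starting masks (the exact
  logit of a binary mask is infinite). We first implemented the alternative —
  continuous best *positions* as attractors — and measured it: positions
  drift to the velocity clamp, per-bit flip probability collapses below 1%,
  and the swarm freezes around near-optima. The mask-attractor form keeps
  equilibrium scores near the +-2 encoding, i.e. a persistent per-bit
  exploration floor; the acceptance suite validates its recovery of the
  brute-force optimum of a planted 10-bit benchmark across 50 seeds.
* **Clamping.** Velocity is clamped to [-6, 6]; the position is clamped to
  the same band because it is the input of the sigmoid transfer — an
  unbounded position saturates the selection probabilities at 0/1.
* **Binarization.** Bits are Bernoulli-sampled at the sigmoid of the score
  (S-shaped transfer); deterministic thresholding at 0.5 is available via
  `binarize = "threshold"`. An empty sample is redrawn once, then the
  highest-probability bit is forced on.

Fitness values are cached per mask and the internal CV folds are frozen at
evaluator construction, so the wrapper accuracy is a pure function of the
mask and the whole run is reproducible from one seed.

The internal CV uses 5 stratified folds by default. With 3 folds (the
minimal common choice) the accuracy estimates on ~130-row training folds are
noisy enough that the search partially fits the fold noise; 5 folds measurably
stabilize which features are selected at a modest cost. The count remains a
config field (`classifier_config(internal_folds = )`).

# Classifier bank

The models behind the comparison table are standard implementations driven at
the stated hyperparameters: RBF-SVM with `C = 10`, `gamma = 0.1`
(`e1071`; a seeded stratified grid search over C in {0.1, 1, 10, 100} and
gamma in {0.001, 0.01, 0.1, 1} is available, with ties broken toward the
smaller C then the smaller gamma — the stated values are the defaults when
the search is off); K-NN with k = 5 or CV over the odd grid 3-11 (`class`);
a Gini decision tree of maximum depth 20 (`rpart`); and a 100-tree random
forest of maximum depth 20 (`ranger`, seeded, single-threaded). Class
imbalance is countered by inverse-frequency class weights in the SVM, both
in the final fits and inside the wrapper fitness (configurable).

The CNN baseline is represented by its architecture: five 3 x 3 convolutions
(32-512 filters, stride 1, same padding, ReLU) in four max-pooled blocks,
dense layers of 256 and 512 units with dropout 0.2/0.1, and a 5-way softmax;
`cnn_param_count()` gives the exact trainable-parameter accounting
(27,393,093 at the 224 x 224 input, 3,800,133 at the 64 x 64 desk size) and
`cnn_forward()` a seeded
He-initialized inference pass used to validate the probability contract.
The package deliberately scopes the CNN component to architectural
specification and inference: the texture/optimization pipeline is the
package's subject, and its tests and experiments run without any
deep-learning framework. The stride column of common tabular descriptions of
this architecture is garbled in circulation; we fix stride 1 for
convolutions and 2 for pooling, the standard reading of "3 x 3, 2 x 2".

# Leakage-safe evaluation

Patients, never images, are the unit of splitting: `patient_split()` shuffles
patients with the seed, orders them round-robin across dominant patient
labels (best-effort grouped stratification — exact stratification can be
infeasible under grouping, so the achieved balance is reported in the plan),
and greedily fills the test side to the 20% image target without ever
splitting a patient. `grouped_kfold()` partitions training patients into 5
folds of near-equal image counts (greedy largest-first assignment, so fold
sizes differ by at most the largest patient).

Within every CV fold the standardizer is fitted on the fold-training rows
only, the HGWO-PSO search runs on the fold-training rows only (the
`fitness_evaluator` object is *constructed* from those rows and cannot see
others), and the fold-validation rows are touched once for scoring. The final
reported wrapper model uses the mask from one further selection run on the
full training set — how fold-wise masks become one deployable model is
genuinely unspecified in the field's descriptions; consolidating by a final
full-training-set run is our choice, and all fold-wise masks are logged in
the report. The held-out test patients are evaluated exactly once per model;
an access audit (image ids recorded at every standardizer, optimizer and
grid-search call) ships inside each report and is asserted empty of test ids
in the acceptance suite.

Metrics: accuracy is `trace / total`, the multi-class equivalent of the
one-vs-rest `(TP + TN) / (TP + TN + FP + FN)` form; per-class precision,
recall and F1 define `0/0 = 0` (this depresses macro averages when a class is
never predicted — documented and tested); macro metrics average over all five
classes whether present or not. Uncertainty comes from a stratified bootstrap
(resampling within true-class strata, 1000 replicates, percentile 95%
intervals) on the aggregated test predictions; class strata are the standard
reading of "stratified" here. Fold-level accuracies of the wrapper SVM and
the plain SVM are compared by a two-sided paired t-test whose degenerate
branches follow documented conventions (identical vectors: t = 0, p = 1;
constant nonzero difference: t = +-Inf with a warning). Cohen's kappa
`(po - pe) / (1 - pe)` is provided for dual-annotation audits; two constant
identical raters give kappa = 1 with a warning. Composite confusion reporting
is ambiguous between CV-aggregated and test-set matrices in the field; the
report carries both, labeled (`fold_accuracies` plus the test confusion).

# The phantom generator

`generate_phantom()` produces statistical stand-ins for radiographs, not
anatomy: a stationary Gaussian random field background (white noise convolved
with a Gaussian kernel, correlation length ~8 px — cheap, controllable,
stationary GLCM statistics), a deterministic per-patient gain (+-6%) that
correlates images within a patient, additive white noise (`noise_sd`, default
0.05 on the [0, 1] scale), and one class-conditional bright component whose
amplitude is `0.15 * effect_size`:

| class | component | texture signature |
|---|---|---|
| implant | one sharp disk, r 8-10 px | compact saturated region, crisp edges |
| crown | one smooth Gaussian blob, r 18-24 px | broad graded dome, low edge contrast |
| bridge | near-horizontal bar, ~0.6-0.85 W long | anisotropy at 0 degrees |
| filling | 10-16 sharp speckles, r 1.5-3 px | high-frequency transitions, high contrast |
| root_canal | 4-6 thin near-vertical streaks | anisotropy at 90 degrees |

At `effect_size = 0` the components vanish and per-class intensities are
indistinguishable; at the default `effect_size = 2` the components nearly
saturate, which emulates the bright metal artifacts that dominate real
radiographs of restorations. The default scale is 40 patients x 4 images of
96 x 96 px with imbalanced priors (0.30/0.15/0.20/0.15/0.20) — large enough
for patient-level 80/20 splits plus 5 grouped folds, small enough that the
full experiment runs in minutes on one CPU.

The generator's calibration contract — an RBF-SVM on the 25 features over a
patient-level 80/20 split reaches at least 0.60 held-out accuracy at
`effect_size >= 2`, against a majority-class chance of at most 0.30 — was
met by design of the component shapes before the defaults were frozen, and
the acceptance suite re-verifies it on three independent generator seeds
as part of the end-to-end experiment. What
passing tests on phantoms does **not** show: robustness to anatomy,
device/exposure variation, multi-restoration images, beam-hardening artifacts
or label noise of real panoramics. The phantoms validate the machinery
(features, selection, leakage control, statistics), not clinical performance.

# Problem sizes and runtime

The default experiment (`experiment_config()`) uses the 160-image phantom
set, 5 grouped CV folds, a desk preset of 30 optimizer iterations with 10
wolves (the full 100-iteration setting is one config switch;
`hgwo_pso_config(iterations = 100)`), 5-fold internal wrapper CV and 1000
bootstrap replicates; it completes in roughly a minute per model arm on one
CPU. The acceptance suite additionally runs the 10-wolf / 100-iteration
configuration against a brute-force enumeration oracle over all 1023 masks
of a planted 10-bit fitness, and a 20-seed planted-feature recovery study on
200-row feature tables.

# Known limitations

* Single-label, image-level formulation; no localization or multi-label
  modeling, no ROI-based features.
* Global GLCM statistics mix restoration and background texture by design.
* The CNN component specifies and verifies the architecture but does not
  train it.
* Phantoms are statistical, not anatomical; all empirical claims in the
  package are about the phantom conditions stated above.
* DICOM ingestion, anonymization and device harmonization are out of scope.
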