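---
title: "Multi-atlas ensemble GAT classification of functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-atlas ensemble GAT classification of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Resting-state fMRI yields, per subject, one BOLD time series per brain
region of interest (ROI). After parcellating the brain with an atlas, a
subject is a `T x N` matrix (`T` time points, `N` ROIs), and the
correlation structure between ROI series — the functional connectivity
network (FCN) — carries diagnostic signal for major depressive disorder
(MDD). `magat` implements a complete pipeline that classifies subjects as
MDD versus healthy control (HC) from such matrices, using **four
parcellations at once** (Dosenbach 160, AAL 116, Craddock 200,
Harvard–Oxford 112): one graph attention network (GAT) is trained per
atlas and their predictions are combined by ensembling. Multi-site
cohorts are harmonized with ComBat before modelling, and class-wise SMOTE
enlarges training data.

Clinical rs-fMRI collections of this kind are access-restricted, so the
package ships a synthetic-cohort generator that reproduces the
*structure* of such data — multi-site location/scale batch effects,
age/sex covariate effects, and class-dependent connectivity — with known
ground truth, making every stage of the pipeline testable end to end.

## Pipeline stages and their models

### ComBat harmonization

Site effects are modelled per feature as
`y = alpha + X beta + gamma_i + delta_i * epsilon`, with `gamma_i` an
additive and `delta_i` a multiplicative site effect. Per feature we fit
`alpha`, `beta` (age standardized, sex as 0/1) by pooled least squares,
standardize by the pooled SD, estimate per-site `gamma`, `delta^2` from
the standardized data and shrink them by parametric empirical Bayes
(normal prior on `gamma`, inverse-gamma on `delta^2`, moment-matched
hyperpriors, iterative conditional updates to tolerance 1e-4). The
adjusted value is `((z - gamma*) / delta*) * pooled_sd + alpha + X beta`,
so covariate effects are reconstructed while site effects are removed.

Two details deserve attention:

* **Feature definition.** The default treats each (atlas, time point,
  ROI) entry as one feature harmonized across subjects. Time points are
  not anatomically aligned across subjects, which makes this unusual,
  but it is the formulation the pipeline is specified with; a per-ROI
  stream alternative (`feature_mode = "roi"`, each ROI stream harmonized
  over subject x time observations) is available.
* **Leakage.** ComBat is fit on the full cohort before any split,
  matching the published processing order. The test folds therefore
  influence the harmonization model; consumers comparing against
  leakage-free protocols should refit per training set.
* Degenerate hyperpriors (a site whose estimates are constant across
  features, as happens with duplicated data) make moment matching
  undefined; the implementation then falls back to the unshrunk
  estimates. Note also that because per-site variances use the `n - 1`
  denominator while the pooled variance uses `n`, the fitted scale on
  data with *no* site effect is `sqrt(n/(n-1))`, not exactly 1 — the
  adjustment is only asymptotically the identity.

### SMOTE on time-series matrices

Oversampling is class-wise: for each real sample, one of its `k = 3`
nearest same-class neighbours (Euclidean distance on the flattened
concatenation of all atlas matrices, so one neighbour serves all
atlases) is drawn, and each time-point row is interpolated with its own
`gap ~ Uniform(0, 1)`:
`row_t(synthetic) = row_t(seed) + (row_t(neighbor) - row_t(seed)) * gap_t`.
Sharing the gap within a row (across ROIs and atlases) preserves the
within-time-point spatial correlation; a single-gap-per-sample mode is
available (`gap_mode = "per_sample"`). Synthetic records are flagged, get
`syn:`-prefixed ids, and are structurally barred from test sets. With
the default multiplier 2 both classes exactly double; on the study's
class sizes (810 MDD / 753 HC, 80/10/10 split) this yields the reference
counts of 2,502 training, 310 validation and 157 real test samples.

### FCN construction and brain graphs

Per subject and atlas: Pearson correlation between ROI series, Fisher
z-transform (`atanh`, correlations clipped to `1 - 1e-7` in magnitude so
perfect correlations stay finite, diagonal forced to 0), then a
k-nearest-neighbour graph: each node connects to the `k = 10` nodes with
the largest **absolute** z-connectivity (strong negative coupling is as
informative as positive), ties to the lower index, union over directions
so the graph is undirected with minimum degree `k`. Node `i`'s feature
vector is row `i` of the z-matrix. Edge weights are kept in the graph
and its text exports but are *not* fed into attention — the attention
mechanism is defined on node features only; weighted-attention variants
are out of scope. R objects use 1-based node indices; text exports are
0-based.

### The GAT classifier

Three stacked attention layers. Per head,
`e_ij = LeakyReLU(a^T [W h_i || W h_j])` over the neighborhood of `i`
(self-loop added inside the layer), normalized by a softmax to
`alpha_ij`, and `h'_i = sigma(sum_j alpha_ij W h_j)`; the 4 heads are
concatenated, so with 64 hidden units per layer each head spans 16
dimensions ("64 hidden units" is read as the total layer width; a
per-head reading is available by adjusting `hidden_units`/`n_heads`, as
is the averaging combination). LeakyReLU slope is 0.2 (the GAT
convention). Dropout (0.5) hits node features before each layer,
training only. Readout is global average pooling, then an affine map to
two classes and a softmax.

Training minimizes cross-entropy with minibatch Adam (batch 16, learning
rate 1e-3, weight decay 5e-4 added to gradients). Early stopping watches
validation loss with patience 20 within at most 200 epochs and restores
the best-validation-epoch parameters; that epoch's validation accuracy
becomes the model's weight in the ensemble. A full grid search over the
four standard lists (learning rate, weight decay, batch size, dropout;
256 cells) is available via `grid_search()`. All parameters initialize
from a uniform fan-in scheme under a named RNG sub-stream, so training
is bit-reproducible given the root seed.

The implementation materializes dense masked attention matrices — brain
graphs have at most a few hundred nodes, where dense linear algebra
beats sparse bookkeeping in R — and backpropagates analytically;
gradients are verified against central finite differences in the test
suite, and the whole forward pass against an independently written
scalar-loop oracle.

### Ensembling

Three rules over the four per-atlas models: **majority** hard voting,
with 2–2 ties broken by the vote of the model with the highest
validation accuracy (accuracy ties: fixed atlas order Dose, AAL, CK,
HO); **sum** of softmax probabilities; and **weighted sum** with weights
`w_j = Acc_j / sum Acc_i` from validation accuracies. Hard labels are
the argmax of each model's softmax, with probability ties going to MDD
(the positive class, a sensitivity-favouring choice); the same
convention applies to argmax ties of the summed probabilities, and such
subjects are logged.

### Evaluation

MDD is the positive class throughout. Accuracy, sensitivity,
specificity, precision and F1 follow their standard confusion-matrix
formulas with divide-by-zero guards returning 0. The 80/10/10 stratified
split uses `test = ceil(0.1 n_c)` per class and `val = test - 1` when
`0.1 n_c` is integral (else `floor(0.1 n_c)`) — the only allocation that
reproduces the reference counts for class sizes 810 and 753; a plain
floor rule is available (`val_rule = "floor"`). Cross-validation is
stratified k-fold (k = 10 by default); within each iteration the
non-test folds are re-split 8:1 per class into train/validation, both
oversampled, so every fold has the validation accuracy ensembling
needs while held-out folds stay real-only. Fold metrics are aggregated
as mean and sample SD; the best fold is the highest-accuracy one (ties:
lowest index). Between-model comparisons use two-sided equal-variance
two-sample t-tests per metric (Welch by flag), with `p = 1` by
convention for identical constant vectors.

## The synthetic cohort generator

`simulation_spec()` defaults describe the emulated study conditions: 16
sites, 49 subjects per site per class (~1,568 subjects), 140 time
points, the four standard atlases. Ages are Normal(34, 12) truncated to
[18, 65] and sex is Bernoulli(0.5), matching the cohort demographics;
labels are balanced per site.

The class signal lives in correlation space, not mean space: each atlas
gets a block-model latent correlation matrix (contiguous modules,
`within_cor = 0.35`, `between_cor = 0.05`; 5 modules by default), and in
the MDD class a random 20% of between-module ROI pairs is shifted by
`class_effect` (default 0.25), then repaired to the nearest
positive-definite correlation matrix. A mean-space signal would be
erased by Pearson centering, so this design makes the benchmark exercise
the pipeline's actual discriminative pathway. Site effects are applied
per (time point, ROI) feature — additive `gamma ~ N(0, site_gamma_sd)`
(default 0.2) and multiplicative `delta ~ U(0.8, 1.25)` — consistent
with how harmonization defines features, plus scalar age/sex effects
and observation noise (SD 0.2). These scales are package choices: the
emulated study reports no generative description of its data, so they
were set once to values that give site effects comparable in magnitude
to the subject-level signal, and are returned as ground truth for
recovery tests.

What the generator does **not** emulate: hemodynamics and realistic BOLD
autocorrelation (rows are temporally exchangeable), head motion,
scanner-specific spectral signatures, and the heterogeneity of real
clinical populations. Passing tests on synthetic cohorts therefore
demonstrate algorithmic correctness and sensitivity to the modelled
structure — not clinical performance.

## Numerical and design choices

* Correlation clipping at `|r| = 1 - 1e-7` bounds Fisher z at ~8.41.
* Constant ROI columns get zero correlations (with a warning) rather
  than NaNs.
* KNN ties break toward the lower node index; best-fold ties toward the
  lower fold index; hard-label and argmax ties toward MDD. All
  tie-breaks are deterministic by design.
* One root seed fans out to named sub-streams (`"folds"`, `"smote"`,
  `"init-<atlas>"`, ...) via a splitmix-style integer hash, so stages
  re-run in isolation reproduce their in-pipeline draws and different
  atlases get independent streams.
* Whether the reference pipeline drew one SMOTE neighbour per synthetic
  sample or per row is ambiguous; one-neighbour-per-sample is
  implemented (with parent bookkeeping for audits).
* The `sum` ensemble operates on softmax probabilities (not logits),
  consistent with the weighted-sum definition.

## Problem sizes used in the shipped checks

The package's own acceptance checks run at reduced scale, chosen once as
the package's evaluation protocol:

* **Learning benchmark:** four atlases of 16/20/24/28 ROIs, `T = 60`,
  two sites, 120 subjects, `class_effect = 0.6` on 20% of between-module
  pairs; GAT width 16 (4 heads), dropout 0.2, up to 40 epochs for the
  single-seed depth check and 20 epochs across the 20-seed
  ensemble-versus-single comparison. At this scale each single-atlas
  model reliably exceeds 70% test accuracy and majority voting matches
  or beats the mean single-atlas model.
* **Harmonization recovery:** 3 sites x 40 subjects, 160 features,
  `site_gamma_sd = 2.0`, `delta ~ U(0.6, 1.6)` — scales at which the
  true effects dominate the `n = 40` estimation noise, so recovery
  correlations above 0.9 are a meaningful bar.
* **Count identities** (2,502 / 310 / 157) run at the full 1,563-subject
  size with minimal 4x3 series, since only bookkeeping is exercised.

`scripts/acceptance.R` recomputes these quantities from scratch against
the installed package and writes them as JSON.

## Known limitations

* Pure-R training: fine for hundreds of graphs with tens to hundreds of
  nodes; a compiled backend would be the next step for full-size
  cohorts at hundreds of epochs.
* No GATv2 or edge-feature attention; no reference-batch or
  non-parametric ComBat; no Borderline-SMOTE/ADASYN.
* The full-cohort harmonization leakage noted above.
* `empirical_site_effect`'s F statistics assume one observation per
  subject per feature and at least two subjects per site.
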