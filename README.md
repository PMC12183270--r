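# magat — multi-atlas ensemble graph attention networks for functional connectomes

`magat` classifies subjects as major depressive disorder (MDD) versus
healthy control (HC) from resting-state fMRI ROI time series. Instead of
committing to one brain parcellation, it trains one graph attention
network (GAT) per atlas — Dosenbach 160, AAL 116, Craddock 200 and
Harvard–Oxford 112 in the reference setup — and combines their
predictions by majority voting or (weighted) probability sums. It is
aimed at researchers who have per-subject `T x N` ROI time-series
matrices from a multi-site collection and want a reproducible,
inspectable implementation of this ensemble pipeline, including its data
plumbing and a fully synthetic benchmark cohort.

## The method in brief

For each subject and atlas, the `T x N` series becomes a functional
connectivity network `B` with `b_ij = corr(y_i, y_j)` (Pearson),
Fisher-z transformed (`z = atanh(b)`); each ROI is a graph node with
feature vector = its FCN row, connected to its `k` strongest-|z|
neighbours (undirected union, weighted adjacency). A 3-layer GAT with
4 concatenated attention heads per layer computes

    e_ij   = LeakyReLU(a^T [W h_i || W h_j])
    α_ij   = softmax_j(e_ij)           (over the neighbourhood of i)
    h'_i   = σ(Σ_j α_ij W h_j)

followed by global average pooling `h_G = (1/N) Σ_i h_i`, a fully
connected layer and a softmax. Models train with Adam (batch 16, lr
1e-3, weight decay 5e-4, dropout 0.5) on cross-entropy.

Around the classifier sit the stages multi-site clinical data need:
ComBat harmonization (`y = α + Xβ + γ_site + δ_site ε`, empirical-Bayes
shrinkage of site effects, age/sex retained), class-wise SMOTE on the
time series (`Z = X_0 + (X − X_0) · gap`, one gap per time-point row,
k = 3 neighbours, doubling train and validation sets only), stratified
80/10/10 splits and stratified 10-fold cross-validation with accuracy,
sensitivity, specificity, precision and F1 (MDD positive). Ensemble
weights are validation accuracies, `w_j = Acc_j / Σ Acc_i`; 2–2 voting
ties go to the most accurate model.

Because the motivating clinical dataset is access-restricted, the
package includes a generator for multi-site two-class cohorts whose
class signal lives in inter-ROI correlation structure, with known site
effects and covariate effects — every pipeline stage is tested against
this ground truth.

## Worked example

Simulate a small separable two-site cohort with two toy atlases, run the
cross-validated pipeline, and inspect the fold summary:

```r
library(magat)

sp <- simulation_spec(
  n_sites = 2, subjects_per_site_per_class = 15, t_points = 60,
  atlases = list(atlas_spec("toyA", 12), atlas_spec("toyB", 16)),
  n_modules = 3, class_effect = 0.6, class_pair_frac = 0.2,
  site_gamma_sd = 0.3, site_delta_range = c(0.8, 1.25), seed = 7)
sim <- simulate_cohort(sp)
sim$cohort
#> <cohort> 60 subjects (30 MDD / 30 HC, 0 synthetic), T = 60
#>   atlas toyA: 12 ROIs
#>   atlas toyB: 16 ROIs
#>   sites: site01, site02

cfg <- pipeline_config(hidden_units = 16, n_heads = 4, knn_k = 4,
                       smote_k = 2, max_epochs = 30, patience = 10,
                       dropout_rate = 0.2, n_folds = 3, seed = 1)
cv <- run_pipeline(cfg, sim$cohort)
cv
#> <cv_summary> 3 folds
#>         model mean.acc  sd.acc mean.sen sd.sen mean.spe sd.spe mean.pre  sd.pre mean.f1   sd.f1
#>          toyA   0.6667 0.12583        1      0   0.3333 0.2517   0.6096 0.09579  0.7546 0.07283
#>          toyB   0.8000 0.05000        1      0   0.6000 0.1000   0.7167 0.05133  0.8343 0.03479
#>      majority   0.7333 0.07638        1      0   0.4667 0.1528   0.6564 0.06365  0.7914 0.04690
#>           sum   0.7000 0.13229        1      0   0.4000 0.2646   0.6358 0.09772  0.7743 0.07520
#>  weighted_sum   0.7167 0.10408        1      0   0.4333 0.2082   0.6455 0.08145  0.7825 0.06141
```

Each row is one model: the two single-atlas GATs and the three ensemble
rules, with mean ± SD of the five metrics over the stratified folds. At
this deliberately small scale (20 test subjects per fold) the
connectivity signal planted in the generator is recovered well above
chance, sensitivity saturates before specificity — the positive-class
tie-breaking is sensitivity-favouring by design — and the ensembles sit
between the weaker and stronger atlas; with more atlases and subjects
the ensemble moves ahead of every single-atlas model (the acceptance
checks demonstrate this on a four-atlas, 120-subject benchmark over 20
seeds). `cv$folds` holds per-fold confusion counts; `cv$best_fold`
names the best fold per model.

The same stages are scriptable from a shell via the thin `mag` CLI
(`exec/mag`): `mag simulate`, `mag harmonize`, `mag oversample`,
`mag build-graphs`, `mag train`, `mag ensemble`, `mag evaluate`,
`mag run-all`, each taking `--config`/`--manifest`/`--series-dir`/
`--out`/`--seed`. Cohorts live on disk as a tab-delimited manifest plus
one `<subject>__<atlas>.tsv` series file per subject and atlas; graphs
export as 0-based edge lists with node-feature tables.

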