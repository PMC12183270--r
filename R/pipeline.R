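# End-to-end orchestration: harmonize -> split -> oversample -> FCN ->
# graphs -> per-atlas GAT training -> ensemble -> metrics.

fold_substream <- function(config, what, fold = NULL) {
  substream_seed(config$seed, paste0(what, if (!is.null(fold)) paste0("-", fold)))
}

records_by_id <- function(x, ids) subset_cohort(x, ids)$subjects

# Split a training pool 8:1 per class into train/val (the within-fold
# re-split applied before oversampling). `min_per_class` floors the
# validation class sizes so a subsequent SMOTE (k neighbours) stays
# feasible on small cohorts.
split_pool <- function(labels, ids, seed, val_frac = 1 / 9,
                       min_per_class = 1L) {
  train <- val <- character(0)
  withr::with_seed(seed, {
    for (lab in c(1L, 0L)) {
      class_ids <- sample(ids[labels == lab])
      n_val <- max(min_per_class, round(val_frac * length(class_ids)))
      if (n_val + min_per_class > length(class_ids))
        stopf("class %s: %d subjects cannot be split into train and validation",
              decode_label(lab), length(class_ids))
      val <- c(val, class_ids[seq_len(n_val)])
      train <- c(train, class_ids[(n_val + 1L):length(class_ids)])
    }
  })
  list(train = train, val = val)
}

# Train one GAT per atlas on (train, val) records and predict test
# probabilities; returns the prediction_set plus per-atlas fits.
train_atlas_models <- function(x, train_records, val_records, test_records,
                               config) {
  probs <- list()
  accs <- numeric(0)
  fits <- list()
  tmp <- x
  for (aname in names(x$atlases)) {
    tmp$subjects <- train_records
    train_graphs <- build_graph_dataset(tmp, aname, config$knn_k)
    tmp$subjects <- val_records
    val_graphs <- build_graph_dataset(tmp, aname, config$knn_k)
    tmp$subjects <- test_records
    test_graphs <- build_graph_dataset(tmp, aname, config$knn_k)
    fit <- train_gat(train_graphs, val_graphs, config, atlas = aname)
    fits[[aname]] <- fit
    probs[[aname]] <- predict_gat(fit, test_graphs)
    accs[aname] <- fit$val_accuracy
  }
  test_ids <- vapply(test_records, `[[`, "", "subject_id")
  list(preds = prediction_set(test_ids, probs, accs), fits = fits)
}

metric_row <- function(fold, model, truth, pred) {
  cc <- confusion_counts(truth, pred)
  data.frame(fold = fold, model = model, TP = cc$TP, TN = cc$TN,
             FP = cc$FP, FN = cc$FN, t(compute_metrics(cc)))
}

#' Single stratified split experiment
#'
#' One 80/10/10 stratified split, SMOTE on train and validation, one GAT
#' per atlas, and the three ensembles evaluated on the held-out real test
#' subjects. The building block of [run_pipeline()]'s cross-validation and
#' the cheapest way to benchmark a cohort.
#'
#' @param config a [pipeline_config()].
#' @param x a `cohort` of real subjects (harmonization is up to the
#'   caller here; [run_pipeline()] handles it).
#' @return List: `metrics` (one row per single-atlas model and ensemble
#'   method), `preds`, `fits`, `split`.
#' @export
run_split_experiment <- function(config, x) {
  plan <- stratified_split(x, seed = fold_substream(config, "split"))
  sm <- smote_spec(k_neighbors = config$smote_k,
                   multiplier = config$smote_multiplier,
                   seed = fold_substream(config, "smote"))
  aug <- oversample_split(records_by_id(x, plan$train),
                          records_by_id(x, plan$val), sm)
  test_records <- records_by_id(x, plan$test)
  fit <- train_atlas_models(x, aug$train, aug$val, test_records, config)
  truth <- vapply(test_records, `[[`, integer(1), "label")
  rows <- list()
  for (aname in names(x$atlases))
    rows[[aname]] <- metric_row(1L, aname, truth, fit$preds$hard_labels[[aname]])
  for (method in c("majority", "sum", "weighted_sum")) {
    res <- ensemble_predict(fit$preds, method)
    rows[[method]] <- metric_row(1L, method, truth, res$final_labels)
  }
  list(metrics = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       preds = fit$preds, fits = fit$fits, split = plan)
}

#' Run the full cross-validated pipeline
#'
#' Executes, in order: ComBat harmonization of the full cohort (when
#' enabled and more than one site is present), a stratified
#' `config$n_folds`-fold partition of the real subjects, and per fold: an
#' 8:1 per-class train/validation re-split of the non-test folds,
#' class-wise SMOTE of both sets, FCN/graph construction per atlas, one
#' GAT per atlas, and ensemble aggregation, scored on the held-out real
#' fold. Test folds never contain synthetic subjects. Fully reproducible
#' given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param x a `cohort` with at least `n_folds` subjects per class.
#' @return A `cv_summary` whose fold table has one row per fold per model
#'   (each atlas plus `majority`, `sum`, `weighted_sum`), with confusion
#'   counts and the five metrics.
#' @export
run_pipeline <- function(config, x) {
  stopifnot(inherits(config, "pipeline_config"), inherits(x, "cohort"))
  labs <- cohort_labels(x)
  if (sum(labs == 1L) < 2L || sum(labs == 0L) < 2L)
    stopf("run_pipeline needs >= 2 subjects per class")
  if (any(cohort_flags(x)))
    stopf("run_pipeline expects a cohort of real subjects")

  if (config$harmonize) {
    if (length(unique(cohort_sites(x))) >= 2L) {
      mag_log("stage harmonize: fitting ComBat on the full cohort")
      model <- fit_combat(x)
      x <- apply_combat(model, x)
    } else {
      mag_log("stage harmonize: single site, skipped")
    }
  }

  folds <- stratified_kfold(x, k = config$n_folds,
                            seed = fold_substream(config, "folds"))
  ids <- cohort_ids(x)
  rows <- list()
  for (f in seq_along(folds)) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stopf("fold %d, stage %s: %s", f, what, conditionMessage(e)))
    }
    pool_ids <- folds[[f]]$train_ids
    pool_labels <- labs[match(pool_ids, ids)]
    min_pc <- if (config$smote_multiplier > 1L) config$smote_k + 1L else 1L
    sp <- split_pool(pool_labels, pool_ids, fold_substream(config, "split", f),
                     min_per_class = min_pc)
    sm <- smote_spec(k_neighbors = config$smote_k,
                     multiplier = config$smote_multiplier,
                     seed = fold_substream(config, "smote", f))
    aug <- stage("oversample",
                 oversample_split(records_by_id(x, sp$train),
                                  records_by_id(x, sp$val), sm))
    test_records <- records_by_id(x, folds[[f]]$test_ids)
    stopifnot(!any(vapply(test_records, `[[`, logical(1), "is_synthetic")))
    fit <- stage("train",
                 train_atlas_models(x, aug$train, aug$val, test_records, config))
    truth <- vapply(test_records, `[[`, integer(1), "label")
    for (aname in names(x$atlases))
      rows[[length(rows) + 1L]] <-
        metric_row(f, aname, truth, fit$preds$hard_labels[[aname]])
    for (method in c("majority", "sum", "weighted_sum")) {
      res <- stage("ensemble", ensemble_predict(fit$preds, method))
      rows[[length(rows) + 1L]] <- metric_row(f, method, truth, res$final_labels)
    }
    mag_log(sprintf("fold %d/%d done", f, length(folds)))
  }
  summarize_cv(do.call(rbind, rows))
}
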