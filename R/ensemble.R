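# Ensemble aggregation of per-atlas model predictions: majority voting
# with an accuracy-based tie-break, plain probability sum, and
# validation-accuracy-weighted probability sum.

#' Bundle per-model predictions for ensembling
#'
#' @param subject_ids ordered subject ids, shared by all models.
#' @param probabilities named list, one `n x 2` matrix per model
#'   (columns HC, MDD; rows must sum to 1 within 1e-6).
#' @param val_accuracies named numeric vector of validation accuracies in
#'   `[0, 1]`, same names as `probabilities`; used for weights and
#'   tie-breaks. Accuracy ties fall back to list order, so pass models in
#'   the fixed atlas order (Dose, AAL, CK, HO).
#' @return A `prediction_set` with hard labels derived by argmax
#'   (probability ties -> MDD, the positive class).
#' @export
prediction_set <- function(subject_ids, probabilities, val_accuracies) {
  stopifnot(is.list(probabilities), length(probabilities) >= 1L)
  models <- names(probabilities)
  if (is.null(models) || any(!nzchar(models)))
    stopf("probabilities must be a named list (one entry per model)")
  if (!all(models %in% names(val_accuracies)))
    stopf("val_accuracies must cover every model")
  val_accuracies <- val_accuracies[models]
  if (any(val_accuracies < 0 | val_accuracies > 1))
    stopf("validation accuracies must lie in [0, 1]")
  n <- length(subject_ids)
  for (m in models) {
    p <- probabilities[[m]]
    if (nrow(p) != n || ncol(p) != 2L)
      stopf("model '%s': probability matrix must be %d x 2", m, n)
    if (any(abs(rowSums(p) - 1) > 1e-6))
      stopf("model '%s': probability rows must sum to 1", m)
  }
  hard <- lapply(probabilities, function(p) as.integer(p[, 2L] >= p[, 1L]))
  structure(list(subject_ids = as.character(subject_ids),
                 probabilities = probabilities, hard_labels = hard,
                 val_accuracies = val_accuracies, models = models),
            class = "prediction_set")
}

#' Majority-vote ensemble
#'
#' Each model casts its hard label as one vote; the final label is the
#' most frequent vote. With an even model count a tie (e.g. 2-2 with four
#' models) is broken by taking the vote of the model with the highest
#' validation accuracy (accuracy ties: first model in the fixed order).
#' Tie subjects are logged in the result.
#'
#' @param preds a [prediction_set()] with at least 2 models.
#' @return An `ensemble_result` with `method = "majority"`,
#'   `final_labels`, and `tie_log` (ids resolved by the tie-break).
#' @export
majority_vote <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  if (length(preds$models) < 2L) stopf("majority voting needs >= 2 models")
  votes <- do.call(cbind, preds$hard_labels)  # n x models
  pos <- rowSums(votes)
  neg <- ncol(votes) - pos
  best_model <- which.max(preds$val_accuracies)  # first max wins accuracy ties
  final <- ifelse(pos > neg, 1L,
                  ifelse(neg > pos, 0L, votes[, best_model]))
  ties <- preds$subject_ids[pos == neg]
  if (length(ties))
    mag_log(sprintf("%d tie(s) broken by model '%s' (highest validation accuracy)",
                    length(ties), preds$models[best_model]), "debug")
  structure(list(method = "majority", final_labels = as.integer(final),
                 final_probabilities = NULL, tie_log = ties,
                 subject_ids = preds$subject_ids),
            class = "ensemble_result")
}

#' Validation-accuracy ensemble weights
#'
#' `w_j = Acc_j / sum_i Acc_i`; weights sum to one.
#'
#' @param accs numeric accuracies in `[0, 1]`, not all zero.
#' @return Normalized weights, same names as `accs`.
#' @examples
#' ensemble_weights(c(Dose = 0.62, AAL = 0.64, CK = 0.65, HO = 0.61))
#' @export
ensemble_weights <- function(accs) {
  if (any(accs < 0 | accs > 1)) stopf("accuracies must lie in [0, 1]")
  s <- sum(accs)
  if (s <= 0) stopf("cannot weight models: all accuracies are zero")
  accs / s
}

#' Weighted-sum (soft-voting) ensemble
#'
#' Per subject, the models' class-probability vectors are combined as
#' `sum_j w_j p_j` and the class with the larger combined probability is
#' chosen; argmax ties go to MDD (the positive class) and are logged.
#' With `weights = NULL` the weights default to
#' `ensemble_weights(val_accuracies)` (the weighted-sum method); uniform
#' weights give the plain sum method, see [ensemble_predict()].
#'
#' @param preds a [prediction_set()].
#' @param weights optional weights, one per model (normalized internally).
#' @return An `ensemble_result` with combined probabilities (rows sum to
#'   1) and final labels.
#' @export
weighted_sum_vote <- function(preds, weights = NULL) {
  stopifnot(inherits(preds, "prediction_set"))
  if (is.null(weights)) weights <- ensemble_weights(preds$val_accuracies)
  if (length(weights) != length(preds$models))
    stopf("got %d weights for %d models", length(weights), length(preds$models))
  weights <- weights / sum(weights)
  comb <- Reduce(`+`, Map(function(p, w) p * w, preds$probabilities, weights))
  final <- as.integer(comb[, 2L] >= comb[, 1L])  # ties -> MDD
  ties <- preds$subject_ids[comb[, 2L] == comb[, 1L]]
  if (length(ties))
    mag_log(sprintf("%d argmax tie(s) resolved toward MDD", length(ties)), "debug")
  structure(list(method = "weighted_sum", final_labels = final,
                 final_probabilities = comb, weights = weights,
                 tie_log = ties, subject_ids = preds$subject_ids),
            class = "ensemble_result")
}

#' Run one of the three ensemble methods
#'
#' `"majority"` = hard voting with the accuracy tie-break, `"sum"` =
#' uniform-weight probability sum, `"weighted_sum"` = validation-accuracy
#' weights.
#'
#' @param preds a [prediction_set()].
#' @param method ensemble rule.
#' @return An `ensemble_result`.
#' @export
ensemble_predict <- function(preds, method = c("majority", "sum", "weighted_sum")) {
  method <- match.arg(method)
  out <- switch(method,
    majority = majority_vote(preds),
    sum = weighted_sum_vote(preds, rep(1, length(preds$models))),
    weighted_sum = weighted_sum_vote(preds)
  )
  out$method <- method
  out
}
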