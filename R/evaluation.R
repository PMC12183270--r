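# Splits, the five classification metrics, cross-validation aggregation
# and between-model significance testing.

#' Stratified train/validation/test split
#'
#' Per class with `n_c` subjects, the test set takes `ceil(f_test * n_c)`
#' subjects. Under the default `"reference"` allocation the validation set
#' takes `test - 1` subjects when `f_val * n_c` is an integer and
#' `floor(f_val * n_c)` otherwise — the rule that reproduces the
#' 649/80/81 (MDD, n = 810) and 602/75/76 (HC, n = 753) allocation of the
#' reference study; `"floor"` uses `floor(f_val * n_c)` throughout.
#' The remainder trains. Assignment is random under `seed`; synthetic
#' subjects are never assigned (split first, oversample after).
#'
#' @param labels integer class vector (1 = MDD, 0 = HC), or a `cohort`.
#' @param ids subject ids aligned with `labels` (ignored when `labels` is
#'   a cohort).
#' @param fractions train/val/test fractions summing to 1.
#' @param seed RNG seed for the shuffle.
#' @param val_rule `"reference"` (default) or `"floor"`.
#' @return A `split_plan`: lists `train`, `val`, `test` of subject ids,
#'   plus the per-class count table.
#' @export
stratified_split <- function(labels, ids = NULL, fractions = c(0.8, 0.1, 0.1),
                             seed = 1L, val_rule = c("reference", "floor")) {
  val_rule <- match.arg(val_rule)
  if (inherits(labels, "cohort")) {
    if (any(cohort_flags(labels)))
      stopf("split synthetic-free data only; oversample after splitting")
    ids <- cohort_ids(labels)
    labels <- cohort_labels(labels)
  }
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  labels <- encode_label(labels)
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3L)
    stopf("fractions must be three numbers summing to 1")
  f_val <- fractions[2L]; f_test <- fractions[3L]
  train <- val <- test <- character(0)
  counts <- list()
  withr::with_seed(as.integer(seed), {
    for (lab in c(1L, 0L)) {
      class_ids <- ids[labels == lab]
      n_c <- length(class_ids)
      n_test <- ceiling(f_test * n_c)
      n_val <- if (val_rule == "reference" && is_wholenumber(f_val * n_c))
        n_test - 1L
      else
        floor(f_val * n_c)
      n_train <- n_c - n_test - n_val
      if (n_train < 1L || n_val < 1L || n_test < 1L)
        stopf("class %s (n = %d): a partition would be empty", decode_label(lab), n_c)
      perm <- sample(class_ids)
      test <- c(test, perm[seq_len(n_test)])
      val <- c(val, perm[n_test + seq_len(n_val)])
      train <- c(train, perm[(n_test + n_val + 1L):n_c])
      counts[[decode_label(lab)]] <- c(train = n_train, val = n_val, test = n_test)
    }
  })
  structure(list(train = train, val = val, test = test,
                 counts = do.call(rbind, counts), val_rule = val_rule),
            class = "split_plan")
}

#' Stratified k-fold partition
#'
#' Shuffles each class under `seed` and deals it round-robin over `k`
#' folds, so per-class fold sizes differ by at most one.
#'
#' @param labels integer class vector or a `cohort`.
#' @param ids subject ids aligned with `labels`.
#' @param k number of folds; every class must have at least `k` subjects.
#' @param seed RNG seed.
#' @return List of `k` elements, each with `train_ids` and `test_ids`;
#'   the test sets partition the subjects.
#' @export
stratified_kfold <- function(labels, ids = NULL, k = 10L, seed = 1L) {
  if (inherits(labels, "cohort")) {
    ids <- cohort_ids(labels)
    labels <- cohort_labels(labels)
  }
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  labels <- encode_label(labels)
  k <- as.integer(k)
  fold_of <- integer(length(ids))
  withr::with_seed(as.integer(seed), {
    for (lab in c(1L, 0L)) {
      idx <- which(labels == lab)
      if (length(idx) < k)
        stopf("class %s has %d subjects, fewer than k = %d",
              decode_label(lab), length(idx), k)
      fold_of[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f)
    list(train_ids = ids[fold_of != f], test_ids = ids[fold_of == f]))
}

#' Confusion counts from labels
#'
#' @param truth,pred integer vectors (1 = MDD positive, 0 = HC negative).
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- encode_label(truth); pred <- encode_label(pred)
  stopifnot(length(truth) == length(pred))
  structure(list(TP = sum(truth == 1L & pred == 1L),
                 TN = sum(truth == 0L & pred == 0L),
                 FP = sum(truth == 0L & pred == 1L),
                 FN = sum(truth == 1L & pred == 0L)),
            class = "confusion_counts")
}

#' The five classification metrics
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` and F1
#' `2*Pre*Sen/(Pre+Sen)`, with MDD as the positive class. Undefined
#' ratios (zero denominators) return 0 with a warning.
#'
#' @param counts a [confusion_counts()] (or list with TP/TN/FP/FN).
#' @return Named numeric vector `acc`, `sen`, `spe`, `pre`, `f1`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0) stopf("empty confusion matrix")
  guard <- function(num, den, what) {
    if (den == 0) {
      warnf("%s undefined (zero denominator); returning 0", what)
      return(0)
    }
    num / den
  }
  acc <- (tp + tn) / total
  sen <- guard(tp, tp + fn, "sensitivity")
  spe <- guard(tn, tn + fp, "specificity")
  pre <- guard(tp, tp + fp, "precision")
  f1 <- if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen)
  c(acc = acc, sen = sen, spe = spe, pre = pre, f1 = f1)
}

#' Aggregate per-fold metric reports
#'
#' @param fold_reports data frame with a `fold` column, an optional
#'   `model` column, and the five metric columns; or a list of metric
#'   vectors from [compute_metrics()].
#' @return A `cv_summary`: the per-fold table, per-model mean and sample
#'   SD of each metric, and `best_fold` (highest accuracy, ties to the
#'   lowest fold index) per model.
#' @export
summarize_cv <- function(fold_reports) {
  metrics <- c("acc", "sen", "spe", "pre", "f1")
  if (!is.data.frame(fold_reports)) {
    fold_reports <- data.frame(fold = seq_along(fold_reports),
                               do.call(rbind, fold_reports))
  }
  if (nrow(fold_reports) < 2L) stopf("need >= 2 folds to summarize")
  if (!"model" %in% names(fold_reports)) fold_reports$model <- "model"
  models <- unique(fold_reports$model)
  summary <- do.call(rbind, lapply(models, function(m) {
    sub <- fold_reports[fold_reports$model == m, , drop = FALSE]
    data.frame(model = m, metric = metrics,
               mean = vapply(metrics, function(x) mean(sub[[x]]), numeric(1)),
               sd = vapply(metrics, function(x) stats::sd(sub[[x]]), numeric(1)),
               row.names = NULL)
  }))
  best_fold <- vapply(models, function(m) {
    sub <- fold_reports[fold_reports$model == m, , drop = FALSE]
    sub$fold[which.max(sub$acc)]  # which.max takes the first (lowest) index
  }, numeric(1))
  structure(list(folds = fold_reports, summary = summary,
                 best_fold = best_fold),
            class = "cv_summary")
}

#' @method print cv_summary
#' @export
print.cv_summary <- function(x, ...) {
  cat("<cv_summary>", length(unique(x$folds$fold)), "folds\n")
  wide <- stats::reshape(x$summary, idvar = "model", timevar = "metric",
                         direction = "wide")
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-metric significance tests between two models
#'
#' Two-sided independent two-sample t-tests across folds for each metric
#' (equal-variance by default; `welch = TRUE` drops that assumption).
#' Identical constant fold vectors (zero pooled variance, equal means)
#' return p = 1 by convention.
#'
#' @param reports_a,reports_b per-fold metric data frames (columns `acc`,
#'   `sen`, `spe`, `pre`, `f1`), at least 2 folds each.
#' @param alpha significance threshold for the flag column.
#' @param welch use Welch's unequal-variance test.
#' @return Data frame: metric, t, p, significant.
#' @export
compare_models <- function(reports_a, reports_b, alpha = 0.05, welch = FALSE) {
  metrics <- c("acc", "sen", "spe", "pre", "f1")
  stopifnot(all(metrics %in% names(reports_a)), all(metrics %in% names(reports_b)))
  if (nrow(reports_a) < 2L || nrow(reports_b) < 2L) stopf("need >= 2 folds per model")
  rows <- lapply(metrics, function(m) {
    a <- reports_a[[m]]; b <- reports_b[[m]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      return(data.frame(metric = m, t = 0, p = 1, significant = FALSE))
    }
    tt <- stats::t.test(a, b, var.equal = !welch)
    data.frame(metric = m, t = unname(tt$statistic), p = tt$p.value,
               significant = tt$p.value < alpha)
  })
  do.call(rbind, rows)
}
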