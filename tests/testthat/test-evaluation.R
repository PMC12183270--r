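# Splits, metrics, CV aggregation and model comparison.

test_that("stratified 80/10/10 split reproduces the reference class allocation", {
  labels <- c(rep(1L, 810), rep(0L, 753))
  ids <- sprintf("s%04d", seq_along(labels))
  plan <- stratified_split(labels, ids, seed = 1)
  expect_equal(plan$counts["MDD", ], c(train = 649, val = 80, test = 81))
  expect_equal(plan$counts["HC", ], c(train = 602, val = 75, test = 76))
  expect_length(plan$test, 157)
  # disjoint and exhaustive
  all_ids <- c(plan$train, plan$val, plan$test)
  expect_identical(sort(all_ids), ids)
  # determinism and seed sensitivity
  expect_identical(plan, stratified_split(labels, ids, seed = 1))
  expect_false(identical(plan$test, stratified_split(labels, ids, seed = 2)$test))
})

test_that("the floor allocation rule is available as an override", {
  labels <- c(rep(1L, 100), rep(0L, 100))
  ref <- stratified_split(labels, seed = 3)              # val = test - 1
  flo <- stratified_split(labels, seed = 3, val_rule = "floor")
  expect_equal(unname(ref$counts[, "val"]), c(9, 9))
  expect_equal(unname(flo$counts[, "val"]), c(10, 10))
  expect_equal(unname(flo$counts[, "train"]), c(80, 80))
  expect_error(stratified_split(c(1L, 0L)), "empty")
})

test_that("stratified k-fold partitions each class evenly", {
  labels <- c(rep(1L, 50), rep(0L, 50))
  folds <- stratified_kfold(labels, k = 10, seed = 5)
  test_sets <- lapply(folds, `[[`, "test_ids")
  expect_length(unlist(test_sets), 100)
  expect_false(anyDuplicated(unlist(test_sets)) > 0)
  for (f in folds) {
    expect_length(f$test_ids, 10)
    expect_equal(sum(as.integer(f$test_ids) <= 50), 5)  # 5 MDD per fold
    expect_setequal(c(f$train_ids, f$test_ids), as.character(1:100))
  }
  # uneven classes: per-class fold sizes differ by at most one
  labels2 <- c(rep(1L, 810), rep(0L, 753))
  folds2 <- stratified_kfold(labels2, k = 10, seed = 6)
  per_fold_mdd <- vapply(folds2, function(f)
    sum(as.integer(f$test_ids) <= 810), integer(1))
  per_fold_hc <- vapply(folds2, function(f)
    sum(as.integer(f$test_ids) > 810), integer(1))
  expect_lte(diff(range(per_fold_mdd)), 1)
  expect_lte(diff(range(per_fold_hc)), 1)
  expect_error(stratified_kfold(c(rep(1L, 5), rep(0L, 50)), k = 10), "fewer")
})

test_that("the five metrics follow their defining formulas", {
  m <- compute_metrics(list(TP = 72, TN = 47, FP = 29, FN = 9))
  expect_equal(unname(round(m, 4)),
               c(0.7580, 0.8889, 0.6184, 0.7129, 0.7912))
  perfect <- compute_metrics(list(TP = 10, TN = 20, FP = 0, FN = 0))
  expect_equal(unname(perfect), rep(1, 5))
  suppressWarnings(worst <- compute_metrics(list(TP = 0, TN = 0, FP = 5, FN = 5)))
  expect_equal(unname(worst), rep(0, 5))
  expect_warning(compute_metrics(list(TP = 0, TN = 5, FP = 0, FN = 5)),
                 "precision")
})

test_that("metric identities hold over random confusion matrices", {
  withr::local_seed(7)
  for (i in 1:200) {
    cc <- list(TP = sample(0:50, 1), TN = sample(0:50, 1),
               FP = sample(0:50, 1), FN = sample(0:50, 1))
    if (sum(unlist(cc)) == 0) next
    m <- suppressWarnings(compute_metrics(cc))
    P <- cc$TP + cc$FN
    N <- cc$TN + cc$FP
    if (P > 0 && N > 0)
      expect_equal(m[["acc"]], (m[["sen"]] * P + m[["spe"]] * N) / (P + N),
                   tolerance = 1e-12)
    if (m[["pre"]] > 0 && m[["sen"]] > 0)
      expect_equal(m[["f1"]],
                   2 / (1 / m[["pre"]] + 1 / m[["sen"]]), tolerance = 1e-12)
  }
})

test_that("confusion_counts cross-tabulates correctly", {
  cc <- confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 2, TN = 1, FP = 1, FN = 1))
})

test_that("summarize_cv computes mean, sample SD and best fold", {
  reps <- data.frame(fold = 1:2, acc = c(0.6, 0.8), sen = c(0.5, 0.7),
                     spe = c(0.7, 0.9), pre = c(0.6, 0.8), f1 = c(0.55, 0.75))
  cv <- summarize_cv(reps)
  acc_row <- cv$summary[cv$summary$metric == "acc", ]
  expect_equal(acc_row$mean, 0.7)
  expect_equal(acc_row$sd, sd(c(0.6, 0.8)))
  expect_equal(round(acc_row$sd, 4), 0.1414)
  expect_equal(unname(cv$best_fold), 2)
  # identical folds: SD zero, best fold is the first
  same <- reps; same$acc <- 0.7
  cv2 <- summarize_cv(same)
  expect_equal(cv2$summary$sd[cv2$summary$metric == "acc"], 0)
  expect_equal(unname(cv2$best_fold), 1)
  # agreement with direct mean/SD on random reports
  withr::local_seed(8)
  rnd <- data.frame(fold = 1:10, acc = runif(10), sen = runif(10),
                    spe = runif(10), pre = runif(10), f1 = runif(10))
  cv3 <- summarize_cv(rnd)
  for (m in c("acc", "sen", "spe", "pre", "f1")) {
    expect_equal(cv3$summary$mean[cv3$summary$metric == m], mean(rnd[[m]]),
                 tolerance = 1e-12)
    expect_equal(cv3$summary$sd[cv3$summary$metric == m], sd(rnd[[m]]),
                 tolerance = 1e-12)
  }
})

test_that("compare_models runs equal-variance t-tests with conventions", {
  mk <- function(acc) data.frame(acc = acc, sen = acc, spe = acc,
                                 pre = acc, f1 = acc)
  # identical constant vectors -> p = 1 convention
  same <- compare_models(mk(rep(0.9, 5)), mk(rep(0.9, 5)))
  expect_equal(same$p, rep(1, 5))
  expect_false(any(same$significant))
  # clearly separated vectors with jitter -> tiny p, symmetric in order
  withr::local_seed(9)
  a <- mk(0.9 + rnorm(5, 0, 0.002))
  b <- mk(0.5 + rnorm(5, 0, 0.002))
  ab <- compare_models(a, b)
  expect_true(all(ab$p < 1e-3))
  expect_true(all(ab$significant))
  ba <- compare_models(b, a)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  # agreement with stats::t.test directly
  direct <- t.test(a$acc, b$acc, var.equal = TRUE)$p.value
  expect_equal(ab$p[ab$metric == "acc"], direct, tolerance = 1e-12)
  welch <- compare_models(a, b, welch = TRUE)
  expect_equal(welch$p[welch$metric == "acc"],
               t.test(a$acc, b$acc)$p.value, tolerance = 1e-12)
})
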