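# ComBat fitting, application, recovery of known site effects, and
# agreement with the reference implementation.

test_that("one site duplicated under two labels gives null additive effects", {
  x <- toy_cohort(seed = 71, n_sites = 1, per_class = 10,
                  site_gamma_sd = 0, site_delta_range = c(1, 1))
  # duplicate every subject verbatim under a second site label: both
  # "sites" carry literally identical data, so there is no batch effect
  dup <- lapply(x$subjects, function(s) {
    s$subject_id <- paste0(s$subject_id, "_copy")
    s$site_id <- "siteB"
    s
  })
  x$subjects <- c(lapply(x$subjects, function(s) { s$site_id <- "siteA"; s }),
                  dup)
  x <- validate_cohort(x)
  fit <- fit_combat(x)
  n_site <- length(x$subjects) / 2
  expect_lt(max(abs(fit$gamma_star)), 1e-8)
  # the scale estimate carries only the n/(n-1) small-sample factor of
  # the per-site variance, identical for both sites and every feature
  expect_equal(unname(as.vector(fit$delta_star)),
               rep(sqrt(n_site / (n_site - 1)), length(fit$delta_star)),
               tolerance = 1e-6)
  # application changes the data only by that uniform scale factor
  h <- apply_combat(fit, x)
  dev <- abs(magat:::flatten_series(h) - magat:::flatten_series(x))
  expect_lt(max(dev / (abs(magat:::flatten_series(x)) + 1)), 0.05)
})

test_that("known gamma and delta are recovered on a 3-site cohort", {
  sp <- simulation_spec(
    n_sites = 3, subjects_per_site_per_class = 20, t_points = 20,
    atlases = list(atlas_spec("toy", 8)), n_modules = 2,
    class_effect = 0, site_gamma_sd = 2.0, site_delta_range = c(0.5, 1.9),
    beta_age = 0, beta_sex = 0, noise_sd = 0.1, seed = 81)
  sim <- simulate_cohort(sp)
  fit <- fit_combat(sim$cohort)
  truth_gamma <- sim$truth$toy$gamma[fit$sites, , drop = FALSE]
  truth_delta <- sim$truth$toy$delta[fit$sites, , drop = FALSE]
  # estimates live on the standardized scale; compare after rescaling
  est_gamma <- fit$gamma_star * rep(fit$pooled_sd, each = nrow(fit$gamma_star))
  # additive effects: centered per feature (the grand mean absorbs the
  # feature-wise mean of gamma), so compare centered values
  tg <- sweep(truth_gamma, 2, colMeans(truth_gamma))
  eg <- sweep(est_gamma, 2, colMeans(est_gamma))
  expect_gt(cor(as.vector(tg), as.vector(eg)), 0.9)
  expect_lt(mean(abs(tg - eg)), 0.1 * 2.0)  # MAE below 0.1 * site_gamma_sd
  # multiplicative effects back on the raw scale: delta* x pooled SD
  est_delta <- fit$delta_star * rep(fit$pooled_sd, each = nrow(fit$delta_star))
  expect_gt(cor(as.vector(truth_delta), as.vector(est_delta)), 0.9)
})

test_that("disabling shrinkage reproduces plain per-site mean/variance estimates", {
  x <- toy_cohort(seed = 91, per_class = 6)
  fit <- fit_combat(x, eb = FALSE)
  expect_identical(fit$gamma_star, fit$gamma_hat)
  expect_identical(fit$delta_star, fit$delta_hat)
  # and the hat estimates really are the site means/SDs of standardized data
  flat <- magat:::flatten_series(x)
  age <- vapply(x$subjects, `[[`, numeric(1), "age")
  sex <- vapply(x$subjects, `[[`, integer(1), "sex")
  sites <- cohort_sites(x)
  design <- model.matrix(~ 0 + factor(sites) + scale(age)[, 1] + sex)
  bh <- solve(crossprod(design), t(design) %*% t(flat))
  n_b <- length(unique(sites))
  resid <- flat - t(design %*% bh)
  var_pooled <- rowMeans(resid^2)
  n_per <- table(factor(sites))[sort(unique(sites))]
  grand <- drop(crossprod(as.numeric(n_per) / ncol(flat), bh[seq_len(n_b), ]))
  covpart <- t(design[, -(seq_len(n_b)), drop = FALSE] %*%
                 bh[-(seq_len(n_b)), , drop = FALSE])
  s_data <- (flat - grand - covpart) / sqrt(var_pooled)
  s1 <- sort(unique(sites))[1]
  expect_equal(unname(fit$gamma_hat[1, ]),
               unname(rowMeans(s_data[, sites == s1])), tolerance = 1e-8)
  expect_equal(unname(fit$delta_hat[1, ]),
               unname(apply(s_data[, sites == s1], 1, sd)), tolerance = 1e-8)
})

test_that("harmonization agrees with the sva reference implementation", {
  skip_if_not_installed("sva")
  x <- toy_cohort(seed = 5, per_class = 6, site_gamma_sd = 0.6,
                  site_delta_range = c(0.7, 1.4))
  h <- apply_combat(fit_combat(x), x)
  flat <- magat:::flatten_series(x)
  age <- vapply(x$subjects, `[[`, numeric(1), "age")
  sex <- vapply(x$subjects, `[[`, integer(1), "sex")
  mod <- stats::model.matrix(~ scale(age) + sex)
  oracle <- suppressMessages(
    sva::ComBat(dat = flat, batch = cohort_sites(x), mod = mod))
  expect_equal(magat:::flatten_series(h), oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("between-site F statistics collapse after harmonization", {
  sim <- simulate_cohort(toy_sim_spec(seed = 7, per_class = 8,
                                      site_gamma_sd = 0.8,
                                      site_delta_range = c(0.6, 1.5)))
  f0 <- empirical_site_effect(sim$cohort)$f_stat
  h <- apply_combat(fit_combat(sim$cohort), sim$cohort)
  f1 <- empirical_site_effect(h)$f_stat
  expect_gt(mean(1 - f1 / f0), 0.8)  # >= 80% reduction on average
  expect_gt(mean(f1 < f0), 0.95)
})

test_that("subjects identical except for site move closer after harmonization", {
  x <- toy_cohort(seed = 13, per_class = 6, site_gamma_sd = 1.0,
                  site_delta_range = c(0.5, 1.9))
  fit <- fit_combat(x)
  h <- apply_combat(fit, x)
  sites <- cohort_sites(x)
  labs <- cohort_labels(x)
  i <- which(sites == "site01" & labs == 1L)[1]
  j <- which(sites == "site02" & labs == 1L)[1]
  d_raw <- sqrt(sum((magat:::flatten_series(x)[, i] -
                       magat:::flatten_series(x)[, j])^2))
  d_adj <- sqrt(sum((magat:::flatten_series(h)[, i] -
                       magat:::flatten_series(h)[, j])^2))
  expect_lt(d_adj, d_raw)
})

test_that("refitting on harmonized data finds near-null site effects", {
  # shrinkage leftovers scale like 1/(n * tau^2), so the 1e-2 tolerance
  # is a large-site property: 200 subjects per site here
  sp <- simulation_spec(
    n_sites = 3, subjects_per_site_per_class = 100, t_points = 8,
    atlases = list(atlas_spec("toy", 6)), n_modules = 2,
    class_effect = 0, site_gamma_sd = 1.5, site_delta_range = c(0.7, 1.4),
    beta_age = 0, beta_sex = 0, noise_sd = 0.1, seed = 17)
  x <- simulate_cohort(sp)$cohort
  h <- apply_combat(fit_combat(x), x)
  refit <- fit_combat(h)
  expect_lt(max(abs(refit$gamma_star)), 1e-2)
  expect_lt(max(abs(refit$delta_star - 1)), 1e-2)
})

test_that("covariate effects survive harmonization", {
  sp <- simulation_spec(
    n_sites = 3, subjects_per_site_per_class = 12, t_points = 12,
    atlases = list(atlas_spec("toy", 6)), n_modules = 2,
    class_effect = 0, site_gamma_sd = 0.6, site_delta_range = c(0.8, 1.3),
    beta_age = 0.05, beta_sex = 0.5, noise_sd = 0.1, seed = 23)
  sim <- simulate_cohort(sp)
  x <- sim$cohort
  h <- apply_combat(fit_combat(x), x)
  age <- vapply(x$subjects, `[[`, numeric(1), "age")
  slope <- function(co) {
    v <- colMeans(magat:::flatten_series(co))  # mean feature per subject
    stats::coef(stats::lm(v ~ age))[["age"]]
  }
  s_raw <- slope(x)
  s_adj <- slope(h)
  expect_gt(s_raw, 0)
  expect_lt(abs(s_adj - s_raw) / abs(s_raw), 0.05)
})

test_that("precondition violations error cleanly", {
  x <- toy_cohort(seed = 3, per_class = 4)
  one <- x
  one$subjects <- lapply(one$subjects, function(s) { s$site_id <- "s"; s })
  expect_error(fit_combat(one), "2 sites")
  lone <- x
  lone$subjects[[1]]$site_id <- "lonely"
  expect_error(fit_combat(lone), "single subject")
  fit <- fit_combat(x)
  y <- x
  y$subjects[[1]]$site_id <- "new_site"
  expect_error(apply_combat(fit, y), "not seen")
})
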