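# Location/scale (ComBat) harmonization of cohort features across sites,
# with parametric empirical-Bayes shrinkage of the per-site additive
# (gamma) and multiplicative (delta) effects and preservation of age/sex
# covariate effects. Fitting and application are separated so a model fit
# on one cohort can be applied to another cohort from the same sites.

#' Fit a ComBat harmonization model
#'
#' Each (atlas, time point, ROI) entry is treated as one feature observed
#' once per subject (`feature_mode = "timepoint"`, the default); with
#' `feature_mode = "roi"` each (atlas, ROI) stream is one feature observed
#' at every time point instead. Per feature, a grand intercept and age/sex
#' coefficients are estimated by pooled least squares, residuals are
#' standardized by the pooled SD, per-site additive and multiplicative
#' effects are estimated from the standardized data, and (when `eb`) are
#' shrunk by parametric empirical Bayes: a normal prior on the additive
#' effect and an inverse-gamma prior on the squared multiplicative effect,
#' with moment-matched hyperpriors and iterative conditional updates to
#' convergence.
#'
#' Zero-variance features are flagged and passed through unharmonized.
#' Age enters the design matrix standardized (fit-time mean/SD); sex
#' enters as 0/1.
#'
#' @param x a `cohort` with at least 2 sites and at least 2 subjects per
#'   site.
#' @param covariates character subset of `c("age", "sex")` to retain as
#'   biological covariates.
#' @param eb apply empirical-Bayes shrinkage (disable to get plain
#'   per-site mean/variance estimates).
#' @param feature_mode `"timepoint"` or `"roi"` (see above).
#' @param tol,max_iter convergence control for the EB updates.
#' @return A `harmonization_model` with per-feature `alpha_hat`,
#'   `beta_hat`, `pooled_sd`, per-site `gamma_star`/`delta_star`
#'   (delta on the SD scale, strictly positive), the feature index, and
#'   bookkeeping needed by [apply_combat()].
#' @references Johnson, W.E., Li, C., Rabinovic, A. (2007) Adjusting batch
#'   effects in microarray expression data using empirical Bayes methods.
#'   Biostatistics 8(1), 118-127.
#' @export
fit_combat <- function(x, covariates = c("age", "sex"), eb = TRUE,
                       feature_mode = c("timepoint", "roi"),
                       tol = 1e-4, max_iter = 100L) {
  stopifnot(inherits(x, "cohort"))
  feature_mode <- match.arg(feature_mode)
  covariates <- match.arg(covariates, c("age", "sex"), several.ok = TRUE)
  sites <- cohort_sites(x)
  usites <- sort(unique(sites))
  if (length(usites) < 2L) stopf("ComBat needs >= 2 sites")
  n_per <- vapply(usites, function(s) sum(sites == s), integer(1))
  if (any(n_per < 2L))
    stopf("site(s) with a single subject (variance undefined): %s",
          paste(usites[n_per < 2L], collapse = ", "))

  age <- vapply(x$subjects, `[[`, numeric(1), "age")
  sex <- vapply(x$subjects, `[[`, integer(1), "sex")
  age_mean <- mean(age)
  age_sd <- stats::sd(age)
  if (!is.finite(age_sd) || age_sd == 0) age_sd <- 1

  flat <- flatten_series(x)  # (atlas, t, roi) x subject
  if (feature_mode == "timepoint") {
    y <- flat
    obs_subject <- seq_len(ncol(flat))
  } else {
    # feature = (atlas, roi); observations = subject x time point
    idx <- feature_index(x)
    key <- paste(idx$atlas, idx$roi)
    streams <- unique(key)
    y <- t(vapply(streams, function(sk) {
      as.vector(flat[key == sk, , drop = FALSE])  # t fastest, then subject
    }, numeric(x$t_points * ncol(flat))))
    obs_subject <- rep(seq_len(ncol(flat)), each = x$t_points)
  }

  batch <- sites[obs_subject]
  design_cov <- cbind(
    age = if ("age" %in% covariates) (age - age_mean) / age_sd else NULL,
    sex = if ("sex" %in% covariates) as.numeric(sex) else NULL
  )
  xcov <- if (is.null(design_cov)) matrix(0, length(obs_subject), 0L)
          else design_cov[obs_subject, , drop = FALSE]

  core <- combat_fit_core(y, batch, xcov, usites, eb = eb,
                          tol = tol, max_iter = max_iter)

  structure(list(
    feature_mode = feature_mode, covariates = covariates,
    sites = usites, age_mean = age_mean, age_sd = age_sd,
    alpha_hat = core$alpha_hat, beta_hat = core$beta_hat,
    pooled_sd = core$pooled_sd, gamma_star = core$gamma_star,
    delta_star = core$delta_star, gamma_hat = core$gamma_hat,
    delta_hat = core$delta_hat, zero_var = core$zero_var,
    eb = eb, feature_index = feature_index(x), t_points = x$t_points,
    atlas_rois = vapply(x$atlases, `[[`, integer(1), "n_rois")
  ), class = "harmonization_model")
}

# Core location/scale EB fit on a features x observations matrix.
# Follows the standard parametric ComBat estimator: pooled OLS for
# intercept + covariates with explicit batch indicators, grand mean as the
# sample-size-weighted mean of batch intercepts, pooled variance across
# all observations, moment-matched normal / inverse-gamma hyperpriors and
# iterative conditional posterior updates.
combat_fit_core <- function(y, batch, xcov, usites, eb, tol, max_iter) {
  n_obs <- ncol(y)
  batch_design <- stats::model.matrix(~ 0 + factor(batch, levels = usites))
  colnames(batch_design) <- usites
  design <- cbind(batch_design, xcov)
  n_batch <- length(usites)
  n_per <- colSums(batch_design)

  zero_var <- apply(y, 1L, stats::var) == 0
  b_hat <- solve(crossprod(design), t(design) %*% t(y))  # p x G
  grand_mean <- crossprod(n_per / n_obs, b_hat[seq_len(n_batch), , drop = FALSE])
  var_pooled <- rowMeans((y - t(design %*% b_hat))^2)
  var_pooled[zero_var | var_pooled == 0] <- 1  # passthrough features

  stand_mean <- matrix(grand_mean, nrow(y), n_obs)
  if (ncol(xcov) > 0L) {
    tmp <- design
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% b_hat)
  }
  s_data <- (y - stand_mean) / sqrt(var_pooled)

  gamma_hat <- matrix(NA_real_, n_batch, nrow(y), dimnames = list(usites, NULL))
  delta_hat <- gamma_hat
  for (i in seq_len(n_batch)) {
    cols <- batch == usites[i]
    gamma_hat[i, ] <- rowMeans(s_data[, cols, drop = FALSE])
    delta_hat[i, ] <- apply(s_data[, cols, drop = FALSE], 1L, stats::var)
  }
  delta_hat[delta_hat == 0] <- 1e-12

  if (eb) {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (i in seq_len(n_batch)) {
      g <- gamma_hat[i, ]; d <- delta_hat[i, ]
      g_bar <- mean(g); t2 <- stats::var(g)
      m <- mean(d); s2 <- stats::var(d)
      if (t2 < 1e-12 || s2 < 1e-12) {
        # degenerate hyperpriors (e.g. constant estimates across features):
        # moment matching is undefined, fall back to the raw estimates
        gamma_star[i, ] <- g
        delta_star[i, ] <- d
        next
      }
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      cols <- s_data[, batch == usites[i], drop = FALSE]
      n_i <- ncol(cols)
      g_old <- g; d_old <- d
      for (it in seq_len(max_iter)) {
        g_new <- (n_i * t2 * g + d_old * g_bar) / (n_i * t2 + d_old)
        sum2 <- rowSums((cols - g_new)^2)
        d_new <- (0.5 * sum2 + b_prior) / (n_i / 2 + a_prior - 1)
        change <- max(abs(g_new - g_old) / abs(g_old),
                      abs(d_new - d_old) / abs(d_old), na.rm = TRUE)
        g_old <- g_new; d_old <- d_new
        if (change < tol) break
      }
      gamma_star[i, ] <- g_old
      delta_star[i, ] <- d_old
    }
  } else {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }

  # neutralize passthrough features
  gamma_star[, zero_var] <- 0
  delta_star[, zero_var] <- 1
  gamma_hat[, zero_var] <- 0
  delta_hat[, zero_var] <- 1
  if (any(zero_var))
    mag_log(sprintf("%d zero-variance feature(s) passed through unharmonized",
                    sum(zero_var)), "warn")

  p <- ncol(xcov)
  beta_hat <- if (p > 0L)
    t(b_hat[n_batch + seq_len(p), , drop = FALSE])
  else
    matrix(0, nrow(y), 0L)
  colnames(beta_hat) <- colnames(xcov)

  list(alpha_hat = as.vector(grand_mean), beta_hat = beta_hat,
       pooled_sd = sqrt(var_pooled),
       gamma_star = gamma_star, delta_star = sqrt(delta_star),
       gamma_hat = gamma_hat, delta_hat = sqrt(delta_hat),
       zero_var = zero_var)
}

#' Remove estimated site effects from a cohort
#'
#' Applies a fitted [fit_combat()] model: per feature, the value is
#' standardized with the fit-time intercept, covariate fit and pooled SD,
#' the site's shrunken additive effect is subtracted and the multiplicative
#' effect divided out, and the covariate/intercept part is added back, so
#' age and sex effects are preserved while site effects are removed.
#'
#' @param model a `harmonization_model`.
#' @param x a `cohort` whose sites were all seen at fit time (there is no
#'   reference-batch mode).
#' @return A `cohort` of the same shape with harmonized series.
#' @export
apply_combat <- function(model, x) {
  stopifnot(inherits(model, "harmonization_model"), inherits(x, "cohort"))
  sites <- cohort_sites(x)
  unseen <- setdiff(unique(sites), model$sites)
  if (length(unseen))
    stopf("site(s) not seen at fit time: %s", paste(unseen, collapse = ", "))
  rois <- vapply(x$atlases, `[[`, integer(1), "n_rois")
  if (x$t_points != model$t_points ||
      !identical(unname(rois[names(model$atlas_rois)]), unname(model$atlas_rois)))
    stopf("cohort shape does not match the fitted model")

  age <- vapply(x$subjects, `[[`, numeric(1), "age")
  sex <- vapply(x$subjects, `[[`, integer(1), "sex")
  cov_vals <- cbind(
    age = if ("age" %in% model$covariates) (age - model$age_mean) / model$age_sd else NULL,
    sex = if ("sex" %in% model$covariates) as.numeric(sex) else NULL
  )

  flat <- flatten_series(x)
  if (model$feature_mode == "timepoint") {
    obs_subject <- seq_len(ncol(flat))
    y <- flat
  } else {
    idx <- feature_index(x)
    key <- paste(idx$atlas, idx$roi)
    streams <- unique(key)
    y <- t(vapply(streams, function(sk) {
      as.vector(flat[key == sk, , drop = FALSE])
    }, numeric(x$t_points * ncol(flat))))
    obs_subject <- rep(seq_len(ncol(flat)), each = x$t_points)
  }

  xcov <- if (is.null(cov_vals)) matrix(0, length(obs_subject), 0L)
          else cov_vals[obs_subject, , drop = FALSE]
  fit_part <- model$alpha_hat +
    if (ncol(model$beta_hat) > 0L) model$beta_hat %*% t(xcov) else 0
  z <- (y - fit_part) / model$pooled_sd
  site_idx <- match(sites[obs_subject], model$sites)
  adj <- (z - t(model$gamma_star[site_idx, , drop = FALSE])) /
    t(model$delta_star[site_idx, , drop = FALSE])
  out <- adj * model$pooled_sd + fit_part
  out[model$zero_var, ] <- y[model$zero_var, , drop = FALSE]

  if (model$feature_mode == "roi") {
    # back to (atlas, t, roi) x subject layout
    idx <- feature_index(x)
    key <- paste(idx$atlas, idx$roi)
    streams <- unique(key)
    flat_out <- flat
    for (si in seq_along(streams)) {
      flat_out[key == streams[si], ] <-
        matrix(out[si, ], nrow = x$t_points)
    }
    out <- flat_out
  }

  x$subjects <- lapply(seq_along(x$subjects), function(j) {
    s <- x$subjects[[j]]
    s$series <- unflatten_series(out[, j], x)
    s
  })
  validate_cohort(x)
}
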