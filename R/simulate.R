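# Synthetic multi-site cohort generator. Produces two-class ROI time
# series with (i) class-dependent inter-ROI correlation structure, (ii)
# additive and multiplicative site effects per (atlas, time point, ROI)
# feature, and (iii) age/sex covariate effects, together with the ground
# truth needed by recovery tests.

#' Specify a synthetic multi-site cohort
#'
#' The class signal is injected in correlation space: each atlas gets a
#' block (community) latent correlation matrix, and in the MDD class a
#' random subset of between-module ROI pairs is shifted by `class_effect`,
#' so the two classes differ in functional connectivity rather than in
#' mean signal (a mean shift would be removed by Pearson centering).
#' Site effects mirror the additive/multiplicative location-scale model
#' that ComBat assumes, applied per (atlas, time point, ROI) feature.
#'
#' Defaults emulate the multi-site study conditions: 16 sites with 49
#' subjects per site per class (~1,568 subjects), 140 time points and the
#' four standard atlases. Distributional knobs the study does not pin down
#' (block structure, effect scales, noise) are package choices documented
#' in the methods vignette.
#'
#' @param n_sites number of acquisition sites (>= 1).
#' @param subjects_per_site_per_class subjects drawn per site per class;
#'   labels are balanced per site by construction.
#' @param t_points time points per series.
#' @param atlases list of [atlas_spec()] objects.
#' @param site_gamma_sd SD of the additive site effect per feature.
#' @param site_delta_range range of the multiplicative site effect
#'   (uniform draw per site/feature); must be positive.
#' @param beta_age,beta_sex covariate effect added to every feature
#'   (`beta_age` per year of centered age, `beta_sex` for sex = 1).
#' @param n_modules latent communities per atlas.
#' @param class_effect correlation shift applied to the perturbed
#'   between-module pairs in the MDD class; resulting target correlations
#'   must stay inside (-1, 1).
#' @param class_pair_frac fraction of between-module upper-triangle pairs
#'   perturbed in the MDD class.
#' @param within_cor,between_cor baseline within/between-module latent
#'   correlations.
#' @param noise_sd SD of additive observation noise.
#' @param seed root seed for the generator.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(n_sites = 16L, subjects_per_site_per_class = 49L,
                            t_points = 140L, atlases = default_atlases(),
                            site_gamma_sd = 0.2, site_delta_range = c(0.8, 1.25),
                            beta_age = 0.01, beta_sex = 0.1,
                            n_modules = 5L, class_effect = 0.25,
                            class_pair_frac = 0.2,
                            within_cor = 0.35, between_cor = 0.05,
                            noise_sd = 0.2, seed = 1L) {
  if (inherits(atlases, "atlas_spec")) atlases <- list(atlases)
  names(atlases) <- vapply(atlases, `[[`, "", "name")
  stopifnot(n_sites >= 1L, subjects_per_site_per_class >= 1L, t_points >= 2L,
            n_modules >= 2L, noise_sd >= 0, site_gamma_sd >= 0)
  if (length(site_delta_range) != 2L || any(site_delta_range <= 0) ||
      diff(site_delta_range) < 0)
    stopf("site_delta_range must be a positive, non-decreasing interval")
  if (class_pair_frac < 0 || class_pair_frac > 1)
    stopf("class_pair_frac must lie in [0, 1]")
  if (abs(between_cor + class_effect) >= 1 || abs(within_cor) >= 1)
    stopf("class_effect keeps no valid correlation: |between_cor + class_effect| must be < 1")
  structure(list(
    n_sites = as.integer(n_sites),
    subjects_per_site_per_class = as.integer(subjects_per_site_per_class),
    t_points = as.integer(t_points), atlases = atlases,
    site_gamma_sd = site_gamma_sd, site_delta_range = site_delta_range,
    beta_age = beta_age, beta_sex = beta_sex,
    n_modules = as.integer(n_modules), class_effect = class_effect,
    class_pair_frac = class_pair_frac, within_cor = within_cor,
    between_cor = between_cor, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "simulation_spec")
}

# Contiguous module assignment for n ROIs.
module_assignment <- function(n_rois, n_modules) {
  sort(rep_len(seq_len(n_modules), n_rois))
}

# Block-model correlation matrix, optionally perturbed on a pair set,
# then repaired to the nearest positive-definite correlation matrix.
build_latent_cor <- function(n_rois, modules, within, between,
                             perturb_pairs = NULL, shift = 0) {
  r <- matrix(between, n_rois, n_rois)
  same <- outer(modules, modules, `==`)
  r[same] <- within
  diag(r) <- 1
  if (!is.null(perturb_pairs) && nrow(perturb_pairs) > 0L) {
    for (k in seq_len(nrow(perturb_pairs))) {
      i <- perturb_pairs[k, 1L]; j <- perturb_pairs[k, 2L]
      r[i, j] <- r[i, j] + shift
      r[j, i] <- r[i, j]
    }
    if (any(abs(r[upper.tri(r)]) >= 1))
      stopf("class_effect pushes a latent correlation outside (-1, 1)")
  }
  ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    r <- as.matrix(Matrix::nearPD(r, corr = TRUE, posd.tol = 1e-8)$mat)
    dimnames(r) <- NULL
  }
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stopf("latent correlation matrix is not positive definite after repair")
  r
}

draw_truncated_age <- function(n, mean = 34, sd = 12, lower = 18, upper = 65) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Simulate a multi-site two-class cohort with known ground truth
#'
#' For each subject and atlas, `t_points` rows are drawn from a
#' multivariate normal with the class's latent correlation matrix; each
#' (time point, ROI) feature is then transformed as
#' `y -> y * delta[site, f] + gamma[site, f] + beta_age * age_c +
#' beta_sex * sex + noise`, with centered age. Ages are Normal(34, 12)
#' truncated to `[18, 65]`, sex is Bernoulli(0.5), and each site gets the
#' same number of MDD and HC subjects.
#'
#' @param spec a [simulation_spec()].
#' @return A list with elements `cohort` (a [cohort()]) and `truth`, the
#'   latter holding per-site `gamma`/`delta` matrices per atlas
#'   (site x feature, features column-major in the T x N matrix), the
#'   class-specific latent correlation matrices, and the perturbed
#'   between-module ROI pair set per atlas.
#' @examples
#' sp <- simulation_spec(n_sites = 2, subjects_per_site_per_class = 3,
#'                       t_points = 30, atlases = list(atlas_spec("toy", 8)),
#'                       n_modules = 2, seed = 7)
#' sim <- simulate_cohort(sp)
#' sim$cohort
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  structure_rng <- substream_seed(spec$seed, "sim-structure")
  subject_rng <- substream_seed(spec$seed, "sim-subjects")

  truth <- withr::with_seed(structure_rng, {
    per_atlas <- lapply(spec$atlases, function(a) {
      modules <- module_assignment(a$n_rois, spec$n_modules)
      ut <- which(upper.tri(matrix(0, a$n_rois, a$n_rois)), arr.ind = TRUE)
      between <- ut[modules[ut[, 1L]] != modules[ut[, 2L]], , drop = FALSE]
      n_pick <- round(spec$class_pair_frac * nrow(between))
      picked <- if (n_pick > 0L)
        between[sample.int(nrow(between), n_pick), , drop = FALSE]
      else
        between[0L, , drop = FALSE]
      cor_hc <- build_latent_cor(a$n_rois, modules, spec$within_cor, spec$between_cor)
      cor_mdd <- build_latent_cor(a$n_rois, modules, spec$within_cor,
                                  spec$between_cor, picked, spec$class_effect)
      n_feat <- spec$t_points * a$n_rois
      gamma <- matrix(stats::rnorm(spec$n_sites * n_feat, 0, spec$site_gamma_sd),
                      nrow = spec$n_sites)
      delta <- matrix(stats::runif(spec$n_sites * n_feat,
                                   spec$site_delta_range[1L],
                                   spec$site_delta_range[2L]),
                      nrow = spec$n_sites)
      rownames(gamma) <- rownames(delta) <- sprintf("site%02d", seq_len(spec$n_sites))
      list(modules = modules, perturbed_pairs = unname(picked),
           cor_hc = cor_hc, cor_mdd = cor_mdd, gamma = gamma, delta = delta)
    })
    names(per_atlas) <- names(spec$atlases)
    per_atlas
  })

  chols <- lapply(truth, function(tr)
    list(hc = chol(tr$cor_hc), mdd = chol(tr$cor_mdd)))

  cohort_obj <- withr::with_seed(subject_rng, {
    subjects <- list()
    n_total <- spec$n_sites * spec$subjects_per_site_per_class * 2L
    ages <- draw_truncated_age(n_total)
    sexes <- stats::rbinom(n_total, 1L, 0.5)
    age_center <- 34  # fixed generator-side center so beta_age is interpretable
    counter <- 0L
    for (site in seq_len(spec$n_sites)) {
      site_id <- sprintf("site%02d", site)
      for (label in c(1L, 0L)) {
        for (rep_i in seq_len(spec$subjects_per_site_per_class)) {
          counter <- counter + 1L
          age <- ages[counter]; sex <- sexes[counter]
          series <- list()
          for (aname in names(spec$atlases)) {
            a <- spec$atlases[[aname]]
            ch <- if (label == 1L) chols[[aname]]$mdd else chols[[aname]]$hc
            z <- matrix(stats::rnorm(spec$t_points * a$n_rois),
                        nrow = spec$t_points) %*% ch
            delta_m <- matrix(truth[[aname]]$delta[site, ],
                              nrow = spec$t_points, ncol = a$n_rois)
            gamma_m <- matrix(truth[[aname]]$gamma[site, ],
                              nrow = spec$t_points, ncol = a$n_rois)
            y <- z * delta_m + gamma_m +
              spec$beta_age * (age - age_center) + spec$beta_sex * sex
            if (spec$noise_sd > 0)
              y <- y + matrix(stats::rnorm(length(y), 0, spec$noise_sd),
                              nrow = spec$t_points)
            series[[aname]] <- y
          }
          subjects[[counter]] <- subject_record(
            sprintf("s%04d_%s", counter, site_id), site_id, label,
            age, sex, series)
        }
      }
    }
    cohort(spec$atlases, subjects, spec$t_points)
  })

  list(cohort = cohort_obj, truth = truth)
}

#' Per-site feature statistics and between-site F tests
#'
#' Diagnostic for site (batch) effects: per-site per-feature means and
#' variances of the flattened (atlas, time point, ROI) features, plus a
#' one-way between-site ANOVA F statistic per feature. Used to quantify
#' how much site signal ComBat removes.
#'
#' @param x a `cohort` with at least two sites.
#' @param atlas atlas name to restrict to (default: all atlases).
#' @return A list: `site_means` and `site_vars` (site x feature matrices),
#'   `f_stat` (per-feature F), `df` (numerator/denominator degrees of
#'   freedom) and `features` (the feature index table).
#' @export
empirical_site_effect <- function(x, atlas = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (!is.null(atlas)) {
    if (!atlas %in% names(x$atlases)) stopf("unknown atlas '%s'", atlas)
    x$atlases <- x$atlases[atlas]
    x$subjects <- lapply(x$subjects, function(s) {
      s$series <- s$series[atlas]
      s
    })
  }
  sites <- cohort_sites(x)
  usites <- sort(unique(sites))
  if (length(usites) < 2L) stopf("between-site statistics need >= 2 sites")
  y <- flatten_series(x)  # features x subjects
  n <- ncol(y)
  site_means <- t(vapply(usites, function(s) rowMeans(y[, sites == s, drop = FALSE]),
                         numeric(nrow(y))))
  site_vars <- t(vapply(usites, function(s) {
    cols <- y[, sites == s, drop = FALSE]
    if (ncol(cols) < 2L) return(rep(NA_real_, nrow(y)))
    apply(cols, 1L, stats::var)
  }, numeric(nrow(y))))
  n_per <- vapply(usites, function(s) sum(sites == s), integer(1))
  grand <- rowMeans(y)
  ssb <- colSums(n_per * (sweep(site_means, 2L, grand))^2)
  ssw <- colSums((n_per - 1L) * site_vars)
  df1 <- length(usites) - 1L
  df2 <- n - length(usites)
  f_stat <- (ssb / df1) / (ssw / df2)
  list(site_means = site_means, site_vars = site_vars, f_stat = f_stat,
       df = c(df1 = df1, df2 = df2), features = feature_index(x))
}
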