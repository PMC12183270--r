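# Shared fixtures, built in code at test time.

# Small two-atlas cohort with hand-set sizes; moderate class signal.
toy_sim_spec <- function(seed = 11, n_sites = 3, per_class = 5, t_points = 30,
                         class_effect = 0.5, site_gamma_sd = 0.2,
                         site_delta_range = c(0.8, 1.25), noise_sd = 0.2) {
  simulation_spec(
    n_sites = n_sites, subjects_per_site_per_class = per_class,
    t_points = t_points,
    atlases = list(atlas_spec("toyA", 8), atlas_spec("toyB", 10)),
    n_modules = 2, class_effect = class_effect, class_pair_frac = 0.2,
    site_gamma_sd = site_gamma_sd, site_delta_range = site_delta_range,
    noise_sd = noise_sd, seed = seed)
}

toy_cohort <- function(...) simulate_cohort(toy_sim_spec(...))$cohort

# Minimal hand-built cohort (deterministic entries, no simulator).
tiny_cohort <- function(n_subjects = 4, t_points = 6, n_rois = 3,
                        atlas_names = "X") {
  atlases <- lapply(atlas_names, function(a) atlas_spec(a, n_rois))
  subjects <- lapply(seq_len(n_subjects), function(i) {
    series <- lapply(atlas_names, function(a)
      matrix(sin(seq_len(t_points * n_rois) * i / 7), t_points, n_rois) +
        i * 0.1)
    names(series) <- atlas_names
    subject_record(sprintf("s%02d", i), sprintf("site%02d", (i %% 2) + 1),
                   i %% 2, 30 + i, i %% 2, series)
  })
  cohort(atlases, subjects, t_points)
}

# Build a brain_graph directly from an edge matrix (rows = i, j pairs).
manual_graph <- function(n, edges, features = NULL, label = 1L, weights = NULL) {
  if (is.null(features)) features <- diag(n)
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  if (is.null(weights)) weights <- rep(1, length(lo))
  structure(list(n_nodes = n, node_features = features,
                 edges = data.frame(src = lo, dst = hi, weight = weights),
                 label = as.integer(label), subject_id = "manual", atlas = "manual"),
            class = "brain_graph")
}

# Independent dense GAT-layer oracle: scalar loops, explicit -Inf masking.
# Deliberately written without reusing any package internals.
dense_gat_layer_oracle <- function(layer, features, adjacency) {
  n <- nrow(features)
  nb <- adjacency | diag(TRUE, n)
  slope <- layer$leaky_slope
  K <- layer$n_heads
  dh <- layer$head_dim
  out_heads <- list()
  alphas <- list()
  for (k in seq_len(K)) {
    W <- layer$W[, ((k - 1) * dh + 1):(k * dh), drop = FALSE]
    H <- features %*% W
    logits <- matrix(-Inf, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (nb[i, j]) {
          e <- sum(layer$a_src[, k] * H[i, ]) + sum(layer$a_dst[, k] * H[j, ])
          logits[i, j] <- if (e > 0) e else slope * e
        }
      }
    }
    alpha <- matrix(0, n, n)
    z <- matrix(0, n, dh)
    for (i in seq_len(n)) {
      w <- exp(logits[i, ] - max(logits[i, ]))
      w[is.nan(w)] <- 0
      alpha[i, ] <- w / sum(w)
      for (j in seq_len(n)) z[i, ] <- z[i, ] + alpha[i, j] * H[j, ]
    }
    out_heads[[k]] <- z
    alphas[[k]] <- alpha
  }
  P <- do.call(cbind, out_heads)
  list(alphas = alphas, out = P * (slope + (1 - slope) * (P > 0)))
}

# Full-network dense oracle matching the package architecture.
dense_gat_forward_oracle <- function(net, graph) {
  X <- graph$node_features
  adj <- matrix(FALSE, graph$n_nodes, graph$n_nodes)
  adj[cbind(graph$edges$src, graph$edges$dst)] <- TRUE
  adj[cbind(graph$edges$dst, graph$edges$src)] <- TRUE
  for (layer in net$layers) X <- dense_gat_layer_oracle(layer, X, adj)$out
  g <- colMeans(X)
  logits <- drop(g %*% net$fc_W) + net$fc_b
  e <- exp(logits - max(logits))
  e / sum(e)
}

expect_cohort_equal <- function(a, b) {
  ids_a <- sort(cohort_ids(a))
  ids_b <- sort(cohort_ids(b))
  expect_identical(ids_a, ids_b)
  a <- subset_cohort(a, ids_a)
  b <- subset_cohort(b, ids_a)
  expect_identical(names(a$atlases), names(b$atlases))
  expect_equal(a$t_points, b$t_points)
  for (i in seq_along(a$subjects)) {
    expect_identical(a$subjects[[i]]$site_id, b$subjects[[i]]$site_id)
    expect_identical(a$subjects[[i]]$label, b$subjects[[i]]$label)
    expect_equal(a$subjects[[i]]$series, b$subjects[[i]]$series, tolerance = 1e-12)
  }
}
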