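# GAT layer and network: attention normalization, dense-oracle agreement,
# permutation invariance, gradient exactness, and training behaviour.

toy_graph <- function(n = 5, d = 4, seed = 1, label = 1L, p_edge = 0.5) {
  withr::with_seed(seed, {
    feats <- matrix(rnorm(n * d), n, d)
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < p_edge
    if (!any(keep)) keep[1] <- TRUE
    manual_graph(n, pairs[keep, , drop = FALSE], features = feats, label = label)
  })
}

toy_net <- function(d, hidden = 8, heads = 2, layers = 3, seed = 2,
                    dropout = 0) {
  cfg <- pipeline_config(hidden_units = hidden, n_heads = heads,
                         n_layers = layers, dropout_rate = dropout)
  withr::with_seed(seed, init_gat(d, cfg))
}

test_that("attention rows sum to one and identical features give uniform attention", {
  # complete graph, identical node features -> alpha = 1/n everywhere
  n <- 6
  g <- manual_graph(n, which(upper.tri(diag(n)), arr.ind = TRUE),
                    features = matrix(1, n, 3))
  net <- toy_net(3)
  alphas <- attention_scores(net$layers[[1]], g$node_features,
                             magat:::graph_adjacency(g))
  for (a in alphas) expect_equal(a, matrix(1 / n, n, n), tolerance = 1e-12)
  # random graph/features: rows still sum to 1 over the neighborhood
  g2 <- toy_graph(n = 7, d = 4, seed = 3)
  net2 <- toy_net(4, seed = 4)
  for (l in 1:3) {
    alphas <- attention_scores(net2$layers[[1]], g2$node_features,
                               magat:::graph_adjacency(g2))
    for (a in alphas) expect_equal(rowSums(a), rep(1, 7), tolerance = 1e-6)
  }
  # single node: self-loop only, alpha = 1
  g1 <- structure(list(n_nodes = 1L, node_features = matrix(1, 1, 3),
                       edges = data.frame(src = integer(0), dst = integer(0),
                                          weight = numeric(0)),
                       label = 1L, subject_id = "x", atlas = "x"),
                  class = "brain_graph")
  a1 <- attention_scores(net$layers[[1]], g1$node_features,
                         matrix(FALSE, 1, 1))
  expect_equal(a1[[1]], matrix(1, 1, 1))
})

test_that("masked-dense implementation matches an independent scalar-loop oracle", {
  for (seed in 1:4) {
    g <- toy_graph(n = sample(4:10, 1), d = 5, seed = seed)
    net <- toy_net(5, hidden = 8, heads = 4, seed = seed + 10)
    adj <- magat:::graph_adjacency(g)
    # layer-level: attention coefficients
    fast <- attention_scores(net$layers[[1]], g$node_features, adj)
    oracle <- dense_gat_layer_oracle(net$layers[[1]], g$node_features, adj)
    for (k in seq_along(fast))
      expect_equal(fast[[k]], oracle$alphas[[k]], tolerance = 1e-6)
    # network-level: class probabilities
    expect_equal(unname(gat_forward(net, g)),
                 unname(dense_gat_forward_oracle(net, g)), tolerance = 1e-5)
  }
})

test_that("probabilities are a valid distribution and inference is deterministic", {
  g <- toy_graph(n = 8, d = 6, seed = 5)
  net <- toy_net(6, seed = 6)
  p <- gat_forward(net, g)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, gat_forward(net, g))
  expect_error(gat_forward(net, toy_graph(n = 8, d = 3, seed = 5)), "width")
})

test_that("graph-level output is invariant to node permutation", {
  g <- toy_graph(n = 9, d = 5, seed = 7)
  net <- toy_net(5, seed = 8)
  perm <- withr::with_seed(9, sample(9))
  inv <- order(perm)
  g_perm <- g
  g_perm$node_features <- g$node_features[perm, ]
  g_perm$edges <- data.frame(src = pmin(inv[g$edges$src], inv[g$edges$dst]),
                             dst = pmax(inv[g$edges$src], inv[g$edges$dst]),
                             weight = g$edges$weight)
  expect_equal(gat_forward(net, g), gat_forward(net, g_perm), tolerance = 1e-6)
})

test_that("all-zero node features reduce the output to the head-bias path", {
  g <- toy_graph(n = 6, d = 4, seed = 10)
  g$node_features <- matrix(0, 6, 4)
  net <- toy_net(4, seed = 11)
  expected <- exp(net$fc_b - max(net$fc_b))
  expected <- expected / sum(expected)
  expect_equal(unname(gat_forward(net, g)), expected, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  g <- toy_graph(n = 6, d = 5, seed = 12)
  net <- toy_net(5, hidden = 6, heads = 2, seed = 13)
  mask <- magat:::graph_mask(g)
  fwd <- magat:::forward_cached(net, g$node_features, mask, FALSE)
  gr <- magat:::backward_graph(net, fwd, mask, 1L)
  flat <- magat:::net_flatten(net)
  eps <- 1e-6
  loss <- function(fl) {
    -log(gat_forward(magat:::net_unflatten(net, fl), g)[["MDD"]])
  }
  withr::with_seed(14, {
    for (nm in names(flat)) {
      for (i in sample(seq_along(flat[[nm]]), min(3, length(flat[[nm]])))) {
        fl <- flat
        fl[[nm]][i] <- fl[[nm]][i] + eps
        up <- loss(fl)
        fl[[nm]][i] <- fl[[nm]][i] - 2 * eps
        dn <- loss(fl)
        expect_equal(gr[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-4)
      }
    }
  })
})

separable_graphs <- function(n_graphs = 40, n = 10, seed = 20) {
  # class signal planted directly in node features
  withr::with_seed(seed, lapply(seq_len(n_graphs), function(i) {
    label <- as.integer(i <= n_graphs / 2)
    feats <- matrix(rnorm(n * n, mean = ifelse(label == 1L, 0.8, -0.8), sd = 0.5),
                    n, n)
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < 0.4
    if (!any(keep)) keep[1] <- TRUE
    manual_graph(n, pairs[keep, , drop = FALSE], features = feats, label = label)
  }))
}

test_that("training learns a separable problem and is seed-deterministic", {
  gs <- separable_graphs()
  cfg <- pipeline_config(hidden_units = 8, n_heads = 2, dropout_rate = 0.1,
                         max_epochs = 30, patience = 30, batch_size = 8,
                         seed = 1)
  fit <- train_gat(gs, gs, cfg, atlas = "sep")
  expect_lte(nrow(fit$training_log), 30)
  expect_lt(fit$training_log$train_loss[nrow(fit$training_log)],
            fit$training_log$train_loss[1])
  preds <- predict_gat(fit, gs)
  acc <- mean((preds[, "MDD"] >= 0.5) == vapply(gs, `[[`, integer(1), "label"))
  expect_gte(acc, 0.95)
  expect_gte(fit$val_accuracy, 0.95)
  # determinism
  fit2 <- train_gat(gs, gs, cfg, atlas = "sep")
  expect_identical(fit$val_accuracy, fit2$val_accuracy)
  expect_equal(magat:::net_flatten(fit$network),
               magat:::net_flatten(fit2$network), tolerance = 1e-12)
})

test_that("zero learning rate leaves parameters unchanged", {
  gs <- separable_graphs(n_graphs = 8, n = 6, seed = 21)
  cfg <- pipeline_config(learning_rate = 0, weight_decay = 0,
                         hidden_units = 8, n_heads = 2, dropout_rate = 0,
                         max_epochs = 3, patience = 5, batch_size = 4, seed = 2)
  fit <- train_gat(gs, gs, cfg, atlas = "frozen")
  init <- withr::with_seed(substream_seed(2L, "init-frozen"),
                           init_gat(6, cfg))
  expect_equal(magat:::net_flatten(fit$network), magat:::net_flatten(init),
               tolerance = 1e-14)
  expect_equal(diff(range(fit$training_log$val_loss)), 0, tolerance = 1e-12)
})

test_that("grid search returns the single cell, avoids sabotaged cells", {
  gs <- separable_graphs(n_graphs = 12, n = 6, seed = 22)
  cfg <- pipeline_config(learning_rate = 5e-3, hidden_units = 8, n_heads = 2,
                         max_epochs = 25, patience = 25, batch_size = 4,
                         dropout_rate = 0, seed = 3)
  one <- grid_search(gs, gs, cfg, grid = list(learning_rate = 0.005))
  expect_equal(one$best_config$learning_rate, 0.005)
  expect_equal(nrow(one$table), 1L)
  # a cell with an absurd weight decay collapses the model to its bias
  # path; the search must not pick it
  sab <- grid_search(gs, gs, cfg,
                     grid = list(weight_decay = c(1e6, 5e-4)))
  expect_equal(sab$best_config$weight_decay, 5e-4)
  expect_equal(nrow(sab$table), 2L)
  expect_lt(sab$table$val_accuracy[sab$table$weight_decay == 1e6],
            sab$table$val_accuracy[sab$table$weight_decay == 5e-4])
  expect_error(grid_search(gs, gs, cfg, grid = list(bogus = 1)), "grid")
})
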