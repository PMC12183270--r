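# Graph attention network for whole-graph classification, written with
# dense masked attention (brain graphs have at most a few hundred nodes).
# Forward pass, analytic backpropagation, Adam with L2 weight decay, and
# the training loop with early stopping live here.
#
# Per head: e_ij = LeakyReLU(a^T [W h_i || W h_j]) for j in N(i) (self-
# loop included), alpha_ij = softmax_j(e_ij), h'_i = sigma(sum_j alpha_ij
# W h_j); heads are concatenated (or averaged). Readout is global average
# pooling followed by an affine map to two classes and a softmax.
#
# For speed the K heads' linear maps are stored as one in_dim x (K *
# head_dim) matrix W (head k owns columns (k-1)*head_dim + 1 ... k *
# head_dim) and the attention vectors as head_dim x K matrices, so the
# node projection is a single matmul per layer.

new_gat_layer <- function(in_dim, head_dim, n_heads, leaky_slope = 0.2,
                          combine = "concat") {
  lim_w <- 1 / sqrt(in_dim)
  lim_a <- 1 / sqrt(2 * head_dim)
  list(
    W = matrix(stats::runif(in_dim * head_dim * n_heads, -lim_w, lim_w),
               in_dim, head_dim * n_heads),
    a_src = matrix(stats::runif(head_dim * n_heads, -lim_a, lim_a),
                   head_dim, n_heads),
    a_dst = matrix(stats::runif(head_dim * n_heads, -lim_a, lim_a),
                   head_dim, n_heads),
    in_dim = in_dim, head_dim = head_dim, n_heads = n_heads,
    leaky_slope = leaky_slope, combine = combine
  )
}

head_cols <- function(layer, k) {
  ((k - 1L) * layer$head_dim + 1L):(k * layer$head_dim)
}

#' Initialize a GAT network
#'
#' Builds `n_layers` stacked attention layers (`in_dim -> hidden_units ->
#' ... -> hidden_units`, each layer's width split across `n_heads`
#' concatenated heads), followed by global average pooling and an affine
#' two-class head. Parameters use a uniform fan-in initialization drawn
#' from the current RNG state; wrap in a seeded context for
#' reproducibility.
#'
#' @param in_dim node-feature width (the atlas's `n_rois`).
#' @param config a [pipeline_config()].
#' @param combine head combination, `"concat"` (default) or `"average"`.
#' @return A `gat_network` object.
#' @export
init_gat <- function(in_dim, config, combine = "concat") {
  combine <- match.arg(combine, c("concat", "average"))
  head_dim <- if (combine == "concat") config$hidden_units %/% config$n_heads
              else config$hidden_units
  out_width <- if (combine == "concat") head_dim * config$n_heads else head_dim
  layers <- vector("list", config$n_layers)
  d <- in_dim
  for (l in seq_len(config$n_layers)) {
    layers[[l]] <- new_gat_layer(d, head_dim, config$n_heads,
                                 leaky_slope = 0.2, combine = combine)
    d <- out_width
  }
  lim <- 1 / sqrt(d)
  structure(list(
    layers = layers,
    fc_W = matrix(stats::runif(d * 2L, -lim, lim), d, 2L),
    fc_b = stats::runif(2L, -lim, lim),
    in_dim = in_dim, out_dim = d,
    dropout_rate = config$dropout_rate
  ), class = "gat_network")
}

# ---- parameter flattening (for the optimizer) -------------------------

net_flatten <- function(net) {
  out <- list()
  for (l in seq_along(net$layers)) {
    out[[sprintf("L%d.W", l)]] <- net$layers[[l]]$W
    out[[sprintf("L%d.a_src", l)]] <- net$layers[[l]]$a_src
    out[[sprintf("L%d.a_dst", l)]] <- net$layers[[l]]$a_dst
  }
  out$fc_W <- net$fc_W
  out$fc_b <- net$fc_b
  out
}

net_unflatten <- function(net, flat) {
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W <- flat[[sprintf("L%d.W", l)]]
    net$layers[[l]]$a_src <- flat[[sprintf("L%d.a_src", l)]]
    net$layers[[l]]$a_dst <- flat[[sprintf("L%d.a_dst", l)]]
  }
  net$fc_W <- flat$fc_W
  net$fc_b <- flat$fc_b
  net
}

# ---- forward ----------------------------------------------------------

# Neighborhood mask including self-loops.
graph_mask <- function(g) {
  m <- graph_adjacency(g)
  diag(m) <- TRUE
  m
}

# Mask plus precomputed non-neighbor indices (hot path helper).
mask_info <- function(mask) {
  if (is.list(mask)) return(mask)
  list(m = mask, neg = which(!mask))
}

#' Per-edge attention coefficients of one layer
#'
#' Computes the softmax-normalized attention coefficients of a fitted (or
#' freshly initialized) layer on given node features. Self-loops are added
#' to every neighborhood, so each row of each head's coefficient matrix
#' sums to one.
#'
#' @param layer one element of a `gat_network`'s `layers` list.
#' @param features `n x in_dim` node-feature matrix.
#' @param adjacency `n x n` logical adjacency (self-loops added here).
#' @return List with one `n x n` matrix per head; entry `(i, j)` is
#'   `alpha_ij` for `j` in the neighborhood of `i` and 0 elsewhere.
#' @export
attention_scores <- function(layer, features, adjacency) {
  mask <- adjacency | diag(TRUE, nrow(features))
  lapply(seq_len(layer$n_heads), function(k) {
    H <- features %*% layer$W[, head_cols(layer, k), drop = FALSE]
    e <- outer(drop(H %*% layer$a_src[, k]), drop(H %*% layer$a_dst[, k]), `+`)
    e <- leaky_relu(e, layer$leaky_slope)
    e[!mask] <- -Inf
    a <- row_softmax(e)
    a[!mask] <- 0
    a
  })
}

gat_layer_forward <- function(layer, X, mi) {
  K <- layer$n_heads
  dh <- layer$head_dim
  H <- X %*% layer$W  # n x K*dh, all heads at once
  n <- nrow(H)
  heads <- vector("list", K)
  concat <- layer$combine == "concat"
  P <- if (concat) matrix(0, n, K * dh) else matrix(0, n, dh)
  for (k in seq_len(K)) {
    cols <- head_cols(layer, k)
    Hk <- H[, cols, drop = FALSE]
    s <- Hk %*% layer$a_src[, k]
    t_ <- Hk %*% layer$a_dst[, k]
    e_raw <- matrix(s, n, n) + rep(t_, each = n)  # e_raw[i, j] = s_i + t_j
    e <- leaky_relu(e_raw, layer$leaky_slope)
    e[mi$neg] <- -Inf
    A <- row_softmax(e)
    Z <- A %*% Hk
    if (concat) P[, cols] <- Z else P <- P + Z / K
    heads[[k]] <- list(e_raw = e_raw, A = A)
  }
  list(out = leaky_relu(P, layer$leaky_slope), P = P, H = H, heads = heads, X = X)
}

forward_cached <- function(net, features, mask, train_mode = FALSE) {
  mi <- mask_info(mask)
  X <- features
  n <- nrow(X)
  caches <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    drop_mask <- NULL
    if (train_mode && net$dropout_rate > 0) {
      keep <- 1 - net$dropout_rate
      drop_mask <- matrix((stats::runif(length(X)) < keep) / keep,
                          nrow(X), ncol(X))
      X <- X * drop_mask
    }
    cache <- gat_layer_forward(net$layers[[l]], X, mi)
    cache$drop_mask <- drop_mask
    caches[[l]] <- cache
    X <- cache$out
  }
  g <- colMeans(X)
  logits <- drop(g %*% net$fc_W) + net$fc_b
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  list(caches = caches, final = X, g = g, logits = logits, p = p, n = n)
}

#' GAT forward pass on one brain graph
#'
#' @param net a `gat_network`.
#' @param graph a `brain_graph` whose feature width matches `net$in_dim`.
#' @param train_mode apply dropout (draws from the current RNG state);
#'   inference (`FALSE`, default) is deterministic.
#' @return Numeric length-2 vector of class probabilities
#'   `c(HC, MDD)`, summing to 1.
#' @export
gat_forward <- function(net, graph, train_mode = FALSE) {
  if (ncol(graph$node_features) != net$in_dim)
    stopf("feature width %d does not match network input width %d",
          ncol(graph$node_features), net$in_dim)
  fwd <- forward_cached(net, graph$node_features, graph_mask(graph), train_mode)
  stats::setNames(fwd$p, c("HC", "MDD"))
}

# ---- backward ---------------------------------------------------------

gat_layer_backward <- function(layer, cache, mi, d_out) {
  slope <- layer$leaky_slope
  K <- layer$n_heads
  dP <- d_out * leaky_relu_grad(cache$P, slope)
  dH <- matrix(0, nrow(cache$H), ncol(cache$H))
  da_src <- matrix(0, layer$head_dim, K)
  da_dst <- matrix(0, layer$head_dim, K)
  for (k in seq_len(K)) {
    cols <- head_cols(layer, k)
    hc <- cache$heads[[k]]
    Hk <- cache$H[, cols, drop = FALSE]
    dZ <- if (layer$combine == "concat") dP[, cols, drop = FALSE] else dP / K
    dA <- tcrossprod(dZ, Hk)
    dHk <- crossprod(hc$A, dZ)
    # softmax backward per row, restricted to the neighborhood
    rs <- rowSums(dA * hc$A)
    dE <- hc$A * (dA - rs)
    dE_raw <- dE * leaky_relu_grad(hc$e_raw, slope)
    dE_raw[mi$neg] <- 0
    ds <- rowSums(dE_raw)
    dt <- colSums(dE_raw)
    dHk <- dHk + tcrossprod(ds, layer$a_src[, k]) + tcrossprod(dt, layer$a_dst[, k])
    da_src[, k] <- crossprod(Hk, ds)
    da_dst[, k] <- crossprod(Hk, dt)
    dH[, cols] <- dHk
  }
  list(W = crossprod(cache$X, dH), a_src = da_src, a_dst = da_dst,
       dX = tcrossprod(dH, layer$W))
}

# Gradient of the cross-entropy loss of one graph w.r.t. all parameters.
backward_graph <- function(net, fwd, mask, label) {
  mi <- mask_info(mask)
  grads <- list()
  y <- label + 1L  # 1 = HC, 2 = MDD
  dlogits <- fwd$p
  dlogits[y] <- dlogits[y] - 1
  grads$fc_W <- outer(fwd$g, dlogits)
  grads$fc_b <- dlogits
  dg <- drop(net$fc_W %*% dlogits)
  dX <- matrix(dg, fwd$n, length(dg), byrow = TRUE) / fwd$n  # GAP backward
  for (l in rev(seq_along(net$layers))) {
    bk <- gat_layer_backward(net$layers[[l]], fwd$caches[[l]], mi, dX)
    grads[[sprintf("L%d.W", l)]] <- bk$W
    grads[[sprintf("L%d.a_src", l)]] <- bk$a_src
    grads[[sprintf("L%d.a_dst", l)]] <- bk$a_dst
    dX <- bk$dX
    if (!is.null(fwd$caches[[l]]$drop_mask)) dX <- dX * fwd$caches[[l]]$drop_mask
  }
  grads
}

# ---- optimizer --------------------------------------------------------

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

# ---- evaluation helpers ----------------------------------------------

#' Predict class probabilities for a list of graphs
#'
#' @param net a `gat_network` or `trained_atlas_model`.
#' @param graphs list of `brain_graph`s.
#' @return Matrix with one row per graph and columns `HC`, `MDD`.
#' @export
predict_gat <- function(net, graphs) {
  if (inherits(net, "trained_atlas_model")) net <- net$network
  out <- t(vapply(graphs, function(g) gat_forward(net, g), numeric(2)))
  colnames(out) <- c("HC", "MDD")
  out
}

eval_loss_acc <- function(net, feats, masks, labels) {
  n <- length(feats)
  loss <- 0
  correct <- 0L
  for (i in seq_len(n)) {
    p <- forward_cached(net, feats[[i]], masks[[i]], FALSE)$p
    loss <- loss - log(max(p[labels[i] + 1L], 1e-12))
    pred <- if (p[2L] >= p[1L]) 1L else 0L  # probability ties -> MDD
    correct <- correct + (pred == labels[i])
  }
  c(loss = loss / n, acc = correct / n)
}

# ---- training ---------------------------------------------------------

#' Train a single-atlas GAT classifier
#'
#' Minibatch Adam on the cross-entropy loss with L2 weight decay added to
#' the gradients, dropout on node features before each layer, and early
#' stopping on validation loss: training stops after `config$patience`
#' epochs without improvement and the parameters of the best-validation
#' epoch are returned together with that epoch's validation accuracy
#' (the quantity ensemble weighting and tie-breaking use).
#'
#' Fully deterministic given `config$seed` (initialization, shuffling and
#' dropout all draw from sub-streams keyed by `atlas`).
#'
#' @param train_graphs,val_graphs lists of `brain_graph`s with labels;
#'   training data must contain both classes.
#' @param config a [pipeline_config()].
#' @param atlas atlas name recorded on the model (also keys the RNG
#'   sub-streams so different atlases get independent draws).
#' @return A `trained_atlas_model`: `atlas`, `network`, `val_accuracy`,
#'   and a per-epoch `training_log` data frame (`epoch`, `train_loss`,
#'   `val_loss`, `val_acc`).
#' @export
train_gat <- function(train_graphs, val_graphs, config, atlas = "atlas") {
  if (!length(train_graphs)) stopf("empty training set")
  labels <- vapply(train_graphs, `[[`, integer(1), "label")
  if (length(unique(labels)) < 2L) stopf("training data must contain both classes")
  val_labels <- vapply(val_graphs, `[[`, integer(1), "label")
  in_dim <- ncol(train_graphs[[1L]]$node_features)

  feats <- lapply(train_graphs, `[[`, "node_features")
  masks <- lapply(train_graphs, function(g) mask_info(graph_mask(g)))
  vfeats <- lapply(val_graphs, `[[`, "node_features")
  vmasks <- lapply(val_graphs, function(g) mask_info(graph_mask(g)))

  net <- withr::with_seed(substream_seed(config$seed, paste0("init-", atlas)),
                          init_gat(in_dim, config))
  flat <- net_flatten(net)
  state <- adam_init(flat)
  n <- length(train_graphs)
  log_rows <- vector("list", config$max_epochs)
  best <- list(loss = Inf, flat = flat, acc = NA_real_)
  wait <- 0L

  withr::with_seed(substream_seed(config$seed, paste0("train-", atlas)), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        acc_grads <- NULL
        for (i in idx) {
          fwd <- forward_cached(net, feats[[i]], masks[[i]], TRUE)
          epoch_loss <- epoch_loss - log(max(fwd$p[labels[i] + 1L], 1e-12))
          g <- backward_graph(net, fwd, masks[[i]], labels[i])
          acc_grads <- if (is.null(acc_grads)) g
                       else Map(`+`, acc_grads, g[names(acc_grads)])
        }
        acc_grads <- lapply(acc_grads, `/`, length(idx))
        if (config$weight_decay > 0)
          acc_grads <- Map(function(gr, p) gr + config$weight_decay * p,
                           acc_grads[names(flat)], flat)
        upd <- adam_step(flat, acc_grads[names(flat)], state, config$learning_rate)
        flat <- upd$flat
        state <- upd$state
        net <- net_unflatten(net, flat)
      }
      val <- eval_loss_acc(net, vfeats, vmasks, val_labels)
      log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = epoch_loss / n,
                                      val_loss = val[["loss"]],
                                      val_acc = val[["acc"]])
      if (val[["loss"]] < best$loss - 1e-9) {
        best <- list(loss = val[["loss"]], flat = flat, acc = val[["acc"]])
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })

  net <- net_unflatten(net, best$flat)
  structure(list(atlas = atlas, network = net, val_accuracy = best$acc,
                 training_log = do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)])),
            class = "trained_atlas_model")
}

#' Exhaustive hyperparameter grid search
#'
#' Sweeps learning rate x weight decay x batch size x dropout (defaults:
#' the four standard lists, 256 cells) by training one model per cell and
#' scoring it on validation accuracy. Ties prefer the lower learning rate,
#' then the lower weight decay.
#'
#' @param train_graphs,val_graphs as in [train_gat()].
#' @param config base [pipeline_config()]; swept fields are overridden
#'   cell by cell.
#' @param grid named list with any of `learning_rate`, `weight_decay`,
#'   `batch_size`, `dropout_rate`.
#' @param atlas passed through to [train_gat()].
#' @return List with `best_config` (a full `pipeline_config`) and
#'   `table`, one row per cell with its validation accuracy.
#' @export
grid_search <- function(train_graphs, val_graphs, config,
                        grid = list(
                          learning_rate = c(1e-2, 1e-3, 1e-4, 1e-5),
                          weight_decay = c(1e-3, 5e-4, 1e-4, 5e-5),
                          batch_size = c(8L, 16L, 32L, 64L),
                          dropout_rate = c(0.2, 0.3, 0.4, 0.5)),
                        atlas = "atlas") {
  allowed <- c("learning_rate", "weight_decay", "batch_size", "dropout_rate")
  if (!length(grid) || !all(names(grid) %in% allowed))
    stopf("grid must be a non-empty list over: %s", paste(allowed, collapse = ", "))
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$val_accuracy <- NA_real_
  best_i <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    cfg <- config
    for (nm in setdiff(names(cells), "val_accuracy")) cfg[[nm]] <- cells[[nm]][i]
    fit <- train_gat(train_graphs, val_graphs, cfg, atlas = atlas)
    cells$val_accuracy[i] <- fit$val_accuracy
    score <- function(j) {  # diverged cells (non-finite accuracy) never win
      v <- cells$val_accuracy[j]
      if (is.finite(v)) v else -Inf
    }
    better <- is.na(best_i) ||
      score(i) > score(best_i) ||
      (score(i) == score(best_i) &&
         !is.null(cells$learning_rate) &&
         (cells$learning_rate[i] < cells$learning_rate[best_i] ||
            (cells$learning_rate[i] == cells$learning_rate[best_i] &&
               !is.null(cells$weight_decay) &&
               cells$weight_decay[i] < cells$weight_decay[best_i])))
    if (is.na(better)) better <- FALSE
    if (better) best_i <- i
  }
  best_cfg <- config
  for (nm in setdiff(names(cells), "val_accuracy"))
    best_cfg[[nm]] <- cells[[nm]][best_i]
  list(best_config = best_cfg, table = cells)
}
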