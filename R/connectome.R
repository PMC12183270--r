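# Functional connectivity networks: Pearson correlation between ROI time
# series, Fisher z-transform, and conversion to an undirected weighted
# k-nearest-neighbour graph whose node features are the FCN rows.

#' Pearson functional connectivity matrix
#'
#' Correlates every pair of columns (ROIs) of a `T x n` time-series
#' matrix. Constant columns get all their off-diagonal correlations set to
#' 0 with a warning; the diagonal is 1.
#'
#' @param series numeric matrix, `T >= 3` rows.
#' @return `n x n` symmetric correlation matrix with entries in
#'   `[-1, 1]`.
#' @export
pearson_fcn <- function(series) {
  series <- as.matrix(series)
  if (nrow(series) < 3L) stopf("pearson_fcn needs at least 3 time points")
  sds <- apply(series, 2L, stats::sd)
  constant <- sds == 0
  r <- suppressWarnings(stats::cor(series))
  if (any(constant)) {
    warnf("%d constant column(s); their correlations set to 0", sum(constant))
    r[constant, ] <- 0
    r[, constant] <- 0
  }
  r[is.na(r)] <- 0
  diag(r) <- 1
  r
}

#' Fisher z-transform a correlation matrix
#'
#' Off-diagonal entries become `atanh(r)` after clipping to
#' `[-1 + 1e-7, 1 - 1e-7]` so perfect correlations stay finite; the
#' diagonal is forced to 0 (self-connectivity carries no information and
#' would otherwise be infinite).
#'
#' @param r correlation matrix with entries in `[-1, 1]`.
#' @param atlas,subject_id optional identifiers carried on the result.
#' @return A `connectivity_matrix`: list with `values` (the z-scale
#'   matrix), `n`, `atlas`, `subject_id`.
#' @export
fisher_z <- function(r, atlas = NA_character_, subject_id = NA_character_) {
  r <- as.matrix(r)
  if (any(r < -1 - 1e-12 | r > 1 + 1e-12, na.rm = TRUE))
    stopf("correlations outside [-1, 1]")
  z <- atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
  diag(z) <- 0
  z <- (z + t(z)) / 2  # enforce exact symmetry against rounding noise
  structure(list(values = z, n = ncol(z), atlas = atlas, subject_id = subject_id),
            class = "connectivity_matrix")
}

#' Build a KNN brain graph from a connectivity matrix
#'
#' Each node is connected to the `k` nodes with the largest absolute
#' Fisher-z connectivity (ties broken toward the lower node index,
#' diagonal excluded); the edge set is the union over both directions, so
#' the graph is undirected and every node has degree at least `k`. Edge
#' weights are the signed z values, and node `i`'s feature vector is row
#' `i` of the connectivity matrix.
#'
#' @param fcn a `connectivity_matrix` (or plain symmetric matrix).
#' @param k neighbours per node, `1 <= k <= n - 1`.
#' @param label optional class label (1 = MDD, 0 = HC) attached to the
#'   graph.
#' @return A `brain_graph`: `n_nodes`, `node_features` (`n x n`),
#'   `edges` data frame with 1-based `src < dst` and `weight` (each
#'   undirected edge stored once; exports use 0-based indices, see
#'   [write_graph()]), `label`, `subject_id`, `atlas`.
#' @export
knn_graph <- function(fcn, k, label = NA_integer_) {
  if (inherits(fcn, "connectivity_matrix")) {
    z <- fcn$values; atlas <- fcn$atlas; subject_id <- fcn$subject_id
  } else {
    z <- as.matrix(fcn); atlas <- NA_character_; subject_id <- NA_character_
  }
  n <- ncol(z)
  k <- as.integer(k)
  if (k < 1L || k > n - 1L) stopf("k must lie in [1, n-1]; got %d for n = %d", k, n)
  src <- integer(0); dst <- integer(0)
  for (i in seq_len(n)) {
    cand <- abs(z[i, ])
    cand[i] <- -Inf
    nb <- order(-cand, seq_len(n))[seq_len(k)]
    src <- c(src, rep.int(i, k)); dst <- c(dst, nb)
  }
  lo <- pmin(src, dst); hi <- pmax(src, dst)
  keep <- !duplicated(cbind(lo, hi))
  edges <- data.frame(src = lo[keep], dst = hi[keep],
                      weight = z[cbind(lo[keep], hi[keep])])
  edges <- edges[order(edges$src, edges$dst), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(n_nodes = n, node_features = z, edges = edges,
                 label = as.integer(label), subject_id = subject_id,
                 atlas = atlas),
            class = "brain_graph")
}

# Dense logical adjacency (no self-loops) from the stored edge list.
graph_adjacency <- function(g) {
  m <- matrix(FALSE, g$n_nodes, g$n_nodes)
  m[cbind(g$edges$src, g$edges$dst)] <- TRUE
  m[cbind(g$edges$dst, g$edges$src)] <- TRUE
  m
}

#' Degrees of a brain graph
#' @param g a `brain_graph`.
#' @return Integer vector of node degrees (self-loops excluded).
#' @export
graph_degrees <- function(g) {
  tabulate(c(g$edges$src, g$edges$dst), nbins = g$n_nodes)
}

#' Build one graph per subject for an atlas
#'
#' Composition `pearson_fcn` -> `fisher_z` -> `knn_graph` applied to every
#' subject's series for the given atlas, with class labels attached.
#'
#' @param x a `cohort`.
#' @param atlas atlas name present in the cohort.
#' @param k KNN parameter passed to [knn_graph()].
#' @return List of `brain_graph`s in cohort subject order.
#' @export
build_graph_dataset <- function(x, atlas, k) {
  stopifnot(inherits(x, "cohort"))
  if (!atlas %in% names(x$atlases)) stopf("unknown atlas '%s'", atlas)
  lapply(x$subjects, function(s) {
    z <- fisher_z(pearson_fcn(s$series[[atlas]]), atlas = atlas,
                  subject_id = s$subject_id)
    knn_graph(z, k, label = s$label)
  })
}

#' Export / import a brain graph as text
#'
#' `write_graph()` writes two tab-delimited files: an edge list
#' (`src  dst  weight`, 0-based node indices, one line per undirected
#' edge) and the node-feature matrix (one row per node).
#'
#' @param g a `brain_graph`.
#' @param edges_path,features_path output paths.
#' @return Invisibly, `edges_path`.
#' @export
write_graph <- function(g, edges_path, features_path) {
  edges <- data.table::data.table(src = g$edges$src - 1L, dst = g$edges$dst - 1L,
                                  weight = g$edges$weight)
  data.table::fwrite(edges, edges_path, sep = "\t")
  data.table::fwrite(data.table::as.data.table(g$node_features), features_path,
                     sep = "\t", col.names = FALSE)
  invisible(edges_path)
}
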