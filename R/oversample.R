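# Class-wise SMOTE on T x N time-series matrices. Interpolation is
# row-wise: one Uniform(0,1) gap per time point, shared across that row's
# ROIs and across atlases, so each synthetic subject is internally
# consistent (one neighbour and one gap vector serve all its matrices).

#' SMOTE settings
#'
#' @param k_neighbors nearest neighbours searched per seed sample
#'   (Euclidean distance on the flattened concatenation of all atlas
#'   matrices); must be >= 1 and smaller than the class size at use time.
#' @param multiplier oversampling factor; 2 doubles the class, 1 is a
#'   no-op.
#' @param gap_mode `"per_row"` draws one gap per time point (default);
#'   `"per_sample"` draws a single gap for the whole subject.
#' @param gap_fixed optional fixed gap in `[0, 1]` overriding the random
#'   draw; `gap_fixed = 0` reproduces the seed sample exactly and
#'   `gap_fixed = 1` the chosen neighbour (degenerate-case checks).
#' @param seed sub-stream seed for neighbour choice and gaps.
#' @return A `smote_spec` object.
#' @export
smote_spec <- function(k_neighbors = 3L, multiplier = 2L,
                       gap_mode = c("per_row", "per_sample"),
                       gap_fixed = NULL, seed = 1L) {
  gap_mode <- match.arg(gap_mode)
  k_neighbors <- as.integer(k_neighbors)
  multiplier <- as.integer(multiplier)
  if (k_neighbors < 1L) stopf("k_neighbors must be >= 1")
  if (multiplier < 1L) stopf("multiplier must be >= 1")
  if (!is.null(gap_fixed) && (gap_fixed < 0 || gap_fixed > 1))
    stopf("gap_fixed must lie in [0, 1]")
  structure(list(k_neighbors = k_neighbors, multiplier = multiplier,
                 gap_mode = gap_mode, gap_fixed = gap_fixed,
                 seed = as.integer(seed)),
            class = "smote_spec")
}

#' Generate synthetic subjects for one class by SMOTE
#'
#' Seed samples are visited in sorted subject-id order, cycling until
#' `(multiplier - 1) * n` synthetic records exist. For each seed sample
#' one of its `k_neighbors` nearest same-class neighbours is chosen
#' uniformly at random; for each time point `t` a gap in `[0, 1]` is drawn
#' and the synthetic row is `seed_row + (neighbor_row - seed_row) * gap`,
#' with the same neighbour and the same per-row gaps reused across all
#' atlases. Synthetic records are flagged `is_synthetic`, inherit the
#' class label and the seed sample's site, get fresh ids prefixed
#' `syn:`, and record their parents in attribute `"parents"`.
#'
#' @param samples list of `subject_record`s, all of one class, of length
#'   at least `k_neighbors + 1`.
#' @param spec a [smote_spec()].
#' @return List of synthetic `subject_record`s (may be empty when
#'   `multiplier = 1`).
#' @export
smote_class <- function(samples, spec) {
  stopifnot(inherits(spec, "smote_spec"))
  n <- length(samples)
  labels <- vapply(samples, `[[`, integer(1), "label")
  if (length(unique(labels)) > 1L) stopf("smote_class: samples span both classes")
  if (n < spec$k_neighbors + 1L)
    stopf("class size %d too small for k_neighbors = %d (need >= k+1)",
          n, spec$k_neighbors)
  n_syn <- (spec$multiplier - 1L) * n
  if (n_syn == 0L) return(list())

  ids <- vapply(samples, `[[`, "", "subject_id")
  samples <- samples[order(ids)]
  ids <- ids[order(ids)]
  flat <- vapply(samples, function(s)
    unlist(lapply(s$series, as.vector), use.names = FALSE),
    numeric(sum(vapply(samples[[1L]]$series, length, integer(1)))))
  d2 <- as.matrix(stats::dist(t(flat)))^2
  diag(d2) <- Inf
  # k nearest same-class neighbours per seed, ties by lower index
  nn <- lapply(seq_len(n), function(i)
    order(d2[i, ], seq_len(n))[seq_len(spec$k_neighbors)])

  t_points <- nrow(samples[[1L]]$series[[1L]])
  withr::with_seed(substream_seed(spec$seed, "smote"), {
    out <- vector("list", n_syn)
    for (s_i in seq_len(n_syn)) {
      seed_i <- ((s_i - 1L) %% n) + 1L
      nb_i <- nn[[seed_i]][sample.int(spec$k_neighbors, 1L)]
      gaps <- if (!is.null(spec$gap_fixed)) {
        rep(spec$gap_fixed, t_points)
      } else if (spec$gap_mode == "per_row") {
        stats::runif(t_points)
      } else {
        rep(stats::runif(1L), t_points)
      }
      seed_s <- samples[[seed_i]]
      nb_s <- samples[[nb_i]]
      # row t of the synthetic matrix uses gaps[t] for every ROI
      series <- lapply(names(seed_s$series), function(a) {
        s0 <- seed_s$series[[a]]
        s1 <- nb_s$series[[a]]
        s0 + (s1 - s0) * matrix(gaps, nrow(s0), ncol(s0))
      })
      names(series) <- names(seed_s$series)
      rec <- subject_record(
        sprintf("syn:%s:%03d", seed_s$subject_id, s_i),
        seed_s$site_id, seed_s$label,
        seed_s$age, seed_s$sex, series, is_synthetic = TRUE)
      attr(rec, "parents") <- c(seed = seed_s$subject_id, neighbor = nb_s$subject_id)
      out[[s_i]] <- rec
    }
    out
  })
}

#' Oversample train and validation sets class-wise
#'
#' Applies [smote_class()] independently per class within each of the two
#' sets; at the default multiplier 2 each class count is exactly doubled.
#' Test data must never be passed through here.
#'
#' @param train,val lists of `subject_record`s, each containing both
#'   classes.
#' @param spec a [smote_spec()]; the validation set uses a derived
#'   sub-stream so the two sets draw independent gaps.
#' @return List with `train` and `val`, each the input records followed by
#'   their synthetic records.
#' @export
oversample_split <- function(train, val, spec) {
  aug <- function(records, set_name) {
    labels <- vapply(records, `[[`, integer(1), "label")
    if (length(unique(labels)) < 2L)
      stopf("%s set must contain both classes", set_name)
    set_spec <- spec
    set_spec$seed <- substream_seed(spec$seed, paste0("smote-", set_name))
    syn <- list()
    for (lab in c(1L, 0L)) {
      syn <- c(syn, smote_class(records[labels == lab], set_spec))
    }
    c(records, syn)
  }
  list(train = aug(train, "train"), val = aug(val, "val"))
}

#' Paired t-test between a real and a synthetic subject
#'
#' Flattens both subjects' series (all atlases) and runs a two-sided
#' paired t-test over the aligned entries, as a realism check that
#' synthetic samples are not systematically shifted from their real
#' counterparts. Identical samples (zero-variance differences) return
#' p = 1 by convention.
#'
#' @param real,synthetic `subject_record`s of identical shape.
#' @return The two-sided p-value.
#' @export
validate_synthetic <- function(real, synthetic) {
  a <- unlist(lapply(real$series, as.vector), use.names = FALSE)
  b <- unlist(lapply(synthetic$series, as.vector), use.names = FALSE)
  if (length(a) != length(b)) stopf("subjects have different shapes")
  d <- b - a
  if (all(d == 0)) {
    mag_log("identical samples (zero differences); p = 1 by convention", "debug")
    return(1)
  }
  # a constant non-zero difference drives |t| unbounded; stats::t.test
  # refuses such ill-conditioned input, so fall back to the closed form
  tryCatch(stats::t.test(b, a, paired = TRUE)$p.value,
           error = function(e) {
             tstat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
             2 * stats::pt(-abs(tstat), df = length(d) - 1)
           })
}
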