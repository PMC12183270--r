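# Internal: flatten per-subject series into a feature x subject matrix.
# A "feature" is one (atlas, time point, ROI) entry, column-major within
# each atlas matrix; this is the unit ComBat harmonizes and the unit the
# simulator attaches site effects to.

feature_index <- function(x) {
  parts <- lapply(x$atlases, function(a) {
    data.table::data.table(
      atlas = a$name,
      t = rep(seq_len(x$t_points), a$n_rois),
      roi = rep(seq_len(a$n_rois), each = x$t_points)
    )
  })
  idx <- data.table::rbindlist(parts)
  idx$feature <- seq_len(nrow(idx))
  idx
}

flatten_series <- function(x) {
  anames <- names(x$atlases)
  cols <- vapply(x$subjects, function(s) {
    unlist(lapply(anames, function(a) as.vector(s$series[[a]])), use.names = FALSE)
  }, numeric(x$t_points * sum(vapply(x$atlases, `[[`, integer(1), "n_rois"))))
  colnames(cols) <- cohort_ids(x)
  cols
}

# Inverse of flatten_series for one subject's column vector.
unflatten_series <- function(values, x) {
  out <- list()
  offset <- 0L
  for (a in x$atlases) {
    len <- x$t_points * a$n_rois
    out[[a$name]] <- matrix(values[(offset + 1L):(offset + len)],
                            nrow = x$t_points, ncol = a$n_rois)
    offset <- offset + len
  }
  out
}
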