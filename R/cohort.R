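# Data model: atlases, subjects, cohorts, pipeline configuration, and the
# on-disk cohort dialect (tab-delimited manifest + one T x N series file per
# subject/atlas pair).

#' Define a parcellation atlas
#'
#' An atlas is a fixed segmentation of the brain into regions of interest
#' (ROIs); every subject carries one `T x n_rois` time-series matrix per
#' atlas. The four atlases of the reference pipeline are available through
#' [default_atlases()].
#'
#' @param name atlas identifier (e.g. `"AAL"`).
#' @param n_rois number of regions, at least 2.
#' @return An `atlas_spec` object.
#' @examples
#' atlas_spec("AAL", 116)
#' @export
atlas_spec <- function(name, n_rois) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_rois <- as.integer(n_rois)
  if (is.na(n_rois) || n_rois < 2L) stopf("atlas '%s': n_rois must be >= 2", name)
  structure(list(name = name, n_rois = n_rois), class = "atlas_spec")
}

#' The four standard atlases
#'
#' Dosenbach's 160 functional ROIs (Dose), Automated Anatomical Labeling
#' (AAL, 116), Craddock's clustering atlas (CK, 200) and Harvard-Oxford
#' (HO, 112).
#'
#' @return Named list of [atlas_spec()] objects in fixed order
#'   Dose, AAL, CK, HO (the order also used for ensemble tie-breaking).
#' @export
default_atlases <- function() {
  list(
    Dose = atlas_spec("Dose", 160L),
    AAL  = atlas_spec("AAL", 116L),
    CK   = atlas_spec("CK", 200L),
    HO   = atlas_spec("HO", 112L)
  )
}

#' Create a subject record
#'
#' @param subject_id unique subject identifier.
#' @param site_id acquisition-site identifier (ComBat batch).
#' @param label diagnostic class: 1 = MDD (positive), 0 = HC (negative).
#'   The strings `"MDD"`/`"HC"` are accepted and recoded.
#' @param age age in years (>= 0).
#' @param sex binary indicator (0/1).
#' @param series named list, one `T x n_rois` numeric matrix per atlas.
#' @param is_synthetic flag marking SMOTE-generated records; synthetic
#'   subjects are barred from test sets.
#' @return A `subject_record` object.
#' @export
subject_record <- function(subject_id, site_id, label, age, sex, series,
                           is_synthetic = FALSE) {
  label <- encode_label(label)
  stopifnot(length(subject_id) == 1L, length(site_id) == 1L)
  if (!is.numeric(age) || age < 0) stopf("subject '%s': age must be >= 0", subject_id)
  sex <- as.integer(sex)
  if (!sex %in% c(0L, 1L)) stopf("subject '%s': sex must be 0/1", subject_id)
  if (!is.list(series) || is.null(names(series)) || any(!nzchar(names(series))))
    stopf("subject '%s': series must be a named list of matrices", subject_id)
  series <- lapply(series, as.matrix)
  structure(
    list(subject_id = as.character(subject_id), site_id = as.character(site_id),
         label = label, age = as.numeric(age), sex = sex, series = series,
         is_synthetic = isTRUE(is_synthetic)),
    class = "subject_record"
  )
}

encode_label <- function(label) {
  if (is.character(label)) {
    up <- toupper(label)
    if (!all(up %in% c("MDD", "HC"))) stopf("labels must be MDD/HC or 1/0")
    return(as.integer(up == "MDD"))
  }
  lab <- as.integer(label)
  if (any(is.na(lab)) || !all(lab %in% c(0L, 1L))) stopf("labels must be MDD/HC or 1/0")
  lab
}

decode_label <- function(label) c("HC", "MDD")[label + 1L]

#' Assemble and validate a cohort
#'
#' A cohort bundles an atlas list with subject records; every subject must
#' carry a complete, finite `t_points x n_rois` series for every atlas.
#'
#' @param atlases list of [atlas_spec()] objects.
#' @param subjects list of [subject_record()] objects.
#' @param t_points number of time points shared by all series.
#' @return A validated `cohort` object.
#' @export
cohort <- function(atlases, subjects, t_points) {
  if (inherits(atlases, "atlas_spec")) atlases <- list(atlases)
  names(atlases) <- vapply(atlases, `[[`, "", "name")
  if (anyDuplicated(names(atlases))) stopf("atlas names must be unique")
  t_points <- as.integer(t_points)
  x <- structure(list(atlases = atlases, subjects = subjects, t_points = t_points),
                 class = "cohort")
  validate_cohort(x)
}

validate_cohort <- function(x) {
  ids <- vapply(x$subjects, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stopf("duplicate subject_ids: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (s in x$subjects) {
    missing <- setdiff(names(x$atlases), names(s$series))
    if (length(missing))
      stopf("subject '%s' lacks series for atlas(es): %s",
            s$subject_id, paste(missing, collapse = ", "))
    for (a in x$atlases) {
      m <- s$series[[a$name]]
      if (nrow(m) != x$t_points)
        stopf("subject '%s', atlas '%s': %d time points, expected %d",
              s$subject_id, a$name, nrow(m), x$t_points)
      if (ncol(m) != a$n_rois)
        stopf("subject '%s', atlas '%s': %d columns, expected %d ROIs",
              s$subject_id, a$name, ncol(m), a$n_rois)
      if (!all(is.finite(m)))
        stopf("subject '%s', atlas '%s': non-finite values", s$subject_id, a$name)
    }
  }
  x
}

#' @method print cohort
#' @export
print.cohort <- function(x, ...) {
  labs <- cohort_labels(x)
  cat(sprintf("<cohort> %d subjects (%d MDD / %d HC, %d synthetic), T = %d\n",
              length(x$subjects), sum(labs == 1L), sum(labs == 0L),
              sum(cohort_flags(x)), x$t_points))
  for (a in x$atlases) cat(sprintf("  atlas %s: %d ROIs\n", a$name, a$n_rois))
  cat(sprintf("  sites: %s\n", paste(sort(unique(cohort_sites(x))), collapse = ", ")))
  invisible(x)
}

#' Subject-level accessors
#'
#' Vectorised views of a cohort: class labels (1 = MDD, 0 = HC), subject
#' ids, site ids and the synthetic flag, in subject order.
#'
#' @param x a `cohort`.
#' @return An atomic vector with one entry per subject.
#' @export
cohort_labels <- function(x) vapply(x$subjects, `[[`, integer(1), "label")

#' @rdname cohort_labels
#' @export
cohort_ids <- function(x) vapply(x$subjects, `[[`, character(1), "subject_id")

#' @rdname cohort_labels
#' @export
cohort_sites <- function(x) vapply(x$subjects, `[[`, character(1), "site_id")

#' @rdname cohort_labels
#' @export
cohort_flags <- function(x) vapply(x$subjects, `[[`, logical(1), "is_synthetic")

#' Subset a cohort by subject id
#'
#' @param x a `cohort`.
#' @param ids character vector of subject ids to keep (order preserved).
#' @return A new `cohort` holding exactly those subjects.
#' @export
subset_cohort <- function(x, ids) {
  idx <- match(ids, cohort_ids(x))
  if (anyNA(idx)) stopf("unknown subject id(s): %s",
                        paste(ids[is.na(idx)], collapse = ", "))
  out <- x
  out$subjects <- x$subjects[idx]
  out
}

#' Pipeline configuration
#'
#' Hyperparameters and run controls for the full pipeline. Defaults are the
#' final configuration of the reference study: batch size 16, learning rate
#' 1e-3, weight decay 5e-4, dropout 0.5, three GAT layers of total width 64
#' with 4 attention heads, SMOTE with k = 3 neighbours and doubling,
#' stratified 10-fold cross-validation.
#'
#' @param batch_size minibatch size for Adam.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 regularization coefficient added to gradients.
#' @param dropout_rate dropout probability applied to node features before
#'   each GAT layer (training only), in (0, 1].
#' @param n_layers number of stacked GAT layers.
#' @param hidden_units total width of each GAT layer (all heads combined).
#' @param n_heads attention heads per layer; must divide `hidden_units`.
#' @param knn_k neighbours per node when building brain graphs.
#' @param smote_k SMOTE nearest-neighbour count.
#' @param smote_multiplier SMOTE oversampling factor (2 = double).
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience on validation loss, in epochs.
#' @param n_folds folds for stratified cross-validation.
#' @param seed root seed; every stage derives a sub-stream from it via
#'   [substream_seed()].
#' @param ensemble_method `"majority"`, `"sum"` or `"weighted_sum"`.
#' @param harmonize whether to run ComBat before splitting (skipped with a
#'   log note when the cohort has a single site).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(batch_size = 16L, learning_rate = 1e-3,
                            weight_decay = 5e-4, dropout_rate = 0.5,
                            n_layers = 3L, hidden_units = 64L, n_heads = 4L,
                            knn_k = 10L, smote_k = 3L, smote_multiplier = 2L,
                            max_epochs = 200L, patience = 20L, n_folds = 10L,
                            seed = 1L, ensemble_method = "majority",
                            harmonize = TRUE) {
  cfg <- list(
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    weight_decay = weight_decay, dropout_rate = dropout_rate,
    n_layers = as.integer(n_layers), hidden_units = as.integer(hidden_units),
    n_heads = as.integer(n_heads), knn_k = as.integer(knn_k),
    smote_k = as.integer(smote_k), smote_multiplier = as.integer(smote_multiplier),
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    n_folds = as.integer(n_folds), seed = as.integer(seed),
    ensemble_method = match.arg(ensemble_method, c("majority", "sum", "weighted_sum")),
    harmonize = isTRUE(harmonize)
  )
  ints <- c("batch_size", "n_layers", "hidden_units", "n_heads", "knn_k",
            "smote_k", "smote_multiplier", "max_epochs", "patience", "n_folds")
  for (f in ints) if (cfg[[f]] < 1L) stopf("%s must be a positive integer", f)
  if (cfg$learning_rate < 0 || cfg$weight_decay < 0)
    stopf("learning_rate and weight_decay must be non-negative")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1)
    stopf("dropout_rate must lie in [0, 1]")
  if (cfg$hidden_units %% cfg$n_heads != 0L)
    stopf("hidden_units (%d) must be divisible by n_heads (%d)",
          cfg$hidden_units, cfg$n_heads)
  structure(cfg, class = "pipeline_config")
}

series_file <- function(subject_id, atlas) sprintf("%s__%s.tsv", subject_id, atlas)

#' Write a cohort to disk
#'
#' Writes the tab-delimited cohort dialect: a manifest table (`subject_id`,
#' `site_id`, `label`, `age`, `sex`, `is_synthetic`) plus one tab-delimited
#' `T x n_rois` numeric file per (subject, atlas) pair, named
#' `<subject_id>__<atlas>.tsv`. Subjects are written sorted by id so output
#' is deterministic.
#'
#' @param x a `cohort`.
#' @param manifest_path path of the manifest file to create.
#' @param series_dir directory receiving the series files (created if
#'   absent).
#' @return Invisibly, the manifest path.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(x, manifest_path, series_dir) {
  validate_cohort(x)
  if (!dir.exists(series_dir) && !dir.create(series_dir, recursive = TRUE))
    stopf("cannot create series directory '%s'", series_dir)
  ord <- order(cohort_ids(x))
  subs <- x$subjects[ord]
  manifest <- data.table::data.table(
    subject_id = vapply(subs, `[[`, "", "subject_id"),
    site_id = vapply(subs, `[[`, "", "site_id"),
    label = decode_label(vapply(subs, `[[`, integer(1), "label")),
    age = vapply(subs, `[[`, numeric(1), "age"),
    sex = vapply(subs, `[[`, integer(1), "sex"),
    is_synthetic = vapply(subs, `[[`, logical(1), "is_synthetic")
  )
  data.table::fwrite(manifest, manifest_path, sep = "\t")
  for (s in subs) {
    for (a in names(x$atlases)) {
      data.table::fwrite(data.table::as.data.table(s$series[[a]]),
                         file.path(series_dir, series_file(s$subject_id, a)),
                         sep = "\t", col.names = FALSE)
    }
  }
  invisible(manifest_path)
}

#' Read a cohort from disk
#'
#' Counterpart of [write_cohort()]. The atlas list is inferred from the
#' series files present for the first manifest subject; every subject must
#' then provide a file for every atlas (a missing file is a hard error
#' naming the pair). Subjects whose series contain any missing or
#' non-finite entry are dropped with a warning, mirroring the exclusion of
#' subjects with missing ROI signals. All series must agree on the number
#' of time points.
#'
#' @param manifest_path manifest file written by [write_cohort()] (or any
#'   delimited table with the same columns; `is_synthetic` is optional).
#' @param series_dir directory holding `<subject_id>__<atlas>.tsv` files.
#' @return A validated `cohort`.
#' @export
read_cohort <- function(manifest_path, series_dir) {
  if (!file.exists(manifest_path)) stopf("manifest '%s' not found", manifest_path)
  manifest <- data.table::fread(manifest_path, sep = "\t", colClasses = list(
    character = c("subject_id", "site_id")))
  need <- c("subject_id", "site_id", "label", "age", "sex")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) stopf("manifest lacks column(s): %s", paste(missing, collapse = ", "))
  if (!"is_synthetic" %in% names(manifest)) manifest$is_synthetic <- FALSE
  if (nrow(manifest) == 0L) stopf("manifest is empty")

  first <- manifest$subject_id[1L]
  pat <- sprintf("^%s__(.+)\\.tsv$", first)
  hits <- list.files(series_dir, pattern = pat)
  if (!length(hits)) stopf("no series files for subject '%s' in '%s'", first, series_dir)
  atlas_names <- sort(sub(pat, "\\1", hits))

  t_points <- NULL
  atlases <- NULL
  subjects <- list()
  dropped <- character()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    series <- list()
    ok <- TRUE
    for (a in atlas_names) {
      f <- file.path(series_dir, series_file(row$subject_id, a))
      if (!file.exists(f))
        stopf("missing series file for subject '%s', atlas '%s' (%s)",
              row$subject_id, a, f)
      m <- as.matrix(data.table::fread(f, sep = "\t", header = FALSE))
      dimnames(m) <- NULL
      if (is.null(t_points)) t_points <- nrow(m)
      if (nrow(m) != t_points)
        stopf("inconsistent time-point count: subject '%s', atlas '%s' has %d rows, expected %d",
              row$subject_id, a, nrow(m), t_points)
      if (!all(is.finite(m))) ok <- FALSE
      series[[a]] <- m
    }
    if (!ok) {
      dropped <- c(dropped, row$subject_id)
      next
    }
    if (is.null(atlases))
      atlases <- lapply(atlas_names, function(a) atlas_spec(a, ncol(series[[a]])))
    subjects[[length(subjects) + 1L]] <- subject_record(
      row$subject_id, row$site_id, row$label, row$age, row$sex, series,
      is_synthetic = isTRUE(row$is_synthetic))
  }
  if (length(dropped))
    warnf("dropped %d subject(s) with missing/non-finite series values: %s",
          length(dropped), paste(dropped, collapse = ", "))
  if (!length(subjects)) stopf("no subjects with complete series")
  cohort(atlases, subjects, t_points)
}
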