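#' Trial/template extraction parameters
#'
#' @param trial_duration seconds of data per template and test trial
#' @param n_templates total number of decoding choices (movies x segments)
#' @param crop_initial seconds removed from the start of every run to
#'   avoid transient onset responses (default 15)
#' @param inter_trial_gap minimum seconds between consecutive trials so
#'   the previous hemodynamic response has faded (default 15)
#' @return list of class `trial_spec`
#' @export
trial_spec <- function(trial_duration, n_templates = 4L, crop_initial = 15,
                       inter_trial_gap = 15) {
  if (!is_number(trial_duration) || trial_duration <= 0) {
    dot_stop("dot_invalid_parameter", "trial_duration must be > 0")
  }
  if (!is_count(n_templates) || n_templates < 2) {
    dot_stop("dot_invalid_parameter", "n_templates must be an integer >= 2")
  }
  if (crop_initial < 0 || inter_trial_gap < 0) {
    dot_stop("dot_invalid_parameter", "crop and gap must be >= 0")
  }
  structure(list(trial_duration = trial_duration,
                 n_templates = as.integer(n_templates),
                 crop_initial = crop_initial,
                 inter_trial_gap = inter_trial_gap),
            class = "trial_spec")
}

#' Split a session's runs into training and test sets
#'
#' Every movie must appear exactly twice (two viewings).  The first
#' viewing of each movie forms the training set (template source) and the
#' second the test set; `train_viewing = 2` swaps the roles.
#'
#' @param runs list of run objects, each with `$run_label` (movie id) and
#'   `$viewing_index` (1 or 2)
#' @param train_viewing which viewing supplies the templates (1 or 2)
#' @return list of class `session_split` with `training`, `test`,
#'   `movie_ids`
#' @export
split_session <- function(runs, train_viewing = 1L) {
  labels <- vapply(runs, function(r) as.character(r$run_label), character(1))
  viewing <- vapply(runs, function(r) as.integer(r$viewing_index), integer(1))
  tab <- table(labels)
  if (any(tab != 2L)) {
    dot_stop("dot_design_error", sprintf(
      "every movie must appear exactly twice; counts: %s",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  for (m in names(tab)) {
    if (!setequal(viewing[labels == m], c(1L, 2L))) {
      dot_stop("dot_design_error",
               sprintf("movie %s lacks distinct viewings 1 and 2", m))
    }
  }
  movie_ids <- sort(names(tab))
  pick <- function(v) {
    sel <- which(viewing == v)
    sel[order(match(labels[sel], movie_ids))]
  }
  tr <- pick(as.integer(train_viewing))
  te <- pick(if (train_viewing == 1L) 2L else 1L)
  structure(list(training = runs[tr], test = runs[te], movie_ids = movie_ids),
            class = "session_split")
}

#' Extract equal-length segments from a run
#'
#' Drops the first `crop_initial` seconds, partitions the remainder into
#' `segments_per_run` equal blocks, and takes the first `trial_duration`
#' seconds of each block as a segment.  Each block must be at least
#' `trial_duration + inter_trial_gap` seconds long, which guarantees the
#' intervening fade-out period between consecutive trials.
#'
#' @param ts a `voxel_timeseries` (typically 1 Hz, post-preprocessing)
#' @param spec a [trial_spec()]
#' @param segments_per_run how many segments to cut from the run
#' @return list of segments; each has `data` (voxels x time), `label`
#'   (run label), `segment` (index within run), `start` (seconds)
#' @export
extract_segments <- function(ts, spec, segments_per_run = 1L) {
  fs <- ts$sampling_rate
  nt <- ncol(ts$data)
  crop_n <- round(spec$crop_initial * fs)
  avail <- nt - crop_n
  k <- as.integer(segments_per_run)
  if (k < 1) dot_stop("dot_invalid_parameter", "segments_per_run must be >= 1")
  block_s <- avail / (k * fs)
  need_s <- spec$trial_duration + spec$inter_trial_gap
  if (block_s < need_s - 1e-9) {
    dot_stop("dot_timing_error", sprintf(
      paste("segments do not fit: block length %.1f s <",
            "trial_duration + gap = %.1f s",
            "(run %.1f s, crop %.1f s, %d segments)"),
      block_s, need_s, nt / fs, spec$crop_initial, k))
  }
  dur_n <- round(spec$trial_duration * fs)
  lapply(seq_len(k), function(i) {
    i0 <- crop_n + floor((i - 1) * avail / k) + 1
    list(data = ts$data[, i0:(i0 + dur_n - 1), drop = FALSE],
         label = ts$run_label, segment = i, start = (i0 - 1) / fs,
         session_id = ts$session_id)
  })
}

## restrict two segments to the usable voxel rows: inside the mask, finite,
## and with nonzero temporal variance in both
usable_rows <- function(Td, Sd, mask) {
  ok <- mask &
    apply(is.finite(Td), 1, all) & apply(is.finite(Sd), 1, all)
  vT <- rowSums((Td - rowMeans(Td))^2)
  vS <- rowSums((Sd - rowMeans(Sd))^2)
  ok & vT > 0 & vS > 0
}

#' Spatiotemporal Pearson correlation between a template and a trial
#'
#' Subtracts from each voxels-by-time array its single scalar mean over
#' all (voxel, time) entries in the mask and window, then correlates the
#' two centered arrays: r = T'.S' / (|T'| |S'|).  Voxels outside the mask,
#' with non-finite values, or with zero temporal variance are excluded
#' from the centering and the dot products (the excluded count is
#' attached as attribute `n_excluded`).
#'
#' @param Td,Sd voxels x time matrices (template and trial), same shape
#' @param mask logical voxel vector (FOV, or FOV intersected with an ROI);
#'   NULL uses all voxels
#' @return correlation in \[-1, 1\]
#' @export
spatiotemporal_correlation <- function(Td, Sd, mask = NULL) {
  if (!identical(dim(Td), dim(Sd))) {
    dot_stop("dot_shape_error", "template and trial differ in shape")
  }
  if (is.null(mask)) mask <- rep(TRUE, nrow(Td))
  if (length(mask) != nrow(Td)) {
    dot_stop("dot_shape_error", "mask length must equal the voxel count")
  }
  ok <- usable_rows(Td, Sd, mask)
  if (!any(ok)) {
    dot_stop("dot_undefined_correlation",
             "no usable voxels inside the mask")
  }
  Tv <- Td[ok, , drop = FALSE]; Sv <- Sd[ok, , drop = FALSE]
  Tc <- Tv - mean(Tv)
  Sc <- Sv - mean(Sv)
  nT <- sqrt(sum(Tc^2)); nS <- sqrt(sum(Sc^2))
  if (nT == 0 || nS == 0) {
    dot_stop("dot_undefined_correlation",
             "centered input has zero norm (constant array)")
  }
  r <- sum(Tc * Sc) / (nT * nS)
  attr(r, "n_excluded") <- sum(mask) - sum(ok)
  r
}

#' Maximum-correlation classification of one trial
#'
#' Computes the spatiotemporal correlation of the trial against every
#' template and decodes the trial as the template with the largest
#' correlation.  Exact ties are broken toward the lowest template index
#' and flagged.
#'
#' @param Sd trial voxels x time matrix
#' @param templates list of template matrices (or segment lists with
#'   `$data`)
#' @param mask logical voxel vector or NULL
#' @return list with `decoded` (index), `r` (correlation vector), `tie`
#' @export
classify_trial <- function(Sd, templates, mask = NULL) {
  if (length(templates) < 2) {
    dot_stop("dot_invalid_parameter", "need at least two templates")
  }
  r <- vapply(templates, function(tp) {
    Td <- if (is.list(tp)) tp$data else tp
    as.numeric(spatiotemporal_correlation(Td, Sd, mask))
  }, numeric(1))
  dec <- which.max(r)  # which.max already takes the lowest index on ties
  list(decoded = dec, r = r, tie = sum(r == max(r)) > 1L)
}

#' Voxelwise temporal correlation map
#'
#' For each voxel in the mask, centers the template and trial time courses
#' by their own temporal means and computes the per-voxel Pearson
#' correlation over time.  Voxels outside the mask, or with zero temporal
#' variance in either input, are returned as NA.
#'
#' @param Td,Sd voxels x time matrices, same shape
#' @param mask logical voxel vector or NULL
#' @return numeric voxel vector of correlations (NA where undefined)
#' @export
correlation_map <- function(Td, Sd, mask = NULL) {
  if (!identical(dim(Td), dim(Sd))) {
    dot_stop("dot_shape_error", "template and trial differ in shape")
  }
  if (is.null(mask)) mask <- rep(TRUE, nrow(Td))
  Tc <- Td - rowMeans(Td)
  Sc <- Sd - rowMeans(Sd)
  num <- rowSums(Tc * Sc)
  den <- sqrt(rowSums(Tc^2) * rowSums(Sc^2))
  out <- ifelse(den > 0, num / den, NA_real_)
  out[!mask] <- NA_real_
  out
}

#' Decode one imaging session by template matching
#'
#' Builds templates from the training runs and trials from the test runs
#' with identical extraction parameters, classifies every trial by maximum
#' spatiotemporal correlation, and accumulates a confusion matrix of true
#' versus decoded segment identity.  Template index (n) enumerates movies
#' (sorted by label) times segments within movie, so `n_templates =
#' n_movies * segments_per_run`.
#'
#' @param split a `session_split` of `voxel_timeseries` runs
#' @param spec a [trial_spec()]; `spec$n_templates` must be a multiple of
#'   the number of movies in the split
#' @param mask logical voxel vector (FOV or FOV-intersected ROI), or NULL
#' @return list of class `session_decoding`: `confusion` (true x decoded
#'   counts), `correlations` (trials x templates), `accuracy`, `ties`
#' @export
decode_session <- function(split, spec, mask = NULL) {
  n_movies <- length(split$movie_ids)
  if (spec$n_templates %% n_movies != 0) {
    dot_stop("dot_invalid_parameter", sprintf(
      "n_templates (%d) must be a multiple of the movie count (%d)",
      spec$n_templates, n_movies))
  }
  segs_per_run <- spec$n_templates %/% n_movies
  cut_all <- function(runs) {
    out <- list()
    for (m in split$movie_ids) {
      run <- runs[[which(vapply(runs, function(r) as.character(r$run_label),
                                character(1)) == m)]]
      out <- c(out, extract_segments(run, spec, segs_per_run))
    }
    out
  }
  templates <- cut_all(split$training)
  trials <- cut_all(split$test)
  k <- spec$n_templates
  conf <- matrix(0L, k, k)
  rmat <- matrix(NA_real_, k, k)
  ties <- 0L
  for (i in seq_along(trials)) {
    res <- classify_trial(trials[[i]]$data, templates, mask)
    conf[i, res$decoded] <- conf[i, res$decoded] + 1L
    rmat[i, ] <- res$r
    if (res$tie) ties <- ties + 1L
  }
  structure(list(confusion = confusion_matrix(conf),
                 correlations = rmat,
                 accuracy = sum(diag(conf)) / sum(conf),
                 ties = ties,
                 n_templates = k,
                 trial_duration = spec$trial_duration),
            class = "session_decoding")
}

#' Confusion matrix container
#'
#' @param counts square matrix of non-negative integer counts, rows =
#'   true class, columns = decoded class
#' @return matrix of class `confusion_matrix`
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    dot_stop("dot_invalid_parameter",
             "counts must be a square non-negative integer matrix")
  }
  structure(counts, class = c("confusion_matrix", class(counts)))
}
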