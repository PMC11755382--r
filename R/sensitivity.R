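#' Construct a sensitivity matrix container
#'
#' @param A channels x voxels numeric matrix
#' @param grid the `voxel_grid` the columns refer to
#' @param wavelength wavelength in nm
#' @param channels channel data frame (as in an `optode_array`)
#' @return object of class `sensitivity_matrix`
#' @export
sensitivity_matrix <- function(A, grid, wavelength, channels = NULL) {
  A <- as.matrix(A)
  if (!all(is.finite(A))) dot_stop("dot_invalid_parameter", "A must be finite")
  if (ncol(A) != n_voxels(grid)) {
    dot_stop("dot_shape_error", "ncol(A) must equal the voxel count of grid")
  }
  if (!is.null(channels) && nrow(channels) != nrow(A)) {
    dot_stop("dot_shape_error", "channel table must have one row per A row")
  }
  structure(list(A = A, grid = grid, wavelength = wavelength,
                 channels = channels),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("<sensitivity_matrix %d channels x %d voxels @ %g nm>\n",
              nrow(x$A), ncol(x$A), x$wavelength))
  invisible(x)
}

#' Analytic exponential-decay sensitivity model
#'
#' Builds one channels-by-voxels forward operator per wavelength for the
#' linear model y = A x relating voxel absorption changes to channel
#' light-level fluctuations.  The entry for channel (s, d) at voxel v is
#' proportional to exp(-(|v - s| + |v - d|) / decay_length): light sampled
#' along the banana-shaped source-detector path falls off exponentially
#' with total optical path length.  This analytic kernel stands in for a
#' finite-element photon-transport model; it reproduces the qualitative
#' depth- and separation-dependence of HD-DOT sensitivity on a synthetic
#' slab, not any subject-specific head anatomy.
#'
#' @param optodes an `optode_array`
#' @param grid a `voxel_grid` (the slab under the optode plane)
#' @param decay_length exponential decay length in mm (default 5)
#' @param scales named numeric vector of per-wavelength overall scale
#'   factors; default gives the longer wavelength a slightly larger gain
#' @return named list of `sensitivity_matrix`, one per wavelength
#' @export
#' @examples
#' arr <- make_optode_grid(2, 2, spacing = 11)
#' g <- voxel_grid(c(4, 4, 2), spacing = 5)
#' sens <- make_sensitivity(arr, g)
#' dim(sens[["830"]]$A)
make_sensitivity <- function(optodes, grid, decay_length = 5, scales = NULL) {
  if (!inherits(grid, "voxel_grid") || n_voxels(grid) < 1) {
    dot_stop("dot_invalid_parameter", "grid must be a non-empty voxel_grid")
  }
  if (!is_number(decay_length) || decay_length <= 0) {
    dot_stop("dot_invalid_parameter", "decay_length must be > 0")
  }
  wl <- optodes$wavelengths
  if (is.null(scales)) {
    scales <- stats::setNames(1 + 0.1 * (seq_along(wl) - 1), as.character(wl))
  }
  vc <- voxel_centers(grid)
  d_src <- t(apply(optodes$source_positions, 1,
                   function(p) sqrt(rowSums(sweep(vc, 2, p, "-")^2))))
  d_det <- t(apply(optodes$detector_positions, 1,
                   function(p) sqrt(rowSums(sweep(vc, 2, p, "-")^2))))
  ch <- optodes$channels
  path <- d_src[ch$source_index, , drop = FALSE] +
    d_det[ch$detector_index, , drop = FALSE]
  base <- exp(-path / decay_length)
  out <- lapply(seq_along(wl), function(i) {
    s <- scales[[as.character(wl[i])]] %||% 1
    sensitivity_matrix(s * base, grid, wl[i], channels = ch)
  })
  stats::setNames(out, as.character(wl))
}

#' Restrict a sensitivity matrix to a subset of channels
#'
#' Used after noisy-channel rejection so the inverse model matches the
#' surviving measurement set.
#'
#' @param sens a `sensitivity_matrix`
#' @param idx integer indices of channels (rows) to keep
#' @return a `sensitivity_matrix` with the selected rows
#' @export
subset_channels <- function(sens, idx) {
  sensitivity_matrix(sens$A[idx, , drop = FALSE], sens$grid, sens$wavelength,
                     channels = if (!is.null(sens$channels))
                       sens$channels[idx, , drop = FALSE] else NULL)
}
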