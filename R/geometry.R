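#' Define a voxel grid
#'
#' Regular voxel lattice used for reconstructed images.  Voxel centers are
#' enumerated with the x index varying fastest (column-major raster), which
#' fixes the voxel ordering used by every voxels-by-time matrix in the
#' package.
#'
#' @param shape integer vector (nx, ny, nz)
#' @param spacing voxel spacing in mm; scalar (isotropic) or per-axis
#'   3-vector (e.g. coarser in depth)
#' @param origin 3-vector, position in mm of the first voxel center
#' @return object of class `voxel_grid`
#' @export
voxel_grid <- function(shape, spacing = 5, origin = c(0, 0, 5)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    dot_stop("dot_invalid_parameter", "shape must be three positive integers")
  }
  if (!length(spacing) %in% c(1L, 3L) || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    dot_stop("dot_invalid_parameter", "spacing must be > 0 (scalar or 3-vector)")
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  structure(list(shape = shape, spacing = spacing, origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %dx%dx%d, %s mm spacing, %d voxels>\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(x$spacing, collapse = "x"), n_voxels(x)))
  invisible(x)
}

#' Number of voxels in a grid
#' @param grid a `voxel_grid`
#' @return integer voxel count
#' @export
n_voxels <- function(grid) prod(grid$shape)

#' Voxel center coordinates
#' @param grid a `voxel_grid`
#' @return n_voxels x 3 matrix of mm coordinates, x index fastest
#' @export
voxel_centers <- function(grid) {
  idx <- voxel_indices(grid)
  sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Voxel integer indices (1-based), x fastest
#' @param grid a `voxel_grid`
#' @return n_voxels x 3 integer matrix of (ix, iy, iz)
#' @export
voxel_indices <- function(grid) {
  g <- expand.grid(ix = seq_len(grid$shape[1]),
                   iy = seq_len(grid$shape[2]),
                   iz = seq_len(grid$shape[3]))
  as.matrix(g)
}

#' Build an interleaved optode array
#'
#' Places sources and detectors on a planar scalp grid (z = 0) in an
#' alternating (checkerboard) arrangement, or alternating along a line, and
#' enumerates every source-detector pair within the separation cutoff as a
#' measurement channel.  Nearest-neighbor order (`nn_order`) is the rank of
#' a channel's separation among the distinct separations present: rank 1 is
#' the first-nearest-neighbor set used to estimate superficial signals.
#'
#' @param n_src number of laser source positions
#' @param n_det number of detector positions
#' @param spacing optode grid spacing in mm (default 11)
#' @param layout "grid" (checkerboard, default) or "line"
#' @param max_separation channel separation cutoff in mm (default 50);
#'   source-detector pairs at or beyond this distance are not measured
#' @param wavelengths laser wavelengths in nm
#' @return object of class `optode_array` with fields `source_positions`,
#'   `detector_positions`, `wavelengths`, `spacing`, `max_separation` and a
#'   `channels` data frame (`source_index`, `detector_index`, `separation`,
#'   `nn_order`)
#' @export
#' @examples
#' arr <- make_optode_grid(8, 8, spacing = 11)
#' nrow(arr$channels)
make_optode_grid <- function(n_src, n_det, spacing = 11,
                             layout = c("grid", "line"),
                             max_separation = 50,
                             wavelengths = c(685, 830)) {
  layout <- match.arg(layout)
  if (!is_count(n_src) || !is_count(n_det)) {
    dot_stop("dot_invalid_parameter", "n_src and n_det must be positive integers")
  }
  if (!is_number(spacing) || spacing <= 0) {
    dot_stop("dot_invalid_parameter", "spacing must be > 0")
  }
  if (length(wavelengths) < 1 || any(wavelengths <= 0) ||
      anyDuplicated(wavelengths)) {
    dot_stop("dot_invalid_parameter",
             "wavelengths must be positive and distinct")
  }
  n <- n_src + n_det
  if (layout == "line") {
    pos <- cbind(x = (seq_len(n) - 1) * spacing, y = 0, z = 0)
    parity <- seq_len(n) %% 2L  # alternate S, D, S, D, ...
  } else {
    ncol_ <- ceiling(sqrt(n))
    nrow_ <- ceiling(n / ncol_)
    g <- expand.grid(col = seq_len(ncol_), row = seq_len(nrow_))[seq_len(n), ]
    pos <- cbind(x = (g$col - 1) * spacing, y = (g$row - 1) * spacing, z = 0)
    parity <- (g$col + g$row) %% 2L
  }
  ## checkerboard assignment: sources on one parity, detectors on the other;
  ## any count imbalance spills over deterministically in enumeration order
  src_cells <- which(parity == 1L)
  det_cells <- which(parity == 0L)
  if (length(src_cells) < n_src) {
    src_cells <- c(src_cells, rev(det_cells)[seq_len(n_src - length(src_cells))])
  }
  src_cells <- sort(src_cells[seq_len(n_src)])
  det_cells <- sort(setdiff(seq_len(n), src_cells))[seq_len(n_det)]

  src <- pos[src_cells, , drop = FALSE]
  det <- pos[det_cells, , drop = FALSE]

  pairs <- expand.grid(source_index = seq_len(n_src),
                       detector_index = seq_len(n_det))
  sep <- sqrt(rowSums((src[pairs$source_index, , drop = FALSE] -
                         det[pairs$detector_index, , drop = FALSE])^2))
  keep <- sep < max_separation
  if (!any(keep)) {
    dot_stop("dot_invalid_parameter",
             "no source-detector pair within max_separation")
  }
  channels <- data.frame(source_index = pairs$source_index[keep],
                         detector_index = pairs$detector_index[keep],
                         separation = sep[keep])
  channels$nn_order <- nn_order_from_separation(channels$separation)
  structure(list(source_positions = src,
                 detector_positions = det,
                 wavelengths = as.numeric(wavelengths),
                 spacing = spacing,
                 max_separation = max_separation,
                 channels = channels),
            class = "optode_array")
}

## rank of distinct separations (tolerance for floating-point ties)
nn_order_from_separation <- function(sep, tol = 1e-6) {
  r <- round(sep / tol) * tol
  match(r, sort(unique(r)))
}

#' @export
print.optode_array <- function(x, ...) {
  cat(sprintf(
    "<optode_array %d sources, %d detectors, %g mm spacing, %d channels (< %g mm)>\n",
    nrow(x$source_positions), nrow(x$detector_positions), x$spacing,
    nrow(x$channels), x$max_separation))
  invisible(x)
}
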