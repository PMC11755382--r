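#' Block-average a localizer run
#'
#' For each stimulation block, subtracts a pre-onset baseline (mean over
#' the `baseline` seconds before onset, per voxel) and summarizes the
#' response as the mean over the within-block plateau window (default 5 to
#' 15 s post-onset, where the HRF to a 15-s block has risen).  Block
#' summaries are averaged across blocks into one voxel map.
#'
#' @param ts a `voxel_timeseries`
#' @param onsets block onset times in seconds
#' @param window block duration in seconds (default 15)
#' @param plateau two-vector, plateau window in seconds post-onset
#' @param baseline pre-onset baseline duration in seconds (0 disables)
#' @return numeric voxel map (one value per voxel)
#' @export
block_average <- function(ts, onsets, window = 15, plateau = c(5, 15),
                          baseline = 2) {
  fs <- ts$sampling_rate
  nt <- ncol(ts$data)
  dur <- nt / fs
  if (length(onsets) < 1) {
    dot_stop("dot_invalid_parameter", "need at least one block onset")
  }
  if (any(onsets < 0) || any(onsets + window > dur + 1e-9)) {
    dot_stop("dot_invalid_parameter",
             "block onset + window falls outside the run")
  }
  maps <- vapply(onsets, function(on) {
    i0 <- floor((on + plateau[1]) * fs) + 1
    i1 <- min(nt, ceiling((on + plateau[2]) * fs))
    resp <- rowMeans(ts$data[, i0:i1, drop = FALSE])
    if (baseline > 0 && on * fs >= 1) {
      b0 <- max(1, floor((on - baseline) * fs) + 1)
      b1 <- max(1, floor(on * fs))
      resp <- resp - rowMeans(ts$data[, b0:b1, drop = FALSE])
    }
    resp
  }, numeric(nrow(ts$data)))
  rowMeans(maps)
}

roi_mask <- function(mask, label, threshold_frac, provenance = list()) {
  structure(list(mask = as.logical(mask), label = label,
                 threshold_frac = threshold_frac, provenance = provenance),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask %s: %d voxels at %g%% of max>\n",
              x$label, sum(x$mask), 100 * x$threshold_frac))
  invisible(x)
}

#' Auditory ROI from block-averaged localizer maps
#'
#' Averages the block-averaged word-hearing maps across runs and keeps
#' voxels at or above `frac` of the mean map's maximum.
#'
#' @param maps list of voxel maps (from [block_average()])
#' @param frac threshold fraction of the maximum (default 0.25)
#' @return `roi_mask` with label "auditory"
#' @export
make_auditory_roi <- function(maps, frac = 0.25) {
  if (length(maps) < 1) dot_stop("dot_invalid_parameter", "no maps supplied")
  if (!is_number(frac) || frac <= 0 || frac >= 1) {
    dot_stop("dot_invalid_parameter", "frac must be in (0, 1)")
  }
  m <- rowMeans(do.call(cbind, maps))
  if (max(m) <= 0) {
    dot_stop("dot_empty_roi", "mean localizer map has non-positive maximum")
  }
  roi_mask(m >= frac * max(m), "auditory", frac,
           provenance = list(n_maps = length(maps)))
}

#' Visual ROI with per-hemisphere thresholding
#'
#' Thresholds the mean checkerboard map at `frac` of each hemisphere's own
#' maximum and unions the two binary masks, so a weakly responding
#' hemisphere still contributes voxels that whole-map thresholding would
#' drop.
#'
#' @param maps list of voxel maps
#' @param frac threshold fraction (default 0.25)
#' @param hemisphere_split logical voxel vector, TRUE for the left
#'   hemisphere (default: left half of the grid's x axis)
#' @param grid `voxel_grid`, used to build the default split
#' @return `roi_mask` with label "visual"
#' @export
make_visual_roi <- function(maps, frac = 0.25, hemisphere_split = NULL,
                            grid = NULL) {
  if (length(maps) < 1) dot_stop("dot_invalid_parameter", "no maps supplied")
  if (!is_number(frac) || frac <= 0 || frac >= 1) {
    dot_stop("dot_invalid_parameter", "frac must be in (0, 1)")
  }
  m <- rowMeans(do.call(cbind, maps))
  if (is.null(hemisphere_split)) {
    if (is.null(grid)) {
      dot_stop("dot_invalid_parameter",
               "supply hemisphere_split or grid for the default split")
    }
    hemisphere_split <- default_hemisphere_split(grid)
  }
  if (length(hemisphere_split) != length(m)) {
    dot_stop("dot_shape_error", "hemisphere_split length must match the map")
  }
  half <- function(sel) {
    v <- m[sel]
    if (max(v) <= 0) {
      warning("one hemisphere has no positive response; it contributes no voxels")
      return(rep(FALSE, sum(sel)))
    }
    v >= frac * max(v)
  }
  mask <- logical(length(m))
  mask[hemisphere_split] <- half(hemisphere_split)
  mask[!hemisphere_split] <- half(!hemisphere_split)
  roi_mask(mask, "visual", frac, provenance = list(n_maps = length(maps)))
}

#' Left/right hemisphere split of a voxel grid
#'
#' @param grid a `voxel_grid`
#' @return logical voxel vector, TRUE for the left half of the x axis
#' @export
default_hemisphere_split <- function(grid) {
  idx <- voxel_indices(grid)
  idx[, 1] <= grid$shape[1] / 2
}
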