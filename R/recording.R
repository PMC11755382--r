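#' Construct a channel-level recording
#'
#' Container for per-run, per-wavelength light-level fluctuation time
#' series.  `data` holds the relative (log-ratio) light-level fluctuation
#' of each measurement channel, one row per channel.
#'
#' @param data channels x time numeric matrix
#' @param sampling_rate sampling rate in Hz
#' @param wavelength wavelength in nm
#' @param channels channel data frame (`source_index`, `detector_index`,
#'   `separation`, `nn_order`)
#' @param run_label movie / localizer identifier
#' @param session_id session identifier
#' @param viewing_index 1 or 2 (which presentation of the run)
#' @return object of class `channel_recording`
#' @export
channel_recording <- function(data, sampling_rate, wavelength, channels,
                              run_label = "run", session_id = "S1",
                              viewing_index = 1L) {
  data <- as.matrix(data)
  if (!is_number(sampling_rate) || sampling_rate <= 0) {
    dot_stop("dot_invalid_parameter", "sampling_rate must be > 0")
  }
  if (nrow(data) != nrow(channels)) {
    dot_stop("dot_shape_error",
             "data must have one row per channel in the channel table")
  }
  if (anyNA(data)) {
    dot_stop("dot_invalid_parameter", "recording data must not contain NA")
  }
  structure(list(data = data, sampling_rate = sampling_rate,
                 wavelength = wavelength, channels = channels,
                 run_label = run_label, session_id = session_id,
                 viewing_index = as.integer(viewing_index)),
            class = "channel_recording")
}

#' @export
print.channel_recording <- function(x, ...) {
  cat(sprintf(
    "<channel_recording %s/%s v%d: %d channels x %d samples @ %g Hz, %g nm>\n",
    x$session_id, x$run_label, x$viewing_index, nrow(x$data), ncol(x$data),
    x$sampling_rate, x$wavelength))
  invisible(x)
}

#' Construct a voxel-level time series
#'
#' @param data voxels x time numeric matrix
#' @param grid the `voxel_grid` the rows refer to
#' @param sampling_rate sampling rate in Hz
#' @param species one of "mu_a", "HbO", "HbR", "HbT"
#' @param fov_mask logical voxel vector (field of view), or NULL
#' @param run_label,session_id,viewing_index run metadata (as in
#'   [channel_recording()])
#' @return object of class `voxel_timeseries`
#' @export
voxel_timeseries <- function(data, grid, sampling_rate,
                             species = c("mu_a", "HbO", "HbR", "HbT"),
                             fov_mask = NULL, run_label = "run",
                             session_id = "S1", viewing_index = 1L) {
  species <- match.arg(species)
  data <- as.matrix(data)
  if (nrow(data) != n_voxels(grid)) {
    dot_stop("dot_shape_error", "data must have one row per voxel")
  }
  if (!is.null(fov_mask) && length(fov_mask) != n_voxels(grid)) {
    dot_stop("dot_shape_error", "fov_mask length must equal the voxel count")
  }
  structure(list(data = data, grid = grid, sampling_rate = sampling_rate,
                 species = species, fov_mask = fov_mask,
                 run_label = run_label, session_id = session_id,
                 viewing_index = as.integer(viewing_index)),
            class = "voxel_timeseries")
}

#' @export
print.voxel_timeseries <- function(x, ...) {
  cat(sprintf("<voxel_timeseries %s: %d voxels x %d samples @ %g Hz>\n",
              x$species, nrow(x$data), ncol(x$data), x$sampling_rate))
  invisible(x)
}
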