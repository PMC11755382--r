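## small shared fixtures, all generated in code

## minimal channel table for hand-built recordings
tiny_channels <- function(n, nn_order = rep(1L, n), separation = rep(11, n)) {
  data.frame(source_index = seq_len(n), detector_index = seq_len(n),
             separation = separation, nn_order = nn_order)
}

tiny_recording <- function(data, fs = 10, nn_order = NULL) {
  n <- nrow(data)
  if (is.null(nn_order)) nn_order <- rep(1L, n)
  channel_recording(data, fs, 830, tiny_channels(n, nn_order))
}

## desk-scale but reduced geometry for fast end-to-end tests
small_config <- function(run_duration = 120, n_sessions = 2L) {
  cfg <- default_config()
  cfg$geometry$n_src <- 8L
  cfg$geometry$n_det <- 8L
  cfg$geometry$grid_shape <- c(8L, 8L, 2L)
  cfg$geometry$grid_spacing <- c(5, 5, 9)
  cfg$geometry$grid_origin <- c(0, 0, 5)
  cfg$design$run_duration <- run_duration
  cfg$decode$grid <- data.frame(n_templates = 4L, trial_duration = 30)
  cfg$n_sessions <- n_sessions
  cfg
}

## tiny identity-forward setup: A = I so channel space == voxel space
identity_sens <- function(nv = 6, wavelengths = c(685, 830)) {
  grid <- voxel_grid(c(nv, 1, 1), spacing = 5)
  ch <- tiny_channels(nv)
  stats::setNames(lapply(wavelengths, function(w) {
    sensitivity_matrix(diag(nv), grid, w, channels = ch)
  }), as.character(wavelengths))
}
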