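#' Noise specification for synthetic runs
#'
#' Amplitudes of the nuisance components added at the channel level, all in
#' the same relative light-level (log-ratio) units as the signal:
#' a shared low-frequency superficial/scalp signal whose channel weight
#' decreases with source-detector separation, a per-channel linear drift,
#' a sinusoidal cardiac "pulse" near 1 Hz, and white measurement noise.
#' `jitter_sd` is the log-SD of the multiplicative (lognormal) amplitude
#' jitter applied per viewing, so the two viewings of a movie share the
#' signature but not the exact response amplitude.  `voxel_noise_sd` adds
#' white noise in voxel space before forward projection (default off).
#'
#' @param superficial_amp superficial signal amplitude (default 0.01)
#' @param drift_amp linear drift amplitude over a run (default 0.01)
#' @param pulse_amp pulse amplitude (default 0.005)
#' @param white_sd white measurement noise SD (default 0.004)
#' @param jitter_sd lognormal viewing-to-viewing amplitude jitter (0.2)
#' @param voxel_noise_sd voxel-space white noise SD (default 0)
#' @param superficial_scale mm scale of the separation weighting (30)
#' @param pulse_freq pulse frequency in Hz (1.0)
#' @return list of class `noise_spec`
#' @export
noise_spec <- function(superficial_amp = 0.01, drift_amp = 0.01,
                       pulse_amp = 0.005, white_sd = 0.004,
                       jitter_sd = 0.2, voxel_noise_sd = 0,
                       superficial_scale = 30, pulse_freq = 1.0) {
  vals <- c(superficial_amp, drift_amp, pulse_amp, white_sd, jitter_sd,
            voxel_noise_sd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    dot_stop("dot_invalid_parameter", "noise amplitudes must be >= 0")
  }
  structure(list(superficial_amp = superficial_amp, drift_amp = drift_amp,
                 pulse_amp = pulse_amp, white_sd = white_sd,
                 jitter_sd = jitter_sd, voxel_noise_sd = voxel_noise_sd,
                 superficial_scale = superficial_scale,
                 pulse_freq = pulse_freq),
            class = "noise_spec")
}

#' Default hemoglobin extinction matrix
#'
#' Two-by-two matrix E mapping (dHbO, dHbR) to absorption changes
#' (dmu_a at 685 nm, dmu_a at 830 nm): dmu_a(lambda) =
#' eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR.  Entries are standard
#' compiled molar extinction coefficients at 685 and 830 nm expressed in
#' arbitrary relative units (a common rescaling leaves all
#' correlation-based analyses unchanged).  At 685 nm deoxyhemoglobin
#' dominates; at 830 nm oxyhemoglobin dominates.
#'
#' @return 2 x 2 numeric matrix with dimnames (wavelength x species)
#' @export
default_extinction <- function() {
  matrix(c(0.277, 2.23,
           0.974, 0.693),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("685", "830"), c("HbO", "HbR")))
}

## default movie-response amplitude in relative light-level units.
## Calibrated once as a package constant so that default-parameter 4-way /
## 240-s decoding on the desk-scale geometry lands near (not at) ceiling.
DEFAULT_SIGNAL_AMP <- 0.13

## shared forward model: hemoglobin response -> per-wavelength channel data
simulate_forward <- function(pattern, resp, design, sens_list, noise,
                             amp, hbr_ratio, extinction, run_label,
                             session_id, viewing_index, return_truth) {
  fs <- design$sampling_rate
  nt <- length(resp)
  grid <- sens_list[[1]]$grid
  if (length(pattern) != n_voxels(grid)) {
    dot_stop("dot_shape_error",
             "spatial pattern length must match the sensitivity grid")
  }
  jitter <- if (noise$jitter_sd > 0) exp(stats::rnorm(1, 0, noise$jitter_sd)) else 1
  hbo_t <- amp * jitter * resp                    # HbO time course (shared)
  ch <- sens_list[[1]]$channels
  nc <- nrow(ch)
  tsec <- (seq_len(nt) - 1) / fs

  ## nuisance components shared across wavelengths where physiology is
  ## systemic (superficial signal, pulse timing); independent where it is
  ## instrumental (white noise, drift)
  g <- NULL
  if (noise$superficial_amp > 0) {
    lp <- signal::butter(2, min(0.1 / (fs / 2), 0.99), "low")
    g <- as.numeric(signal::filtfilt(lp, stats::rnorm(nt)))
    g <- (g - mean(g)) / stats::sd(g)
  }
  w_sup <- exp(-(ch$separation - min(ch$separation)) / noise$superficial_scale)
  pulse_phase <- stats::runif(1, 0, 2 * pi)
  vnoise <- NULL
  if (noise$voxel_noise_sd > 0) {
    vnoise <- matrix(stats::rnorm(n_voxels(grid) * nt, sd = noise$voxel_noise_sd),
                     nrow = n_voxels(grid))
  }

  recs <- lapply(sens_list, function(sens) {
    wl <- as.character(sens$wavelength)
    if (!wl %in% rownames(extinction)) {
      dot_stop("dot_invalid_parameter",
               sprintf("no extinction row for wavelength %s", wl))
    }
    ## dHbR tracks dHbO with opposite sign (washout of deoxyhemoglobin)
    mua_coef <- extinction[wl, "HbO"] - hbr_ratio * extinction[wl, "HbR"]
    gain <- as.vector(sens$A %*% pattern)
    y <- outer(gain, mua_coef * hbo_t)
    if (!is.null(vnoise)) y <- y + mua_coef * (sens$A %*% vnoise)
    if (!is.null(g)) {
      y <- y + noise$superficial_amp * abs(mua_coef) * outer(w_sup, g)
    }
    if (noise$drift_amp > 0) {
      slope <- stats::runif(nc, -1, 1)
      y <- y + noise$drift_amp * outer(slope, seq(-0.5, 0.5, length.out = nt))
    }
    if (noise$pulse_amp > 0) {
      pw <- stats::runif(nc, 0.5, 1.5)
      y <- y + noise$pulse_amp *
        outer(pw, sin(2 * pi * noise$pulse_freq * tsec + pulse_phase))
    }
    if (noise$white_sd > 0) {
      y <- y + matrix(stats::rnorm(nc * nt, sd = noise$white_sd), nrow = nc)
    }
    channel_recording(y, fs, sens$wavelength, ch, run_label = run_label,
                      session_id = session_id, viewing_index = viewing_index)
  })
  truth <- NULL
  if (return_truth) {
    hbo <- outer(pattern, hbo_t)
    if (!is.null(vnoise)) hbo <- hbo + vnoise
    truth <- voxel_timeseries(hbo, grid, fs, species = "HbO",
                              run_label = run_label, session_id = session_id,
                              viewing_index = viewing_index)
  }
  list(recordings = recs, truth = truth, amplitude = amp * jitter)
}

#' Simulate one movie-viewing run
#'
#' Generates the ground-truth hemoglobin image x(t) = spatial pattern
#' (outer) HRF-convolved stimulus time course, converts it to absorption
#' at each wavelength through the extinction matrix (with dHbR =
#' -hbr_ratio * dHbO), forward-projects through y = A x, and adds the
#' nuisance terms of the noise specification.  The two viewings of a movie
#' share the signature but draw independent noise and amplitude jitter.
#'
#' @param design a `session_design`
#' @param signature a `movie_signature`
#' @param sens_list named per-wavelength list from [make_sensitivity()]
#' @param noise a [noise_spec()]
#' @param seed integer seed (identical seed gives an identical run)
#' @param amp movie-response amplitude in light-level units
#' @param hbr_ratio magnitude of the anticorrelated dHbR relative to dHbO
#' @param extinction 2 x 2 extinction matrix (see [default_extinction()])
#' @param session_id,viewing_index run metadata
#' @param return_truth keep the ground-truth voxel time series
#' @return list with `recordings` (per-wavelength `channel_recording`),
#'   `truth` (`voxel_timeseries` of HbO, or NULL) and `amplitude`
#' @export
simulate_movie_run <- function(design, signature, sens_list,
                               noise = noise_spec(), seed = NULL,
                               amp = DEFAULT_SIGNAL_AMP, hbr_ratio = 0.35,
                               extinction = default_extinction(),
                               session_id = "S1", viewing_index = 1L,
                               return_truth = TRUE) {
  fs <- design$sampling_rate
  nt <- round(design$run_duration * fs)
  if (length(signature$stimulus_timecourse) != nt) {
    dot_stop("dot_shape_error",
             "signature time course does not match the design run duration")
  }
  with_seed(seed, {
    ## unit-area kernel: convolution preserves the stimulus scale, so `amp`
    ## is the voxel response amplitude in light-level units
    h <- canonical_hrf(fs); h <- h / sum(h)
    resp <- hrf_convolve(signature$stimulus_timecourse, h)
    simulate_forward(signature$spatial_pattern, resp, design, sens_list,
                     noise, amp, hbr_ratio, extinction,
                     run_label = as.character(signature$movie_id),
                     session_id = session_id, viewing_index = viewing_index,
                     return_truth = return_truth)
  })
}

#' Simulate one block-design localizer run
#'
#' A boxcar (15 s on / 15 s off, six blocks by default) convolved with the
#' canonical HRF is placed in the designated region (unit-norm indicator
#' pattern), forward-projected and noise-corrupted exactly as in
#' [simulate_movie_run()].
#'
#' @param design a `session_design` whose `localizer_blocks` fit in the run
#' @param region logical voxel vector marking the responsive region
#' @param sens_list per-wavelength sensitivity list
#' @param noise a [noise_spec()]
#' @param seed integer seed
#' @param amp,hbr_ratio,extinction as in [simulate_movie_run()]
#' @param session_id run metadata
#' @param return_truth keep the ground-truth voxel time series
#' @return as [simulate_movie_run()]
#' @export
simulate_localizer_run <- function(design, region, sens_list,
                                   noise = noise_spec(), seed = NULL,
                                   amp = DEFAULT_SIGNAL_AMP, hbr_ratio = 0.35,
                                   extinction = default_extinction(),
                                   session_id = "S1", return_truth = TRUE) {
  fs <- design$sampling_rate
  nt <- round(design$run_duration * fs)
  blocks <- design$localizer_blocks
  if (is.null(blocks) || nrow(blocks) < 1) {
    dot_stop("dot_invalid_parameter", "design has no localizer blocks")
  }
  cycle <- blocks[, 1] + 2 * blocks[, 2]  # block + equal rest must fit
  if (max(cycle) > design$run_duration + 1e-9) {
    dot_stop("dot_timing_error", sprintf(
      "localizer blocks need %g s but the run is %g s",
      max(cycle), design$run_duration))
  }
  region <- as.logical(region)
  if (!any(region)) dot_stop("dot_invalid_parameter", "region is empty")
  pattern <- as.numeric(region) / sqrt(sum(region))
  stim <- numeric(nt)
  for (b in seq_len(nrow(blocks))) {
    i0 <- floor(blocks[b, 1] * fs) + 1
    i1 <- min(nt, floor((blocks[b, 1] + blocks[b, 2]) * fs))
    stim[i0:i1] <- 1
  }
  with_seed(seed, {
    h <- canonical_hrf(fs); h <- h / sum(h)
    resp <- hrf_convolve(stim, h)
    simulate_forward(pattern, resp, design, sens_list, noise, amp,
                     hbr_ratio, extinction, run_label = "localizer",
                     session_id = session_id, viewing_index = 1L,
                     return_truth = return_truth)
  })
}
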