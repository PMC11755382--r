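#' Default end-to-end pipeline configuration
#'
#' Nested list driving [run_experiment()].  The defaults define the
#' desk-scale study conditions: a 6 x 6 interleaved optode array at 11 mm
#' spacing over a 12 x 12 x 3 voxel slab, two wavelengths (685 / 830 nm),
#' 10 Hz acquisition, sessions of four unique 315-s movies viewed twice
#' each, the standard cleaning chain, lambda1 = 0.05 / lambda2 = 0.1
#' reconstruction with a 10% flat-field FOV, and 4-way / 240-s decoding of
#' the oxyhemoglobin signal.
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    geometry = list(n_src = 18L, n_det = 18L, spacing = 11, layout = "grid",
                    max_separation = 50, wavelengths = c(685, 830),
                    grid_shape = c(12L, 12L, 3L), grid_spacing = c(5, 5, 9),
                    grid_origin = c(0, 0, 5), decay_length = 5),
    design = list(n_movies = 4L, run_duration = 315, sampling_rate = 10),
    signal = list(amp = DEFAULT_SIGNAL_AMP, hbr_ratio = 0.35,
                  max_xcorr = 0.3),
    noise = unclass(noise_spec()),
    preprocess = unclass(preprocess_params()),
    reconstruct = list(lambda1 = 0.05, lambda2 = 0.1, fov_frac = 0.10,
                       fov_wavelength = 830),
    roi = list(frac = 0.25, plateau = c(5, 15), baseline = 2),
    decode = list(grid = data.frame(n_templates = 4L, trial_duration = 240),
                  crop_initial = 15, inter_trial_gap = 15,
                  species = "HbO", train_viewing = 1L),
    n_sessions = 4L,
    seed = 1L,
    out_dir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Checks the nested structure against [default_config()]: unknown keys
#' are rejected, missing keys are filled in from the defaults, and the
#' decoding grid is checked for feasibility against the run duration
#' before any simulation starts.
#'
#' @param config (partial) configuration list
#' @return completed, validated configuration
#' @export
validate_config <- function(config) {
  ref <- default_config()
  merge_section <- function(user, def, path) {
    if (is.null(user)) return(def)
    unknown <- setdiff(names(user), names(def))
    if (length(unknown) > 0) {
      dot_stop("dot_invalid_parameter", sprintf(
        "unknown config key%s under '%s': %s",
        if (length(unknown) > 1) "s" else "", path,
        paste(unknown, collapse = ", ")))
    }
    for (k in names(user)) def[[k]] <- user[[k]]
    def
  }
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown) > 0) {
    dot_stop("dot_invalid_parameter",
             sprintf("unknown config section: %s", paste(unknown, collapse = ", ")))
  }
  out <- ref
  for (sec in names(ref)) {
    if (is.list(ref[[sec]]) && !is.data.frame(ref[[sec]])) {
      out[[sec]] <- merge_section(config[[sec]], ref[[sec]], sec)
    } else if (!is.null(config[[sec]])) {
      out[[sec]] <- config[[sec]]
    }
  }
  ## fail fast on an infeasible decoding grid
  g <- out$decode$grid
  avail <- out$design$run_duration - out$decode$crop_initial
  for (i in seq_len(nrow(g))) {
    segs <- g$n_templates[i] / out$design$n_movies
    if (segs != round(segs)) {
      dot_stop("dot_invalid_parameter", sprintf(
        "n_templates %d is not a multiple of n_movies %d",
        g$n_templates[i], out$design$n_movies))
    }
    block <- avail / segs
    if (block < g$trial_duration[i] + out$decode$inter_trial_gap) {
      dot_stop("dot_invalid_parameter", sprintf(
        "infeasible grid point %d-way / %g s: block %.1f s < %.1f s needed",
        g$n_templates[i], g$trial_duration[i], block,
        g$trial_duration[i] + out$decode$inter_trial_gap))
    }
  }
  out
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file; keys mirror [default_config()]
#' @return validated configuration list
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$decode$grid)) {
    cfg$decode$grid <- as.data.frame(cfg$decode$grid)
  }
  validate_config(cfg)
}

#' Derive a per-session seed from the master seed
#'
#' Deterministic affine-modular derivation so sessions are independent
#' streams but the whole experiment is reproducible from one seed.
#'
#' @param master master integer seed
#' @param i session index (>= 1)
#' @return integer seed below 2^31
#' @export
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 100000) * 20011 + i * 7919) %% 2147483647L
}

#' Build the fixed geometry objects of an experiment
#'
#' Optode array, voxel grid, per-wavelength sensitivity matrices and
#' inverse operators, and the flat-field FOV mask (computed from the
#' 830 nm matrix by default).
#'
#' @param config validated configuration
#' @return list: `optodes`, `grid`, `sens`, `inv`, `fov`, `regions`
#' @export
build_geometry <- function(config) {
  gc_ <- config$geometry
  optodes <- make_optode_grid(gc_$n_src, gc_$n_det, gc_$spacing,
                              layout = gc_$layout,
                              max_separation = gc_$max_separation,
                              wavelengths = gc_$wavelengths)
  grid <- voxel_grid(gc_$grid_shape, gc_$grid_spacing, gc_$grid_origin)
  sens <- make_sensitivity(optodes, grid, decay_length = gc_$decay_length)
  rc <- config$reconstruct
  inv <- lapply(sens, invert_sensitivity, lambda1 = rc$lambda1,
                lambda2 = rc$lambda2)
  fov_wl <- as.character(rc$fov_wavelength)
  fov <- flatfield_fov(sens[[fov_wl]], frac = rc$fov_frac, inv = inv[[fov_wl]])
  list(optodes = optodes, grid = grid, sens = sens, inv = inv,
       fov = fov, regions = default_region_layout(grid))
}

## channel recordings (both wavelengths) -> 1 Hz hemoglobin voxel run.
## inv_cache memoizes re-inversions for recurring kept-channel sets.
process_run_pair <- function(recs, geom, config, inv_cache = NULL) {
  pp <- do.call(preprocess_params, config$preprocess)
  wl <- names(geom$sens)
  mu <- lapply(wl, function(w) {
    clean <- preprocess_run(recs[[w]], pp)
    kept <- attr(clean, "provenance")$kept
    inv <- if (length(kept) < nrow(recs[[w]]$data)) {
      key <- paste0(w, ":", paste(kept, collapse = ","))
      if (!is.null(inv_cache) && !is.null(inv_cache[[key]])) {
        inv_cache[[key]]
      } else {
        iv <- invert_sensitivity(subset_channels(geom$sens[[w]], kept),
                                 config$reconstruct$lambda1,
                                 config$reconstruct$lambda2)
        if (!is.null(inv_cache)) inv_cache[[key]] <- iv
        iv
      }
    } else geom$inv[[w]]
    reconstruct_timeseries(inv, clean)
  })
  names(mu) <- wl
  hb <- spectral_decompose(mu[[1]], mu[[2]])
  out <- hb[[config$decode$species]]
  out$fov_mask <- geom$fov
  out
}

#' Simulate and process one full synthetic session
#'
#' Draws per-session movie signatures, simulates both viewings of every
#' movie at both wavelengths, runs the cleaning chain, reconstructs, and
#' spectrally decomposes to the decoding species.  Returns the list of
#' processed 1 Hz voxel runs ready for [decode_session()].
#'
#' @param geom geometry from [build_geometry()]
#' @param config validated configuration
#' @param session_seed integer seed for this session
#' @param session_id label
#' @param amp signal amplitude override (NULL = config value)
#' @return list of `voxel_timeseries` runs (each movie twice)
#' @export
simulate_session <- function(geom, config, session_seed,
                             session_id = "S1", amp = NULL) {
  des <- session_design(movie_ids = seq_len(config$design$n_movies),
                        run_duration = config$design$run_duration,
                        sampling_rate = config$design$sampling_rate)
  amp <- amp %||% config$signal$amp
  noise <- do.call(noise_spec, config$noise)
  sigs <- make_movie_signatures(config$design$n_movies, geom$grid, des,
                                region_layout = geom$regions,
                                max_xcorr = config$signal$max_xcorr,
                                seed = session_seed)
  runs <- list()
  inv_cache <- new.env(parent = emptyenv())
  for (m in seq_along(sigs)) {
    for (v in 1:2) {
      sim <- simulate_movie_run(
        des, sigs[[m]], geom$sens, noise,
        seed = derive_seed(session_seed, m * 10L + v),
        amp = amp, hbr_ratio = config$signal$hbr_ratio,
        session_id = session_id, viewing_index = v, return_truth = FALSE)
      runs[[length(runs) + 1L]] <-
        process_run_pair(sim$recordings, geom, config, inv_cache)
    }
  }
  runs
}

#' Run a full synthetic decoding experiment
#'
#' Simulates `n_sessions` independent sessions from one master seed,
#' decodes each session at every grid point of `config$decode$grid`, and
#' aggregates the results into one report per grid point.  If
#' `config$out_dir` is set, the sweep table (CSV), the per-point reports
#' and aggregate confusion matrices (JSON/CSV) and a provenance record
#' are written there.
#'
#' @param config configuration list (validated internally)
#' @return list: `table` (sweep data frame), `reports`,
#'   `session_accuracies` (sessions x grid points), `config`, `seeds`
#' @export
run_experiment <- function(config = default_config()) {
  config <- validate_config(config)
  geom <- build_geometry(config)
  grid <- config$decode$grid
  seeds <- vapply(seq_len(config$n_sessions), derive_seed,
                  integer(1), master = config$seed)
  confs <- rep(list(list()), nrow(grid))
  acc <- matrix(NA_real_, config$n_sessions, nrow(grid))
  for (s in seq_len(config$n_sessions)) {
    runs <- simulate_session(geom, config, seeds[s],
                             session_id = sprintf("S%02d", s))
    split <- split_session(runs, config$decode$train_viewing)
    for (gi in seq_len(nrow(grid))) {
      sp <- trial_spec(grid$trial_duration[gi], grid$n_templates[gi],
                       config$decode$crop_initial,
                       config$decode$inter_trial_gap)
      dec <- decode_session(split, sp, geom$fov)
      confs[[gi]][[s]] <- dec$confusion
      acc[s, gi] <- dec$accuracy
    }
  }
  reports <- lapply(seq_len(nrow(grid)), function(gi) {
    decoding_report(confs[[gi]], grid$n_templates[gi],
                    grid$trial_duration[gi])
  })
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(n_templates = r$n_templates, trial_duration = r$trial_duration,
               chance = r$chance, chance_pct = as.numeric(format_pct(r$chance)),
               mean_accuracy = r$mean_accuracy, sem = r$sem,
               p_value = r$p_value, cohens_d = r$cohens_d,
               n_correct = r$n_correct, n_trials = r$n_trials)
  }))
  out <- list(table = tab, reports = reports, session_accuracies = acc,
              config = config, seeds = seeds)
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

#' Matched / mismatched inter-run correlation summary
#'
#' For every within-session (training, test) run pair, computes the
#' voxelwise temporal correlation map over the full post-crop window and
#' averages the maps separately over matched (same movie) and mismatched
#' pairs, reporting the pair counts.
#'
#' @param sessions list of sessions (lists of `voxel_timeseries` runs)
#' @param mask logical voxel vector or NULL
#' @param crop_initial seconds cropped from each run start
#' @param train_viewing which viewing counts as training
#' @return list: `matched_mean`, `mismatched_mean` (voxel maps),
#'   `n_matched`, `n_mismatched`
#' @export
interrun_correlation_summary <- function(sessions, mask = NULL,
                                         crop_initial = 15,
                                         train_viewing = 1L) {
  if (length(sessions) < 1) {
    dot_stop("dot_invalid_parameter", "need at least one session")
  }
  n_mat <- 0L; n_mis <- 0L
  sum_mat <- NULL; sum_mis <- NULL
  for (runs in sessions) {
    split <- split_session(runs, train_viewing)
    for (tr in split$training) {
      for (te in split$test) {
        fs <- tr$sampling_rate
        i0 <- round(crop_initial * fs) + 1
        n <- min(ncol(tr$data), ncol(te$data))
        cm <- correlation_map(tr$data[, i0:n, drop = FALSE],
                              te$data[, i0:n, drop = FALSE], mask)
        if (is.null(sum_mat)) {
          sum_mat <- numeric(length(cm)); sum_mis <- numeric(length(cm))
        }
        cm0 <- ifelse(is.na(cm), 0, cm)
        if (identical(as.character(tr$run_label),
                      as.character(te$run_label))) {
          sum_mat <- sum_mat + cm0; n_mat <- n_mat + 1L
        } else {
          sum_mis <- sum_mis + cm0; n_mis <- n_mis + 1L
        }
      }
    }
  }
  list(matched_mean = sum_mat / max(n_mat, 1L),
       mismatched_mean = sum_mis / max(n_mis, 1L),
       n_matched = n_mat, n_mismatched = n_mis)
}
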