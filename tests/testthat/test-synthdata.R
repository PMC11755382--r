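test_that("optode grids enumerate channels within the separation cutoff", {
  ## single pair: one channel, first nearest neighbor
  arr <- make_optode_grid(1, 1, spacing = 11)
  expect_equal(nrow(arr$channels), 1L)
  expect_equal(arr$channels$nn_order, 1L)

  ## 4 + 4 interleaved line: brute-force pair enumeration oracle
  arr <- make_optode_grid(4, 4, spacing = 11, layout = "line")
  pos_s <- arr$source_positions; pos_d <- arr$detector_positions
  brute <- 0L
  seps <- c()
  for (i in seq_len(nrow(pos_s))) {
    for (j in seq_len(nrow(pos_d))) {
      s <- sqrt(sum((pos_s[i, ] - pos_d[j, ])^2))
      if (s < 50) { brute <- brute + 1L; seps <- c(seps, s) }
    }
  }
  expect_equal(nrow(arr$channels), brute)
  expect_setequal(round(sort(arr$channels$separation), 9), round(sort(seps), 9))
  ## nn_order ranks distinct separations, smallest first
  expect_equal(min(arr$channels$nn_order), 1L)
  expect_equal(
    arr$channels$nn_order[which.min(arr$channels$separation)], 1L)
  o <- order(arr$channels$separation)
  expect_true(all(diff(arr$channels$nn_order[o]) >= 0))

  expect_error(make_optode_grid(4, 4, spacing = 0),
               class = "dot_invalid_parameter")
})

test_that("analytic sensitivity decays with optical path length", {
  arr <- make_optode_grid(1, 1, spacing = 11, layout = "line")
  grid <- voxel_grid(c(3, 1, 1), spacing = 5.5, origin = c(0, 0, 5))
  sens <- make_sensitivity(arr, grid, decay_length = 10)
  A <- sens[["685"]]$A
  ## voxel nearest the source-detector midpoint carries the row maximum
  expect_equal(which.max(A[1, ]), 2L)

  ## doubling decay_length never decreases any entry (3 x 3 x 2 grid)
  arr2 <- make_optode_grid(2, 2, spacing = 11)
  g2 <- voxel_grid(c(3, 3, 2), spacing = 5)
  A1 <- make_sensitivity(arr2, g2, decay_length = 10)[["830"]]$A
  A2 <- make_sensitivity(arr2, g2, decay_length = 20)[["830"]]$A
  ## direct recomputation oracle at one entry
  vc <- voxel_centers(g2)
  d <- sqrt(sum((vc[1, ] - arr2$source_positions[1, ])^2)) +
    sqrt(sum((vc[1, ] - arr2$detector_positions[1, ])^2))
  ch1 <- which(arr2$channels$source_index == 1 &
                 arr2$channels$detector_index == 1)
  expect_equal(A1[ch1, 1], 1.1 * exp(-d / 10), tolerance = 1e-12)
  expect_true(all(A2 >= A1 - 1e-15))
  expect_true(all(A1 >= 0))

  ## a very distant voxel has (numerically) zero sensitivity
  gf <- voxel_grid(c(2, 1, 1), spacing = 5000, origin = c(0, 0, 5))
  Af <- make_sensitivity(arr, gf, decay_length = 10)[["685"]]$A
  expect_lt(Af[1, 2], 1e-100)

  expect_error(make_sensitivity(arr, list(), 10),
               class = "dot_invalid_parameter")
  expect_error(make_sensitivity(arr, grid, decay_length = -1),
               class = "dot_invalid_parameter")
})

test_that("movie signatures are unit-norm, separable, seeded", {
  grid <- voxel_grid(c(8, 8, 2), spacing = c(7, 7, 12), origin = c(-6, -6, 5))
  des <- session_design(run_duration = 60, sampling_rate = 10)
  layout <- default_region_layout(grid)
  sigs <- make_movie_signatures(4, grid, des, max_xcorr = 0.3, seed = 11)
  expect_length(sigs, 4)
  h <- canonical_hrf(10)
  for (s in sigs) {
    expect_equal(sqrt(sum(s$spatial_pattern^2)), 1, tolerance = 1e-12)
    ## nonzero loading in both designated sensory regions
    expect_gt(sum(abs(s$spatial_pattern[layout$auditory])), 0.05)
    expect_gt(sum(abs(s$spatial_pattern[layout$visual])), 0.05)
  }
  ## pairwise spatiotemporal correlation ceiling, verified directly
  resp <- sapply(sigs, function(s)
    as.vector(outer(s$spatial_pattern, hrf_convolve(s$stimulus_timecourse, h))))
  cc <- cor(resp)
  expect_lte(max(abs(cc[upper.tri(cc)])), 0.3)

  ## seeded determinism
  sigs2 <- make_movie_signatures(4, grid, des, max_xcorr = 0.3, seed = 11)
  expect_identical(sigs, sigs2)

  expect_error(make_movie_signatures(1, grid, des),
               class = "dot_invalid_parameter")
  ## an unattainable ceiling fails loudly, naming the parameters
  expect_error(
    make_movie_signatures(4, grid, des, max_xcorr = 1e-8, seed = 1,
                          max_retries = 2),
    class = "dot_generation_failure")
})

test_that("noiseless identity forward model reproduces the HRF response", {
  nv <- 6
  sens <- identity_sens(nv)
  des <- session_design(movie_ids = 1:2, run_duration = 30, sampling_rate = 10)
  p <- c(3, 1, -2, 0, 1, 4); p <- p / sqrt(sum(p^2))
  stim <- sin(2 * pi * 0.05 * seq(0, 29.9, by = 0.1))
  sig <- structure(list(movie_id = 1, spatial_pattern = p,
                        stimulus_timecourse = stim, sampling_rate = 10),
                   class = "movie_signature")
  silent <- noise_spec(0, 0, 0, 0, 0, 0)
  E <- diag(2); dimnames(E) <- list(c("685", "830"), c("HbO", "HbR"))
  sim <- simulate_movie_run(des, sig, sens, silent, seed = 5, amp = 1,
                            hbr_ratio = 0, extinction = E)
  h <- canonical_hrf(10); h <- h / sum(h)
  expected <- outer(p, hrf_convolve(stim, h))
  expect_equal(sim$recordings[["685"]]$data, expected, tolerance = 1e-12)
  expect_equal(sim$truth$data, expected, tolerance = 1e-12)

  ## same seed, bit-identical output with noise on
  noisy <- noise_spec()
  a <- simulate_movie_run(des, sig, sens, noisy, seed = 42)
  b <- simulate_movie_run(des, sig, sens, noisy, seed = 42)
  expect_identical(a$recordings, b$recordings)

  ## zero signal amplitude: white noise only -> run variance at the white level
  wn <- noise_spec(0, 0, 0, white_sd = 0.01, jitter_sd = 0, voxel_noise_sd = 0)
  z <- simulate_movie_run(des, sig, sens, wn, seed = 9, amp = 0)
  sds <- apply(z$recordings[["830"]]$data, 1, sd)
  expect_equal(mean(sds), 0.01, tolerance = 0.15)
})

test_that("localizer runs place an HRF-convolved boxcar in the region", {
  nv <- 6
  sens <- identity_sens(nv)
  blocks <- cbind(onset = seq(0, by = 30, length.out = 6), duration = 15)
  des <- session_design(run_duration = 180, sampling_rate = 10,
                        localizer_blocks = blocks)
  region <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  silent <- noise_spec(0, 0, 0, 0, 0, 0)
  sim <- simulate_localizer_run(des, region, sens, silent, seed = 3, amp = 1)
  x <- sim$truth$data
  ## outside the region: exactly zero
  expect_equal(max(abs(x[!region, ])), 0)
  ## inside: the HRF-convolved boxcar, same for both region voxels (scaled)
  stim <- numeric(1800)
  for (b in 1:6) stim[(300 * (b - 1)) + 1:150] <- 1
  h <- canonical_hrf(10); h <- h / sum(h)
  expected <- hrf_convolve(stim, h) / sqrt(2)
  expect_equal(x[1, ], expected, tolerance = 1e-12)

  ## direct averaging oracle: the mean over the 6 observed cycles equals
  ## the average of superposed single-block responses (the response to one
  ## 15-s block outlasts the 30-s cycle, so tails carry over)
  cyc <- sapply(0:5, function(b) x[1, (300 * b) + 1:300])
  one_block <- hrf_convolve(c(rep(1, 150), rep(0, 500)), h) / sqrt(2)
  full <- numeric(1800 + 650)
  for (b in 0:5) {
    i <- 300 * b + seq_along(one_block)
    full[i] <- full[i] + one_block
  }
  oracle <- rowMeans(matrix(full[1:1800], nrow = 300))
  expect_equal(rowMeans(cyc), oracle, tolerance = 1e-10)

  ## 6 blocks x 30 s need at least 180 s
  des_short <- session_design(run_duration = 179, sampling_rate = 10,
                              localizer_blocks = blocks)
  expect_error(simulate_localizer_run(des_short, region, sens, silent),
               class = "dot_timing_error")
})

test_that("zero-noise forward-then-inverse recovers the spatial pattern", {
  cfg <- default_config()
  geom <- build_geometry(cfg)
  des <- session_design(run_duration = 60,
                        sampling_rate = cfg$design$sampling_rate)
  sigs <- make_movie_signatures(2, geom$grid, des, seed = 21)
  silent <- noise_spec(0, 0, 0, 0, 0, 0)
  sim <- simulate_movie_run(des, sigs[[1]], geom$sens, silent, seed = 2,
                            amp = 1)
  mu <- lapply(names(geom$inv), function(w)
    reconstruct_timeseries(geom$inv[[w]], sim$recordings[[w]]))
  names(mu) <- names(geom$inv)
  hb <- spectral_decompose(mu[["685"]], mu[["830"]])
  ## summarize the reconstruction as its projection on the true time course
  h <- canonical_hrf(10); h <- h / sum(h)
  resp <- hrf_convolve(sigs[[1]]$stimulus_timecourse, h)
  est <- as.vector(hb$HbO$data %*% resp)
  truth <- sigs[[1]]$spatial_pattern
  expect_gt(cor(est[geom$fov], truth[geom$fov]), 0.8)
})
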