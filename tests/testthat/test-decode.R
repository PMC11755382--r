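## minimal stand-in for a run: only the fields the splitter needs
meta_run <- function(movie, viewing) {
  list(run_label = movie, viewing_index = as.integer(viewing))
}

test_that("session splitting assigns one viewing per set", {
  runs <- c(lapply(1:4, meta_run, viewing = 1),
            lapply(1:4, meta_run, viewing = 2))
  split <- split_session(runs)
  expect_length(split$training, 4)
  expect_length(split$test, 4)
  expect_true(all(vapply(split$training, `[[`, 1L, "viewing_index") == 1L))
  expect_true(all(vapply(split$test, `[[`, 1L, "viewing_index") == 2L))
  ## swapped roles
  split2 <- split_session(runs, train_viewing = 2L)
  expect_true(all(vapply(split2$training, `[[`, 1L, "viewing_index") == 2L))

  ## a movie seen once is a design error
  expect_error(split_session(runs[-1]), class = "dot_design_error")
  expect_error(split_session(c(runs, list(meta_run(1, 1)))),
               class = "dot_design_error")
})

test_that("13 sessions of 4 movies give 52 matched and 156 mismatched pairs", {
  ## exhaustive enumeration over every within-session (training, test) pair
  n_mat <- 0L; n_mis <- 0L
  for (s in 1:13) {
    runs <- c(lapply(1:4, meta_run, viewing = 1),
              lapply(1:4, meta_run, viewing = 2))
    split <- split_session(runs)
    for (tr in split$training) {
      for (te in split$test) {
        if (identical(tr$run_label, te$run_label)) n_mat <- n_mat + 1L
        else n_mis <- n_mis + 1L
      }
    }
  }
  expect_equal(n_mat, 52L)
  expect_equal(n_mis, 156L)
})

test_that("segment extraction honors crop, partition, and gap", {
  grid <- voxel_grid(c(2, 1, 1), spacing = 5)
  ts <- voxel_timeseries(matrix(rnorm(2 * 315), 2, 315), grid, 1,
                         species = "HbO", run_label = "m1")

  ## one 240-s template starting at t = 15 s
  segs <- extract_segments(ts, trial_spec(240, 4), 1)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$start, 15)
  expect_equal(ncol(segs[[1]]$data), 240)
  expect_equal(segs[[1]]$data, ts$data[, 16:255])

  ## 8 segments of 37.5-s blocks with 15-s trials -> 8 trials per run
  segs8 <- extract_segments(ts, trial_spec(15, 32), 8)
  expect_length(segs8, 8)
  expect_true(all(vapply(segs8, function(s) ncol(s$data), 1L) == 15L))
  starts <- vapply(segs8, `[[`, numeric(1), "start")
  expect_equal(starts, 15 + floor((0:7) * 300 / 8))
  expect_true(all(diff(starts) >= 15 + 15))  # trial + fade gap

  ## 240-s trials cannot fit twice in a 315-s run
  expect_error(extract_segments(ts, trial_spec(240, 8), 2),
               class = "dot_timing_error")
})

test_that("spatiotemporal correlation matches the flatten-then-Pearson oracle", {
  ## hand-picked 2 voxels x 3 time points
  Td <- rbind(c(1, 2, 3), c(0, -1, 4))
  Sd <- rbind(c(2, 2, 1), c(1, 0, 2))
  r <- spatiotemporal_correlation(Td, Sd)
  expect_equal(as.numeric(r), cor(as.vector(Td), as.vector(Sd)),
               tolerance = 1e-12)

  ## self-correlation and exact anti-correlation with a shift
  expect_equal(as.numeric(spatiotemporal_correlation(Td, Td)), 1,
               tolerance = 1e-12)
  expect_equal(as.numeric(spatiotemporal_correlation(Td, -Td + 7)), -1,
               tolerance = 1e-12)

  ## invariance to adding constants and positive rescaling
  set.seed(23)
  A <- matrix(rnorm(40), 5, 8); B <- matrix(rnorm(40), 5, 8)
  r0 <- as.numeric(spatiotemporal_correlation(A, B))
  expect_equal(as.numeric(spatiotemporal_correlation(3.2 * A + 5, B)), r0,
               tolerance = 1e-12)
  expect_equal(as.numeric(spatiotemporal_correlation(A, 0.1 * B - 2)), r0,
               tolerance = 1e-12)

  ## 100 random instances against the oracle, with masks
  set.seed(29)
  for (i in 1:100) {
    nv <- sample(3:10, 1); nt <- sample(3:12, 1)
    Td <- matrix(rnorm(nv * nt), nv, nt)
    Sd <- matrix(rnorm(nv * nt), nv, nt)
    mask <- rep(TRUE, nv); mask[sample(nv, 1)] <- FALSE
    if (!any(mask)) mask[1] <- TRUE
    r <- spatiotemporal_correlation(Td, Sd, mask)
    oracle <- cor(as.vector(Td[mask, ]), as.vector(Sd[mask, ]))
    expect_equal(as.numeric(r), oracle, tolerance = 1e-12)
  }

  ## degenerate inputs fail loudly
  expect_error(spatiotemporal_correlation(matrix(1, 2, 3), matrix(1, 2, 3)),
               class = "dot_undefined_correlation")
  expect_error(spatiotemporal_correlation(matrix(rnorm(6), 2, 3),
                                          matrix(rnorm(4), 2, 2)),
               class = "dot_shape_error")
})

test_that("classification takes the maximum correlation with the tie rule", {
  set.seed(31)
  templates <- lapply(1:4, function(i) matrix(rnorm(30), 5, 6))
  S <- templates[[3]] + matrix(rnorm(30, sd = 0.01), 5, 6)
  res <- classify_trial(S, templates)
  expect_equal(res$decoded, 3L)
  expect_false(res$tie)

  ## brute-force argmax oracle on random instances
  for (i in 1:20) {
    S <- matrix(rnorm(30), 5, 6)
    res <- classify_trial(S, templates)
    oracle <- vapply(templates, function(Td)
      cor(as.vector(Td), as.vector(S)), numeric(1))
    expect_equal(res$r, oracle, tolerance = 1e-12)
    expect_equal(res$decoded, which.max(oracle))
  }

  ## exact tie: lowest index wins and the tie is flagged
  tied <- list(templates[[1]], templates[[1]], templates[[2]])
  res_t <- classify_trial(templates[[1]], tied)
  expect_equal(res_t$decoded, 1L)
  expect_true(res_t$tie)

  ## permuting templates permutes the decision accordingly
  perm <- c(3, 1, 4, 2)
  S <- templates[[3]] + matrix(rnorm(30, sd = 0.01), 5, 6)
  res_p <- classify_trial(S, templates[perm])
  expect_equal(perm[res_p$decoded], 3L)

  expect_error(classify_trial(S, templates[1]),
               class = "dot_invalid_parameter")
})

test_that("voxelwise correlation maps match the scalar Pearson oracle", {
  set.seed(37)
  Td <- matrix(rnorm(6 * 100), 6, 100)
  Sd <- matrix(rnorm(6 * 100), 6, 100)
  cm <- correlation_map(Td, Sd)
  for (v in 1:6) expect_equal(cm[v], cor(Td[v, ], Sd[v, ]), tolerance = 1e-12)

  ## self-correlation: 1 wherever temporal variance is positive
  expect_equal(correlation_map(Td, Td), rep(1, 6), tolerance = 1e-12)

  ## independent white noise: map mean near 0
  big <- correlation_map(matrix(rnorm(50 * 100), 50, 100),
                         matrix(rnorm(50 * 100), 50, 100))
  expect_lt(abs(mean(big)), 0.1)

  ## zero-variance voxels and out-of-mask voxels are NA, not 0
  Tz <- Td; Tz[2, ] <- 5
  mask <- rep(TRUE, 6); mask[4] <- FALSE
  cmz <- correlation_map(Tz, Sd, mask)
  expect_true(is.na(cmz[2]))
  expect_true(is.na(cmz[4]))
  expect_false(anyNA(cmz[c(1, 3, 5, 6)]))
})

test_that("a noiseless session decodes perfectly with a diagonal confusion", {
  grid <- voxel_grid(c(6, 1, 1), spacing = 5)
  set.seed(41)
  nt <- 315
  mk_run <- function(m, v, data) {
    voxel_timeseries(data, grid, 1, species = "HbO",
                     run_label = paste0("m", m), viewing_index = v)
  }
  patterns <- lapply(1:4, function(i) rnorm(6))
  stims <- lapply(1:4, function(i) rnorm(nt))
  runs <- list()
  for (m in 1:4) {
    for (v in 1:2) {
      runs[[length(runs) + 1]] <- mk_run(m, v, outer(patterns[[m]], stims[[m]]))
    }
  }
  split <- split_session(runs)
  dec <- decode_session(split, trial_spec(240, 4))
  expect_equal(dec$accuracy, 1)
  expect_equal(unclass(dec$confusion), diag(1L, 4), ignore_attr = TRUE)
  ## row sums equal trials presented per class
  expect_equal(unname(rowSums(dec$confusion)), rep(1L, 4))

  ## 8-way subdivision keeps row sums consistent
  dec8 <- decode_session(split, trial_spec(105, 8))
  expect_equal(sum(dec8$confusion), 8L)
  expect_equal(unname(rowSums(dec8$confusion)), rep(1L, 8))
  expect_equal(dec8$accuracy, 1)
})
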