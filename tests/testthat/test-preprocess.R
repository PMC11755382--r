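test_that("noisy channels are rejected at the 7.5% SD criterion", {
  set.seed(1)
  n <- 20; nt <- 500
  X <- matrix(rnorm(n * nt, sd = 0.01), n, nt)
  planted <- c(3, 11, 17)
  X[planted, ] <- matrix(rnorm(3 * nt, sd = 0.2), 3, nt)
  X[5, ] <- 0.3                       # constant channel: SD 0, kept
  rec <- tiny_recording(X)
  out <- drop_noisy_channels(rec, 0.075)
  ## independent per-channel SD oracle
  oracle <- which(apply(X, 1, sd) > 0.075)
  expect_equal(out$rejected, oracle)
  expect_equal(out$rejected, planted)
  expect_true(5 %in% out$kept)
  ## original order preserved
  expect_equal(out$kept, sort(out$kept))

  ## SD 0.10 at threshold 0.075 is rejected
  one <- tiny_recording(matrix(rnorm(nt, sd = 0.10), 1, nt))
  expect_error(drop_noisy_channels(one, 0.075),
               class = "dot_empty_recording")

  ## idempotence: applying the rejection twice equals once
  twice <- drop_noisy_channels(out$recording, 0.075)
  expect_identical(twice$recording$data, out$recording$data)
  expect_length(twice$rejected, 0)
})

test_that("band-edge filters reject DC and attenuate out-of-band tones", {
  fs <- 10
  t <- seq(0, 99.9, by = 1 / fs)
  mid <- 300:700                       # away from the edges
  amp_at <- function(x, f) {
    ## FFT amplitude oracle at frequency f on the mid-signal window
    w <- x[mid]
    n <- length(w)
    2 * abs(sum(w * exp(-2i * pi * f * (seq_len(n) - 1) / fs))) / n
  }
  X <- rbind(sin(2 * pi * 2 * t),       # out of band for the low-pass
             sin(2 * pi * 0.05 * t),    # in band
             rep(1, length(t)))         # DC
  rec <- tiny_recording(X, fs)

  lp <- bandpass_step(rec, 0.5, "low")
  expect_lt(amp_at(lp$data[1, ], 2), 0.1)            # >= 90% attenuation
  expect_equal(amp_at(lp$data[2, ], 0.05), 1, tolerance = 0.05)

  hp <- bandpass_step(rec, 0.02, "high")
  expect_lt(max(abs(hp$data[3, mid])), 1e-6)          # DC rejected

  expect_error(bandpass_step(rec, 5, "low"), class = "dot_invalid_parameter")
  expect_error(bandpass_step(rec, 6, "high"), class = "dot_invalid_parameter")
})

test_that("filtering is linear; regression is linear for a fixed regressor", {
  set.seed(7)
  nt <- 300
  x <- matrix(rnorm(4 * nt), 4, nt)
  y <- matrix(rnorm(4 * nt), 4, nt)
  a <- 2.5; b <- -1.3
  for (op in list(
    function(m) bandpass_step(tiny_recording(m), 0.5, "low")$data,
    function(m) bandpass_step(tiny_recording(m), 0.02, "high")$data)) {
    lhs <- op(a * x + b * y)
    rhs <- a * op(x) + b * op(y)
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
  ## the superficial regressor is estimated from the data, so the step is a
  ## data-dependent projection: it is homogeneous under rescaling of the
  ## whole recording, and additive for inputs sharing the regressor
  reg <- function(m) superficial_regression(
    tiny_recording(m, nn_order = c(1L, 1L, 2L, 3L)))$data
  expect_equal(reg(a * x), a * reg(x), tolerance = 1e-8)
  ## same nn-1 rows => same regressor => additivity holds
  y_shared <- y
  y_shared[1:2, ] <- x[1:2, ]
  expect_equal(reg(x + b * y_shared)[3:4, ],
               (reg(x) + b * reg(y_shared))[3:4, ], tolerance = 1e-8)
})

test_that("superficial regression leaves residuals orthogonal to the regressor", {
  set.seed(3)
  nt <- 400
  ## 5 random channels, nn-1 channels 1-2 define the regressor
  X <- matrix(rnorm(5 * nt), 5, nt)
  rec <- tiny_recording(X, nn_order = c(1L, 1L, 2L, 2L, 3L))
  out <- superficial_regression(rec)
  g <- colMeans(X[1:2, ])
  ## orthogonality, relative to the norms
  for (i in 1:5) {
    ip <- abs(sum(out$data[i, ] * g))
    expect_lt(ip / (sqrt(sum(out$data[i, ]^2)) * sqrt(sum(g^2)) + 1e-30), 1e-8)
  }
  ## independent normal-equations oracle, channel by channel
  for (i in 1:5) {
    fit <- lm.fit(cbind(1, g), X[i, ])
    expect_equal(out$data[i, ], unname(fit$residuals), tolerance = 1e-10)
  }

  ## channels equal to g: residuals vanish
  Xg <- rbind(g, g, g)
  recg <- tiny_recording(Xg, nn_order = c(1L, 1L, 1L))
  resg <- superficial_regression(recg)
  expect_lt(max(abs(resg$data)), 1e-10 * max(abs(g)))

  ## channel orthogonal to both the intercept and g passes through unchanged
  gc <- g - mean(g)
  go <- rnorm(nt); go <- go - mean(go)
  go <- go - gc * sum(go * gc) / sum(gc^2)
  reco <- tiny_recording(rbind(g, go), nn_order = c(1L, 2L))
  reso <- superficial_regression(reco)
  expect_equal(reso$data[2, ], go, tolerance = 1e-8)

  ## no first-nearest-neighbor channels
  bad <- tiny_recording(X, nn_order = rep(2L, 5))
  expect_error(superficial_regression(bad), class = "dot_missing_regressor")
})

test_that("decimation preserves counts, constants, and identity", {
  rec <- tiny_recording(matrix(seq_len(100), 1, 100), fs = 10)
  out <- downsample(rec, 1)
  expect_equal(ncol(out$data), 10L)
  expect_equal(out$sampling_rate, 1)

  same <- downsample(rec, 10)
  expect_identical(same$data, rec$data)

  const <- tiny_recording(matrix(2.5, 1, 100), fs = 10)
  expect_true(all(downsample(const, 1)$data == 2.5))

  expect_error(downsample(rec, 3), class = "dot_invalid_parameter")
})

test_that("the full cleaning chain runs in the contracted order", {
  set.seed(11)
  X <- matrix(rnorm(6 * 900, sd = 0.01), 6, 900)
  rec <- tiny_recording(X, nn_order = c(1L, 1L, 2L, 2L, 3L, 3L))
  out <- preprocess_run(rec)
  prov <- attr(out, "provenance")
  expect_equal(prov$steps,
               c("drop_noisy_channels", "highpass",
                 "superficial_regression", "lowpass", "downsample"))
  expect_equal(out$sampling_rate, 1)
  expect_equal(ncol(out$data), 90L)
  expect_length(prov$rejected, 0)

  ## all channels too noisy -> empty-recording error propagates
  loud <- tiny_recording(matrix(rnorm(2 * 900, sd = 0.5), 2, 900))
  expect_error(preprocess_run(loud), class = "dot_empty_recording")
})

test_that("cleaning preserves a brain signal carried by long channels", {
  ## short (nn-1) channels carry only the superficial signal; long channels
  ## carry signal plus a superficial leak.  After the chain, the cleaned
  ## long channels must still track the band-limited HRF response.
  set.seed(13)
  fs <- 10; nt <- 3000
  h <- canonical_hrf(fs); h <- h / sum(h)
  ## stimulus band-limited to 0.03-0.2 Hz, inside the analysis band, so
  ## the cleaned signal should track the response nearly perfectly
  stim <- as.numeric(signal::filtfilt(
    signal::butter(2, c(0.006, 0.04), "pass"), rnorm(nt)))
  resp <- hrf_convolve(stim / sd(stim), h)
  g <- as.numeric(signal::filtfilt(signal::butter(2, 0.02, "low"), rnorm(nt)))
  g <- 0.01 * g / sd(g)               # realistic scalp-signal amplitude
  X <- rbind(g, g,
             0.02 * resp + 0.5 * g,
             -0.015 * resp + 0.8 * g)
  rec <- tiny_recording(X, nn_order = c(1L, 1L, 2L, 3L))
  out <- preprocess_run(rec)
  resp1 <- resp[seq(1, nt, by = 10)]
  expect_gt(abs(cor(out$data[3, ], resp1)), 0.95)
  expect_gt(abs(cor(out$data[4, ], resp1)), 0.95)
})
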