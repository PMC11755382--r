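#' Channel-cleaning parameters
#'
#' Defaults follow standard HD-DOT practice: channels whose full-run
#' temporal SD of the log-ratio light level exceeds 7.5% are omitted,
#' drift is removed by a 0.02 Hz high-pass, superficial/global physiology
#' by regression of the mean first-nearest-neighbor signal, residual pulse
#' by a 0.5 Hz low-pass, and the cleaned data are downsampled to 1 Hz
#' (task hemodynamics live in the 0.02 to 0.5 Hz band).
#'
#' @param variance_threshold channel rejection threshold on the temporal
#'   SD of the log-ratio signal (0.075 = 7.5%)
#' @param highpass_cutoff high-pass cutoff in Hz (0.02)
#' @param lowpass_cutoff low-pass cutoff in Hz (0.5)
#' @param target_rate output sampling rate in Hz (1)
#' @return list of class `preprocess_params`
#' @export
preprocess_params <- function(variance_threshold = 0.075,
                              highpass_cutoff = 0.02,
                              lowpass_cutoff = 0.5,
                              target_rate = 1) {
  if (!(variance_threshold > 0)) {
    dot_stop("dot_invalid_parameter", "variance_threshold must be > 0")
  }
  if (!(highpass_cutoff > 0 && highpass_cutoff < lowpass_cutoff)) {
    dot_stop("dot_invalid_parameter",
             "need 0 < highpass_cutoff < lowpass_cutoff")
  }
  if (!(target_rate > 0)) {
    dot_stop("dot_invalid_parameter", "target_rate must be > 0")
  }
  structure(list(variance_threshold = variance_threshold,
                 highpass_cutoff = highpass_cutoff,
                 lowpass_cutoff = lowpass_cutoff,
                 target_rate = target_rate),
            class = "preprocess_params")
}

#' Omit noisy channels
#'
#' Rejects channels whose temporal standard deviation over the full run
#' exceeds `threshold` (the 7.5% light-level variability criterion, applied
#' to the raw log-ratio run before any filtering).  Surviving channels keep
#' their original order.
#'
#' @param rec a `channel_recording`
#' @param threshold SD threshold (default 0.075)
#' @return list with `recording` (cleaned) and `rejected` (integer indices
#'   into the original channel list; also recorded as attribute `kept`)
#' @export
drop_noisy_channels <- function(rec, threshold = 0.075) {
  sds <- apply(rec$data, 1, stats::sd)
  rejected <- which(sds > threshold)
  kept <- setdiff(seq_len(nrow(rec$data)), rejected)
  if (length(kept) == 0) {
    dot_stop("dot_empty_recording", "all channels rejected as noisy")
  }
  out <- rec
  out$data <- rec$data[kept, , drop = FALSE]
  out$channels <- rec$channels[kept, , drop = FALSE]
  list(recording = out, rejected = rejected, kept = kept)
}

## Zero-phase order-1 Butterworth, all channels at once.  The
## forward-backward application of a Butterworth filter has transfer
## function |H(w)|^2 with zero phase; we apply that response exactly in
## the frequency domain on the even (mirrored) extension of the signal,
## which imposes reflective boundary handling and costs one FFT pair for
## the whole channels x time matrix.  Bilinear prewarping maps the cutoff:
## tan(pi * cutoff / fs).
zerophase_filter <- function(X, cutoff, fs, type) {
  nyq <- fs / 2
  if (!(cutoff > 0 && cutoff < nyq)) {
    dot_stop("dot_invalid_parameter",
             sprintf("cutoff %g Hz outside (0, Nyquist = %g Hz)", cutoff, nyq))
  }
  nt <- ncol(X)
  Y <- t(cbind(X, X[, nt:1, drop = FALSE]))  # even extension, 2 nt x channels
  n_p <- 2L * nt
  w <- 2 * pi * (seq_len(n_p) - 1) / n_p
  w <- pmin(w, 2 * pi - w)                   # fold onto [0, pi]
  tw <- tan(w / 2)
  tc <- tan(pi * cutoff / fs)
  H2 <- if (type == "low") tc^2 / (tc^2 + tw^2) else tw^2 / (tc^2 + tw^2)
  ## H2 is real and even, so filtering two real channels packed into one
  ## complex column keeps them separated in the real and imaginary parts
  nc <- ncol(Y)
  n1 <- ceiling(nc / 2)
  Zc <- Y[, seq_len(n1), drop = FALSE] + 0i
  if (nc > n1) {
    Zc[, seq_len(nc - n1)] <- Zc[, seq_len(nc - n1)] +
      1i * Y[, (n1 + 1):nc, drop = FALSE]
  }
  Ff <- stats::mvfft(Zc)
  Zf <- stats::mvfft(Ff * H2, inverse = TRUE) / n_p
  Yf <- cbind(Re(Zf), Im(Zf[, seq_len(nc - n1), drop = FALSE]))
  t(Yf[seq_len(nt), , drop = FALSE])
}

#' Zero-phase band-edge filtering
#'
#' Applies the zero-phase order-1 Butterworth response (the squared
#' magnitude of the filter, as produced by forward-backward application)
#' with mirrored boundary handling; `kind = "high"` removes DC and slow
#' drift exactly, `kind = "low"` removes pulse and high-frequency noise.
#'
#' @param rec a `channel_recording`
#' @param cutoff cutoff frequency in Hz, inside (0, Nyquist)
#' @param kind "high" or "low"
#' @return filtered `channel_recording`, same shape
#' @export
bandpass_step <- function(rec, cutoff, kind = c("high", "low")) {
  kind <- match.arg(kind)
  out <- rec
  out$data <- zerophase_filter(rec$data, cutoff, rec$sampling_rate, kind)
  out
}

#' Superficial signal regression
#'
#' Estimates the global scalp signal g(t) as the mean of all
#' first-nearest-neighbor channels (nn_order 1) and replaces every channel
#' by its least-squares residual after regressing onto g with an intercept.
#' Residuals are exactly orthogonal to the regressor.
#'
#' @param rec a `channel_recording`
#' @return `channel_recording` of residuals, with the regressor stored in
#'   attribute `superficial_signal`
#' @export
superficial_regression <- function(rec) {
  nn1 <- which(rec$channels$nn_order == 1L)
  if (length(nn1) == 0) {
    dot_stop("dot_missing_regressor",
             "no first-nearest-neighbor channels available")
  }
  g <- colMeans(rec$data[nn1, , drop = FALSE])
  X <- cbind(1, g)
  ## one shared normal-equations solve for all channels
  beta <- solve(crossprod(X), crossprod(X, t(rec$data)))
  res <- t(rec$data) - X %*% beta
  out <- rec
  out$data <- t(res)
  attr(out, "superficial_signal") <- g
  out
}

#' Downsample by decimation
#'
#' Keeps every k-th sample (k = sampling_rate / target_rate, which must be
#' an integer), relying on the preceding 0.5 Hz low-pass as the anti-alias
#' filter.  Output length is floor(n / k).
#'
#' @param rec a `channel_recording`
#' @param target_rate output rate in Hz
#' @return decimated `channel_recording`
#' @export
downsample <- function(rec, target_rate = 1) {
  k <- rec$sampling_rate / target_rate
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    dot_stop("dot_invalid_parameter",
             "sampling_rate must be an integer multiple of target_rate")
  }
  k <- as.integer(round(k))
  n_out <- floor(ncol(rec$data) / k)
  idx <- seq(1L, by = k, length.out = n_out)
  out <- rec
  out$data <- rec$data[, idx, drop = FALSE]
  out$sampling_rate <- target_rate
  out
}

## the contract: cleaning steps in this order
PREPROCESS_STEPS <- c("drop_noisy_channels", "highpass",
                      "superficial_regression", "lowpass", "downsample")

#' Run the full channel-cleaning chain
#'
#' Applies, in order: noisy-channel omission, 0.02 Hz high-pass,
#' superficial signal regression, 0.5 Hz low-pass, decimation to 1 Hz.
#' The order is part of the contract and is recorded in the provenance
#' attached to the result.
#'
#' @param rec a `channel_recording` (typically 10 Hz)
#' @param params a [preprocess_params()]
#' @return cleaned `channel_recording` with attribute `provenance`
#'   (list: `steps`, `params`, `rejected`, `kept`)
#' @export
preprocess_run <- function(rec, params = preprocess_params()) {
  dropped <- drop_noisy_channels(rec, params$variance_threshold)
  x <- dropped$recording
  x <- bandpass_step(x, params$highpass_cutoff, "high")
  x <- superficial_regression(x)
  x <- bandpass_step(x, params$lowpass_cutoff, "low")
  x <- downsample(x, params$target_rate)
  attr(x, "provenance") <- list(steps = PREPROCESS_STEPS,
                                params = unclass(params),
                                rejected = dropped$rejected,
                                kept = dropped$kept)
  x
}
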