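#' Canonical double-gamma hemodynamic response function
#'
#' Double-gamma HRF with a response peak at 6 s, an undershoot peaking at
#' 16 s, and a 1:6 undershoot-to-peak ratio, sampled at `fs` Hz and
#' normalized to unit peak amplitude.  This is the kernel used by the
#' synthetic-session generator to turn stimulus time courses into
#' hemodynamic responses.
#'
#' @param fs sampling rate in Hz (default 10)
#' @param duration kernel length in seconds (default 32)
#' @param peak time-to-peak of the positive lobe in seconds
#' @param undershoot time-to-peak of the undershoot in seconds
#' @param ratio undershoot amplitude relative to the peak lobe
#' @return numeric vector of kernel samples (first sample at t = 0)
#' @export
#' @examples
#' h <- canonical_hrf(fs = 10)
#' which.max(h)  # peak near 6 s, i.e. sample index ~61
canonical_hrf <- function(fs = 10, duration = 32, peak = 6, undershoot = 16,
                          ratio = 1 / 6) {
  if (!is_number(fs) || fs <= 0) dot_stop("dot_invalid_parameter", "fs must be > 0")
  t <- seq(0, duration, by = 1 / fs)
  ## gamma densities with rate 1 peak at shape - 1; shift shapes so the
  ## lobes peak at `peak` and `undershoot` seconds
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot + 1, rate = 1)
  h / max(h)
}

#' Convolve a stimulus time course with an HRF kernel
#'
#' Causal ("full" convolution truncated to the input length), so the
#' response at time t depends only on stimulus at times <= t.
#'
#' @param x stimulus time course
#' @param h HRF kernel (as from [canonical_hrf()])
#' @return numeric vector, same length as `x`
#' @export
hrf_convolve <- function(x, h) {
  n <- length(x)
  out <- stats::convolve(x, rev(h), type = "open")
  out[seq_len(n)]
}
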