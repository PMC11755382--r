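#' Invert a sensitivity matrix with spatially variant Tikhonov regularization
#'
#' Implements the standard two-step HD-DOT inversion of y = A x.  Voxels
#' are first rescaled by the spatially variant weight
#' L_v = sqrt(W_v + lambda2 * max_v(W_v)) with W = diag(A'A), which
#' counters the depth bias of the diffuse measurement; the rescaled system
#' is then inverted in measurement space with a Tikhonov penalty
#' proportional to the largest eigenvalue of the rescaled Gram matrix:
#'
#'   A~ = A diag(1/L),
#'   x^ = diag(1/L) A~' (A~ A~' + lambda1 * sigma_max I)^{-1} y.
#'
#' As lambda1, lambda2 -> 0 the operator approaches the Moore-Penrose
#' pseudoinverse; larger lambda1 shrinks the solution monotonically.
#' The lambda1 penalty is scaled relative to sigma_max (the largest
#' eigenvalue of A~ A~'), a convention recorded in the operator provenance.
#'
#' @param sens a `sensitivity_matrix`
#' @param lambda1 Tikhonov regularization parameter (default 0.05)
#' @param lambda2 spatially variant regularization parameter (default 0.1)
#' @return object of class `inverse_operator` with fields `A_inv`
#'   (voxels x channels), `lambda1`, `lambda2`, `grid`, `wavelength`,
#'   `provenance`
#' @export
invert_sensitivity <- function(sens, lambda1 = 0.05, lambda2 = 0.1) {
  A <- sens$A
  if (!is_number(lambda1) || lambda1 < 0 || !is_number(lambda2) || lambda2 < 0) {
    dot_stop("dot_invalid_parameter", "lambda1 and lambda2 must be >= 0")
  }
  W <- colSums(A^2)
  if (max(W) <= 0) dot_stop("dot_degenerate_matrix", "A is all zero")
  L <- sqrt(W + lambda2 * max(W))
  invL <- ifelse(L > 0, 1 / L, 0)   # zero-sensitivity voxels stay zero
  At <- sweep(A, 2, invL, "*")
  G <- tcrossprod(At)
  sigma_max <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  M <- G + lambda1 * sigma_max * diag(nrow(G))
  A_inv <- invL * crossprod(At, solve(M))
  structure(list(A_inv = A_inv, lambda1 = lambda1, lambda2 = lambda2,
                 grid = sens$grid, wavelength = sens$wavelength,
                 channels = sens$channels,
                 provenance = list(
                   sigma_max = sigma_max,
                   lambda1_scale = "relative to sigma_max(G)",
                   n_channels = nrow(A), n_voxels = ncol(A))),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf(
    "<inverse_operator %d voxels x %d channels, lambda1=%g lambda2=%g>\n",
    nrow(x$A_inv), ncol(x$A_inv), x$lambda1, x$lambda2))
  invisible(x)
}

#' Reconstruct a voxel time series from channel data
#'
#' Applies the inverse operator column by column: x^(t) = A_inv y(t).
#' The map is linear in the channel data.
#'
#' @param inv an `inverse_operator`
#' @param rec a `channel_recording` (or channels x time matrix)
#' @return `voxel_timeseries` of species "mu_a"
#' @export
reconstruct_timeseries <- function(inv, rec) {
  Y <- if (inherits(rec, "channel_recording")) rec$data else as.matrix(rec)
  if (ncol(inv$A_inv) != nrow(Y)) {
    dot_stop("dot_shape_error", sprintf(
      "recording has %d channels but the operator expects %d",
      nrow(Y), ncol(inv$A_inv)))
  }
  X <- inv$A_inv %*% Y
  fs <- if (inherits(rec, "channel_recording")) rec$sampling_rate else NA_real_
  voxel_timeseries(X, inv$grid, fs, species = "mu_a",
                   run_label = if (inherits(rec, "channel_recording"))
                     rec$run_label else "run",
                   session_id = if (inherits(rec, "channel_recording"))
                     rec$session_id else "S1",
                   viewing_index = if (inherits(rec, "channel_recording"))
                     rec$viewing_index else 1L)
}

#' Flat-field field-of-view mask
#'
#' Reconstructs the response to a uniform all-ones voxel image
#' (f = A_inv A 1) and keeps voxels at or above `frac` of the maximum.
#' This conservative mask delineates where the measurement array actually
#' carries image information.
#'
#' @param sens a `sensitivity_matrix`
#' @param frac threshold fraction of the flat-field maximum (default 0.10)
#' @param inv optional precomputed `inverse_operator` for `sens`
#' @param lambda1,lambda2 regularization used if `inv` is NULL
#' @return logical voxel vector with attribute `flatfield` (the image f)
#' @export
flatfield_fov <- function(sens, frac = 0.10, inv = NULL,
                          lambda1 = 0.05, lambda2 = 0.1) {
  if (!is_number(frac) || frac <= 0 || frac > 1) {
    dot_stop("dot_invalid_parameter", "frac must be in (0, 1]")
  }
  if (is.null(inv)) inv <- invert_sensitivity(sens, lambda1, lambda2)
  f <- as.vector(inv$A_inv %*% (sens$A %*% rep(1, ncol(sens$A))))
  if (diff(range(f)) < 1e-12 * max(abs(f), 1e-300)) {
    warning("flat-field image is degenerate (constant); mask is all voxels")
    mask <- rep(TRUE, length(f))
  } else {
    mask <- f >= frac * max(f)
  }
  attr(mask, "flatfield") <- f
  mask
}

#' Spectral decomposition of two-wavelength absorption to hemoglobin
#'
#' Solves E (dHbO, dHbR)' = (dmu_a685, dmu_a830)' per voxel and time point
#' and returns relative oxy-, deoxy- and total-hemoglobin time series.
#'
#' @param mu685,mu830 `voxel_timeseries` of species "mu_a" on matched
#'   grids and time axes
#' @param E 2 x 2 extinction matrix (rows: wavelengths, cols: HbO, HbR)
#' @return list of `voxel_timeseries`: `HbO`, `HbR`, `HbT`
#' @export
spectral_decompose <- function(mu685, mu830, E = default_extinction()) {
  if (!identical(dim(mu685$data), dim(mu830$data))) {
    dot_stop("dot_shape_error", "wavelength time series differ in shape")
  }
  if (!isTRUE(all.equal(mu685$grid$shape, mu830$grid$shape))) {
    dot_stop("dot_shape_error", "wavelength time series differ in grid")
  }
  if (!all(is.finite(E)) || abs(det(E)) < 1e-12 ||
      kappa(E) > 1e6) {
    dot_stop("dot_degenerate_matrix", "extinction matrix is singular")
  }
  Einv <- solve(E)
  hbo <- Einv[1, 1] * mu685$data + Einv[1, 2] * mu830$data
  hbr <- Einv[2, 1] * mu685$data + Einv[2, 2] * mu830$data
  mk <- function(d, sp) {
    voxel_timeseries(d, mu685$grid, mu685$sampling_rate, species = sp,
                     fov_mask = mu685$fov_mask, run_label = mu685$run_label,
                     session_id = mu685$session_id,
                     viewing_index = mu685$viewing_index)
  }
  list(HbO = mk(hbo, "HbO"), HbR = mk(hbr, "HbR"), HbT = mk(hbo + hbr, "HbT"))
}
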