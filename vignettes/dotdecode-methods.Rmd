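---
title: "Decoding naturalistic stimuli from HD-DOT data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding naturalistic stimuli from HD-DOT data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotdecode)
```

## Overview

High-density diffuse optical tomography (HD-DOT) measures cortical
hemodynamics through a dense scalp grid of near-infrared sources and
detectors.  Each source–detector pair within a separation cutoff is a
measurement *channel*; the relative light-level fluctuation of all
channels, `y`, relates linearly to the map of absorption changes `x`
through a channels-by-voxels sensitivity matrix `A`:

$$y = A x.$$

`dotdecode` implements, end to end, a template-matching analysis that asks:
*which of several movie clips was a participant viewing, given only their
HD-DOT recording?*  The pipeline is

1. **synthesis** — seeded generation of channel-level sessions with known
   ground truth;
2. **preprocessing** — the standard five-step channel cleaning chain;
3. **reconstruction** — spatially variant Tikhonov inversion of `y = Ax`,
   flat-field field-of-view (FOV) estimation, and spectral decomposition
   to hemoglobin;
4. **ROI construction** — auditory and visual masks from block-design
   localizers;
5. **decoding** — spatiotemporal template matching by maximum Pearson
   correlation;
6. **evaluation** — confusion matrices, exact binomial tests against
   chance, Cohen's *d*, and parameter sweeps.

Every stage is driven by one configuration list (`default_config()`), and
`run_experiment()` executes the whole chain reproducibly from a single
master seed.

## The synthetic-data generator

No real recordings ship with the package; the generator emulates the
statistical structure the analysis relies on, at a desk scale that runs in
seconds.

**Geometry.** The default array interleaves 18 sources and 18 detectors in
a 6 × 6 checkerboard at 11 mm spacing; every source–detector pair closer
than 50 mm is a channel (264 channels), and `nn_order` ranks channels by
distinct separation (rank 1 = first nearest neighbors).  The voxel slab is
12 × 12 × 3 voxels at 5 × 5 × 9 mm, tucked inside the optode footprint
with the first layer 5 mm below the array.  Sensitivity is analytic:
the entry for channel (s, d) at voxel v is proportional to
$\exp(-(|v-s|+|v-d|)/\ell)$ with decay length $\ell = 5$ mm, and the
830 nm matrix carries a 10% larger overall gain than 685 nm.  This kernel
reproduces the qualitative depth and separation dependence of diffuse
measurements — it is not a photon-transport model, and no subject anatomy
is represented.  The slab dimensions and decay length were chosen together
so that three properties hold simultaneously on the default geometry:
the 10% flat-field FOV excludes exactly the deepest layer (sensitivity
reaching roughly 1 cm below the surface), noiseless single-voxel sources
reconstruct to a face-adjacent voxel everywhere in the FOV, and noiseless
forward-then-inverse recovery correlates with the true pattern above 0.8.

**Movie responses.** Each movie is a *signature*: a smooth unit-norm
spatial pattern with loadings in designated auditory-like and visual-like
regions, paired with a band-limited stimulus time course at 10 Hz.
Signatures are rejection-resampled until all pairwise spatiotemporal
correlations of the noiseless responses are below 0.3, so classes are
separable but not orthogonal.  The voxel response is the stimulus time
course convolved with a canonical double-gamma HRF (peak 6 s, undershoot
16 s, 1:6 ratio).  Inside the generators the kernel is normalized to unit
area, so convolution preserves the stimulus scale and the amplitude
parameter is directly the response amplitude in light-level units.
Deoxyhemoglobin tracks oxyhemoglobin with opposite sign,
$\Delta HbR = -0.35\,\Delta HbO$, a typical washout ratio.

**Forward spectroscopy.** Absorption at each wavelength is
$\Delta\mu_a(\lambda) = \varepsilon_{HbO}(\lambda)\Delta HbO +
\varepsilon_{HbR}(\lambda)\Delta HbR$ with standard compiled extinction
coefficients at 685 and 830 nm in arbitrary relative units
(`default_extinction()`); correlation-based decoding is invariant to the
common scale.

**Noise.** Channels receive four nuisance terms: a shared low-frequency
superficial signal whose weight decreases exponentially with channel
separation (30 mm scale), a per-channel linear drift, a ~1 Hz sinusoidal
pulse with shared phase, and white measurement noise.  The two viewings of
a movie share the signature but draw independent noise and a lognormal
amplitude jitter (log-SD 0.2), so matched runs correlate strongly but not
perfectly.  Defaults (0.01, 0.01, 0.005, 0.004 in light-level units) give
realistic channel SDs near 1%, far below the 7.5% rejection criterion.

**SNR calibration.** The movie-response amplitude default (0.13) is a
package constant calibrated once so that default-parameter 4-way / 240-s
decoding lands near — not at — ceiling (about 96% over 12 calibration
sessions).  It is a property of this synthetic testbed, not an empirical
claim about real tissue.

**What the generator does not emulate.** Motion artifacts, heterogeneous
optical properties, subject-specific anatomy, scalp/skull layering
(consequently the first-nearest-neighbor channels here see cortex
directly, so superficial regression removes somewhat more brain signal
than it would in vivo), and session-to-session optode repositioning.
Passing tests show the *analysis* is correct and well calibrated on data
with the assumed structure; they do not certify performance on real
recordings.

## Preprocessing

`preprocess_run()` applies, in contracted order: (1) omission of channels
whose full-run temporal SD of the log-ratio signal exceeds 7.5% (computed
on the raw run, before filtering); (2) 0.02 Hz high-pass; (3) superficial
signal regression — the mean of all first-nearest-neighbor channels is
regressed (with intercept) out of every channel; (4) 0.5 Hz low-pass;
(5) decimation to 1 Hz, for which the preceding low-pass is the anti-alias
filter.  Task hemodynamics live in the 0.02–0.5 Hz band, so 1 Hz sampling
is lossless for the analysis.

The filters realize the zero-phase order-1 Butterworth response: the
squared magnitude $|H(\omega)|^2$ that forward–backward filtering
produces, applied in the frequency domain on the even (mirrored) extension
of each signal.  This is numerically identical to the steady-state
forward–backward filter, imposes reflective boundary handling, removes DC
exactly, and filters all channels in a single FFT pair.  Filter-accuracy
assertions in the tests avoid the first and last five seconds.

The regression step estimates its regressor from the data, so it is a
data-dependent projection: exactly homogeneous under rescaling, additive
only for inputs sharing the regressor subspace, and its residuals are
orthogonal to the regressor to machine precision.  A provenance record
(step order, parameters, rejected channels) travels with every cleaned
run.

## Reconstruction

`invert_sensitivity()` implements the standard two-step spatially variant
scheme.  With $W = \mathrm{diag}(A^\top A)$ and
$L_v = \sqrt{W_v + \lambda_2 \max_v W_v}$,

$$\tilde A = A\, \mathrm{diag}(1/L), \qquad
\hat x = \mathrm{diag}(1/L)\,\tilde A^\top
(\tilde A \tilde A^\top + \lambda_1 \sigma_{max} I)^{-1} y,$$

where $\sigma_{max}$ is the largest eigenvalue of
$\tilde A \tilde A^\top$.  Defaults are $\lambda_1 = 0.05$ and
$\lambda_2 = 0.1$.  Scaling the $\lambda_1$ penalty by $\sigma_{max}$ is a
design choice recorded in the operator provenance; each wavelength is
inverted with its own matrix.  Useful limits: larger $\lambda_1$ shrinks
$\|\hat x\|$ monotonically; as both penalties vanish the operator becomes
an exact right-inverse — the unique least-squares solution (the Moore–
Penrose solution) for square or overdetermined systems, and the
sensitivity-weighted minimum-norm solution for underdetermined ones.

The FOV is the flat-field reconstruction (the operator applied to
$A\mathbf{1}$) thresholded at 10% of its maximum, computed from the 830 nm
matrix by convention (config-switchable).  Oxy-/deoxy-hemoglobin come from
solving the 2 × 2 extinction system per voxel and time point; decoding
uses HbO by default with HbR/HbT selectable.  After channel rejection the
inverse is recomputed for the surviving rows (memoized per channel set).

## ROI construction

Localizer runs are block averaged: per block, a pre-onset baseline (mean
of the 2 s before onset) is subtracted and the response summarized as the
mean over the 5–15 s post-onset plateau — the full 15-s window versus a
plateau sub-window is an open choice; the plateau is the default and both
are configurable.  The auditory ROI thresholds the run-averaged map at 25%
of its maximum (with `>=` at the boundary).  The visual ROI thresholds
each hemisphere at 25% of *its own* maximum before the union, so a weakly
responding hemisphere still contributes voxels.  The hemisphere split is
the left/right half of the grid's x axis, and ROI masks are intersected
with the FOV at decoding time.

## Template matching

Each session is analyzed separately.  Runs split into training (first
viewing of each movie) and test (second viewing); a flag swaps the roles.
Both sets drop their first 15 s (onset transients), are partitioned into
equal blocks — one per template segment — and the first `trial_duration`
seconds of each block form the template or trial.  Each block must exceed
`trial_duration` plus a 15-s gap so the previous hemodynamic response has
faded; infeasible requests fail with the violated inequality.  The exact
segment offsets for the 8/16/32-way subdivisions are one consistent
realization of that constraint (trials at block starts), recorded in
provenance.

The classifier is maximum spatiotemporal correlation.  Template and trial
arrays are centered by their single scalar mean over all (voxel, time)
entries in the mask and window, and

$$r_{n,m} = \frac{T_n' \cdot S_m'}{|T_n'|\,|S_m'|}, \qquad
D_m = \arg\max_n r_{n,m}.$$

Exact ties break toward the lowest template index and are logged; they
have measure zero on continuous data.  Voxels that are masked out,
non-finite, or have zero temporal variance are excluded from the centering
and dot products, with the excluded count recorded.  Voxelwise maps center
each time course by its own temporal mean and correlate over time only;
undefined voxels are `NA`, never zero.

## Evaluation

Confusion matrices (rows true, columns decoded) accumulate per session and
sum across sessions.  Reported accuracy is pooled — total correct over
total trials — while SEM and Cohen's
$d = (\bar{acc} - chance)/\mathrm{SD}(acc)$ (sample SD, $n-1$) are
computed over per-session accuracies.  Significance uses the one-sided
exact binomial upper tail $P(X \ge k)$ at $p_0 = 1/N_{templates}$, pooled
over trials; sweep p-values are reported uncorrected.  Percentages render
half-up to one decimal (two below 10%), giving the chance column 25.0,
12.5, 6.25, 3.13 for 4-, 8-, 16-, 32-way decoding.

## Problem sizes and reproducibility

The default experiment simulates sessions of four 315-s movies viewed
twice at 10 Hz on the desk-scale geometry; one session simulates and
processes in a few seconds.  The package's own validation uses 50 sessions
for the joint parameter sweep (4/240 → 32/15), 200 zero-signal sessions on
a reduced 8 × 8 geometry for null calibration, and 13 metadata-scale
sessions for design bookkeeping (52 matched / 156 mismatched run pairs).
All randomness flows from one master seed through a documented affine
derivation (`derive_seed()`), so reruns are bit-identical; generators
restore the caller's RNG state.

## Known limitations

* The analytic sensitivity model has no scalp/skull compartment, so
  short-separation channels carry cortical signal; superficial regression
  is therefore conservative here.
* Hemoglobin units are relative; absolute quantification is out of scope.
* The full-scale array geometry (128 sources, 125 detectors) is expressible
  through the configuration but untested at that scale.
* Decoding transfers nothing across sessions or subjects by design; the
  classifier sees one session at a time.
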