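#' Describe a synthetic imaging session
#'
#' A decoding session presents each of `movie_ids` twice (two viewings);
#' localizer runs use the block schedule in `localizer_blocks` (15 s of
#' stimulation followed by 15 s of rest, six blocks, by default).
#'
#' @param movie_ids vector of unique movie identifiers
#' @param run_duration run length in seconds (default 315, i.e. a 5- to
#'   6-minute movie clip)
#' @param viewings_per_movie presentations of each movie (2 for decoding)
#' @param localizer_blocks two-column matrix (onset s, duration s)
#' @param sampling_rate acquisition rate in Hz (default 10)
#' @param seed optional integer seed recorded with the design
#' @return object of class `session_design`
#' @export
session_design <- function(movie_ids = 1:4, run_duration = 315,
                           viewings_per_movie = 2L,
                           localizer_blocks = cbind(
                             onset = seq(15, by = 30, length.out = 6),
                             duration = 15),
                           sampling_rate = 10, seed = NULL) {
  if (anyDuplicated(movie_ids)) {
    dot_stop("dot_invalid_parameter", "movie_ids must be unique")
  }
  if (!is_number(run_duration) || run_duration <= 0) {
    dot_stop("dot_invalid_parameter", "run_duration must be > 0")
  }
  structure(list(movie_ids = movie_ids, run_duration = run_duration,
                 viewings_per_movie = as.integer(viewings_per_movie),
                 localizer_blocks = localizer_blocks,
                 sampling_rate = sampling_rate, seed = seed),
            class = "session_design")
}

#' Default synthetic region layout
#'
#' Designates an "auditory" patch (temporal-like, one contiguous block) and
#' two lateralized "visual" patches (occipital-like, one per hemisphere) on
#' the upper layers of the voxel slab.  Returns logical voxel vectors.
#'
#' @param grid a `voxel_grid`
#' @return list with logical vectors `auditory`, `visual_left`,
#'   `visual_right`, and `visual` (union of the two visual patches)
#' @export
default_region_layout <- function(grid) {
  idx <- voxel_indices(grid)
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  top <- idx[, 3] <= max(1L, ceiling(2 * nz / 3))  # superficial layers
  third_x <- max(1L, floor(nx / 4))
  post_y <- idx[, 2] <= ceiling(ny / 2)
  ant_y <- idx[, 2] > ceiling(ny / 2)
  visual_left <- top & post_y & idx[, 1] <= third_x
  visual_right <- top & post_y & idx[, 1] > nx - third_x
  auditory <- top & ant_y & idx[, 1] > third_x & idx[, 1] <= nx - third_x
  list(auditory = auditory, visual_left = visual_left,
       visual_right = visual_right, visual = visual_left | visual_right)
}

## one pass of 6-neighbour + self smoothing on the voxel lattice
smooth_field <- function(values, grid, iters = 2) {
  a <- array(values, dim = grid$shape)
  shift1 <- function(arr, d, by) {
    dims <- dim(arr)
    if (dims[d] - abs(by) < 1) return(array(0, dims))
    idx_to <- lapply(dims, seq_len)
    idx_from <- lapply(dims, seq_len)
    src <- seq_len(dims[d] - abs(by))
    if (by > 0) {
      idx_to[[d]] <- src + by; idx_from[[d]] <- src
    } else {
      idx_to[[d]] <- src; idx_from[[d]] <- src + abs(by)
    }
    out <- array(0, dims)
    out[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
      arr[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
    out
  }
  ones <- array(1, dim = dim(a))
  for (i in seq_len(iters)) {
    acc <- a
    cnt <- array(1, dim = dim(a))
    for (d in 1:3) {
      if (dim(a)[d] < 2) next
      for (by in c(-1L, 1L)) {
        acc <- acc + shift1(a, d, by)
        cnt <- cnt + shift1(ones, d, by)
      }
    }
    a <- acc / cnt
  }
  as.vector(a)
}

#' Generate distinct movie response signatures
#'
#' Each synthetic movie is represented by a smooth unit-norm spatial
#' pattern with loadings in both the designated auditory-like and
#' visual-like regions, paired with a band-limited stimulus time course at
#' the acquisition rate.  Signatures are rejection-resampled until the
#' pairwise spatiotemporal correlation between the noiseless voxel
#' responses (pattern outer HRF-convolved time course) of distinct movies
#' is at most `max_xcorr`, so classes are separable but not orthogonal by
#' construction.
#'
#' @param n_movies number of movies (>= 2)
#' @param grid a `voxel_grid`
#' @param design a `session_design` (sets duration and sampling rate)
#' @param region_layout as from [default_region_layout()]
#' @param max_xcorr ceiling on pairwise spatiotemporal correlation
#'   (default 0.3)
#' @param seed integer seed
#' @param max_retries resampling attempts before giving up
#' @param smooth_iters lattice smoothing passes for the spatial patterns
#' @return list of `movie_signature` objects (fields `movie_id`,
#'   `spatial_pattern`, `stimulus_timecourse`, `sampling_rate`)
#' @export
make_movie_signatures <- function(n_movies, grid, design = session_design(),
                                  region_layout = default_region_layout(grid),
                                  max_xcorr = 0.3, seed = NULL,
                                  max_retries = 100, smooth_iters = 3) {
  if (!is_count(n_movies) || n_movies < 2) {
    dot_stop("dot_invalid_parameter", "n_movies must be an integer >= 2")
  }
  if (!is_number(max_xcorr) || max_xcorr <= 0 || max_xcorr >= 1) {
    dot_stop("dot_invalid_parameter", "max_xcorr must be in (0, 1)")
  }
  fs <- design$sampling_rate
  nt <- round(design$run_duration * fs)
  nv <- n_voxels(grid)
  h <- canonical_hrf(fs)
  bump <- function(region) {
    b <- smooth_field(as.numeric(region), grid, iters = smooth_iters)
    b / max(b)
  }
  b_aud <- bump(region_layout$auditory)
  b_vl <- bump(region_layout$visual_left)
  b_vr <- bump(region_layout$visual_right)
  lp <- signal::butter(2, min(0.2 / (fs / 2), 0.99), "low")

  gen_one <- function(id) {
    base <- smooth_field(stats::rnorm(nv), grid, iters = smooth_iters)
    base <- base / stats::sd(base)
    w <- stats::rnorm(3, mean = 0, sd = 1)
    w <- sign(w) * pmax(abs(w), 0.5)  # keep region loadings away from zero
    p <- 0.6 * base + w[1] * b_aud + w[2] * b_vl + w[3] * b_vr
    p <- p / sqrt(sum(p^2))
    stim <- as.numeric(signal::filtfilt(lp, stats::rnorm(nt)))
    stim <- (stim - mean(stim)) / stats::sd(stim)
    structure(list(movie_id = id, spatial_pattern = p,
                   stimulus_timecourse = stim, sampling_rate = fs),
              class = "movie_signature")
  }

  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      sigs <- lapply(seq_len(n_movies), gen_one)
      resp <- vapply(sigs, function(s) {
        as.vector(outer(s$spatial_pattern,
                        hrf_convolve(s$stimulus_timecourse, h)))
      }, numeric(nv * nt))
      cc <- stats::cor(resp)
      if (max(abs(cc[upper.tri(cc)])) <= max_xcorr) {
        for (i in seq_len(n_movies)) {
          sigs[[i]]$movie_id <- if (length(design$movie_ids) >= i)
            design$movie_ids[i] else i
        }
        return(sigs)
      }
    }
    dot_stop("dot_generation_failure", sprintf(
      "could not generate %d signatures with pairwise |r| <= %g in %d tries",
      n_movies, max_xcorr, max_retries))
  })
}
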