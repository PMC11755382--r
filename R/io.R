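#' Write a voxel time series as 4D NIfTI
#'
#' The voxel raster order (x fastest) maps directly onto the NIfTI array
#' layout; grid spacing and the sampling interval go into pixdim.
#'
#' @param ts a `voxel_timeseries`
#' @param path output path (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
write_voxel_nifti <- function(ts, path) {
  arr <- array(ts$data, dim = c(ts$grid$shape, ncol(ts$data)))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(ts$grid$spacing,
                                   if (is.finite(ts$sampling_rate))
                                     1 / ts$sampling_rate else 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a voxel time series from 4D NIfTI
#'
#' @param path NIfTI file written by [write_voxel_nifti()]
#' @param species hemoglobin / absorption species label
#' @return a `voxel_timeseries`
#' @export
read_voxel_nifti <- function(path, species = "HbO") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  grid <- voxel_grid(d[1:3], spacing = pd[1:3])
  nt <- if (length(d) >= 4) d[4] else 1L
  fs <- if (length(pd) >= 4 && pd[4] > 0) 1 / pd[4] else NA_real_
  voxel_timeseries(matrix(as.vector(img), nrow = prod(d[1:3]), ncol = nt),
                   grid, fs, species = species)
}

#' Write a binary voxel mask as 3D NIfTI
#'
#' @param mask logical voxel vector
#' @param grid the `voxel_grid`
#' @param path output path
#' @return the path, invisibly
#' @export
write_mask_nifti <- function(mask, grid, path) {
  arr <- array(as.integer(mask), dim = grid$shape)
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, grid$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary voxel mask from 3D NIfTI
#'
#' @param path NIfTI file
#' @return logical voxel vector with attribute `grid`
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  mask <- as.vector(img) != 0
  attr(mask, "grid") <- voxel_grid(dim(img)[1:3],
                                   spacing = RNifti::pixdim(img)[1:3])
  mask
}

#' Write a decoding report as JSON
#'
#' @param report a `decoding_report`
#' @param path output .json path
#' @return the path, invisibly
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  x$aggregate_confusion <- unclass(x$aggregate_confusion)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Write a confusion matrix as CSV
#'
#' @param conf a `confusion_matrix` (rows = true, cols = decoded)
#' @param path output .csv path
#' @return the path, invisibly
#' @export
write_confusion_csv <- function(conf, path) {
  m <- as.data.frame(unclass(conf))
  names(m) <- paste0("decoded_", seq_len(ncol(m)))
  m <- cbind(true = seq_len(nrow(m)), m)
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Read a confusion matrix written by [write_confusion_csv()]
#'
#' @param path CSV path
#' @return a `confusion_matrix`
#' @export
read_confusion_csv <- function(path) {
  m <- utils::read.csv(path)
  confusion_matrix(as.matrix(m[, -1, drop = FALSE]))
}

## write all artifacts of a finished experiment with provenance
write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$table, file.path(out_dir, "sweep_table.csv"),
                   row.names = FALSE)
  for (i in seq_along(result$reports)) {
    r <- result$reports[[i]]
    stem <- sprintf("report_%dway_%gs", r$n_templates, r$trial_duration)
    write_report_json(r, file.path(out_dir, paste0(stem, ".json")))
    write_confusion_csv(r$aggregate_confusion,
                        file.path(out_dir, paste0(stem, "_confusion.csv")))
  }
  prov <- list(seed = result$config$seed, session_seeds = result$seeds,
               n_sessions = result$config$n_sessions,
               package_version = as.character(utils::packageVersion("dotdecode")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
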