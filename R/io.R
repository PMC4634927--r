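# Readers/writers for the pipeline's on-disk artifacts.
#
# Image sequences are exported as NIfTI volumes with frames along the
# third axis (the dynamic-series convention used throughout).  Sinogram
# sequences and system matrices are stored as compressed archives of
# named arrays (R serialization, gzip-compressed) carrying the geometry
# needed to re-load them without external context.  Run manifests are
# plain JSON.

#' Write / read an image-frame sequence as NIfTI
#'
#' Frames (columns of `X`) become slices along the third axis; pixels use
#' the package's row-major vectorization, so slice `[r, c]` is image row
#' `r`, column `c`.
#'
#' @param X image-frame matrix `P x T`.
#' @param grid the [image_grid()] the frames live on.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_image_nifti`: the path, invisibly; `read_image_nifti`:
#'   a `P x T` matrix.
#' @export
write_image_nifti <- function(X, grid, path) {
  X <- as_frame_matrix(X, grid$height * grid$width, "X")
  arr <- array(0, dim = c(grid$height, grid$width, ncol(X)))
  for (t in seq_len(ncol(X))) arr[, , t] <- unvec_image(X[, t], grid)
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = rep(grid$pixel_size, 3)),
                     file = path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_image_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  g <- image_grid(dim(arr)[1], dim(arr)[2])
  X <- matrix(0, g$height * g$width, dim(arr)[3])
  for (t in seq_len(dim(arr)[3])) X[, t] <- vec_image(arr[, , t])
  X
}

#' Write / read a sinogram archive
#'
#' Stores the count matrix together with its acquisition geometry as a
#' compressed archive of named arrays (`entries`, `shape`, `angles`,
#' `n_bins`, `bin_spacing`, plus the simulation `scale` and
#' `contamination` when present).
#'
#' @param sim a `"sinogram_sim"` from [simulate_sinograms()], or a plain
#'   `D x T` matrix (then `geometry` must be given).
#' @param path output `.rds` path.
#' @param geometry a [sinogram_geometry()] (only needed for plain
#'   matrices).
#' @return `write_sinogram_archive`: the path, invisibly;
#'   `read_sinogram_archive`: a list with elements `Y`, `geometry`,
#'   `scale`, `contamination`.
#' @export
write_sinogram_archive <- function(sim, path, geometry = NULL) {
  if (inherits(sim, "sinogram_sim")) {
    Y <- sim$Y; geometry <- sim$geometry
    scale <- sim$scale; contamination <- sim$contamination
  } else {
    Y <- as.matrix(sim)
    if (is.null(geometry)) stop("geometry required for a plain matrix")
    scale <- 1; contamination <- 0
  }
  saveRDS(list(entries = Y, shape = dim(Y), angles = geometry$angles,
               n_bins = geometry$n_bins, bin_spacing = geometry$bin_spacing,
               scale = scale, contamination = contamination),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname write_sinogram_archive
#' @export
read_sinogram_archive <- function(path) {
  a <- readRDS(path)
  list(Y = a$entries,
       geometry = sinogram_geometry(a$n_bins, a$angles, a$bin_spacing),
       scale = a$scale %||% 1, contamination = a$contamination %||% 0)
}

#' Write / read a system matrix archive
#'
#' @param G a `"system_matrix"`.
#' @param path output `.rds` path.
#' @return the path invisibly, resp. the restored `"system_matrix"`.
#' @export
write_system_matrix <- function(G, path) {
  stopifnot(inherits(G, "system_matrix"))
  saveRDS(list(entries = G$entries,
               grid = unclass(G$grid),
               n_bins = G$geometry$n_bins, angles = G$geometry$angles,
               bin_spacing = G$geometry$bin_spacing),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname write_system_matrix
#' @export
read_system_matrix <- function(path) {
  a <- readRDS(path)
  structure(list(entries = a$entries,
                 grid = image_grid(a$grid$height, a$grid$width,
                                   a$grid$pixel_size),
                 geometry = sinogram_geometry(a$n_bins, a$angles,
                                              a$bin_spacing)),
            class = "system_matrix")
}

#' Write / read a run manifest
#'
#' A JSON record of everything needed to re-run a pipeline step (seed,
#' counts, fractions, geometry, parameters).
#'
#' @param info named list of scalar settings.
#' @param path output `.json` path.
#' @return the path invisibly, resp. the manifest list.
#' @export
write_manifest <- function(info, path) {
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
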