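#' Image grid for reconstruction
#'
#' Describes the pixel lattice on which activity images live.  Images are
#' stored as numeric matrices with `height` rows and `width` columns; when a
#' frame is needed as a vector (a column of the image-sequence matrix `X`)
#' pixels are taken in row-major order with 0-based row/column indices, i.e.
#' pixel `(r, c)` maps to vector position `r * width + c + 1`.
#'
#' @param height,width grid dimensions in pixels (>= 1).
#' @param pixel_size side length of a pixel, in arbitrary length units.
#' @return an object of class `"image_grid"`.
#' @seealso [vec_image()], [unvec_image()]
#' @export
image_grid <- function(height, width, pixel_size = 1.0) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L) stop("grid dimensions must be >= 1")
  if (!is.finite(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(height = height, width = width, pixel_size = pixel_size),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image grid: %d x %d pixels, pixel size %g\n",
              x$height, x$width, x$pixel_size))
  invisible(x)
}

#' Parallel-beam sinogram geometry
#'
#' @param n_bins number of detector bins per projection angle (>= 1).
#' @param angles strictly increasing projection angles in degrees, each in
#'   `[0, 180)`.
#' @param bin_spacing detector bin pitch in the same length units as the
#'   image grid.
#' @return an object of class `"sinogram_geometry"`.  A single sinogram
#'   frame is a vector of length `D = n_bins * length(angles)`, ordered
#'   angle-major (all bins of angle 1, then all bins of angle 2, ...).
#' @export
sinogram_geometry <- function(n_bins, angles, bin_spacing = 1.0) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  angles <- as.numeric(angles)
  if (length(angles) < 1L) stop("need at least one projection angle")
  if (any(angles < 0 | angles >= 180)) stop("angles must lie in [0, 180)")
  if (length(angles) > 1L && any(diff(angles) <= 0))
    stop("angles must be strictly increasing")
  if (!is.finite(bin_spacing) || bin_spacing <= 0)
    stop("bin_spacing must be > 0")
  structure(list(n_bins = n_bins, angles = angles, bin_spacing = bin_spacing,
                 n_angles = length(angles), D = n_bins * length(angles)),
            class = "sinogram_geometry")
}

#' @export
print.sinogram_geometry <- function(x, ...) {
  cat(sprintf("sinogram geometry: %d bins x %d angles (D = %d), bin spacing %g\n",
              x$n_bins, x$n_angles, x$D, x$bin_spacing))
  invisible(x)
}

#' Vectorize / restore an image frame
#'
#' Row-major (0-based) vectorization convention used throughout the package:
#' `vec_image` flattens a `height x width` matrix row by row;
#' `unvec_image` is its inverse.
#'
#' @param M image matrix (`height x width`).
#' @param v numeric vector of length `height * width`.
#' @param grid an [image_grid()].
#' @return `vec_image`: a numeric vector; `unvec_image`: an image matrix.
#' @export
vec_image <- function(M) as.vector(t(M))

#' @rdname vec_image
#' @export
unvec_image <- function(v, grid) {
  matrix(v, nrow = grid$height, ncol = grid$width, byrow = TRUE)
}

#' Circular field-of-view mask
#'
#' Pixels whose centers fall outside the inscribed circle of the grid are
#' outside the field of view: their projections may fall off the detector,
#' so their system-matrix columns can be zero and reconstructions freeze
#' them at zero.
#'
#' @param grid an [image_grid()].
#' @return logical `height x width` matrix, `TRUE` inside the FOV.
#' @export
fov_mask <- function(grid) {
  ps <- grid$pixel_size
  yc <- (seq_len(grid$height) - 1 - (grid$height - 1) / 2) * ps
  xc <- (seq_len(grid$width)  - 1 - (grid$width  - 1) / 2) * ps
  r  <- min(grid$height, grid$width) / 2 * ps
  outer(yc, xc, function(y, x) x^2 + y^2 <= r^2 + 1e-9)
}
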