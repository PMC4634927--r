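#' Build a parallel-beam PET system matrix
#'
#' Constructs the sparse nonnegative operator `G` (`D x P`) mapping a
#' vectorized activity image to its expected sinogram: row `d` of `G`
#' holds the contribution weights of every pixel to detector bin `d`.
#' Weights are pixel-driven line-integral weights: each pixel center is
#' projected onto the detector axis of each angle and its path length
#' (`pixel_size`) is split between the two nearest bins by linear
#' interpolation.  Because the interpolation weights of an in-range pixel
#' sum to one, the per-angle bin sums of a projection equal
#' `pixel_size * sum(x)` for every angle, the defining mass-consistency
#' property of a parallel-beam projector.
#'
#' Conventions (fixed so sinograms are reproducible bit for bit): images
#' are vectorized row-major 0-based ([vec_image()]); the detector
#' coordinate of pixel `(r, c)` at angle `theta` (degrees) is
#' `t = y cos(theta) - x sin(theta)` with `x = (c - (w-1)/2) * pixel_size`
#' and `y = (r - (h-1)/2) * pixel_size`, so angle 0 projects along image
#' rows; sinogram rows are ordered angle-major with bins fastest.
#'
#' Pixels outside the circular field of view ([fov_mask()]) may project
#' off the detector and can yield all-zero columns; inside the FOV every
#' column is nonzero provided the detector covers the FOV diameter.
#'
#' @param grid an [image_grid()].
#' @param geometry a [sinogram_geometry()].
#' @return an object of class `"system_matrix"` with elements `entries`
#'   (a `Matrix::dgCMatrix`), `grid`, and `geometry`.
#' @examples
#' G <- build_parallel_projector(image_grid(16, 16),
#'                               sinogram_geometry(16, seq(0, 165, by = 15)))
#' @export
build_parallel_projector <- function(grid, geometry) {
  stopifnot(inherits(grid, "image_grid"), inherits(geometry, "sinogram_geometry"))
  h <- grid$height; w <- grid$width; ps <- grid$pixel_size
  P <- h * w; nb <- geometry$n_bins; na <- geometry$n_angles
  # pixel centers in row-major vectorization order
  rr <- rep(seq_len(h) - 1L, each = w)
  cc <- rep(seq_len(w) - 1L, times = h)
  x <- (cc - (w - 1) / 2) * ps
  y <- (rr - (h - 1) / 2) * ps

  ti <- ii <- jj <- vector("list", na)
  for (a in seq_len(na)) {
    th <- geometry$angles[a] * pi / 180
    t_det <- y * cos(th) - x * sin(th)
    pos <- t_det / geometry$bin_spacing + (nb - 1) / 2
    i0 <- floor(pos)
    w1 <- pos - i0
    # two-bin linear split of the path length ps
    bin <- c(i0, i0 + 1)
    wt  <- c(1 - w1, w1) * ps
    pix <- c(seq_len(P), seq_len(P))
    keep <- bin >= 0 & bin <= nb - 1 & wt > 0
    ii[[a]] <- (a - 1L) * nb + bin[keep] + 1L
    jj[[a]] <- pix[keep]
    ti[[a]] <- wt[keep]
  }
  entries <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                  x = unlist(ti), dims = c(nb * na, P))
  structure(list(entries = entries, grid = grid, geometry = geometry),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("PET system matrix: %d x %d (%.2f%% nonzero), %d angles x %d bins\n",
              nrow(x$entries), ncol(x$entries),
              100 * Matrix::nnzero(x$entries) / prod(dim(x$entries)),
              x$geometry$n_angles, x$geometry$n_bins))
  invisible(x)
}

as_frame_matrix <- function(X, n, what) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  X <- as.matrix(X)
  if (nrow(X) != n)
    stop(sprintf("%s has %d rows, expected %d", what, nrow(X), n))
  X
}

#' Forward and back projection of frame sequences
#'
#' `forward_project` applies `G` to each column (frame) of the image
#' sequence `X` (`P x T`), producing the noiseless sinogram sequence
#' `G X` (`D x T`).  `back_project` applies the exact transpose `G'` to
#' each column of a sinogram sequence.
#'
#' @param G a `"system_matrix"` from [build_parallel_projector()].
#' @param X image-frame matrix, `P x T` (or a length-`P` vector).
#' @param Y sinogram matrix, `D x T` (or a length-`D` vector).
#' @return dense numeric matrix (`D x T`, resp. `P x T`).
#' @export
forward_project <- function(G, X) {
  X <- as_frame_matrix(X, ncol(G$entries), "X")
  as.matrix(G$entries %*% X)
}

#' @rdname forward_project
#' @export
back_project <- function(G, Y) {
  Y <- as_frame_matrix(Y, nrow(G$entries), "Y")
  as.matrix(Matrix::crossprod(G$entries, Y))
}

#' Spectral norm of the system matrix
#'
#' Largest singular value of `G`, computed by power iteration on `G'G`
#' from a fixed deterministic starting vector (all ones, normalized).
#' The solver's convergence condition requires step constants
#' `beta >= operator_norm(G)^2`.
#'
#' @param G a `"system_matrix"`.
#' @param tol relative tolerance on successive singular-value estimates.
#' @param max_iter iteration cap; failure to converge within it signals an
#'   ill-posed operator and is an error.
#' @return the scalar `||G||_2`.
#' @export
operator_norm <- function(G, tol = 1e-8, max_iter = 10000L) {
  A <- G$entries
  v <- rep(1, ncol(A)); v <- v / sqrt(sum(v^2))
  s_old <- 0
  for (k in seq_len(max_iter)) {
    u <- as.vector(A %*% v)
    v <- as.vector(Matrix::crossprod(A, u))
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(0)
    v <- v / nv
    s <- sqrt(nv)
    if (abs(s - s_old) <= tol * max(s, .Machine$double.eps)) return(s)
    s_old <- s
  }
  stop("power iteration did not converge; operator may be ill-posed")
}

#' Identity system matrix
#'
#' A degenerate "scanner" whose system matrix is the identity: each pixel
#' is observed directly.  In this limit the reconstruction model reduces
#' to robust principal component analysis of the frame matrix, which is
#' useful for validating the solver against planted low-rank + sparse
#' decompositions.
#'
#' @param grid an [image_grid()].
#' @return a `"system_matrix"` with `G = I` (`P x P`).
#' @export
identity_system_matrix <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  P <- grid$height * grid$width
  geometry <- sinogram_geometry(P, 0, grid$pixel_size)
  entries <- Matrix::sparseMatrix(i = seq_len(P), j = seq_len(P), x = 1,
                                  dims = c(P, P))
  structure(list(entries = entries, grid = grid, geometry = geometry),
            class = "system_matrix")
}
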