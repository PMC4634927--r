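# Tight framelet analysis/synthesis used to sparsify the time-varying
# component.  The transform is undecimated (stationary), acts spatially on
# each frame, and is normalized so the analysis operator A satisfies
# A'A = I exactly; synthesis is then the adjoint A' and is a left inverse
# on the range of A, the identity the solver's linearization relies on.
#
# Boundary handling: periodic (default) filters circularly, giving the
# compact coefficient layout (band size = image size); symmetric
# (reflective) extends a length-n signal to the 2n-periodic [x, rev(x)]
# before filtering (the extension E satisfies E'E = 2I, so a 1/sqrt(2)
# scale keeps the isometry) and avoids any wrap-around seam at the cost
# of 4x larger bands.  Both keep constants constant under the low pass
# and both are exact tight frames.  Deeper levels use a-trous (dilated)
# filters.  At the desk-scale grids this package targets the full
# analysis operator is materialized as one sparse matrix (Kronecker
# products of the per-dimension filter operators), so applying A or A' is
# a single sparse-dense product.

framelet_filters <- function(family) {
  switch(family,
    linear_bspline = list(h0 = c(1, 2, 1) / 4,
                          h1 = c(1, 0, -1) * sqrt(2) / 4,
                          h2 = c(-1, 2, -1) / 4),
    haar = list(h0 = c(1, 1) / 2,
                h1 = c(1, -1) / 2),
    stop(sprintf("unknown framelet family '%s'", family))
  )
}

# circulant convolution matrix (sparse) of size m for filter h, centered,
# with taps dilated by `dilation` (a-trous)
circulant_filter_matrix <- function(h, m, dilation = 1L) {
  L <- length(h)
  center <- floor((L - 1) / 2)
  offs <- (seq_len(L) - 1L - center) * dilation
  i <- rep(seq_len(m), times = L)
  j <- ((rep(seq_len(m), times = L) - 1L - rep(offs, each = m)) %% m) + 1L
  Matrix::sparseMatrix(i = i, j = j, x = rep(h, each = m), dims = c(m, m))
}

# symmetric extension matrix E: R^n -> R^{2n}, Ex = c(x, rev(x))
extension_matrix <- function(n) {
  Matrix::sparseMatrix(i = seq_len(2L * n), j = c(seq_len(n), rev(seq_len(n))),
                       x = 1, dims = c(2L * n, n))
}

#' Build a tight framelet operator
#'
#' Constructs the undecimated 2D tight-frame analysis operator `A` used to
#' sparsify the time-varying component.  The default filter bank is the
#' piecewise-linear B-spline tight frame (low-pass `[1,2,1]/4`, band-pass
#' `[1,0,-1] * sqrt(2)/4`, high-pass `[-1,2,-1]/4`), whose squared filter
#' responses sum to one, so the normalized transform is an exact isometry
#' (`A'A = I`).  `family = "haar"` gives the two-filter Haar tight frame and
#' `family = "identity"` a pass-through operator (analysis and synthesis
#' both the identity), useful for running the solver as plain robust PCA.
#'
#' Coefficients are stored band by band: for each level, all high-pass
#' band combinations in filter order, with the final low-pass band last;
#' each band has `4 * height * width` coefficients (the symmetric
#' extension doubles each dimension).
#'
#' @param grid an [image_grid()]; each dimension must be at least
#'   `2^levels`.
#' @param levels decomposition depth (>= 1).
#' @param family `"linear_bspline"` (default), `"haar"`, or `"identity"`.
#' @param boundary `"periodic"` (default; circulant filtering, band size
#'   equals the image size) or `"symmetric"` (reflective extension folded
#'   into the operator; no wrap-around seam, bands 4x larger).
#' @return an object of class `"framelet_operator"` with the analysis
#'   matrix in `$op` (`coeff_length x P`).
#' @export
build_framelet <- function(grid, levels = 1L, family = "linear_bspline",
                           boundary = "periodic") {
  stopifnot(inherits(grid, "image_grid"))
  family <- match.arg(family, c("linear_bspline", "haar", "identity"))
  boundary <- match.arg(boundary, c("periodic", "symmetric"))
  if (family == "identity") {
    return(structure(list(family = "identity", levels = 0L, grid = grid,
                          op = NULL, coeff_length = grid$height * grid$width,
                          band_size = grid$height * grid$width),
                     class = "framelet_operator"))
  }
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  if (min(grid$height, grid$width) < 2^levels)
    stop("grid too small for requested number of levels")
  filt <- framelet_filters(family)
  K <- length(filt)
  if (boundary == "symmetric") {
    h2 <- 2L * grid$height; w2 <- 2L * grid$width
    # per-dimension level-1 operators: (1/sqrt(2)) H_k E, an isometric set
    Er <- extension_matrix(grid$height) / sqrt(2)
    Ec <- extension_matrix(grid$width) / sqrt(2)
    Sr <- lapply(filt, function(h) circulant_filter_matrix(h, h2) %*% Er)
    Sc <- lapply(filt, function(h) circulant_filter_matrix(h, w2) %*% Ec)
  } else {
    h2 <- grid$height; w2 <- grid$width
    Sr <- lapply(filt, circulant_filter_matrix, m = h2)
    Sc <- lapply(filt, circulant_filter_matrix, m = w2)
  }
  high <- list()      # high-band operators, in order
  low_op <- NULL      # cumulative low-pass operator (rows act on vec(X))
  for (j in seq_len(levels)) {
    if (j == 1L) {
      ops <- lapply(seq_len(K), function(k)
        lapply(seq_len(K), function(l) Matrix::kronecker(Sr[[k]], Sc[[l]])))
    } else {
      d <- 2L^(j - 1L)
      Tr <- lapply(filt, circulant_filter_matrix, m = h2, dilation = d)
      Tc <- lapply(filt, circulant_filter_matrix, m = w2, dilation = d)
      ops <- lapply(seq_len(K), function(k)
        lapply(seq_len(K), function(l)
          Matrix::kronecker(Tr[[k]], Tc[[l]]) %*% low_op))
    }
    for (k in seq_len(K)) for (l in seq_len(K)) {
      if (k == 1L && l == 1L) next
      high[[length(high) + 1L]] <- ops[[k]][[l]]
    }
    low_op <- ops[[1L]][[1L]]
  }
  op <- methods::as(do.call(rbind, c(high, list(low_op))), "CsparseMatrix")
  structure(list(family = family, levels = levels, grid = grid,
                 boundary = boundary, n_filters = K, op = op,
                 band_size = h2 * w2, n_bands = length(high) + 1L,
                 coeff_length = nrow(op)),
            class = "framelet_operator")
}

#' @export
print.framelet_operator <- function(x, ...) {
  cat(sprintf("tight framelet operator: family '%s', %d level(s), %d x %d grid, C = %d\n",
              x$family, x$levels, x$grid$height, x$grid$width, x$coeff_length))
  invisible(x)
}

#' Framelet analysis and synthesis of frame sequences
#'
#' `analyze` applies the 2D framelet decomposition independently to each
#' column (frame) of `X`, returning the coefficient matrix (`C x T`);
#' `synthesize` applies the adjoint, which for this normalized tight frame
#' is a left inverse: `synthesize(A, analyze(A, X))` equals `X` to
#' round-off.
#'
#' The row-major image vectorization of [vec_image()] is assumed, matching
#' the rest of the package.
#'
#' @param A a `"framelet_operator"` from [build_framelet()].
#' @param X image-frame matrix `P x T` (or length-`P` vector).
#' @param C coefficient matrix `C x T` as produced by `analyze`.
#' @return `analyze`: a `C x T` numeric matrix; `synthesize`: a `P x T`
#'   image-frame matrix.
#' @export
analyze <- function(A, X) {
  stopifnot(inherits(A, "framelet_operator"))
  P <- A$grid$height * A$grid$width
  X <- as_frame_matrix(X, P, "X")
  if (A$family == "identity") return(X)
  as.matrix(A$op %*% X)
}

#' @rdname analyze
#' @export
synthesize <- function(A, C) {
  stopifnot(inherits(A, "framelet_operator"))
  if (is.null(dim(C))) C <- matrix(C, ncol = 1L)
  if (nrow(C) != A$coeff_length) stop("coefficient length mismatch")
  if (A$family == "identity") return(as.matrix(C))
  as.matrix(Matrix::crossprod(A$op, C))
}
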