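#' Singular value thresholding
#'
#' Proximal operator of the nuclear norm: for `W = U diag(s) V'`,
#' `svt(W, eps)` returns `U diag(max(s - eps, 0)) V'`, the unique minimizer
#' of `eps * ||X||_* + 0.5 * ||X - W||_F^2`.  The sign of each left
#' singular vector is fixed so that its largest-magnitude entry is
#' nonnegative; this does not change the product but makes decompositions
#' reproducible.
#'
#' @param W numeric matrix with finite entries.
#' @param eps threshold, `>= 0`.
#' @return matrix of the same shape, with rank `<= rank(W)` and nuclear
#'   norm `<= ||W||_*`.
#' @export
svt <- function(W, eps) {
  svt_core(W, eps)$X
}

# svt plus the thresholded singular values (the nuclear norm of the
# output comes for free inside the solver loop)
svt_core <- function(W, eps) {
  if (!all(is.finite(W))) stop("svt: non-finite input")
  if (eps < 0) stop("svt: eps must be >= 0")
  sv <- svd(W)
  # deterministic sign convention
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) { sv$u[, j] <- -sv$u[, j]; sv$v[, j] <- -sv$v[, j] }
  }
  d <- pmax(sv$d - eps, 0)
  keep <- d > 0
  X <- if (!any(keep)) matrix(0, nrow(W), ncol(W))
  else sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
  list(X = X, d = d)
}

#' Elementwise soft thresholding
#'
#' Proximal operator of the (scaled) l1 norm:
#' `max(0, |w| - eps) * sign(w)` applied entrywise, the minimizer of
#' `eps * ||X||_1 + 0.5 * ||X - W||_F^2`.
#'
#' @param W numeric matrix or vector with finite entries.
#' @param eps threshold, `>= 0`.
#' @return object of the same shape; `||output||_1 <= ||W||_1`, and every
#'   entry keeps its sign or is zeroed.
#' @export
soft_threshold <- function(W, eps) {
  if (!all(is.finite(W))) stop("soft_threshold: non-finite input")
  if (eps < 0) stop("soft_threshold: eps must be >= 0")
  sign(W) * pmax(abs(W) - eps, 0)
}
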