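#' Per-frame ML-EM reconstruction
#'
#' Classical maximum-likelihood expectation-maximization for emission
#' tomography, applied independently to each frame of a dynamic study:
#' the multiplicative update `x <- (x / s) * G'(y / (G x))` with
#' sensitivity `s = G' 1`.  Iterates stay nonnegative and the Poisson
#' log-likelihood is non-decreasing (the classical EM guarantee).
#'
#' Pixels with zero sensitivity (rays never cross them, e.g. outside the
#' field of view) are frozen at zero.  Bins where `(G x) = 0` and `y = 0`
#' contribute a ratio of 1 (no information); `(G x) = 0` with `y > 0` is
#' guarded by a small floor (`1e-12`) on the denominator — an
#' implementation guard, not model content.
#'
#' @param Y sinogram matrix `D x T`, nonnegative counts.
#' @param G a `"system_matrix"`.
#' @param n_iter number of EM iterations (default 100).
#' @param init_value positive uniform starting value inside the FOV.
#' @param keep_loglik record the Poisson log-likelihood
#'   `sum(y log(Gx) - Gx)` (constant terms dropped) after every iteration.
#' @return an object of class `"mlem"`: `X` (`P x T` reconstruction),
#'   `loglik_trace` (`n_iter x T` matrix if requested),
#'   `residual_trace` (Frobenius residual per iteration), `n_iter`.
#' @export
mlem <- function(Y, G, n_iter = 100L, init_value = 1.0, keep_loglik = TRUE) {
  stopifnot(inherits(G, "system_matrix"))
  Y <- as_frame_matrix(Y, nrow(G$entries), "Y")
  if (any(Y < 0)) stop("negative counts in Y")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (init_value <= 0) stop("init_value must be > 0")
  P <- ncol(G$entries); Tn <- ncol(Y)
  s <- back_project(G, matrix(1, nrow(G$entries), 1))[, 1]
  live <- s > 0
  X <- matrix(0, P, Tn)
  X[live, ] <- init_value
  floor_eps <- 1e-12
  ll <- if (keep_loglik) matrix(NA_real_, n_iter, Tn) else NULL
  resid <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    GX <- forward_project(G, X)
    ratio <- matrix(0, nrow(GX), Tn)
    pos <- GX > 0
    ratio[pos] <- Y[pos] / GX[pos]
    zz <- !pos & Y == 0
    ratio[zz] <- 1
    starved <- !pos & Y > 0
    ratio[starved] <- Y[starved] / floor_eps
    corr <- back_project(G, ratio)
    X[live, ] <- X[live, , drop = FALSE] / s[live] * corr[live, , drop = FALSE]
    GXn <- forward_project(G, X)
    resid[it] <- sqrt(sum((GXn - Y)^2))
    if (keep_loglik) {
      lg <- ifelse(Y > 0, Y * log(pmax(GXn, floor_eps)), 0)
      ll[it, ] <- colSums(lg - GXn)
    }
  }
  structure(list(X = X, loglik_trace = ll, residual_trace = resid,
                 n_iter = as.integer(n_iter), G = G, Y = Y),
            class = "mlem")
}

#' @export
print.mlem <- function(x, ...) {
  cat(sprintf("ML-EM reconstruction: %d pixels x %d frames, %d iterations\n",
              nrow(x$X), ncol(x$X), x$n_iter))
  cat(sprintf("  final residual norm %.6g\n", utils::tail(x$residual_trace, 1)))
  invisible(x)
}

#' @export
fitted.mlem <- function(object, ...) object$X

#' @export
residuals.mlem <- function(object, ...) {
  object$Y - forward_project(object$G, object$X)
}

#' @export
logLik.mlem <- function(object, ...) {
  if (is.null(object$loglik_trace))
    stop("fit was run with keep_loglik = FALSE")
  ll <- sum(object$loglik_trace[object$n_iter, ])
  structure(ll, df = NA_integer_, class = "logLik")
}
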