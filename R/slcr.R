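# Sparse-plus-low-rank constrained reconstruction (SLCR).
#
# Model: stack the T frames of a dynamic study as columns of X (P x T) and
# decompose X = X1 + X2, where X1 is low rank (the quasi-stationary
# background shared across frames) and A X2 is sparse for a tight framelet
# transform A (the frame-to-frame variation).  Given sinogram data
# Y (D x T) and system matrix G, the reconstruction solves
#
#   min_{X1, X2}  ||X1||_*  +  lambda ||A X2||_1
#                 +  1/(2 tau) ||G (X1 + X2) - Y||_F^2
#
# by a linearized alternating direction method: per outer iteration one
# singular-value-thresholding step on X1 and one framelet-domain shrinkage
# step on X2, each applied to a gradient step on the linearized fidelity.

#' Default sparsity weight
#'
#' The robust-PCA rule of thumb `lambda = 1 / sqrt(max(n, m))` applied to
#' the stacked sinogram matrix dimensions (rows `n_rows = D`, columns
#' `n_cols = T` by default).
#'
#' @param n_rows,n_cols matrix dimensions, both `>= 1`.
#' @return the scalar weight.
#' @export
default_lambda <- function(n_rows, n_cols) {
  if (n_rows < 1 || n_cols < 1) stop("dimensions must be >= 1")
  1 / sqrt(max(n_rows, n_cols))
}

#' Solver parameters for SLCR
#'
#' @param lam sparsity weight `lambda > 0`, or `"auto"` to apply
#'   [default_lambda()] to the sinogram matrix at fit time.
#' @param tau data-fidelity weight `tau > 0`; larger values down-weight
#'   fidelity relative to the low-rank and sparsity penalties.
#' @param beta1,beta2 linearization step constants; `NULL` means
#'   `max(||G||^2, 0.1)`, which satisfies the convergence condition
#'   `beta_i >= ||G||^2`.  When `enforce_convergence_bound` is `FALSE`,
#'   user-supplied values are clipped to the search range `[0.1, 10]`
#'   instead.
#' @param max_iter outer-iteration cap (default 1000).
#' @param tol relative-change stopping tolerance for both components
#'   (default 1e-4), `0 < tol < 1`.
#' @param enforce_convergence_bound if `TRUE` (default), `beta1`/`beta2`
#'   are raised to `||G||^2` when below it.
#' @return a list of class `"slcr_params"`.
#' @export
slcr_params <- function(lam = "auto", tau = 1.0, beta1 = NULL, beta2 = NULL,
                        max_iter = 1000L, tol = 1e-4,
                        enforce_convergence_bound = TRUE) {
  if (!identical(lam, "auto") && (!is.numeric(lam) || lam <= 0))
    stop("lam must be > 0 or \"auto\"")
  if (tau <= 0) stop("tau must be > 0")
  if (tol <= 0 || tol >= 1) stop("tol must be in (0, 1)")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(lam = lam, tau = tau, beta1 = beta1, beta2 = beta2,
                 max_iter = as.integer(max_iter), tol = tol,
                 enforce_convergence_bound = isTRUE(enforce_convergence_bound)),
            class = "slcr_params")
}

resolve_betas <- function(p, G_norm2) {
  pick <- function(b) {
    if (is.null(b)) b <- max(G_norm2, 0.1)
    if (p$enforce_convergence_bound) b <- max(b, G_norm2)
    else b <- min(max(b, 0.1), 10)
    b
  }
  list(beta1 = pick(p$beta1), beta2 = pick(p$beta2))
}

#' SLCR objective value
#'
#' Evaluates the convex objective
#' `||X1||_* + lam * ||A X2||_1 + ||G (X1 + X2) - Y||_F^2 / (2 tau)`.
#'
#' @param X1,X2 image-frame matrices `P x T`.
#' @param Y sinogram matrix `D x T`.
#' @param G a `"system_matrix"`.
#' @param A a `"framelet_operator"`.
#' @param lam,tau positive weights.
#' @return nonnegative scalar.
#' @export
slcr_objective <- function(X1, X2, Y, G, A, lam, tau) {
  if (!all(dim(X1) == dim(X2))) stop("X1 and X2 must have identical shape")
  nuc <- sum(svd(X1, nu = 0, nv = 0)$d)
  l1  <- sum(abs(analyze(A, X2)))
  R   <- forward_project(G, X1 + X2) - Y
  nuc + lam * l1 + sum(R^2) / (2 * tau)
}

fidelity_gradient <- function(G, X1, X2, Y) {
  2 * back_project(G, forward_project(G, X1 + X2) - Y)
}

#' One low-rank (X1) update of the linearized scheme
#'
#' Linearizes the data-fidelity term at the current iterate and solves the
#' resulting surrogate exactly: with fidelity gradient
#' `g = 2 G'(G(X1 + X2) - Y)`, the surrogate
#' `||X1||_* + (1/(2 tau)) (<g, X1 - X1k> + beta1 ||X1 - X1k||_F^2)`
#' has minimizer `svt(X1 - g / (2 beta1), tau / beta1)`.  (The factor 2
#' of the squared-residual gradient is absorbed into the step constant,
#' the convention under which the convergence condition
#' `beta_i >= ||G||^2` is the classical linearized-ADM stability bound.)
#'
#' @param X1k,X2k current iterates (`P x T`).
#' @param Y sinogram matrix.
#' @param G system matrix.
#' @param lam,tau,beta1 solver constants (`lam` unused here, kept for a
#'   uniform signature).
#' @return the updated `X1`.
#' @export
x1_update <- function(X1k, X2k, Y, G, tau, beta1, lam = NULL) {
  g <- fidelity_gradient(G, X1k, X2k, Y)
  svt(X1k - g / (2 * beta1), tau / beta1)
}

#' One sparse (X2) update of the linearized scheme
#'
#' Works in the framelet coefficient domain: linearizing the fidelity at
#' `A X2k` gives the gradient step `C = A X2k - A g / (2 beta2)` with
#' `g = 2 G'(G(X1 + X2k) - Y)`, followed by elementwise shrinkage at
#' threshold `tau * lam / beta2` and synthesis back to image space (same
#' step-constant convention as [x1_update()]).
#'
#' @param X1k1 the already-updated low-rank component.
#' @param X2k current sparse component.
#' @param Y sinogram matrix.
#' @param G system matrix.
#' @param A framelet operator.
#' @param lam,tau,beta2 solver constants.
#' @return the updated `X2`.
#' @export
x2_update <- function(X1k1, X2k, Y, G, A, lam, tau, beta2) {
  g <- fidelity_gradient(G, X1k1, X2k, Y)
  # by linearity A X2k - A g/(2 beta2) = A (X2k - g/(2 beta2))
  C <- analyze(A, X2k - g / (2 * beta2))
  synthesize(A, soft_threshold(C, tau * lam / beta2))
}

rel_change <- function(Xnew, Xold) {
  num <- sqrt(sum((Xnew - Xold)^2))
  den <- sqrt(sum(Xold^2))
  if (den == 0) { if (num == 0) 0 else Inf } else num / den
}

#' Sparse-plus-low-rank constrained dynamic PET reconstruction
#'
#' Fits the SLCR decomposition to a multi-frame sinogram: the image
#' sequence is estimated as `X1 + X2` with `X1` low rank (stationary
#' background) and `A X2` framelet-sparse (frame-to-frame variation), by
#' alternating one singular-value-thresholding step and one shrinkage step
#' per outer iteration on linearized surrogates of the data-fidelity term.
#' Iteration stops when the relative changes of both components fall below
#' `tol`, or after `max_iter` iterations.  With
#' `enforce_convergence_bound = TRUE` the step constants satisfy
#' `beta_i >= ||G||^2`.
#'
#' Both components start from zero, which makes `Y = 0` an exact fixed
#' point.  If an iterate's norm is zero, its relative change is taken as 0
#' when the step is also zero and `Inf` otherwise.
#'
#' @param Y sinogram matrix `D x T` (frames as columns).
#' @param G a `"system_matrix"` from [build_parallel_projector()].
#' @param A a `"framelet_operator"`; defaults to a one-level linear
#'   B-spline frame on `G`'s grid.
#' @param params an [slcr_params()] object.
#' @param verbose print one line per iteration (`k`, objective, relative
#'   changes).
#' @return an object of class `"slcr"` with components `X1`, `X2` (each
#'   `P x T`), `objective_trace`, `eps1_trace`, `eps2_trace`,
#'   `iterations`, `converged`, `lam`, `tau`, `beta1`, `beta2`, plus the
#'   operators used.  `fitted()` returns `X1 + X2`; `residuals()` returns
#'   `Y - G (X1 + X2)`.
#' @examples
#' grid <- image_grid(16, 16)
#' geom <- sinogram_geometry(16, seq(0, 170, by = 30))
#' G <- build_parallel_projector(grid, geom)
#' X <- matrix(vec_image(fov_mask(grid)) * 1.0, 256, 4)
#' fit <- slcr(forward_project(G, X), G,
#'             params = slcr_params(max_iter = 25))
#' @export
slcr <- function(Y, G, A = NULL, params = slcr_params(), verbose = FALSE) {
  stopifnot(inherits(G, "system_matrix"), inherits(params, "slcr_params"))
  Y <- as_frame_matrix(Y, nrow(G$entries), "Y")
  if (is.null(A)) A <- build_framelet(G$grid)
  stopifnot(inherits(A, "framelet_operator"))
  P <- ncol(G$entries); Tn <- ncol(Y)

  lam <- if (identical(params$lam, "auto"))
    default_lambda(nrow(Y), ncol(Y)) else params$lam
  tau <- params$tau
  G_norm2 <- operator_norm(G)^2
  b <- resolve_betas(params, G_norm2)

  X1 <- matrix(0, P, Tn); X2 <- matrix(0, P, Tn)
  obj <- eps1 <- eps2 <- numeric(params$max_iter)
  converged <- FALSE
  k <- 0L
  # residual R = G(X1 + X2) - Y, updated incrementally across the two
  # half-steps; the loop body is algebraically identical to calling
  # x1_update() then x2_update() but reuses projections and the SVT's
  # thresholded singular values for the objective trace.
  R <- -Y
  thr2 <- tau * lam / b$beta2
  Gm <- G$entries
  Am <- if (A$family == "identity") NULL else A$op
  for (k in seq_len(params$max_iter)) {
    s1 <- svt_core(X1 - as.matrix(Matrix::crossprod(Gm, R)) / b$beta1,
                   tau / b$beta1)
    X1n <- s1$X
    R <- R + as.matrix(Gm %*% (X1n - X1))
    U <- X2 - as.matrix(Matrix::crossprod(Gm, R)) / b$beta2
    # framelet-domain soft threshold via clipping: c - clamp(c, -thr, thr);
    # elementwise work stays on the coefficient vector to avoid copies
    if (is.null(Am)) {
      X2n <- U - pmax(pmin(U, thr2), -thr2)
      l1 <- sum(abs(X2n))
    } else {
      Cmat <- Am %*% U
      cs <- Cmat@x
      Cmat@x <- cs - pmax(pmin(cs, thr2), -thr2)
      X2n <- as.matrix(Matrix::crossprod(Am, Cmat))
      # objective needs ||A X2||_1 of the synthesized iterate (A A' != I)
      l1 <- sum(abs(Am %*% X2n))
    }
    if (!is.finite(sum(X1n)) || !is.finite(sum(X2n)))
      stop(sprintf("non-finite iterate at outer iteration %d", k))
    R <- R + as.matrix(Gm %*% (X2n - X2))
    eps1[k] <- rel_change(X1n, X1)
    eps2[k] <- rel_change(X2n, X2)
    X1 <- X1n; X2 <- X2n
    obj[k] <- sum(s1$d) + lam * l1 + sum(R^2) / (2 * tau)
    if (verbose)
      message(sprintf("iter %4d  objective %.6e  eps1 %.3e  eps2 %.3e",
                      k, obj[k], eps1[k], eps2[k]))
    if (eps1[k] < params$tol && eps2[k] < params$tol) { converged <- TRUE; break }
  }
  structure(list(X1 = X1, X2 = X2, Y = Y, G = G, A = A,
                 objective_trace = obj[seq_len(k)],
                 eps1_trace = eps1[seq_len(k)], eps2_trace = eps2[seq_len(k)],
                 iterations = k, converged = converged,
                 lam = lam, tau = tau, beta1 = b$beta1, beta2 = b$beta2,
                 params = params),
            class = "slcr")
}

#' @export
print.slcr <- function(x, ...) {
  cat("Sparse + low-rank dynamic PET reconstruction\n")
  cat(sprintf("  %d pixels x %d frames; %d iterations (%s)\n",
              nrow(x$X1), ncol(x$X1), x$iterations,
              if (x$converged) "converged" else "iteration cap reached"))
  cat(sprintf("  lambda = %.4g, tau = %.4g, beta1 = %.4g, beta2 = %.4g\n",
              x$lam, x$tau, x$beta1, x$beta2))
  cat(sprintf("  final objective %.6g, eps1 %.3g, eps2 %.3g\n",
              utils::tail(x$objective_trace, 1),
              utils::tail(x$eps1_trace, 1), utils::tail(x$eps2_trace, 1)))
  invisible(x)
}

#' @export
summary.slcr <- function(object, ...) {
  d <- svd(object$X1, nu = 0, nv = 0)$d
  C <- abs(analyze(object$A, object$X2))
  ans <- list(
    iterations = object$iterations, converged = object$converged,
    objective = utils::tail(object$objective_trace, 1),
    rank_X1 = sum(d > max(d) * 1e-8),
    # fraction of framelet coefficients carrying appreciable energy
    sparsity_X2 = if (max(C) == 0) 0 else mean(C > 0.01 * max(C)),
    residual_norm = sqrt(sum(residuals.slcr(object)^2)),
    lam = object$lam, tau = object$tau)
  class(ans) <- "summary.slcr"
  ans
}

#' @export
print.summary.slcr <- function(x, ...) {
  cat(sprintf(paste0("SLCR fit: %d iterations (%s), objective %.6g\n",
                     "  rank(X1) = %d, active framelet coefficients of X2",
                     " = %.2f%%, residual norm %.4g\n"),
              x$iterations, if (x$converged) "converged" else "not converged",
              x$objective, x$rank_X1, 100 * x$sparsity_X2, x$residual_norm))
  invisible(x)
}

#' @export
fitted.slcr <- function(object, ...) object$X1 + object$X2

#' @export
residuals.slcr <- function(object, ...) {
  object$Y - forward_project(object$G, fitted.slcr(object))
}

#' Display reconstructed components
#'
#' Shows the stationary component, the time-varying component, and their
#' sum for one frame as grayscale images.
#'
#' @param x an `"slcr"` fit.
#' @param frame frame index to display.
#' @param ... passed to [graphics::image()].
#' @export
plot.slcr <- function(x, frame = 1L, ...) {
  grid <- x$G$grid
  imgs <- list(`stationary (X1)` = unvec_image(x$X1[, frame], grid),
               `time-varying (X2)` = unvec_image(x$X2[, frame], grid),
               `sum (X1 + X2)` = unvec_image(x$X1[, frame] + x$X2[, frame], grid))
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (nm in names(imgs)) {
    M <- imgs[[nm]]
    graphics::image(t(M)[, nrow(M):1], axes = FALSE, main = nm,
                    col = grDevices::gray.colors(128), ...)
  }
  invisible(x)
}
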