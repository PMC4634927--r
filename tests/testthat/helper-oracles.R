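# Independent oracles used by the tests.  Each solves the same problem as
# a package routine by a different, generic route (dense algebra, a
# generic smooth optimizer, scalar loops, or a different algorithm
# family); none shares code with the implementation it checks.

# minimizer of eps * ||X||_* + 0.5 ||X - W||_F^2 by BFGS on a smoothed
# nuclear norm (sum sqrt(sigma^2 + delta)); generic convex solver, no
# thresholding formula involved
nuclear_prox_oracle <- function(W, eps, delta = 1e-14) {
  n <- nrow(W); m <- ncol(W)
  fn <- function(p) {
    X <- matrix(p, n, m)
    s <- svd(X, nu = 0, nv = 0)$d
    eps * sum(sqrt(s^2 + delta)) + 0.5 * sum((X - W)^2)
  }
  gr <- function(p) {
    X <- matrix(p, n, m)
    sv <- svd(X)
    as.vector(eps * sv$u %*% (sv$d / sqrt(sv$d^2 + delta) * t(sv$v)) + (X - W))
  }
  o <- stats::optim(as.vector(W), fn, gr, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-15))
  matrix(o$par, n, m)
}

# scalar minimizer of eps*|x| + 0.5*(x - w)^2 by golden-section search
l1_prox_oracle <- function(W, eps) {
  out <- W
  for (i in seq_along(W)) {
    f <- function(x) eps * abs(x) + 0.5 * (x - W[i])^2
    out[i] <- stats::optimize(f, c(min(0, W[i]) - 1, max(0, W[i]) + 1),
                              tol = 1e-10)$minimum
  }
  out
}

# inexact augmented-Lagrangian robust PCA solving the constrained form
#   min ||L||_* + lambda ||S||_1  s.t.  L + S = M
# (different algorithm family and formulation from the package solver;
# self-contained SVD shrinkage)
ialm_rpca <- function(M, lambda, tol = 1e-7, max_iter = 500) {
  shrink <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  sn <- svd(M, nu = 0, nv = 0)$d[1]
  Yd <- M / max(sn, max(abs(M)) / lambda)
  mu <- 1.25 / sn; rho <- 1.5
  S <- matrix(0, nrow(M), ncol(M))
  for (k in seq_len(max_iter)) {
    sv <- svd(M - S + Yd / mu)
    L <- sv$u %*% (shrink(sv$d, 1 / mu) * t(sv$v))
    S <- shrink(M - L + Yd / mu, lambda / mu)
    Z <- M - L - S
    Yd <- Yd + mu * Z
    mu <- mu * rho
    if (sqrt(sum(Z^2)) / sqrt(sum(M^2)) < tol) break
  }
  list(L = L, S = S, iterations = k)
}

# Poisson log-likelihood (constant terms dropped), evaluated directly
poisson_loglik <- function(y, lam, floor_eps = 1e-12) {
  sum(ifelse(y > 0, y * log(pmax(lam, floor_eps)), 0) - lam)
}
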