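make_small_instance <- function(seed = 13, n = 8L, Tn = 3L, n_angles = 6L) {
  set.seed(seed)
  G <- tiny_projector(n, n_angles)
  P <- ncol(G$entries)
  X1 <- matrix(rnorm(P * Tn), P, Tn)
  X2 <- matrix(rnorm(P * Tn), P, Tn)
  Y <- forward_project(G, X1 + X2) + matrix(rnorm(nrow(G$entries) * Tn),
                                            ncol = Tn)
  list(G = G, X1 = X1, X2 = X2, Y = Y, P = P, Tn = Tn)
}

test_that("objective equals its three terms computed independently", {
  inst <- make_small_instance()
  A <- build_framelet(inst$G$grid)
  lam <- 0.3; tau <- 1.7
  # zero cases
  Z <- matrix(0, inst$P, inst$Tn)
  Y0 <- matrix(0, nrow(inst$G$entries), inst$Tn)
  expect_equal(slcr_objective(Z, Z, Y0, inst$G, A, lam, tau), 0)
  expect_equal(slcr_objective(Z, Z, inst$Y, inst$G, A, lam, tau),
               sum(inst$Y^2) / (2 * tau))
  # term-by-term oracle
  nuc <- sum(svd(inst$X1)$d)
  l1 <- sum(abs(analyze(A, inst$X2)))
  fid <- sum((as.matrix(inst$G$entries) %*% (inst$X1 + inst$X2) - inst$Y)^2) /
    (2 * tau)
  expect_equal(slcr_objective(inst$X1, inst$X2, inst$Y, inst$G, A, lam, tau),
               nuc + lam * l1 + fid, tolerance = 1e-10)
  expect_error(slcr_objective(inst$X1, inst$X2[, 1:2], inst$Y, inst$G, A,
                              lam, tau), "shape")
})

test_that("x1 update solves its linearized surrogate (generic-solver oracle)", {
  inst <- make_small_instance(14, n = 4L, Tn = 2L, n_angles = 4L)
  tau <- 0.9; beta1 <- operator_norm(inst$G)^2
  out <- x1_update(inst$X1, inst$X2, inst$Y, inst$G, tau = tau, beta1 = beta1)
  # surrogate: ||X||_* + (1/2tau) (<g, X - X1k> + beta1 ||X - X1k||_F^2),
  # minimized by smoothed BFGS with no knowledge of the closed form
  g <- 2 * back_project(inst$G,
                        forward_project(inst$G, inst$X1 + inst$X2) - inst$Y)
  sur <- function(p) {
    X <- matrix(p, inst$P, inst$Tn)
    s <- svd(X, nu = 0, nv = 0)$d
    sum(sqrt(s^2 + 1e-14)) +
      (sum(g * (X - inst$X1)) + beta1 * sum((X - inst$X1)^2)) / (2 * tau)
  }
  o <- stats::optim(as.vector(inst$X1), sur, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-15))
  expect_lt(max(abs(out - matrix(o$par, inst$P, inst$Tn))), 1e-5)
  # the surrogate does not increase at the update
  expect_lte(sur(as.vector(out)), sur(as.vector(inst$X1)) + 1e-10)
  # zero-residual, zero-gradient case reduces to svt of the iterate
  Gid <- identity_system_matrix(inst$G$grid)
  expect_equal(x1_update(inst$X1, 0 * inst$X2, forward_project(Gid, inst$X1),
                         Gid, tau = tau, beta1 = 2),
               svt(inst$X1, tau / 2), tolerance = 1e-12)
  Z <- matrix(0, inst$P, inst$Tn)
  expect_equal(x1_update(Z, Z, 0 * inst$Y, inst$G, tau = tau, beta1 = beta1), Z)
})

test_that("x2 update solves its coefficient-domain surrogate (scalar-optimizer oracle)", {
  inst <- make_small_instance(15, n = 4L, Tn = 2L, n_angles = 4L)
  A <- build_framelet(inst$G$grid, family = "haar")
  lam <- 0.25; tau <- 1.3; beta2 <- operator_norm(inst$G)^2
  out <- x2_update(inst$X1, inst$X2, inst$Y, inst$G, A,
                   lam = lam, tau = tau, beta2 = beta2)
  g <- 2 * back_project(inst$G,
                        forward_project(inst$G, inst$X1 + inst$X2) - inst$Y)
  Ck <- analyze(A, inst$X2); gA <- analyze(A, g)
  # elementwise surrogate lam|c| + (1/2tau)(gA (c - ck) + beta2 (c - ck)^2),
  # each coordinate minimized by golden-section search
  Copt <- Ck
  for (i in seq_along(Ck)) {
    f <- function(c) lam * abs(c) +
      (gA[i] * (c - Ck[i]) + beta2 * (c - Ck[i])^2) / (2 * tau)
    lo <- Ck[i] - abs(gA[i]) / beta2 - 1; hi <- Ck[i] + abs(gA[i]) / beta2 + 1
    Copt[i] <- stats::optimize(f, c(lo, hi), tol = 1e-12)$minimum
  }
  expect_lt(max(abs(out - synthesize(A, Copt))), 1e-5)
  # pass-through transform reduces the zero-residual case to plain shrinkage
  Gid <- identity_system_matrix(inst$G$grid)
  Aid <- build_framelet(inst$G$grid, family = "identity")
  expect_equal(x2_update(inst$X1, inst$X2,
                         forward_project(Gid, inst$X1 + inst$X2), Gid, Aid,
                         lam = lam, tau = tau, beta2 = 2),
               soft_threshold(inst$X2, tau * lam / 2), tolerance = 1e-12)
  Z <- matrix(0, inst$P, inst$Tn)
  expect_equal(x2_update(Z, Z, 0 * inst$Y, inst$G, A,
                         lam = lam, tau = tau, beta2 = beta2), Z)
})

test_that("zero data is an exact fixed point reached at the first iteration", {
  G <- tiny_projector(8, 6)
  Y0 <- matrix(0, nrow(G$entries), 3)
  fit <- slcr(Y0, G, params = slcr_params(max_iter = 50))
  expect_true(fit$converged)
  expect_equal(fit$iterations, 1L)
  expect_equal(fit$X1, matrix(0, 64, 3))
  expect_equal(fit$X2, matrix(0, 64, 3))
})

test_that("relative-change guard treats 0/0 as converged and x/0 as divergent", {
  expect_equal(slcr:::rel_change(matrix(0, 2, 2), matrix(0, 2, 2)), 0)
  expect_equal(slcr:::rel_change(matrix(1, 2, 2), matrix(0, 2, 2)), Inf)
})

test_that("objective is non-increasing and convergence flags match the stopping rule", {
  set.seed(16)
  ph <- make_dynamic_phantom(phantom_preset("brain", image_grid(16, 16), 4))
  G <- tiny_projector(16, 8)
  sim <- simulate_sinograms(ph$X, G, acquisition_spec(5e4, seed = 2))
  fit <- slcr(sim$Y, G, params = slcr_params(max_iter = 400))
  expect_lte(max(diff(fit$objective_trace)), 1e-8)
  expect_true(all(is.finite(fit$objective_trace)))
  if (fit$converged) {
    expect_lt(tail(fit$eps1_trace, 1), 1e-4)
    expect_lt(tail(fit$eps2_trace, 1), 1e-4)
  }
  expect_gte(fit$beta1, operator_norm(G)^2)
})

test_that("large lambda suppresses the sparse component entirely", {
  inst <- planted_rpca_instance()
  G <- identity_system_matrix(image_grid(4, 5))
  A <- build_framelet(image_grid(4, 5), family = "identity")
  fit <- slcr(inst$Y, G, A,
              params = slcr_params(lam = 1e4, max_iter = 100))
  expect_equal(max(abs(fit$X2)), 0)
})

test_that("shrinking tau drives the fidelity residual down monotonically", {
  inst <- planted_rpca_instance()
  G <- identity_system_matrix(image_grid(4, 5))
  A <- build_framelet(image_grid(4, 5), family = "identity")
  res <- vapply(c(4, 1, 0.25), function(tau) {
    fit <- slcr(inst$Y, G, A,
                params = slcr_params(lam = inst$lambda, tau = tau,
                                     max_iter = 300, tol = 1e-6))
    sqrt(sum((fit$X1 + fit$X2 - inst$Y)^2))
  }, numeric(1))
  expect_true(all(diff(res) < 0))
})

test_that("identity-operator limit recovers a planted low-rank + sparse split", {
  inst <- planted_rpca_instance()
  G <- identity_system_matrix(image_grid(4, 5))
  A <- build_framelet(image_grid(4, 5), family = "identity")
  fit <- slcr(inst$Y, G, A,
              params = slcr_params(lam = inst$lambda, max_iter = 1000))
  expect_true(fit$converged)
  expect_lt(rel_fro(fit$X1, inst$L), 0.05)
  expect_lt(rel_fro(fit$X2, inst$S), 0.05)
  # independent cross-check: a different RPCA algorithm splits it the same way
  ref <- ialm_rpca(inst$Y, inst$lambda)
  expect_lt(rel_fro(ref$L, inst$L), 0.05)
  expect_lt(rel_fro(ref$S, inst$S), 0.05)
  expect_lt(rel_fro(fit$X1, ref$L), 0.1)
})

test_that("default lambda follows the 1/sqrt(max(n, m)) rule", {
  expect_equal(default_lambda(100, 64), 0.1)
  expect_equal(default_lambda(7, 7), 1 / sqrt(7))
  expect_equal(default_lambda(16, 9), 0.25)
  expect_error(default_lambda(0, 3))
})

test_that("solver parameter validation catches bad settings", {
  expect_error(slcr_params(lam = -1))
  expect_error(slcr_params(tau = 0))
  expect_error(slcr_params(tol = 2))
  p <- slcr_params(beta1 = 0.5, beta2 = 0.5, enforce_convergence_bound = FALSE)
  b <- slcr:::resolve_betas(p, G_norm2 = 100)
  expect_equal(b$beta1, 0.5)          # clipped only to [0.1, 10]
  b2 <- slcr:::resolve_betas(slcr_params(beta1 = 0.5), G_norm2 = 100)
  expect_equal(b2$beta1, 100)         # raised to ||G||^2
})

test_that("the solver loop reproduces manual alternation of the two updates", {
  set.seed(24)
  G <- tiny_projector(8, 6)
  A <- build_framelet(G$grid)
  ph <- make_dynamic_phantom(phantom_preset("brain", image_grid(8, 8), 3))
  Y <- forward_project(G, ph$X) + abs(matrix(rnorm(nrow(G$entries) * 3), ncol = 3))
  p <- slcr_params(max_iter = 5, tol = 1e-12)
  fit <- slcr(Y, G, A, params = p)
  lam <- default_lambda(nrow(Y), ncol(Y))
  b <- operator_norm(G)^2
  X1 <- X2 <- matrix(0, 64, 3)
  for (k in 1:5) {
    X1 <- x1_update(X1, X2, Y, G, tau = 1, beta1 = b)
    X2 <- x2_update(X1, X2, Y, G, A, lam = lam, tau = 1, beta2 = b)
  }
  expect_equal(fit$X1, X1, tolerance = 1e-10)
  expect_equal(fit$X2, X2, tolerance = 1e-10)
  expect_equal(tail(fit$objective_trace, 1),
               slcr_objective(X1, X2, Y, G, A, lam, 1), tolerance = 1e-10)
})
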