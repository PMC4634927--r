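# Small fixtures shared across test files; everything is built in code.

tiny_grid <- function(n = 16L) image_grid(n, n)

tiny_projector <- function(n = 16L, n_angles = 12L) {
  build_parallel_projector(
    tiny_grid(n),
    sinogram_geometry(n, (0:(n_angles - 1)) * 180 / n_angles))
}

# planted low-rank + spikes instance used by the robust-PCA limit tests
planted_rpca_instance <- function(seed = 7) {
  set.seed(seed)
  u <- 5 + 3 * sin(seq(0, pi, length.out = 20))
  v <- 1 + 0.3 * cos(seq(0, 2 * pi, length.out = 8))
  L <- outer(u, v)
  S <- matrix(0, 20, 8)
  idx <- sample(length(S), 5)
  S[idx] <- sample(c(-1, 1), 5, replace = TRUE) * runif(5, 15, 25)
  list(L = L, S = S, Y = L + S, lambda = 1 / sqrt(20))
}

rel_fro <- function(A, B) sqrt(sum((A - B)^2)) / sqrt(sum(B^2))
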