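test_that("default filter bank satisfies the unit power-complementarity identity", {
  filt <- slcr:::framelet_filters("linear_bspline")
  omega <- seq(0, 2 * pi, length.out = 257)
  total <- Reduce(`+`, lapply(filt, function(h) {
    Hf <- vapply(omega, function(w) sum(h * exp(-1i * w * (0:2))), complex(1))
    Mod(Hf)^2
  }))
  expect_equal(total, rep(1, length(omega)), tolerance = 1e-12)
  # Haar bank too
  filth <- slcr:::framelet_filters("haar")
  totalh <- Reduce(`+`, lapply(filth, function(h) {
    Hf <- vapply(omega, function(w) sum(h * exp(-1i * w * (0:1))), complex(1))
    Mod(Hf)^2
  }))
  expect_equal(totalh, rep(1, length(omega)), tolerance = 1e-12)
})

test_that("constant images live entirely in the low-pass band", {
  g <- image_grid(8, 8)
  A <- build_framelet(g)
  C <- analyze(A, rep(3, 64))
  high <- C[seq_len((A$n_bands - 1L) * A$band_size), 1]
  expect_equal(max(abs(high)), 0, tolerance = 1e-12)
  # adding a constant changes only the low-pass band
  set.seed(5)
  x <- rnorm(64)
  dC <- analyze(A, x + 2) - analyze(A, x)
  expect_equal(max(abs(dC[seq_len((A$n_bands - 1L) * A$band_size), 1])), 0,
               tolerance = 1e-12)
})

test_that("analysis-synthesis round trip is the identity (tight frame)", {
  set.seed(6)
  for (cfg in list(list(g = image_grid(8, 8), lv = 1, fam = "linear_bspline"),
                   list(g = image_grid(16, 16), lv = 2, fam = "linear_bspline"),
                   list(g = image_grid(16, 12), lv = 1, fam = "linear_bspline"),
                   list(g = image_grid(8, 8), lv = 1, fam = "haar"),
                   list(g = image_grid(16, 16), lv = 3, fam = "haar"),
                   list(g = image_grid(16, 12), lv = 2, fam = "linear_bspline",
                        bd = "symmetric"),
                   list(g = image_grid(8, 8), lv = 1, fam = "haar",
                        bd = "symmetric"))) {
    A <- build_framelet(cfg$g, levels = cfg$lv, family = cfg$fam,
                        boundary = if (is.null(cfg$bd)) "periodic" else cfg$bd)
    P <- cfg$g$height * cfg$g$width
    for (i in 1:4) {
      x <- matrix(rnorm(P * 4), P, 4)
      xr <- synthesize(A, analyze(A, x))
      expect_lt(max(abs(xr - x)) / max(abs(x)), 1e-10)
    }
  }
})

test_that("a delta image is reproduced exactly by the round trip", {
  g <- image_grid(16, 16)
  A <- build_framelet(g)
  x <- numeric(256); x[77] <- 1
  expect_equal(synthesize(A, analyze(A, x))[, 1], x, tolerance = 1e-12)
})

test_that("the normalized analysis operator is a linear isometry", {
  g <- image_grid(8, 8)
  A <- build_framelet(g, levels = 2)
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(64)
    expect_equal(sqrt(sum(analyze(A, x)^2)), sqrt(sum(x^2)),
                 tolerance = 1e-10)
  }
  x <- rnorm(64); z <- rnorm(64)
  expect_equal(analyze(A, x + z), analyze(A, x) + analyze(A, z),
               tolerance = 1e-12)
})

test_that("zero maps to zero in both directions", {
  A <- build_framelet(image_grid(8, 8))
  expect_equal(analyze(A, numeric(64)), matrix(0, A$coeff_length, 1))
  expect_equal(synthesize(A, numeric(A$coeff_length)), matrix(0, 64, 1))
})

test_that("identity family passes frames through unchanged", {
  g <- image_grid(4, 5)
  A <- build_framelet(g, family = "identity")
  set.seed(8)
  X <- matrix(rnorm(60), 20, 3)
  expect_identical(analyze(A, X), X)
  expect_identical(synthesize(A, X), X)
})

test_that("bad configurations are rejected", {
  expect_error(build_framelet(image_grid(8, 8), family = "curvelet"))
  expect_error(build_framelet(image_grid(4, 4), levels = 3), "too small")
  A <- build_framelet(image_grid(8, 8))
  expect_error(analyze(A, numeric(10)), "rows")
  expect_error(synthesize(A, numeric(10)), "mismatch")
})
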