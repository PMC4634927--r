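test_that("constant TACs give a rank-1 frame matrix", {
  spec <- phantom_preset("brain", image_grid(32, 32), 6)
  for (l in names(spec$tacs)) spec$tacs[[l]] <- rep(spec$tacs[[l]][1], 6)
  ph <- make_dynamic_phantom(spec)
  expect_true(all(ph$X == ph$X[, 1]))
  expect_equal(qr(ph$X)$rank, 1L)
})

test_that("ground truth splits into a rank<=2 background plus a sparse target", {
  for (preset in c("brain", "thorax")) {
    ph <- make_dynamic_phantom(phantom_preset(preset, image_grid(64, 64), 8))
    expect_equal(ph$X, ph$background + ph$target, tolerance = 1e-12)
    d <- svd(ph$background)$d
    expect_lte(sum(d > d[1] * 1e-10), 2L)
    expect_lt(mean(ph$target != 0), 0.05)
    # target support is confined to the target region masks
    tgt_mask <- Reduce(`|`, ph$rois[setdiff(names(ph$rois), "background")])
    expect_true(all(ph$target[!vec_image(tgt_mask), ] == 0))
  }
})

test_that("a single-pixel pulse target changes only its own pixel across frames", {
  spec <- phantom_preset("brain", image_grid(32, 32), 6)
  # shrink target 3 to a single pixel centered on the half-integer lattice
  spec$regions[[3]]$a <- 0.3
  spec$regions[[3]]$cy <- -4.5
  spec$regions[[3]]$cx <- -3.5
  spec$regions <- spec$regions[1:3]
  spec$target_labels <- 3L
  spec$tacs <- list(`1` = rep(1, 6), `2` = rep(2, 6),
                    `3` = c(1, 5, 1, 1, 1, 1))
  ph <- make_dynamic_phantom(spec)
  D <- ph$X - ph$X[, 1]
  moved <- which(rowSums(abs(D)) > 0)
  expect_equal(length(moved), 1L)
})

test_that("cardiac preset deforms the target boundary across frames", {
  ph <- make_dynamic_phantom(phantom_preset("cardiac", image_grid(64, 64), 8))
  supports <- apply(ph$target != 0, 2, which)
  expect_false(identical(supports[[1]], supports[[3]]))
})

test_that("simulated totals concentrate at the requested count level", {
  ph <- make_dynamic_phantom(phantom_preset("brain", image_grid(32, 32), 4))
  G <- tiny_projector(32, 12)
  total <- 5e5
  sim <- simulate_sinograms(ph$X, G,
                            acquisition_spec(total, 0.1, 0.05, seed = 3))
  expect_true(all(sim$Y >= 0) && all(sim$Y == round(sim$Y)))
  expect_lt(abs(sum(sim$Y) - total), 4 * sqrt(total))
})

test_that("noise vanishes in the high-count limit", {
  ph <- make_dynamic_phantom(phantom_preset("brain", image_grid(32, 32), 4))
  G <- tiny_projector(32, 12)
  sim <- simulate_sinograms(ph$X, G, acquisition_spec(1e7, seed = 4))
  lam <- forward_project(G, ph$X)
  expect_lt(sum(abs(sim$Y / sum(sim$Y) - lam / sum(lam))), 0.01)
})

test_that("the same seed reproduces the sinogram bit for bit", {
  ph <- make_dynamic_phantom(phantom_preset("thorax", image_grid(32, 32), 4))
  G <- tiny_projector(32, 8)
  acq <- acquisition_spec(1e5, 0.2, 0.01, seed = 99)
  s1 <- simulate_sinograms(ph$X, G, acq)
  s2 <- simulate_sinograms(ph$X, G, acq)
  expect_identical(s1$Y, s2$Y)
  s3 <- simulate_sinograms(ph$X, G, acquisition_spec(1e5, 0.2, 0.01, seed = 100))
  expect_false(identical(s1$Y, s3$Y))
})

test_that("contamination raises the uniform background by the stated fraction", {
  ph <- make_dynamic_phantom(phantom_preset("brain", image_grid(32, 32), 4))
  G <- tiny_projector(32, 12)
  total <- 2e6
  sim <- simulate_sinograms(ph$X, G, acquisition_spec(total, 0.3, 0.1, seed = 5))
  expect_equal(sim$contamination,
               total * 0.4 / (nrow(sim$Y) * ncol(sim$Y)))
  # expected true counts carry the remaining 60%
  expect_equal(sim$scale * sum(forward_project(G, ph$X)), total * 0.6,
               tolerance = 1e-9)
})

test_that("invalid specifications are rejected", {
  expect_error(acquisition_spec(0))
  expect_error(acquisition_spec(1e5, 0.6, 0.5))
  ph <- make_dynamic_phantom(phantom_preset("brain", image_grid(32, 32), 4))
  G <- tiny_projector(32, 8)
  Xneg <- ph$X; Xneg[1] <- -1
  expect_error(simulate_sinograms(Xneg, G, acquisition_spec(1e5)), "negative")
  spec <- phantom_preset("brain", image_grid(32, 32), 4)
  spec$tacs$`3` <- spec$tacs$`3` - 10
  expect_error(make_dynamic_phantom(spec), "negative")
})
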