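# slcr — sparse-plus-low-rank constrained reconstruction for dynamic PET

Dynamic PET studies acquire a sequence of short sinogram frames; frame-by-frame
reconstruction wastes the strong correlation between frames and becomes very
noisy at low counts.  This package reconstructs the whole sequence at once by
decomposing the stacked image matrix `X` (pixels × frames) into

* `X1` — a **low-rank stationary background** (tracer distribution that changes
  slowly and coherently over the study), penalized by the nuclear norm, and
* `X2` — a **time-varying component** (focal uptake changes, wall motion),
  sparse under a tight framelet transform `A`, penalized by an l1 norm,

by solving the convex program

```
min  ||X1||_*  +  lambda ||A X2||_1  +  1/(2 tau) ||G (X1 + X2) - Y||_F^2
```

with `G` the system matrix and `Y` the stacked sinograms — robust principal
component analysis put behind a tomographic operator.  The program is solved by
a linearized alternating direction method: one singular-value-thresholding step
on `X1` and one framelet-domain soft-shrinkage step on `X2` per outer
iteration, with relative-change stopping.  The package is aimed at method
developers and students who want a complete, testable desk-scale
implementation: projector, tight frame, solver, classical ML-EM baseline,
dynamic phantom simulator, and the bias / variance / contrast-recovery metrics
used to compare reconstructions.

## Worked example

```r
library(slcr)

grid <- image_grid(64, 64)
geom <- sinogram_geometry(64, seq(0, 179, by = 6))   # 30 angles
G    <- build_parallel_projector(grid, geom)

## brain-like dynamic phantom: two hot lesions on a quasi-stationary background
ph  <- make_dynamic_phantom(phantom_preset("brain", grid, n_frames = 8))
sim <- simulate_sinograms(ph$X, G,
                          acquisition_spec(total_counts = 2e6,
                                           scatter_fraction = 0.0012,
                                           random_fraction = 0.00063,
                                           seed = 1))

fit <- slcr(sim$Y, G, params = slcr_params())
fit
#> Sparse + low-rank dynamic PET reconstruction
#>   4096 pixels x 8 frames; 1000 iterations (iteration cap reached)
#>   lambda = 0.02282, tau = 1, beta1 = 1837, beta2 = 1837
#>   final objective 128043, eps1 6.65e-05, eps2 0.000147

## compare against per-frame ML-EM (100 iterations) in the lesion region
fitm  <- mlem(sim$Y, G, n_iter = 100)
fr    <- 4
truth <- ph$X[, fr]
roi   <- vec_image(ph$rois$target3)
bg    <- vec_image(ph$rois$background)
xs <- (fit$X1[, fr] + fit$X2[, fr]) / sim$scale   # back to activity units
xm <- fitm$X[, fr] / sim$scale
c(bias_slcr = bias(xs, truth, roi),  bias_mlem = bias(xm, truth, roi))
#>   bias_slcr   bias_mlem
#> -0.06917283 -0.04181510
c(var_slcr  = variance(xs, truth, roi), var_mlem = variance(xm, truth, roi))
#>   var_slcr   var_mlem
#> 0.03095911 0.05224032
c(crc_sum   = crc(xs, truth, roi, bg), crc_mlem = crc(xm, truth, roi, bg))
#>   crc_sum  crc_mlem
#> 0.8455299 0.8807666
```

Reading the numbers: both methods recover most of the lesion contrast
(CRC ~0.85–0.88 of the true contrast); the decomposition's estimate is
smoother (40% lower variance of the relative pixel errors) at the cost of a
slightly larger underestimate of the hot lesion (bias −6.9% vs −4.2%), since
the solver stops at its iteration cap here (`eps2` is still above the 1e-4
stopping tolerance — the relative-change rule fires near iteration 2000 on
this problem).  Its real payoff is the decomposition itself: the
time-varying component isolates the lesions from the background
(`plot(fit, frame = 4)`), with higher target contrast than either
reconstruction at this count level.  `fitted(fit)` returns `X1 + X2`,
`residuals(fit)` the sinogram residual, and `summary(fit)` the rank of `X1`
and the active-coefficient fraction of `X2`.  `run_demo()` wraps this whole
pipeline, adding the noise-robustness half of the story: at 10–40x fewer
counts ML-EM's bias and variance degrade faster than the decomposition's.

An equivalent command-line pipeline is installed as `exec/dynpet`:

```sh
dynpet simulate --out run1 --preset brain --counts 2e6 --seed 1
dynpet reconstruct-mlem --run run1
dynpet reconstruct-slcr --run run1
dynpet evaluate --run run1
```

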