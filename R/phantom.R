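# Synthetic dynamic phantoms: piecewise-constant labeled regions, each
# carrying a time-activity curve (TAC).  Background regions share one
# temporal drift profile, so the stacked background matrix has rank <= 2
# (a static level plus a drift direction); the target region's TAC varies
# strongly across frames, so the target component is column-sparse.  This
# planted low-rank + sparse structure is exactly what the SLCR solver
# exploits, which makes parameter-recovery tests meaningful.

shape_mask <- function(kind, grid, cy, cx, a, b = a, inner = 0) {
  yc <- (seq_len(grid$height) - 1) - (grid$height - 1) / 2
  xc <- (seq_len(grid$width) - 1) - (grid$width - 1) / 2
  Y <- matrix(yc, grid$height, grid$width)
  X <- matrix(xc, grid$height, grid$width, byrow = TRUE)
  d2 <- ((Y - cy) / a)^2 + ((X - cx) / b)^2
  switch(kind,
    ellipse = d2 <= 1,
    disk    = d2 <= 1,
    annulus = d2 <= 1 & (((Y - cy)^2 + (X - cx)^2) >= inner^2),
    stop("unknown shape kind"))
}

drift_profile <- function(n_frames) {
  if (n_frames == 1L) return(0)
  seq(0, 1, length.out = n_frames)
}

bump_profile <- function(n_frames) {
  # smooth uptake-washout bump peaking mid-scan, range [0, 1]
  t <- seq(0, 1, length.out = n_frames)
  b <- (t^1.5) * exp(-3 * t)
  b / max(b)
}

#' Dynamic phantom specification presets
#'
#' Three bundled phantom families emulating typical dynamic PET studies
#' on a desk-scale grid:
#' \describe{
#'   \item{`"brain"`}{an elliptical head with a cortical rim, a central
#'     white-matter region (the CRC background), and two small hot
#'     lesions with strongly time-varying uptake (the targets).}
#'   \item{`"thorax"`}{a body ellipse with two lungs and a liver, plus a
#'     small mediastinal target region with time-varying uptake.}
#'   \item{`"cardiac"`}{a myocardial annulus whose inner/outer boundary
#'     deforms from frame to frame (wall motion), around a blood-pool
#'     cavity; the moving wall is the target.}
#' }
#' Background regions follow TACs of the form `a + b * drift(t)` with a
#' shared linear drift (quasi-stationary, stacked rank <= 2); targets
#' follow a strong uptake-washout bump.
#'
#' @param name `"brain"`, `"thorax"`, or `"cardiac"`.
#' @param grid an [image_grid()] (default 64 x 64).
#' @param n_frames number of time frames (default 8).
#' @return an object of class `"phantom_spec"`.
#' @export
phantom_preset <- function(name = c("brain", "thorax", "cardiac"),
                           grid = image_grid(64, 64), n_frames = 8L) {
  name <- match.arg(name)
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("need at least 2 frames for a dynamic study")
  d <- drift_profile(n_frames); bp <- bump_profile(n_frames)
  sc <- min(grid$height, grid$width) / 64   # shapes scale with the grid
  spec <- switch(name,
    brain = list(
      regions = list(
        list(label = 2L, kind = "ellipse", cy = 0, cx = 0, a = 28 * sc, b = 24 * sc),
        list(label = 1L, kind = "ellipse", cy = 0, cx = 0, a = 20 * sc, b = 16 * sc),
        list(label = 3L, kind = "disk", cy = -8 * sc, cx = -7 * sc, a = 3.2 * sc),
        list(label = 4L, kind = "disk", cy = 7 * sc, cx = 8 * sc, a = 3.2 * sc)),
      tacs = list(`1` = 1.0 + 0.05 * d, `2` = 2.0 + 0.12 * d,
                  `3` = 1.0 + 4.0 * bp, `4` = 1.0 + 3.2 * bp),
      background_labels = c(1L, 2L), target_labels = c(3L, 4L),
      crc_background_label = 1L, deform = FALSE),
    thorax = list(
      regions = list(
        list(label = 1L, kind = "ellipse", cy = 0, cx = 0, a = 26 * sc, b = 30 * sc),
        list(label = 2L, kind = "ellipse", cy = -4 * sc, cx = -13 * sc, a = 13 * sc, b = 8 * sc),
        list(label = 2L, kind = "ellipse", cy = -4 * sc, cx = 13 * sc, a = 13 * sc, b = 8 * sc),
        list(label = 3L, kind = "ellipse", cy = 14 * sc, cx = 8 * sc, a = 7 * sc, b = 12 * sc),
        list(label = 4L, kind = "disk", cy = -2 * sc, cx = 0, a = 4 * sc)),
      tacs = list(`1` = 1.0 + 0.05 * d, `2` = 0.4 + 0.03 * d,
                  `3` = 1.6 + 0.06 * d, `4` = 1.2 + 3.5 * bp),
      background_labels = 1:3, target_labels = 4L,
      crc_background_label = 1L, deform = FALSE),
    cardiac = list(
      regions = list(
        list(label = 1L, kind = "ellipse", cy = 0, cx = 0, a = 28 * sc, b = 28 * sc),
        list(label = 2L, kind = "disk", cy = 0, cx = 0, a = 7 * sc)),
      tacs = list(`1` = 0.6 + 0.03 * d, `2` = 0.4 + 0.02 * d,
                  `3` = 2.5 + 1.8 * bp),
      background_labels = c(1L, 2L), target_labels = 3L,
      crc_background_label = 1L, deform = TRUE,
      # myocardial annulus: outer radius oscillates over the cycle
      wall = list(r_out = function(t, Tn) (13 + 1.5 * sin(2 * pi * (t - 1) / Tn)) * sc,
                  thickness = 4.5 * sc)))
  structure(c(list(name = name, grid = grid, n_frames = n_frames), spec),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom spec '%s': %d x %d grid, %d frames, %d region(s)%s\n",
              x$name, x$grid$height, x$grid$width, x$n_frames,
              length(x$regions), if (x$deform) ", deforming target" else ""))
  invisible(x)
}

label_map_for_frame <- function(spec, t) {
  lab <- matrix(0L, spec$grid$height, spec$grid$width)
  for (rg in spec$regions) {
    m <- shape_mask(rg$kind, spec$grid, rg$cy, rg$cx, rg$a, rg$b %||% rg$a,
                    rg$inner %||% 0)
    lab[m] <- rg$label
  }
  if (isTRUE(spec$deform)) {
    ro <- spec$wall$r_out(t, spec$n_frames)
    m <- shape_mask("annulus", spec$grid, 0, 0, ro, ro,
                    inner = ro - spec$wall$thickness)
    lab[m] <- spec$target_labels[1]
  }
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a ground-truth dynamic image sequence
#'
#' Renders the phantom: each pixel takes the value of its region's TAC at
#' each frame.  For non-deforming specs the result decomposes exactly as
#' `X = background + target`, where `background` (pixels carry their
#' underlying background TAC everywhere, including under the targets) has
#' rank at most 2 and `target` (the excess activity of target regions) is
#' column-sparse.  For deforming specs the target support moves from
#' frame to frame.
#'
#' @param spec a `"phantom_spec"` from [phantom_preset()].
#' @return an object of class `"dynamic_phantom"`: `X` (`P x T` ground
#'   truth), `background`, `target` (same shape, `X = background +
#'   target`), `label_map` (frame-1 labels, `height x width`), `rois`
#'   (named list of logical masks: one per target label plus
#'   `"background"`, for metric evaluation), and `spec`.
#' @export
make_dynamic_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  Tn <- spec$n_frames
  P <- spec$grid$height * spec$grid$width
  tac <- function(l, t) {
    v <- spec$tacs[[as.character(l)]]
    if (is.null(v)) 0 else v[t]
  }
  if (any(unlist(spec$tacs) < 0)) stop("negative TAC values")
  X <- Xbg <- matrix(0, P, Tn)
  for (t in seq_len(Tn)) {
    lab <- label_map_for_frame(spec, t)
    vl <- vec_image(lab)
    xt <- xbg <- numeric(P)
    for (l in sort(unique(vl[vl > 0]))) {
      sel <- vl == l
      xt[sel] <- tac(l, t)
      # underlying background value: target pixels sit on top of the
      # innermost background region that contains them
      xbg[sel] <- if (l %in% spec$target_labels)
        tac(underlying_background(spec, l), t) else tac(l, t)
    }
    X[, t] <- xt; Xbg[, t] <- xbg
  }
  lab1 <- label_map_for_frame(spec, 1L)
  rois <- list()
  for (l in spec$target_labels) {
    m <- matrix(FALSE, spec$grid$height, spec$grid$width)
    for (t in seq_len(Tn)) m <- m | (label_map_for_frame(spec, t) == l)
    rois[[paste0("target", l)]] <- m
  }
  rois$background <- lab1 == spec$crc_background_label
  structure(list(X = X, background = Xbg, target = X - Xbg,
                 label_map = lab1, rois = rois, spec = spec),
            class = "dynamic_phantom")
}

underlying_background <- function(spec, target_label) {
  # the background region a target is embedded in; by construction the
  # presets embed every target in the CRC background (or the body) region
  spec$crc_background_label
}

#' @export
print.dynamic_phantom <- function(x, ...) {
  cat(sprintf("dynamic phantom '%s': %d pixels x %d frames\n",
              x$spec$name, nrow(x$X), ncol(x$X)))
  cat(sprintf("  target support %.2f%% of pixel-frames\n",
              100 * mean(x$target != 0)))
  invisible(x)
}

#' Acquisition settings for sinogram simulation
#'
#' @param total_counts expected total number of recorded events summed
#'   over all bins and frames (> 0).
#' @param scatter_fraction,random_fraction fractions of the total expected
#'   counts contributed by scattered resp. random coincidences, each in
#'   `[0, 1)` with sum `< 1`.  Both are modeled as a uniform additive
#'   expected-count background in the sinogram.
#' @param seed integer seed controlling the Poisson draw; all randomness
#'   flows through it.
#' @return an object of class `"acquisition_spec"`.
#' @export
acquisition_spec <- function(total_counts, scatter_fraction = 0,
                             random_fraction = 0, seed = 1L) {
  if (total_counts <= 0) stop("total_counts must be > 0")
  if (scatter_fraction < 0 || random_fraction < 0 ||
      scatter_fraction + random_fraction >= 1)
    stop("contamination fractions must be >= 0 and sum to < 1")
  structure(list(total_counts = total_counts,
                 scatter_fraction = scatter_fraction,
                 random_fraction = random_fraction,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate noisy multi-frame sinograms
#'
#' Forms the noiseless projections `G X`, rescales them so that the
#' expected true-coincidence count equals
#' `total_counts * (1 - scatter_fraction - random_fraction)`, adds a
#' uniform expected-contamination sinogram carrying the remaining
#' fraction, and draws independent Poisson counts per bin per frame.
#' Identical seeds give identical sinograms.
#'
#' @param X nonnegative ground-truth image sequence (`P x T`), e.g. from
#'   [make_dynamic_phantom()].
#' @param G a `"system_matrix"`.
#' @param acq an [acquisition_spec()].
#' @return an object of class `"sinogram_sim"`: `Y` (`D x T` integer
#'   counts), `scale` (the factor by which the true activity was
#'   multiplied before projection — divide reconstructions by it to
#'   compare against `X`), `contamination` (expected uniform counts per
#'   bin), and `acq`.
#' @export
simulate_sinograms <- function(X, G, acq) {
  stopifnot(inherits(G, "system_matrix"), inherits(acq, "acquisition_spec"))
  X <- as_frame_matrix(X, ncol(G$entries), "X")
  if (any(X < 0)) stop("negative activities in X")
  lam_true <- forward_project(G, X)
  total_true <- sum(lam_true)
  if (total_true <= 0) stop("phantom projects to zero counts")
  frac_true <- 1 - acq$scatter_fraction - acq$random_fraction
  scale <- acq$total_counts * frac_true / total_true
  contamination <- acq$total_counts * (acq$scatter_fraction +
                                       acq$random_fraction) / length(lam_true)
  lam <- scale * lam_true + contamination
  Y <- with_seed(acq$seed,
                 matrix(stats::rpois(length(lam), as.vector(lam)),
                        nrow(lam), ncol(lam)))
  structure(list(Y = Y, scale = scale, contamination = contamination,
                 acq = acq, geometry = G$geometry),
            class = "sinogram_sim")
}

#' @export
print.sinogram_sim <- function(x, ...) {
  cat(sprintf(paste0("simulated sinogram: %d bins x %d frames, %g total",
                     " counts (seed %d)\n"),
              nrow(x$Y), ncol(x$Y), sum(x$Y), x$acq$seed))
  invisible(x)
}
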