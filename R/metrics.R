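# Quantitative evaluation of reconstructions against ground truth:
# mean relative error (bias), raw second moment of relative errors
# (variance, exactly as conventionally reported for these studies: no
# mean-centering, so it is not a central variance), and the contrast
# recovery coefficient (CRC).

eval_pixels <- function(xhat, x, mask = NULL) {
  xhat <- as.vector(xhat); x <- as.vector(x)
  if (length(xhat) != length(x)) stop("shape mismatch between xhat and x")
  idx <- if (is.null(mask)) seq_along(x) else which(as.vector(mask))
  zero <- x[idx] == 0
  n_dropped <- sum(zero)
  if (n_dropped > 0) {
    message(sprintf("excluding %d pixel(s) with zero ground truth", n_dropped))
    idx <- idx[!zero]
  }
  if (length(idx) == 0) stop("no evaluable pixels (all ground truth zero)")
  list(rel = (xhat[idx] - x[idx]) / x[idx], n = length(idx),
       n_dropped = n_dropped)
}

#' Reconstruction bias
#'
#' Mean relative pixel error `(1/n) sum_i (xhat_i - x_i) / x_i` over the
#' evaluated pixels.  Pixels with zero ground truth are excluded (relative
#' error undefined there) with a message.  For a sparse-plus-low-rank fit,
#' pass `xhat = X1 + X2` (the component sum is the activity estimate).
#'
#' @param xhat reconstructed image (vector or matrix).
#' @param x ground-truth image, same shape, `> 0` on evaluated pixels.
#' @param mask optional logical mask (or index set) restricting evaluation.
#' @return scalar bias (signed).
#' @export
bias <- function(xhat, x, mask = NULL) {
  e <- eval_pixels(xhat, x, mask)
  mean(e$rel)
}

#' Reconstruction variance
#'
#' `1/(n-1) * sum_i ((xhat_i - x_i)/x_i)^2` — the raw (non-centered)
#' second moment of relative errors divided by `n - 1`, implemented
#' exactly as conventionally reported for this evaluation; note it is not
#' the centered sample variance.
#'
#' @inheritParams bias
#' @return nonnegative scalar.
#' @export
variance <- function(xhat, x, mask = NULL) {
  e <- eval_pixels(xhat, x, mask)
  if (e$n < 2) stop("variance needs at least 2 evaluated pixels")
  sum(e$rel^2) / (e$n - 1)
}

#' Contrast recovery coefficient
#'
#' `CRC = ((S/B)_measured - 1) / ((S/B)_theory - 1)`, where `S` is the
#' mean activity over the region of interest and `B` the mean over the
#' background region, in the reconstruction (measured) and the ground
#' truth (theory).  A perfect reconstruction gives 1; a reconstruction
#' with no contrast (`S = B`) gives 0.  Invariant under global rescaling
#' of the reconstruction.
#'
#' @param recon reconstructed image (vector or matrix).
#' @param truth ground-truth image, same shape.
#' @param roi logical mask (or indices) of the region of interest `S`.
#' @param background logical mask (or indices) of the background region
#'   `B`; must be disjoint from `roi` and have nonzero mean activity.
#' @return scalar CRC.
#' @export
crc <- function(recon, truth, roi, background) {
  recon <- as.vector(recon); truth <- as.vector(truth)
  if (length(recon) != length(truth)) stop("shape mismatch")
  iS <- if (is.logical(roi)) which(as.vector(roi)) else as.integer(roi)
  iB <- if (is.logical(background)) which(as.vector(background)) else
    as.integer(background)
  if (length(iS) == 0 || length(iB) == 0) stop("empty region")
  if (length(intersect(iS, iB)) > 0) stop("roi and background must be disjoint")
  Bm <- mean(recon[iB]); Bt <- mean(truth[iB])
  if (Bm == 0 || Bt == 0) stop("zero background mean")
  contrast_m <- mean(recon[iS]) / Bm - 1
  contrast_t <- mean(truth[iS]) / Bt - 1
  if (contrast_t == 0) stop("unit theoretical contrast: CRC undefined")
  contrast_m / contrast_t
}
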