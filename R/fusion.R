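#' Co-register and normalize modality images
#'
#' All four modalities are computed in one head-centered coordinate frame,
#' so co-registration reduces to (bilinear) resampling onto the common
#' configuration grid; images already on that grid pass through unchanged.
#' Each image is then min-max normalized to [0, 1]; constant images
#' normalize to all-zeros and are flagged (`degenerate` attribute).
#'
#' @param images non-empty list of [intensity_image()]s.
#' @param grid target [make_image_grid()].
#' @return list of [intensity_image()]s on `grid`.
#' @export
coregister_normalize <- function(images, grid = make_image_grid()) {
  if (length(images) == 0) stop("empty image list")
  lapply(images, function(im) {
    v <- if (same_grid(im$grid, grid)) im$values
         else bilinear_resample(im, grid)
    rng <- range(v)
    degen <- (rng[2] - rng[1]) == 0
    v <- if (degen) matrix(0, nrow(v), ncol(v))
         else (v - rng[1]) / (rng[2] - rng[1])
    out <- intensity_image(v, grid, modality = im$modality, normalize = FALSE)
    attr(out, "degenerate") <- degen
    out
  })
}

same_grid <- function(g1, g2) {
  length(g1$x) == length(g2$x) && length(g1$y) == length(g2$y) &&
    max(abs(g1$x - g2$x)) < 1e-12 && max(abs(g1$y - g2$y)) < 1e-12
}

bilinear_resample <- function(im, grid) {
  gx <- im$grid$x; gy <- im$grid$y
  fx <- function(q, g) pmin(pmax(q, g[1]), g[length(g)])
  xq <- fx(grid$x, gx); yq <- fx(grid$y, gy)
  ix <- pmin(pmax(findInterval(xq, gx), 1), length(gx) - 1)
  iy <- pmin(pmax(findInterval(yq, gy), 1), length(gy) - 1)
  tx <- (xq - gx[ix]) / (gx[ix + 1] - gx[ix])
  ty <- (yq - gy[iy]) / (gy[iy + 1] - gy[iy])
  v <- im$values
  out <- matrix(0, length(grid$x), length(grid$y))
  for (j in seq_along(yq)) {
    v1 <- v[cbind(ix, iy[j])] * (1 - tx) + v[cbind(ix + 1, iy[j])] * tx
    v2 <- v[cbind(ix, iy[j] + 1)] * (1 - tx) + v[cbind(ix + 1, iy[j] + 1)] * tx
    out[, j] <- v1 * (1 - ty[j]) + v2 * ty[j]
  }
  out
}

#' Region of agreement across modalities
#'
#' Pixels where at least `min_agree` of the normalized modality images
#' exceed the threshold. If the mask is empty, `min_agree` is decremented
#' until it is non-empty (or 1); the count actually used and whether the
#' fallback fired are reported as attributes `k_used` and `fallback`.
#'
#' @param images normalized images, see [coregister_normalize()].
#' @param tau intensity threshold (default 0.5).
#' @param min_agree required number of agreeing modalities (default 3).
#' @return logical matrix mask.
#' @export
agreement_region <- function(images, tau = 0.5, min_agree = 3L) {
  votes <- Reduce(`+`, lapply(images, function(im) im$values > tau))
  k <- min(min_agree, length(images))
  fallback <- FALSE
  while (k > 1 && !any(votes >= k)) {
    k <- k - 1L
    fallback <- TRUE
  }
  mask <- votes >= k
  attr(mask, "k_used") <- k
  attr(mask, "fallback") <- fallback
  mask
}

#' Smooth, dilate and overlay modalities into the fused heatmap
#'
#' Each modality is Gaussian-smoothed (sigma in pixels), the agreement mask
#' is dilated with a disk brush, and the heatmap is the mean of the
#' smoothed modalities restricted to the dilated mask, renormalized.
#'
#' @param images normalized images.
#' @param mask agreement mask from [agreement_region()].
#' @param grid the common [make_image_grid()].
#' @param sigma_px Gaussian sigma in pixels.
#' @param dilate_px dilation disk radius in pixels.
#' @return list `heatmap` ([intensity_image()], modality `"fused"`) and
#'   `mask_dilated`.
#' @export
smooth_dilate_overlay <- function(images, mask, grid = make_image_grid(),
                                  sigma_px = 2, dilate_px = 2) {
  sm <- lapply(images, function(im) EBImage::gblur(im$values, sigma = sigma_px))
  mean_sm <- Reduce(`+`, sm) / length(sm)
  brush <- EBImage::makeBrush(2 * dilate_px + 1, shape = "disc")
  mdil <- EBImage::dilate(mask * 1, brush) > 0
  v <- mean_sm * mdil
  v[v < 0] <- 0
  list(heatmap = intensity_image(v, grid, modality = "fused"),
       mask_dilated = mdil)
}

#' Fuse classifier-ensemble and DMM decisions
#'
#' The ensemble's fused probability vector (weighted by its certainty) is
#' combined with the DMM decision mapped to a pseudo-probability vector:
#' detected type 0.8 / other stroke 0.1 / healthy 0.1, or healthy 0.8 when
#' nothing was detected. The fused class is the argmax of the weighted
#' mean.
#'
#' @param ensemble an [classify_ensemble()] result.
#' @param dmm_type `"ICH"`, `"IS"` or `"n/a"`.
#' @param dmm_detected logical.
#' @return list `label`, `probs`, `certainty`.
#' @export
fuse_decisions <- function(ensemble, dmm_type, dmm_detected) {
  lv <- c("healthy", "ICH", "IS")
  p_ens <- ensemble$fused[lv]
  p_dmm <- stats::setNames(rep(0.1, 3), lv)
  if (!dmm_detected) {
    p_dmm["healthy"] <- 0.8
  } else if (dmm_type %in% c("ICH", "IS")) {
    p_dmm[dmm_type] <- 0.8
  }
  w <- c(ensemble$certainty, max(p_dmm))
  probs <- (w[1] * p_ens + w[2] * p_dmm) / sum(w)
  probs <- probs / sum(probs)
  list(label = lv[which.max(probs)], probs = probs,
       certainty = max(probs))
}
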