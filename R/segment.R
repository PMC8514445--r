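# Brain-boundary segmentation baseline (Otsu), segmentation-quality metrics
# (area difference, SSIM, PSNR, MSE), adaptive-threshold vessel masking and
# fast-marching vessel inpainting.

#' Otsu threshold segmentation of a brain frame
#'
#' The image is min-max scaled to `[0, 255]`, a 256-bin histogram is built,
#' and the threshold maximizing the between-class variance is selected; the
#' mask (`image > threshold`) is then cleaned with [clean_mask()] (largest
#' connected component, holes filled).
#'
#' @param image 2D numeric matrix with at least two distinct values.
#' @return list with `threshold` (on the original intensity scale) and
#'   `mask` (binary matrix).
#' @export
otsu_segment <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) stop("constant image: Otsu threshold is undefined")
  scaled <- (image - rng[1]) / diff(rng) * 255
  counts <- tabulate(pmin(floor(scaled), 255) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  # between-class variance for threshold "t" = class boundary after bin t
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  t_bin <- levels[which.max(sigma_b)]
  threshold <- rng[1] + t_bin / 255 * diff(rng)
  mask <- clean_mask((image > threshold) * 1L)
  list(threshold = threshold, mask = mask)
}

#' Clean a binary brain mask
#'
#' Keeps the largest connected component and fills enclosed holes.
#' Idempotent; an empty mask is returned unchanged.
#'
#' @param mask binary matrix.
#' @return cleaned binary integer matrix.
#' @export
clean_mask <- function(mask) {
  m <- (mask > 0) * 1
  if (!any(m == 1)) return(matrix(0L, nrow(m), ncol(m)))
  cc <- EBImage::bwlabel(m)
  sizes <- tabulate(cc[cc > 0])
  m <- (cc == which.max(sizes)) * 1
  m <- EBImage::fillHull(m)
  out <- matrix(as.integer(m > 0), nrow(mask), ncol(mask))
  out
}

#' Percent area difference between two masks
#'
#' `100 * |pred XOR truth| / (H * W)`: the fraction of frame pixels on which
#' the two masks disagree, as a percentage.
#'
#' @param pred,truth binary matrices of identical shape.
#' @return scalar percentage.
#' @export
area_difference <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  100 * sum((pred > 0) != (truth > 0)) / length(pred)
}

# Separable Gaussian filtering with replicate (edge-clamped) padding.
gaussian_filter2 <- function(x, sigma, radius = ceiling(3 * sigma)) {
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, radius), seq_len(n), rep(n, radius))
  xp <- x[pad_idx(nrow(x)), , drop = FALSE]
  xr <- apply(xp, 2, function(col) stats::filter(col, k, sides = 2))
  xr <- xr[(radius + 1):(radius + nrow(x)), , drop = FALSE]
  xp <- xr[, pad_idx(ncol(x)), drop = FALSE]
  xc <- t(apply(xp, 1, function(row) stats::filter(row, k, sides = 2)))
  xc[, (radius + 1):(radius + ncol(x)), drop = FALSE]
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM in the standard luminance-contrast-structure form with a
#' Gaussian weighting window.
#'
#' @param a,b numeric matrices of identical shape.
#' @param window window size in pixels (Gaussian support; default 11).
#' @param sigma Gaussian window sd (default 1.5).
#' @param k1,k2 stabilizing constants (defaults 0.01, 0.03).
#' @param dynamic_range intensity dynamic range (default 255).
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b, window = 11, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                 dynamic_range = 255) {
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  stopifnot(dynamic_range > 0)
  radius <- (window - 1) / 2
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  mu_a <- gaussian_filter2(a, sigma, radius)
  mu_b <- gaussian_filter2(b, sigma, radius)
  var_a <- gaussian_filter2(a * a, sigma, radius) - mu_a^2
  var_b <- gaussian_filter2(b * b, sigma, radius) - mu_b^2
  cov_ab <- gaussian_filter2(a * b, sigma, radius) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2)
  mean(num / den)
}

#' Mean squared error and peak signal-to-noise ratio
#'
#' `mse` is the mean squared intensity difference; `psnr` is
#' `10 * log10(max_value^2 / mse)` in dB, `Inf` for identical images.
#'
#' @param a,b numeric matrices of identical shape.
#' @param max_value peak intensity (default 255).
#' @return scalar.
#' @export
mse <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  mean((a - b)^2)
}

#' @rdname mse
#' @export
psnr <- function(a, b, max_value = 255) {
  m <- mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

#' Adaptive-threshold vessel mask
#'
#' Flags pixels darker than their local block mean minus `offset`; blood
#' vessels appear as dark curves on the bright cortex, so this recovers
#' them without a global threshold.
#'
#' @param image 2D numeric matrix.
#' @param block_size odd local-window size in pixels (>= 3).
#' @param offset intensity offset below the local mean required to flag a
#'   pixel.
#' @return binary matrix (1 = vessel).
#' @export
vessel_mask <- function(image, block_size = 15, offset = 10) {
  if (block_size %% 2 == 0 || block_size < 3) {
    stop("block_size must be odd and >= 3")
  }
  local_mu <- box_mean(image, (block_size - 1) / 2)
  (image < local_mu - offset) * 1L
}

# Local mean over a (2r+1)^2 box with replicate padding, via integral image.
box_mean <- function(x, r) {
  n <- nrow(x); m <- ncol(x)
  pad <- function(v, k) c(rep(v[1], k), v, rep(v[length(v)], k))
  xp <- x[pad(seq_len(n), r), pad(seq_len(m), r), drop = FALSE]
  s <- apply(apply(xp, 2, cumsum), 1, cumsum)  # transposed integral image
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  w <- 2 * r + 1
  i0 <- seq_len(n); j0 <- seq_len(m)
  (s[i0 + w, j0 + w, drop = FALSE] - s[i0, j0 + w, drop = FALSE] -
      s[i0 + w, j0, drop = FALSE] + s[i0, j0, drop = FALSE]) / w^2
}

#' Fast-marching inpainting of masked regions
#'
#' Fills hole pixels from the hole boundary inward: pixels are processed in
#' increasing distance-to-known order, each replaced by a normalized
#' weighted average of first-order estimates from already-known pixels
#' within `radius` (each known neighbor contributes its value extrapolated
#' along the local intensity gradient, weighted by inverse squared
#' distance). Pixels outside the hole are never modified.
#'
#' @param image 2D numeric matrix.
#' @param hole_mask binary matrix, 1 where intensities must be
#'   reconstructed.
#' @param radius neighborhood radius in pixels (default 3).
#' @return inpainted matrix.
#' @export
inpaint_fast_marching <- function(image, hole_mask, radius = 3) {
  if (!all(dim(image) == dim(hole_mask))) stop("mask shape differs from image")
  hole <- hole_mask > 0
  if (!any(hole)) return(image)
  if (all(hole)) stop("hole covers the entire image; nothing known to fill from")
  h <- nrow(image); w <- ncol(image)
  dist <- EBImage::distmap((hole) * 1)      # distance to nearest known pixel
  known <- !hole
  out <- image
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2 &
                 !(offs$dr == 0 & offs$dc == 0), ]
  wts <- 1 / (offs$dr^2 + offs$dc^2)
  # one-sided/central intensity gradient using currently known pixels
  grad_at <- function(r, c) {
    g <- c(0, 0)
    for (ax in 1:2) {
      if (ax == 1) { p1 <- c(r - 1, c); p2 <- c(r + 1, c) }
      else { p1 <- c(r, c - 1); p2 <- c(r, c + 1) }
      ok1 <- p1[1] >= 1 && p1[2] >= 1 && p1[1] <= h && p1[2] <= w &&
        known[p1[1], p1[2]]
      ok2 <- p2[1] >= 1 && p2[2] >= 1 && p2[1] <= h && p2[2] <= w &&
        known[p2[1], p2[2]]
      if (ok1 && ok2) {
        g[ax] <- (out[p2[1], p2[2]] - out[p1[1], p1[2]]) / 2
      } else if (ok2) {
        g[ax] <- out[p2[1], p2[2]] - out[r, c]
      } else if (ok1) {
        g[ax] <- out[r, c] - out[p1[1], p1[2]]
      }
    }
    g
  }
  idx <- which(hole)
  ord <- idx[order(dist[idx])]
  coords <- arrayInd(ord, c(h, w))
  for (i in seq_along(ord)) {
    r <- coords[i, 1]; c <- coords[i, 2]
    rr <- r + offs$dr; cc <- c + offs$dc
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    nb <- cbind(rr[ok], cc[ok])
    kn <- known[nb]
    if (any(kn)) {
      ww <- wts[ok][kn]
      nbk <- nb[kn, , drop = FALSE]
      est <- vapply(seq_len(nrow(nbk)), function(j) {
        q <- nbk[j, ]
        g <- grad_at(q[1], q[2])
        out[q[1], q[2]] + g[1] * (r - q[1]) + g[2] * (c - q[2])
      }, numeric(1))
      out[r, c] <- sum(ww * est) / sum(ww)
      known[r, c] <- TRUE
    }
  }
  # isolated deep pixels with no known neighbor in radius get the nearest
  # known value (can only happen for very large holes relative to radius)
  left <- hole & !known
  if (any(left)) {
    ki <- which(known)
    kc <- arrayInd(ki, c(h, w))
    for (p in which(left)) {
      pc <- arrayInd(p, c(h, w))
      d2 <- (kc[, 1] - pc[1])^2 + (kc[, 2] - pc[2])^2
      out[p] <- out[ki[which.min(d2)]]
    }
  }
  out
}

#' Bundle the four segmentation-quality metrics
#'
#' @param pred,truth binary masks (compared on the 0-255 scale for SSIM,
#'   PSNR and MSE, as mask images).
#' @param dynamic_range intensity range of the mask images (default 255).
#' @return list of class `segmentation_quality` with fields
#'   `area_difference` (%), `ssim`, `psnr` (dB) and `mse`.
#' @export
evaluate_segmentation <- function(pred, truth, dynamic_range = 255) {
  a <- (pred > 0) * dynamic_range
  b <- (truth > 0) * dynamic_range
  structure(list(area_difference = area_difference(pred, truth),
                 ssim = ssim(a, b, dynamic_range = dynamic_range),
                 psnr = psnr(a, b, max_value = dynamic_range),
                 mse = mse(a, b)),
            class = "segmentation_quality")
}

#' @export
print.segmentation_quality <- function(x, ...) {
  cat(sprintf(
    "segmentation quality: area diff %.2f%%, SSIM %.3f, PSNR %s dB, MSE %.1f\n",
    x$area_difference, x$ssim,
    if (is.finite(x$psnr)) sprintf("%.2f", x$psnr) else "Inf", x$mse))
  invisible(x)
}

#' Batch segmentation evaluation
#'
#' @param preds,truths lists of masks of equal length.
#' @param dynamic_range see [evaluate_segmentation()].
#' @return data.frame with one row per image plus mean and SEM rows
#'   available via `attr(, "summary")`.
#' @export
evaluate_segmentation_batch <- function(preds, truths, dynamic_range = 255) {
  stopifnot(length(preds) == length(truths))
  rows <- lapply(seq_along(preds), function(i) {
    q <- evaluate_segmentation(preds[[i]], truths[[i]], dynamic_range)
    data.frame(image_id = i, area_diff_pct = q$area_difference,
               ssim = q$ssim, psnr_db = q$psnr, mse = q$mse)
  })
  d <- do.call(rbind, rows)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  attr(d, "summary") <- data.frame(
    metric = c("area_diff_pct", "ssim", "psnr_db", "mse"),
    mean = c(mean(d$area_diff_pct), mean(d$ssim), mean(d$psnr_db), mean(d$mse)),
    sem = c(sem(d$area_diff_pct), sem(d$ssim), sem(d$psnr_db), sem(d$mse)))
  d
}
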