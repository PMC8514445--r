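# Accuracy statistics: landmark distances, midline angle and named-point
# alignment errors, and sensory-centroid-to-ROI distances.

#' Landmark placement errors between two point sets
#'
#' Per-landmark Euclidean distances in mm between matched landmark indices
#' (only indices present in both sets are compared), with mean, SEM and the
#' RMSE aggregate.
#'
#' @param a,b landmark sets: either [landmark_observations()] tables or
#'   matrices of (row, col) points (rows matched by position).
#' @param mm_per_px pixel size in mm (default 1: distances stay in px).
#' @return list of class `landmark_error_report`: `per_landmark`
#'   (data.frame `index, distance`), `mean`, `sem`, `rmse`, `n`.
#' @export
landmark_errors <- function(a, b, mm_per_px = 1) {
  pts <- function(x) {
    if (inherits(x, "landmark_obs") || (is.data.frame(x) && "row" %in% names(x))) {
      list(idx = x$index, p = cbind(x$row, x$col))
    } else {
      p <- rbind_points(x)
      list(idx = seq_len(nrow(p)), p = p)
    }
  }
  pa <- pts(a); pb <- pts(b)
  shared <- intersect(pa$idx, pb$idx)
  if (!length(shared)) stop("no shared landmark indices to compare")
  d <- vapply(shared, function(i) {
    sqrt(sum((pa$p[match(i, pa$idx), ] - pb$p[match(i, pb$idx), ])^2))
  }, numeric(1)) * mm_per_px
  structure(list(per_landmark = data.frame(index = shared, distance = d),
                 mean = mean(d),
                 sem = stats::sd(d) / sqrt(length(d)),
                 rmse = sqrt(mean(d^2)),
                 n = length(d)),
            class = "landmark_error_report")
}

#' @export
print.landmark_error_report <- function(x, ...) {
  cat(sprintf("landmark errors (n = %d): mean %.4f +/- %.4f (SEM), RMSE %.4f\n",
              x$n, x$mean, if (is.na(x$sem)) 0 else x$sem, x$rmse))
  invisible(x)
}

#' Unsigned midline angle error
#'
#' Acute angle, in degrees, between the segment through two registered
#' midline points and the atlas vertical axis.
#'
#' @param p,q (row, col) points on the registered midline (e.g. bregma and
#'   lambda after registration).
#' @return angle in `[0, 90]` degrees.
#' @export
midline_angle_error <- function(p, q) {
  v <- c(q[1] - p[1], q[2] - p[2])
  if (sum(v^2) < 1e-24) stop("midline points coincide")
  # angle to the vertical (column-constant) axis
  ang <- atan2(abs(v[2]), abs(v[1])) * 180 / pi
  min(ang, 180 - ang)
}

#' Alignment error at the two named atlas points
#'
#' Euclidean mm distance between registered and atlas positions of the two
#' points used to score brain-to-atlas alignment: the posterior midline
#' landmark (lambda, standing in for the anterior tip of the interparietal
#' bone) and the anterior midline cross point of the frontal-pole line
#' (the top-center landmark).
#'
#' @param registered 9 x 2 (row, col) registered landmark matrix (or a
#'   [landmark_observations()] table).
#' @param atlas_px 9 x 2 atlas landmark pixel matrix.
#' @param mm_per_px pixel size in mm.
#' @return named numeric vector with `lambda` and `top_center` distances in
#'   mm.
#' @export
alignment_point_error <- function(registered, atlas_px, mm_per_px = 1) {
  if (inherits(registered, "landmark_obs") || is.data.frame(registered)) {
    full <- matrix(NA_real_, 9, 2)
    full[registered$index, ] <- cbind(registered$row, registered$col)
    registered <- full
  }
  registered <- rbind_points(registered)
  d <- function(i) sqrt(sum((registered[i, ] - atlas_px[i, ])^2)) * mm_per_px
  c(lambda = d(6L), top_center = d(4L))
}

#' Distance between a sensory activation centroid and an ROI centroid
#'
#' The ROI centroid is the mean of its mask pixel coordinates; the distance
#' is Euclidean, in mm.
#'
#' @param sensory a `sensory_map` (see [peak_map()]).
#' @param roi a `region_roi`.
#' @param mm_per_px pixel size in mm.
#' @return scalar mm distance.
#' @export
centroid_roi_distance <- function(sensory, roi, mm_per_px = 1) {
  stopifnot(inherits(sensory, "sensory_map"), inherits(roi, "region_roi"))
  sel <- which(roi$pixel_mask, arr.ind = TRUE)
  roi_centroid <- colMeans(sel)
  sqrt(sum((sensory$centroid_px - roi_centroid)^2)) * mm_per_px
}
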