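# Landmark-based registration: observation container, triple selection,
# per-hemisphere atlas-to-brain warping and brain-to-atlas normalization.
#
# Landmark indexing convention (matches the synthetic atlas definitions):
#   1 left lateral extreme, 2 left frontal pole, 3 left posterior RSP tip,
#   4 top-center midline, 5 bregma, 6 lambda,
#   7 right lateral extreme, 8 right frontal pole, 9 right posterior RSP tip.
# The left-hemisphere landmark pool is {1,2,3} plus the shared midline
# landmarks {4,5,6}; the right pool is {7,8,9} plus {4,5,6}.

LEFT_POOL <- c(1L, 2L, 3L, 4L, 5L, 6L)
RIGHT_POOL <- c(4L, 5L, 6L, 7L, 8L, 9L)
DEFAULT_TRIPLE <- list(left = c(1L, 4L, 6L), right = c(7L, 4L, 6L))

#' Landmark observations on a brain image
#'
#' @param index landmark indices (1..9).
#' @param name landmark names.
#' @param px n x 2 matrix of (row, col) pixel positions.
#' @param confidence detector confidences in `[0, 1]`.
#' @return data.frame of class `landmark_obs` with columns
#'   `index,name,row,col,confidence`.
#' @export
landmark_observations <- function(index, name, px, confidence) {
  px <- rbind_points(px)
  stopifnot(all(confidence >= 0), all(confidence <= 1),
            all(index %in% 1:9))
  d <- data.frame(index = as.integer(index), name = as.character(name),
                  row = px[, 1], col = px[, 2],
                  confidence = as.numeric(confidence),
                  stringsAsFactors = FALSE)
  class(d) <- c("landmark_obs", "data.frame")
  d
}

obs_points <- function(obs) cbind(obs$row, obs$col)

usable_obs <- function(obs, min_confidence = 0.5) {
  obs[obs$confidence >= min_confidence, , drop = FALSE]
}

# All 3-subsets of x (n small).
triples_of <- function(x) {
  if (length(x) < 3L) return(list())
  utils::combn(x, 3L, simplify = FALSE)
}

#' Select per-hemisphere landmark triples
#'
#' `mode = "default"` uses the prescribed triples: the lateral extreme of the
#' hemisphere, the top-center midline landmark and lambda; if one of these is
#' unavailable, the fallback is the first three usable indices of the left
#' pool and the last three of the right pool. `mode = "confidence"` picks,
#' per hemisphere, the non-collinear triple with maximal summed confidence
#' (ties resolved in favor of the default triple, then lexicographically).
#' `mode = "user"` passes through user-chosen triples.
#'
#' @param obs a [landmark_observations()] table.
#' @param mode `"default"`, `"confidence"` or `"user"`.
#' @param min_confidence observations below this confidence are unusable.
#' @param user_left,user_right index triples for `mode = "user"`.
#' @param atlas_px 9 x 2 matrix of atlas landmark pixels, used for the
#'   collinearity screen in confidence mode (defaults to the bundled atlas).
#' @return list with `left` and `right` integer index triples; a hemisphere
#'   with fewer than three usable observations gets `NULL`, signalling the
#'   caller to fall back to a two-point or global fit.
#' @export
select_triples <- function(obs, mode = c("default", "confidence", "user"),
                           min_confidence = 0.5,
                           user_left = NULL, user_right = NULL,
                           atlas_px = synthetic_atlas()$landmarks_px) {
  mode <- match.arg(mode)
  use <- usable_obs(obs, min_confidence)
  pick <- function(pool, default_triple, take_last) {
    avail <- sort(intersect(pool, use$index))
    if (length(avail) < 3L) return(NULL)
    if (mode == "user") {
      sel <- if (take_last) user_right else user_left
      if (is.null(sel)) {
        # fallback rule: first three selected on the left, last three on the
        # right
        sel <- if (take_last) utils::tail(avail, 3L) else utils::head(avail, 3L)
      }
      return(as.integer(sel))
    }
    default_ok <- all(default_triple %in% avail)
    if (mode == "default") {
      if (default_ok) return(default_triple)
      return(if (take_last) utils::tail(avail, 3L) else utils::head(avail, 3L))
    }
    cands <- triples_of(avail)
    ok <- vapply(cands, function(tr) {
      !is_collinear(atlas_px[tr, , drop = FALSE])
    }, logical(1))
    cands <- cands[ok]
    if (!length(cands)) return(NULL)
    score <- vapply(cands, function(tr) {
      sum(use$confidence[match(tr, use$index)])
    }, numeric(1))
    best <- which(score > max(score) - 1e-12)
    if (length(best) > 1L && default_ok) {
      is_def <- vapply(cands[best], function(tr) {
        all(sort(tr) == sort(default_triple))
      }, logical(1))
      if (any(is_def)) return(cands[best][[which(is_def)[1]]])
    }
    cands[[best[1]]]
  }
  list(left = pick(LEFT_POOL, DEFAULT_TRIPLE$left, FALSE),
       right = pick(RIGHT_POOL, DEFAULT_TRIPLE$right, TRUE))
}

# Fit one hemisphere's transform. src_of/dst_of give the point in source and
# destination frames for a landmark index. Returns NULL when the hemisphere
# has < 2 usable observations.
fit_hemisphere <- function(idx_pool, use, src_pts, dst_pts, triple) {
  avail <- sort(intersect(idx_pool, use$index))
  if (length(avail) >= 3L && !is.null(triple)) {
    s <- src_pts[triple, , drop = FALSE]
    d <- dst_pts[match(triple, use$index), , drop = FALSE]
    if (!is_collinear(s)) return(fit_affine_three(s, d))
    # degenerate triple: fall through to all available points
  }
  if (length(avail) >= 3L) {
    s <- src_pts[avail, , drop = FALSE]
    d <- dst_pts[match(avail, use$index), , drop = FALSE]
    if (qr(cbind(s, 1))$rank == 3L) return(fit_affine_multi(s, d))
  }
  if (length(avail) >= 2L) {
    pair <- avail[1:2]
    return(fit_similarity_two(src_pts[pair, , drop = FALSE],
                              dst_pts[match(pair, use$index), , drop = FALSE]))
  }
  NULL
}

# Per-hemisphere transforms between atlas landmark pixels and observed
# pixels. direction "atlas_to_brain" maps atlas -> image; "brain_to_atlas"
# maps image -> atlas.
hemisphere_transforms <- function(obs, atlas_px,
                                  direction = c("atlas_to_brain", "brain_to_atlas"),
                                  mode = "default", min_confidence = 0.5,
                                  user_left = NULL, user_right = NULL) {
  direction <- match.arg(direction)
  use <- usable_obs(obs, min_confidence)
  if (nrow(use) < 2L) stop("no usable landmarks (need at least two)")
  trip <- select_triples(obs, mode, min_confidence, user_left, user_right,
                         atlas_px)
  obs_px_full <- function(idx) atlas_px[idx, , drop = FALSE]
  fit_one <- function(pool, triple) {
    src_atlas <- atlas_px                     # indexed by landmark index 1..9
    dst_obs <- obs_points(use)                # indexed by row of `use`
    if (direction == "atlas_to_brain") {
      fit_hemisphere(pool, use, src_atlas, dst_obs, triple)
    } else {
      # swap: source points live on the image, destinations on the atlas
      avail <- sort(intersect(pool, use$index))
      if (length(avail) >= 3L && !is.null(triple)) {
        s <- dst_obs[match(triple, use$index), , drop = FALSE]
        d <- src_atlas[triple, , drop = FALSE]
        if (!is_collinear(s)) return(fit_affine_three(s, d))
      }
      if (length(avail) >= 3L) {
        s <- dst_obs[match(avail, use$index), , drop = FALSE]
        d <- src_atlas[avail, , drop = FALSE]
        if (qr(cbind(s, 1))$rank == 3L) return(fit_affine_multi(s, d))
      }
      if (length(avail) >= 2L) {
        pair <- avail[1:2]
        return(fit_similarity_two(dst_obs[match(pair, use$index), , drop = FALSE],
                                  src_atlas[pair, , drop = FALSE]))
      }
      NULL
    }
  }
  left <- fit_one(LEFT_POOL, trip$left)
  right <- fit_one(RIGHT_POOL, trip$right)
  if (is.null(left) || is.null(right)) {
    # global fallback: one whole-brain transform from every usable point
    pts_img <- obs_points(use)
    pts_atl <- atlas_px[use$index, , drop = FALSE]
    if (direction == "brain_to_atlas") { s <- pts_img; d <- pts_atl }
    else { s <- pts_atl; d <- pts_img }
    glob <- if (nrow(s) >= 3L && qr(cbind(s, 1))$rank == 3L) {
      fit_affine_multi(s, d)
    } else {
      fit_similarity_two(s[1:2, , drop = FALSE], d[1:2, , drop = FALSE])
    }
    if (is.null(left)) left <- glob
    if (is.null(right)) right <- glob
  }
  list(left = left, right = right, triples = trip)
}

# Midline in the image frame: through observed bregma and lambda when both
# are usable, else vertical through bregma, else the warped atlas midline.
brain_midline <- function(obs, maps, atlas_px, min_confidence = 0.5) {
  use <- usable_obs(obs, min_confidence)
  b <- match(5L, use$index); l <- match(6L, use$index)
  if (!is.na(b) && !is.na(l)) {
    p0 <- c(use$row[b], use$col[b])
    v <- c(use$row[l] - use$row[b], use$col[l] - use$col[b])
    if (sum(v^2) > 1e-12) return(list(p0 = p0, v = v / sqrt(sum(v^2))))
  }
  if (!is.na(b)) {
    return(list(p0 = c(use$row[b], use$col[b]), v = c(1, 0)))
  }
  mid <- affine_apply(maps$left, atlas_px[c(5L, 6L), , drop = FALSE])
  v <- mid[2, ] - mid[1, ]
  list(p0 = mid[1, ], v = v / sqrt(sum(v^2)))
}

# Signed side of the midline for points: negative = left hemisphere,
# positive = right. v points from bregma towards lambda (posterior).
midline_side <- function(midline, pts) {
  pts <- rbind_points(pts)
  d <- cbind(pts[, 1] - midline$p0[1], pts[, 2] - midline$p0[2])
  midline$v[1] * d[, 2] - midline$v[2] * d[, 1]
}

#' Warp the reference atlas onto a brain image (atlas-to-brain)
#'
#' The left and right atlas halves are warped by independent transforms
#' fitted per hemisphere from the available landmark observations (three-
#' point affine when a triple is available, two-point similarity when only
#' two landmarks remain, a single whole-brain transform when one hemisphere
#' has none). Each output pixel takes its label from the hemisphere whose
#' side of the image-frame midline it falls on; single-pixel seam gaps are
#' closed by one nearest-region dilation pass, and the result is clipped to
#' the brain mask.
#'
#' @param atlas a [region_atlas()].
#' @param obs a [landmark_observations()] table for the target image.
#' @param defs a [landmark_defs()] table.
#' @param ccs the atlas [coord_system()].
#' @param mask binary brain mask of the target frame.
#' @param mode triple-selection mode, see [select_triples()].
#' @param min_confidence usable-landmark confidence threshold.
#' @return list with `labels` (warped label image), `boundary` (region
#'   outline overlay of the warped labels) and `maps` (per-hemisphere
#'   `affine_map`s).
#' @export
atlas_to_brain <- function(atlas, obs, defs, ccs, mask,
                           mode = "default", min_confidence = 0.5) {
  stopifnot(inherits(atlas, "region_atlas"))
  atlas_px <- atlas_landmark_pixels(atlas, defs, ccs)
  maps <- hemisphere_transforms(obs, atlas_px, "atlas_to_brain",
                                mode, min_confidence)
  h <- nrow(mask); w <- ncol(mask)
  if (all(mask == 0)) {
    return(list(labels = matrix(0L, h, w), boundary = matrix(FALSE, h, w),
                maps = maps))
  }
  midline <- brain_midline(obs, maps, atlas_px, min_confidence)
  grid <- pixel_grid(h, w)
  side <- midline_side(midline, grid)
  labels <- integer(h * w)
  for (hemi in c("left", "right")) {
    sel <- if (hemi == "left") side <= 0 else side > 0
    if (!any(sel)) next
    src <- affine_apply(affine_invert(maps[[hemi]]), grid[sel, , drop = FALSE])
    v <- sample_image(atlas$label_image, src, "nearest")
    # a hemisphere transform may only place its own half of the atlas
    hemi_ids <- atlas$regions$id[atlas$regions$hemisphere %in%
                                   c(hemi, "midline")]
    v[!(v %in% hemi_ids)] <- 0
    labels[sel] <- as.integer(v)
  }
  labels <- matrix(labels, h, w)
  labels <- fill_label_gaps(labels, mask)
  labels[mask == 0] <- 0L
  list(labels = labels, boundary = label_boundaries(labels), maps = maps)
}

# One nearest-neighbor dilation pass restricted to uncovered mask pixels.
fill_label_gaps <- function(labels, mask) {
  gap <- labels == 0L & mask != 0
  if (!any(gap)) return(labels)
  dil <- dilate_once(labels)
  labels[gap] <- dil[gap]
  labels
}

#' Register a brain image into the common atlas frame (brain-to-atlas)
#'
#' Each hemisphere of the masked image is warped independently into the
#' atlas canvas by a transform fitted from that hemisphere's landmarks; the
#' output canvas has the atlas dimensions and each atlas pixel is filled by
#' the hemisphere on its side of the atlas midline. An optional olfactory-
#' bulb mask (tissue anterior to the frontal poles, outside the main cortex
#' outline) is carried along with its hemisphere's transform.
#'
#' @inheritParams atlas_to_brain
#' @param image 2D intensity matrix (same frame as `mask`).
#' @param atlas_dim `(H, W)` of the output canvas (default: atlas size).
#' @param ob_mask optional binary olfactory-bulb mask in the image frame.
#' @param interpolation interpolation for `image` (`"bilinear"` default;
#'   pass `"nearest"` for label input).
#' @return list with `image` (registered image on the atlas canvas), `mask`
#'   (registered brain mask), and `maps`.
#' @export
brain_to_atlas <- function(image, obs, defs, ccs, mask, atlas = NULL,
                           atlas_dim = NULL, ob_mask = NULL,
                           mode = "default", min_confidence = 0.5,
                           interpolation = "bilinear") {
  if (is.null(atlas)) atlas <- synthetic_atlas()$atlas
  if (is.null(atlas_dim)) atlas_dim <- dim(atlas$label_image)
  atlas_px <- atlas_landmark_pixels(atlas, defs, ccs)
  maps <- hemisphere_transforms(obs, atlas_px, "brain_to_atlas",
                                mode, min_confidence)
  midline_img <- brain_midline(obs, maps, atlas_px, min_confidence)
  # split the brain mask into hemispheres in the image frame
  hgrid <- pixel_grid(nrow(mask), ncol(mask))
  img_side <- matrix(midline_side(midline_img, hgrid), nrow(mask), ncol(mask))
  hemi_mask <- list(left = mask * (img_side <= 0), right = mask * (img_side > 0))
  if (!is.null(ob_mask)) {
    hemi_mask$left <- pmax(hemi_mask$left, ob_mask * (img_side <= 0))
    hemi_mask$right <- pmax(hemi_mask$right, ob_mask * (img_side > 0))
  }
  # atlas midline is vertical through the bregma column
  bcol <- atlas_px[5L, 2]
  grid <- pixel_grid(atlas_dim[1], atlas_dim[2])
  out_img <- numeric(atlas_dim[1] * atlas_dim[2])
  out_mask <- numeric(length(out_img))
  for (hemi in c("left", "right")) {
    sel <- if (hemi == "left") grid[, 2] <= bcol else grid[, 2] > bcol
    if (!any(sel)) next
    src <- affine_apply(affine_invert(maps[[hemi]]), grid[sel, , drop = FALSE])
    m <- sample_image(hemi_mask[[hemi]], src, "nearest")
    v <- sample_image(image * (hemi_mask[[hemi]] > 0), src, interpolation)
    out_img[sel] <- v * (m > 0)
    out_mask[sel] <- m > 0
  }
  list(image = matrix(out_img, atlas_dim[1], atlas_dim[2]),
       mask = matrix(as.integer(out_mask > 0), atlas_dim[1], atlas_dim[2]),
       maps = maps)
}

#' Map image-frame points into the atlas frame with fitted hemisphere maps
#'
#' Convenience for scoring a registration: applies the appropriate
#' hemisphere transform (by side of the image-frame midline) to each point.
#'
#' @param pts n x 2 (row, col) points in the image frame.
#' @param obs the observations the maps were fitted from.
#' @param maps result of a `brain_to_atlas` fit (`$maps`).
#' @param atlas_px 9 x 2 atlas landmark pixels.
#' @param min_confidence usable-landmark threshold used in the fit.
#' @return n x 2 matrix of atlas-frame points.
#' @export
register_points <- function(pts, obs, maps, atlas_px, min_confidence = 0.5) {
  pts <- rbind_points(pts)
  midline <- brain_midline(obs, maps, atlas_px, min_confidence)
  side <- midline_side(midline, pts)
  out <- matrix(NA_real_, nrow(pts), 2)
  lsel <- side <= 0
  if (any(lsel)) out[lsel, ] <- affine_apply(maps$left, pts[lsel, , drop = FALSE])
  if (any(!lsel)) out[!lsel, ] <- affine_apply(maps$right, pts[!lsel, , drop = FALSE])
  colnames(out) <- c("row", "col")
  out
}
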