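# Brain-region ROI extraction: label-image dilation, contour tracing, pole
# of inaccessibility (the ROI label anchor), the two labeling methods, and
# JSON / MAT-file export.

#' One denoising dilation pass of a label image
#'
#' Every background pixel whose 3x3 neighborhood contains region pixels is
#' assigned the smallest neighboring region ID (ties between expanding
#' regions go to the lower ID); region pixels are never overwritten.
#'
#' @param label_image 2D integer matrix (0 = background).
#' @return dilated label matrix.
#' @export
dilate_once <- function(label_image) {
  h <- nrow(label_image); w <- ncol(label_image)
  if (!any(label_image > 0)) return(label_image)
  best <- matrix(Inf, h, w)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      shifted <- matrix(Inf, h, w)
      rs <- max(1, 1 + dr):min(h, h + dr)
      cs <- max(1, 1 + dc):min(w, w + dc)
      shifted[rs, cs] <- label_image[rs - dr, cs - dc]
      shifted[shifted == 0] <- Inf
      best <- pmin(best, shifted)
    }
  }
  out <- label_image
  fill <- label_image == 0 & is.finite(best)
  out[fill] <- as.integer(best[fill])
  out
}

#' Extract outer contours of a binary region
#'
#' One polygon per connected component, outer boundary only (holes are
#' ignored), vertices ordered counter-clockwise (positive shoelace area in
#' the (x = col, y = row) plane). Contours run along the 0.5-level between
#' region and background pixel centers, so they enclose exactly the
#' component's pixels.
#'
#' @param binary_region binary matrix.
#' @return list of polygons, each an n x 2 (row, col) matrix.
#' @export
extract_contours <- function(binary_region) {
  m <- (binary_region > 0) * 1
  if (!any(m == 1)) return(list())
  cc <- EBImage::bwlabel(m)
  polys <- list()
  for (id in seq_len(max(cc))) {
    comp <- EBImage::fillHull((cc == id) * 1)   # outer boundary only
    padded <- matrix(0, nrow(m) + 2, ncol(m) + 2)
    padded[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- comp
    cl <- grDevices::contourLines(x = 0:(nrow(m) + 1), y = 0:(ncol(m) + 1),
                                  z = padded, levels = 0.5)
    if (!length(cl)) next
    # a filled component yields exactly one closed contour; keep the longest
    # as a guard
    len <- vapply(cl, function(ctr) length(ctr$x), integer(1))
    ctr <- cl[[which.max(len)]]
    poly <- cbind(row = ctr$x, col = ctr$y)
    # drop the duplicated closing vertex if present
    if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ])) {
      poly <- poly[-nrow(poly), , drop = FALSE]
    }
    if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
    polys[[length(polys) + 1L]] <- poly
  }
  polys
}

# Signed shoelace area in the (x = col, y = row) plane.
polygon_area <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

# Even-odd point-in-polygon test (vectorized over points).
point_in_polygon <- function(poly, pts) {
  pts <- rbind_points(pts)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- ((yi > pts[, 1]) != (yj > pts[, 1])) &
      (pts[, 2] < (xj - xi) * (pts[, 1] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum distance from points to the polygon boundary (segments).
dist_to_boundary <- function(poly, pts) {
  pts <- rbind_points(pts)
  n <- nrow(poly)
  dmin <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (pts[, 1] - (a[1] + t * ab[1]))^2 +
            (pts[, 2] - (a[2] + t * ab[2]))^2
    }
    dmin <- pmin(dmin, sqrt(d2))
  }
  dmin
}

# Signed distance: positive inside the polygon.
signed_distance <- function(poly, pts) {
  d <- dist_to_boundary(poly, pts)
  ifelse(point_in_polygon(poly, pts), d, -d)
}

#' Pole of inaccessibility of a simple polygon
#'
#' The interior point with maximal distance to the polygon boundary, found
#' by iterative grid refinement: square cells over the bounding box are
#' prioritized by their best possible distance
#' (`center distance + half-diagonal`) and subdivided until no cell can beat
#' the current best by more than `precision`.
#'
#' @param polygon n x 2 (row, col) vertex matrix of a simple polygon.
#' @param precision tolerance in pixels on the returned clearance
#'   (default 0.5).
#' @return list with `point` (row, col) and `clearance` (distance to the
#'   boundary).
#' @export
pole_of_inaccessibility <- function(polygon, precision = 0.5) {
  polygon <- rbind_points(polygon)
  stopifnot(precision > 0, nrow(polygon) >= 3L)
  if (abs(polygon_area(polygon)) < 1e-12) {
    stop("degenerate (zero-area) polygon")
  }
  rmin <- min(polygon[, 1]); rmax <- max(polygon[, 1])
  cmin <- min(polygon[, 2]); cmax <- max(polygon[, 2])
  size <- min(rmax - rmin, cmax - cmin)
  cell <- size / 2
  if (cell == 0) stop("degenerate (zero-width) polygon")
  centers <- as.matrix(expand.grid(
    r = seq(rmin + cell, rmax, by = 2 * cell),
    c = seq(cmin + cell, cmax, by = 2 * cell)))
  queue <- data.frame(r = centers[, 1], c = centers[, 2], h = cell)
  queue$d <- signed_distance(polygon, centers)
  # seed with the centroid as a reasonable starting best
  centroid <- colMeans(polygon)
  best <- list(point = centroid, clearance = signed_distance(polygon, centroid))
  repeat {
    if (!nrow(queue)) break
    pot <- queue$d + queue$h * sqrt(2)
    keep <- pot > best$clearance + precision
    queue <- queue[keep, , drop = FALSE]
    if (!nrow(queue)) break
    k <- which.max(queue$d + queue$h * sqrt(2))
    top <- queue[k, ]
    queue <- queue[-k, , drop = FALSE]
    if (top$d > best$clearance) {
      best <- list(point = c(top$r, top$c), clearance = top$d)
    }
    h2 <- top$h / 2
    if (h2 * sqrt(2) < precision / 4 && top$d + top$h * sqrt(2) <=
          best$clearance + precision) next
    kids <- as.matrix(expand.grid(r = top$r + c(-h2, h2),
                                  c = top$c + c(-h2, h2)))
    kd <- signed_distance(polygon, kids)
    queue <- rbind(queue,
                   data.frame(r = kids[, 1], c = kids[, 2], h = h2, d = kd))
  }
  names(best$point) <- c("row", "col")
  best
}

#' Build region ROIs from a warped label image (label-by-ID method)
#'
#' One ROI per region ID present after masking (one per connected component
#' when the mask splits a region), each carrying its outer contour, pole-of-
#' inaccessibility center, and pixel mask.
#'
#' @param warped_labels 2D integer label matrix (atlas warped into the image
#'   frame).
#' @param mask binary brain mask; labels outside it are dropped.
#' @param regions optional atlas region table used to attach acronyms.
#' @param precision pole-of-inaccessibility precision in px.
#' @return list of `region_roi` objects: each a list with `roi_number`,
#'   `region_id`, `acronym`, `contour`, `center`, `clearance`, `pixel_mask`.
#' @export
label_by_id <- function(warped_labels, mask, regions = NULL, precision = 0.5) {
  labs <- warped_labels
  labs[mask == 0] <- 0L
  ids <- setdiff(sort(unique(as.vector(labs))), 0L)
  rois <- list()
  for (id in ids) {
    comp <- EBImage::bwlabel((labs == id) * 1)
    for (k in seq_len(max(comp))) {
      pm <- comp == k
      if (sum(pm) < 3) next                  # too small to carry a contour
      polys <- extract_contours(pm * 1)
      if (!length(polys)) next
      pole <- tryCatch(pole_of_inaccessibility(polys[[1]], precision),
                       error = function(e) NULL)
      if (is.null(pole)) next
      acr <- if (!is.null(regions)) {
        regions$acronym[match(id, regions$id)]
      } else NA_character_
      rois[[length(rois) + 1L]] <- structure(
        list(roi_number = length(rois) + 1L, region_id = as.integer(id),
             acronym = acr, contour = polys[[1]],
             center = pole$point, clearance = pole$clearance,
             pixel_mask = pm),
        class = "region_roi")
    }
  }
  rois
}

#' Renumber ROIs spatially (top-left to bottom-right per hemisphere)
#'
#' Within each hemisphere (ROI center column left/right of `bregma_col`),
#' ROIs are ordered by center column then row; any maximal chain of centers
#' whose columns pairwise differ by less than `alignment_tol` is treated as
#' vertically aligned and re-sorted top to bottom. Numbering starts at 1 in
#' the left hemisphere and continues through the right; it is deterministic
#' and independent of the input order.
#'
#' @param rois list of `region_roi` objects.
#' @param bregma_col column of bregma in the ROI frame.
#' @param alignment_tol column tolerance in px for vertical alignment
#'   (default 5).
#' @return the ROIs, reordered, with `roi_number` rewritten.
#' @export
order_spatial <- function(rois, bregma_col, alignment_tol = 5) {
  if (!length(rois)) return(rois)
  centers <- t(vapply(rois, function(r) r$center, numeric(2)))
  hemi <- ifelse(centers[, 2] < bregma_col, "left", "right")
  order_hemi <- function(ix) {
    if (!length(ix)) return(integer())
    cc <- centers[ix, , drop = FALSE]
    # canonical pre-sort so the result cannot depend on input order
    base <- ix[order(cc[, 2], cc[, 1])]
    cols <- centers[base, 2]
    groups <- cumsum(c(1, diff(cols) >= alignment_tol))
    out <- integer()
    for (g in unique(groups)) {
      members <- base[groups == g]
      out <- c(out, members[order(centers[members, 1], centers[members, 2])])
    }
    out
  }
  perm <- c(order_hemi(which(hemi == "left")),
            order_hemi(which(hemi == "right")))
  out <- rois[perm]
  for (i in seq_along(out)) out[[i]]$roi_number <- i
  out
}

#' Export ROIs to JSON or a MAT-file
#'
#' JSON: a list of `{roi_number, region_id, acronym, center, clearance,
#' contour, mask_dim, mask_pixels}` (mask pixels as 1-based linear indices,
#' so the JSON round-trips losslessly). MAT-file: one uint8 mask array per
#' ROI, named `roi_<n>`.
#'
#' @param rois list of `region_roi` objects.
#' @param path output file.
#' @param format `"json"` or `"matfile"`.
#' @return `path`, invisibly.
#' @export
export_rois <- function(rois, path, format = c("json", "matfile")) {
  format <- match.arg(format)
  if (format == "json") {
    items <- lapply(rois, function(r) {
      list(roi_number = r$roi_number, region_id = r$region_id,
           acronym = r$acronym, center = as.numeric(r$center),
           clearance = r$clearance,
           contour = unname(apply(r$contour, 1, as.numeric, simplify = FALSE)),
           mask_dim = dim(r$pixel_mask), mask_pixels = which(r$pixel_mask))
    })
    jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA)
  } else {
    arrays <- lapply(rois, function(r) {
      m <- r$pixel_mask * 1L
      storage.mode(m) <- "integer"
      m
    })
    names(arrays) <- vapply(rois, function(r) sprintf("roi_%d", r$roi_number),
                            character(1))
    write_mat5(arrays, path)
  }
  invisible(path)
}

#' Read ROIs back from a JSON export
#'
#' @param path JSON file written by [export_rois()].
#' @return list of `region_roi` objects.
#' @export
read_rois_json <- function(path) {
  items <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(items, function(it) {
    md <- unlist(it$mask_dim)
    pm <- matrix(FALSE, md[1], md[2])
    pm[unlist(it$mask_pixels)] <- TRUE
    contour <- do.call(rbind, lapply(it$contour, unlist))
    colnames(contour) <- c("row", "col")
    structure(list(roi_number = it$roi_number,
                   region_id = if (is.null(it$region_id)) NA_integer_ else it$region_id,
                   acronym = if (is.null(it$acronym)) NA_character_ else it$acronym,
                   contour = contour,
                   center = stats::setNames(unlist(it$center), c("row", "col")),
                   clearance = it$clearance, pixel_mask = pm),
              class = "region_roi")
  })
}

#' @export
print.region_roi <- function(x, ...) {
  cat(sprintf("ROI %d: region %s (%s), center (%.1f, %.1f), %d px\n",
              x$roi_number, x$region_id, x$acronym,
              x$center[1], x$center[2], sum(x$pixel_mask)))
  invisible(x)
}
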