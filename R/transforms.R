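# Affine maps, similarity/affine fitting, piecewise-affine maps and dense
# deformation fields. All pixel coordinates are (row, col), 1-based, with the
# pixel center at the integer coordinate; the mm frame used elsewhere is
# converted to this pixel frame before any function here is called.

#' Construct a 2D affine map
#'
#' An affine map acts on points `p = (row, col)` as
#' `p' = m[, 1:2] %*% p + m[, 3]`.
#'
#' @param m numeric 2x3 matrix (linear part in columns 1:2, translation in
#'   column 3).
#' @return an object of class `affine_map`.
#' @export
affine_map <- function(m) {
  m <- as.matrix(m)
  dimnames(m) <- NULL
  if (!is.numeric(m) || !all(dim(m) == c(2L, 3L))) {
    stop("affine map must be a numeric 2x3 matrix")
  }
  if (!all(is.finite(m))) stop("affine map entries must be finite")
  if (abs(det(m[, 1:2])) < 1e-12) {
    stop("affine map is singular (non-invertible linear part)")
  }
  structure(list(m = m), class = "affine_map")
}

#' @export
print.affine_map <- function(x, ...) {
  cat("2D affine map (row,col convention):\n")
  print(x$m)
  invisible(x)
}

#' Identity affine map
#' @return an `affine_map` that leaves every point unchanged.
#' @export
affine_identity <- function() {
  affine_map(cbind(diag(2), c(0, 0)))
}

#' Build a similarity map (rotation + uniform scale + translation)
#'
#' The rotation acts in the (row, col) plane: an offset `(dr, dc)` from
#' `center` maps to `(cos t * dr - sin t * dc, sin t * dr + cos t * dc)`
#' scaled by `scale`, then shifted by `translation`.
#'
#' @param rotation_deg rotation angle in degrees.
#' @param scale uniform scale factor (> 0).
#' @param translation length-2 `(dr, dc)` shift in pixels.
#' @param center length-2 `(row, col)` fixed point of rotation/scaling.
#' @return an `affine_map`.
#' @export
similarity_map <- function(rotation_deg = 0, scale = 1,
                           translation = c(0, 0), center = c(0, 0)) {
  stopifnot(scale > 0)
  t <- rotation_deg * pi / 180
  rot <- matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2L, 2L)
  lin <- scale * rot
  off <- center - lin %*% center + translation
  affine_map(cbind(lin, off))
}

#' Apply an affine map to points
#'
#' @param map an `affine_map`.
#' @param pts n x 2 matrix of (row, col) points (a length-2 vector is treated
#'   as one point).
#' @return n x 2 matrix of mapped points.
#' @export
affine_apply <- function(map, pts) {
  stopifnot(inherits(map, "affine_map"))
  pts <- rbind_points(pts)
  out <- pts %*% t(map$m[, 1:2])
  out[, 1] <- out[, 1] + map$m[1, 3]
  out[, 2] <- out[, 2] + map$m[2, 3]
  colnames(out) <- c("row", "col")
  out
}

rbind_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L, byrow = TRUE)
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 2L)
  storage.mode(pts) <- "double"
  pts
}

#' Compose two affine maps
#'
#' `affine_compose(a, b)` returns the map `p -> a(b(p))`.
#' @param a,b `affine_map` objects.
#' @return an `affine_map`.
#' @export
affine_compose <- function(a, b) {
  stopifnot(inherits(a, "affine_map"), inherits(b, "affine_map"))
  lin <- a$m[, 1:2] %*% b$m[, 1:2]
  off <- a$m[, 1:2] %*% b$m[, 3] + a$m[, 3]
  affine_map(cbind(lin, off))
}

#' Invert an affine map
#' @param a an `affine_map`.
#' @return the inverse `affine_map`.
#' @export
affine_invert <- function(a) {
  stopifnot(inherits(a, "affine_map"))
  lin <- solve(a$m[, 1:2])
  affine_map(cbind(lin, -lin %*% a$m[, 3]))
}

# Twice the signed triangle area; used for collinearity checks.
triangle_area2 <- function(p) {
  (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
    (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])
}

is_collinear <- function(pts, scale_ref = NULL) {
  pts <- rbind_points(pts)
  if (is.null(scale_ref)) {
    scale_ref <- max(1, diff(range(pts[, 1])), diff(range(pts[, 2])))
  }
  abs(triangle_area2(pts)) / 2 < 1e-6 * scale_ref^2
}

#' Fit the exact affine map through three point pairs
#'
#' @param src,dst 3 x 2 matrices of (row, col) points; `src` must be
#'   non-collinear.
#' @return the unique `affine_map` with `map(src[i, ]) == dst[i, ]`.
#' @export
fit_affine_three <- function(src, dst) {
  src <- rbind_points(src); dst <- rbind_points(dst)
  stopifnot(nrow(src) == 3L, nrow(dst) == 3L)
  if (is_collinear(src)) stop("source points are collinear; cannot fit affine")
  a <- cbind(src, 1)
  x <- solve(a, dst)           # 3x2; columns are (row', col') coefficients
  affine_map(t(x)[, c(1, 2, 3)])
}

#' Fit a similarity map (no shear, no reflection) through two point pairs
#'
#' @param src,dst 2 x 2 matrices of (row, col) points; `src` points must be
#'   distinct.
#' @return an `affine_map` whose linear part is rotation times uniform scale.
#' @export
fit_similarity_two <- function(src, dst) {
  src <- rbind_points(src); dst <- rbind_points(dst)
  stopifnot(nrow(src) == 2L, nrow(dst) == 2L)
  zs <- complex(real = src[, 2], imaginary = src[, 1])
  zd <- complex(real = dst[, 2], imaginary = dst[, 1])
  if (abs(zs[2] - zs[1]) < 1e-12) stop("source points coincide")
  a <- (zd[2] - zd[1]) / (zs[2] - zs[1])
  b <- zd[1] - a * zs[1]
  # z = col + i*row, z' = a z + b  =>  row' = Re(a) row + Im(a) col + Im(b)
  lin <- matrix(c(Re(a), -Im(a), Im(a), Re(a)), 2L, 2L)
  affine_map(cbind(lin, c(Im(b), Re(b))))
}

#' Least-squares affine fit through n >= 3 point pairs
#'
#' Minimizes the summed squared residual `sum(|map(src_i) - dst_i|^2)`.
#' For exactly three pairs this reduces to [fit_affine_three()].
#'
#' @param src,dst n x 2 matrices of (row, col) points, n >= 3.
#' @return an `affine_map`.
#' @export
fit_affine_multi <- function(src, dst) {
  src <- rbind_points(src); dst <- rbind_points(dst)
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 3L)
  a <- cbind(src, 1)
  if (qr(a)$rank < 3L) stop("source points are collinear; rank-deficient fit")
  x <- qr.solve(a, dst)
  affine_map(t(x))
}

#' Serialize / deserialize an affine map as JSON
#'
#' The on-disk form is the 2x3 matrix, row-major.
#' @param map an `affine_map`.
#' @param path file path.
#' @return `read_affine_json` returns an `affine_map`.
#' @export
write_affine_json <- function(map, path) {
  stopifnot(inherits(map, "affine_map"))
  jsonlite::write_json(list(matrix = as.vector(t(map$m))), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_map(matrix(as.numeric(x$matrix), 2L, 3L, byrow = TRUE))
}

# ---- image resampling ------------------------------------------------------

# Sample image at fractional (row, col) positions. Positions outside the image
# return `fill`.
sample_image <- function(image, pts, interpolation = c("bilinear", "nearest"),
                         fill = 0) {
  interpolation <- match.arg(interpolation)
  pts <- rbind_points(pts)
  h <- nrow(image); w <- ncol(image)
  r <- pts[, 1]; c <- pts[, 2]
  out <- rep(fill, nrow(pts))
  if (interpolation == "nearest") {
    ri <- round(r); ci <- round(c)
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out[ok] <- image[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(r); c0 <- floor(c)
    fr <- r - r0; fc <- c - c0
    ok <- r0 >= 1 & r0 + 1 <= h & c0 >= 1 & c0 + 1 <= w
    # points exactly on the last row/col still interpolate cleanly
    edge <- (r0 == h & fr == 0 & c0 >= 1 & c0 <= w) |
            (c0 == w & fc == 0 & r0 >= 1 & r0 <= h)
    ok <- ok | (edge & r0 >= 1 & r0 <= h & c0 >= 1 & c0 <= w)
    r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
    i <- which(ok)
    if (length(i)) {
      v00 <- image[cbind(r0[i], c0[i])]
      v01 <- image[cbind(r0[i], c1[i])]
      v10 <- image[cbind(r1[i], c0[i])]
      v11 <- image[cbind(r1[i], c1[i])]
      out[i] <- v00 * (1 - fr[i]) * (1 - fc[i]) + v01 * (1 - fr[i]) * fc[i] +
        v10 * fr[i] * (1 - fc[i]) + v11 * fr[i] * fc[i]
    }
  }
  out
}

pixel_grid <- function(h, w) {
  cbind(rep(seq_len(h), times = w), rep(seq_len(w), each = h))
}

#' Warp an image with an affine map
#'
#' `map` sends source-image coordinates to output coordinates; the output is
#' computed by inverse mapping, so `out(p) = image(map^{-1}(p))`.
#'
#' @param image 2D numeric matrix.
#' @param map `affine_map` from source frame to output frame.
#' @param output_dim `(H, W)` of the output (default: same as `image`).
#' @param interpolation `"bilinear"` (intensities) or `"nearest"` (labels and
#'   masks, which must stay integral).
#' @param fill value for pixels that map outside the source image.
#' @return warped matrix of size `output_dim`.
#' @export
warp_affine <- function(image, map, output_dim = dim(image),
                        interpolation = c("bilinear", "nearest"), fill = 0) {
  interpolation <- match.arg(interpolation)
  inv <- affine_invert(map)
  grid <- pixel_grid(output_dim[1], output_dim[2])
  src <- affine_apply(inv, grid)
  matrix(sample_image(image, src, interpolation, fill),
         output_dim[1], output_dim[2])
}

# ---- piecewise affine ------------------------------------------------------

# Bowyer-Watson Delaunay triangulation; n is small (sensory-peak control
# points), so the O(n^2) insertion loop is fine.
delaunay_triangulate <- function(pts) {
  pts <- rbind_points(pts)
  n <- nrow(pts)
  stopifnot(n >= 3L)
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1)
  mid <- colMeans(pts)
  big <- 20 * span
  verts <- rbind(pts,
                 mid + c(-big, -big), mid + c(big, -big), mid + c(0, big))
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), ncol = 3L)
  circum <- function(tri) {
    p <- verts[tri, , drop = FALSE]
    ax <- p[1, 1]; ay <- p[1, 2]; bx <- p[2, 1]; by <- p[2, 2]
    cx <- p[3, 1]; cy <- p[3, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(c(NA, NA, Inf))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  cc <- list(circum(tris[1, ]))
  for (i in seq_len(n)) {
    p <- verts[i, ]
    bad <- vapply(seq_len(nrow(tris)), function(k) {
      ck <- cc[[k]]
      (p[1] - ck[1])^2 + (p[2] - ck[2])^2 <= ck[3] + 1e-9
    }, logical(1))
    edges <- NULL
    for (k in which(bad)) {
      t <- tris[k, ]
      edges <- rbind(edges, t[c(1, 2)], t[c(2, 3)], t[c(3, 1)])
    }
    keep_edge <- rep(TRUE, NROW(edges))
    if (NROW(edges) > 1) {
      key <- apply(edges, 1, function(e) paste(sort(e), collapse = "-"))
      dup <- key %in% key[duplicated(key)]
      keep_edge <- !dup
    }
    tris <- tris[!bad, , drop = FALSE]
    cc <- cc[!bad]
    for (e in which(keep_edge)) {
      tri <- c(edges[e, ], i)
      tris <- rbind(tris, tri)
      cc <- c(cc, list(circum(tri)))
    }
  }
  keep <- apply(tris, 1, function(t) all(t <= n))
  tris <- tris[keep, , drop = FALSE]
  rownames(tris) <- NULL
  tris
}

#' Fit a piecewise-affine map from control-point pairs
#'
#' The source points are Delaunay-triangulated; each triangle carries the
#' exact affine map onto the corresponding destination triangle, so every
#' control point maps exactly. Points outside the convex hull use the affine
#' of the nearest source triangle.
#'
#' @param src,dst n x 2 matrices (n >= 3, not all collinear) of (row, col)
#'   control points.
#' @return an object of class `piecewise_affine_map`.
#' @export
fit_piecewise_affine <- function(src, dst) {
  src <- rbind_points(src); dst <- rbind_points(dst)
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 3L)
  if (qr(cbind(src, 1))$rank < 3L) stop("control points are collinear")
  tris <- delaunay_triangulate(src)
  if (nrow(tris) == 0L) stop("degenerate control-point configuration")
  maps <- lapply(seq_len(nrow(tris)), function(k) {
    fit_affine_three(src[tris[k, ], ], dst[tris[k, ], ])
  })
  structure(list(src = src, dst = dst, triangles = tris, maps = maps),
            class = "piecewise_affine_map")
}

#' @export
print.piecewise_affine_map <- function(x, ...) {
  cat(sprintf("piecewise-affine map: %d control points, %d triangles\n",
              nrow(x$src), nrow(x$triangles)))
  invisible(x)
}

# Barycentric coordinates of points wrt one triangle.
barycentric <- function(tri, pts) {
  d <- (tri[2, 2] - tri[3, 2]) * (tri[1, 1] - tri[3, 1]) +
       (tri[3, 1] - tri[2, 1]) * (tri[1, 2] - tri[3, 2])
  l1 <- ((tri[2, 2] - tri[3, 2]) * (pts[, 1] - tri[3, 1]) +
         (tri[3, 1] - tri[2, 1]) * (pts[, 2] - tri[3, 2])) / d
  l2 <- ((tri[3, 2] - tri[1, 2]) * (pts[, 1] - tri[3, 1]) +
         (tri[1, 1] - tri[3, 1]) * (pts[, 2] - tri[3, 2])) / d
  cbind(l1, l2, 1 - l1 - l2)
}

#' Apply a piecewise-affine map to points
#'
#' @param map a `piecewise_affine_map`.
#' @param pts n x 2 matrix of (row, col) points.
#' @return mapped n x 2 matrix.
#' @export
piecewise_apply <- function(map, pts) {
  stopifnot(inherits(map, "piecewise_affine_map"))
  pts <- rbind_points(pts)
  n <- nrow(pts)
  out <- matrix(NA_real_, n, 2)
  assigned <- rep(FALSE, n)
  for (k in seq_len(nrow(map$triangles))) {
    tri <- map$src[map$triangles[k, ], , drop = FALSE]
    todo <- which(!assigned)
    if (!length(todo)) break
    b <- barycentric(tri, pts[todo, , drop = FALSE])
    inside <- rowSums(b >= -1e-9) == 3L
    idx <- todo[inside]
    if (length(idx)) {
      out[idx, ] <- affine_apply(map$maps[[k]], pts[idx, , drop = FALSE])
      assigned[idx] <- TRUE
    }
  }
  todo <- which(!assigned)
  if (length(todo)) {
    # extrapolate with the nearest triangle's affine (nearest by centroid)
    cents <- t(vapply(seq_len(nrow(map$triangles)), function(k) {
      colMeans(map$src[map$triangles[k, ], , drop = FALSE])
    }, numeric(2)))
    for (i in todo) {
      d2 <- (cents[, 1] - pts[i, 1])^2 + (cents[, 2] - pts[i, 2])^2
      k <- which.min(d2)
      out[i, ] <- affine_apply(map$maps[[k]], pts[i, , drop = FALSE])
    }
  }
  colnames(out) <- c("row", "col")
  out
}

#' Warp an image with a piecewise-affine map
#'
#' As with [warp_affine()], `map` is the source-to-output map; the output is
#' filled by inverse mapping, using the reverse piecewise-affine map fitted
#' from destination to source control points.
#'
#' @inheritParams warp_affine
#' @param map a `piecewise_affine_map` (source -> output control points).
#' @return warped matrix.
#' @export
warp_piecewise <- function(image, map, output_dim = dim(image),
                           interpolation = c("bilinear", "nearest"),
                           fill = 0) {
  interpolation <- match.arg(interpolation)
  rev_map <- fit_piecewise_affine(map$dst, map$src)
  grid <- pixel_grid(output_dim[1], output_dim[2])
  src <- piecewise_apply(rev_map, grid)
  matrix(sample_image(image, src, interpolation, fill),
         output_dim[1], output_dim[2])
}

# ---- deformation fields ----------------------------------------------------

#' Construct a dense deformation field
#'
#' A deformation field stores per-pixel displacements: warped output at pixel
#' `p` samples the input at `p + field(p)`.
#'
#' @param drow,dcol H x W matrices of row/col displacements in pixels.
#' @return object of class `deformation_field`.
#' @export
deformation_field <- function(drow, dcol) {
  stopifnot(is.matrix(drow), is.matrix(dcol), all(dim(drow) == dim(dcol)))
  structure(list(drow = drow, dcol = dcol), class = "deformation_field")
}

#' Apply a dense deformation field to an image
#'
#' @param field a `deformation_field` whose shape matches `image`.
#' @param image 2D matrix.
#' @param interpolation `"bilinear"` or `"nearest"` (labels use nearest).
#' @param fill fill value for displaced samples outside the image.
#' @return warped matrix, same shape.
#' @export
apply_deformation <- function(field, image,
                              interpolation = c("bilinear", "nearest"),
                              fill = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(field, "deformation_field"))
  if (!all(dim(field$drow) == dim(image))) {
    stop("deformation field shape does not match image")
  }
  h <- nrow(image); w <- ncol(image)
  grid <- pixel_grid(h, w)
  src <- cbind(grid[, 1] + as.vector(field$drow),
               grid[, 2] + as.vector(field$dcol))
  matrix(sample_image(image, src, interpolation, fill), h, w)
}

#' Read / write a deformation field as a two-page TIFF
#'
#' Page 1 holds row displacements, page 2 col displacements, as 32-bit
#' floats encoded on `[0, 1]` with the fixed affine convention
#' `stored = displacement / (2 * max(H, W)) + 0.5` (displacements larger
#' than the image span are not representable and are rejected).
#'
#' @param field a `deformation_field`.
#' @param path file path.
#' @return `read_deformation_tiff` returns a `deformation_field`.
#' @export
write_deformation_tiff <- function(field, path) {
  stopifnot(inherits(field, "deformation_field"))
  s <- 2 * max(dim(field$drow))
  if (max(abs(field$drow), abs(field$dcol)) > s / 2) {
    stop("displacements exceed the image span; not representable")
  }
  tiff::writeTIFF(list(field$drow / s + 0.5, field$dcol / s + 0.5), path,
                  bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_deformation_tiff
#' @export
read_deformation_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2L) stop("deformation TIFF must have exactly 2 pages")
  s <- 2 * max(dim(pages[[1]]))
  deformation_field((pages[[1]] - 0.5) * s, (pages[[2]] - 0.5) * s)
}
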