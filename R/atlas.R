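# Reference parcellation, common bregma-origin coordinate system, and the
# nine-landmark definition table.

#' Common coordinate system of the reference atlas
#'
#' Millimetre coordinates are anchored at bregma: `(0, 0) mm` is the bregma
#' pixel. x is lateral (positive to the animal's right, i.e. increasing
#' column) and y is anterior (positive up, i.e. decreasing row).
#'
#' @param bregma_px length-2 `(row, col)` pixel position of bregma.
#' @param mm_per_px positive scalar, millimetres per pixel.
#' @return object of class `coord_system`.
#' @export
coord_system <- function(bregma_px, mm_per_px) {
  stopifnot(length(bregma_px) == 2L, is.numeric(mm_per_px), mm_per_px > 0)
  structure(list(bregma_px = as.numeric(bregma_px),
                 mm_per_px = as.numeric(mm_per_px),
                 axes = "x lateral-right (+col), y anterior (-row)"),
            class = "coord_system")
}

#' @export
print.coord_system <- function(x, ...) {
  cat(sprintf("bregma-origin coordinate system: bregma at (%.2f, %.2f) px, %.4f mm/px\n",
              x$bregma_px[1], x$bregma_px[2], x$mm_per_px))
  invisible(x)
}

#' Convert between mm (bregma-origin) and pixel coordinates
#'
#' @param ccs a [coord_system()].
#' @param p n x 2 matrix: for `mm_to_px` columns are `(x_mm, y_mm)`; for
#'   `px_to_mm` columns are `(row, col)`.
#' @return n x 2 matrix in the other frame. The two functions are exact
#'   inverses; `(0, 0)` mm maps to `bregma_px`.
#' @export
mm_to_px <- function(ccs, p) {
  stopifnot(inherits(ccs, "coord_system"))
  p <- rbind_points(p)
  out <- cbind(ccs$bregma_px[1] - p[, 2] / ccs$mm_per_px,
               ccs$bregma_px[2] + p[, 1] / ccs$mm_per_px)
  colnames(out) <- c("row", "col")
  out
}

#' @rdname mm_to_px
#' @export
px_to_mm <- function(ccs, p) {
  stopifnot(inherits(ccs, "coord_system"))
  p <- rbind_points(p)
  out <- cbind((p[, 2] - ccs$bregma_px[2]) * ccs$mm_per_px,
               (ccs$bregma_px[1] - p[, 1]) * ccs$mm_per_px)
  colnames(out) <- c("x_mm", "y_mm")
  out
}

# Outline pixels: nonzero where a pixel's 4-neighborhood contains a
# different label.
label_boundaries <- function(label_image) {
  h <- nrow(label_image); w <- ncol(label_image)
  b <- matrix(FALSE, h, w)
  if (h > 1) {
    d <- label_image[-1, ] != label_image[-h, ]
    b[-h, ] <- b[-h, ] | d
    b[-1, ] <- b[-1, ] | d
  }
  if (w > 1) {
    d <- label_image[, -1] != label_image[, -w]
    b[, -w] <- b[, -w] | d
    b[, -1] <- b[, -1] | d
  }
  b & label_image > 0
}

#' Construct a region atlas
#'
#' @param label_image 2D integer matrix; 0 is background, positive values are
#'   region IDs.
#' @param regions data.frame with columns `id`, `acronym`, `name`,
#'   `hemisphere` (`"left"`, `"right"` or `"midline"`). Every ID present in
#'   `label_image` must appear in the table, IDs must be unique, and every
#'   left acronym must have a right counterpart.
#' @return object of class `region_atlas` with fields `label_image`,
#'   `regions` and `boundary_image` (binary outline image).
#' @export
region_atlas <- function(label_image, regions) {
  label_image <- as.matrix(label_image)
  if (any(label_image != round(label_image)) || any(label_image < 0)) {
    stop("label image must contain non-negative integers")
  }
  storage.mode(label_image) <- "integer"
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  needed <- c("id", "acronym", "name", "hemisphere")
  if (!all(needed %in% names(regions))) {
    stop("region table must have columns id, acronym, name, hemisphere")
  }
  if (anyDuplicated(regions$id)) {
    stop("duplicate region IDs in table: ",
         paste(unique(regions$id[duplicated(regions$id)]), collapse = ", "))
  }
  present <- setdiff(sort(unique(as.vector(label_image))), 0L)
  orphans <- setdiff(present, regions$id)
  if (length(orphans)) {
    stop("label image contains IDs missing from the region table: ",
         paste(orphans, collapse = ", "))
  }
  left <- regions$acronym[regions$hemisphere == "left"]
  right <- regions$acronym[regions$hemisphere == "right"]
  unpaired <- setdiff(sub("-L$", "", left), sub("-R$", "", right))
  if (length(unpaired)) {
    stop("left regions without right counterpart: ",
         paste(unpaired, collapse = ", "))
  }
  structure(list(label_image = label_image, regions = regions,
                 boundary_image = label_boundaries(label_image)),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("region atlas: %d x %d px, %d regions\n",
              nrow(x$label_image), ncol(x$label_image), nrow(x$regions)))
  invisible(x)
}

#' Load a region atlas from a label image and a region table
#'
#' @param label_path PNG or single-page TIFF with unsigned-integer pixels
#'   (region IDs; PNG intensities are rescaled back to 8-bit integer IDs).
#' @param table_path CSV with header `id,acronym,name,hemisphere`.
#' @return a [region_atlas()].
#' @export
load_atlas <- function(label_path, table_path) {
  label_image <- read_label_image(label_path)
  regions <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  region_atlas(label_image, regions)
}

#' Landmark definition table
#'
#' The nine-landmark set used for registration, in atlas mm coordinates:
#' left/right lateral extremes, left/right frontal-pole tips, left/right
#' posterior retrosplenial tips, the top (anterior) midline point, bregma and
#' lambda. Bregma is pinned at `(0, 0)` mm and left/right pairs mirror in x.
#'
#' @param index integer 1..9.
#' @param name landmark names.
#' @param x_mm,y_mm atlas-frame mm coordinates (x lateral, y anterior).
#' @param hemisphere_role `"left"`, `"right"` or `"midline"` per landmark.
#' @return data.frame of class `landmark_defs`.
#' @export
landmark_defs <- function(index, name, x_mm, y_mm, hemisphere_role) {
  d <- data.frame(index = as.integer(index), name = name,
                  x_mm = x_mm, y_mm = y_mm,
                  hemisphere_role = hemisphere_role,
                  stringsAsFactors = FALSE)
  if (nrow(d) != 9L) stop("exactly nine landmark definitions are required")
  if (anyDuplicated(d$index)) stop("landmark indices must be unique")
  bi <- which(d$name == "bregma")
  if (length(bi) != 1L || any(abs(c(d$x_mm[bi], d$y_mm[bi])) > 1e-9)) {
    stop("the bregma landmark must sit at (0, 0) mm")
  }
  l <- d[d$hemisphere_role == "left", ]
  r <- d[d$hemisphere_role == "right", ]
  if (nrow(l) != nrow(r)) stop("left/right landmarks must pair up")
  class(d) <- c("landmark_defs", "data.frame")
  d
}

#' Read landmark definitions from CSV
#'
#' CSV header: `index,name,x_mm,y_mm,hemisphere_role`. Users with the
#' published landmark coordinate table can supply it here to override the
#' geometric defaults of the bundled synthetic atlas.
#' @param path CSV path.
#' @return a [landmark_defs()] table.
#' @export
read_landmark_defs <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  landmark_defs(d$index, d$name, d$x_mm, d$y_mm, d$hemisphere_role)
}

#' Pixel positions of the defined landmarks on an atlas
#'
#' @param atlas a [region_atlas()] (bounds check only).
#' @param defs a [landmark_defs()] table.
#' @param ccs the atlas [coord_system()].
#' @return 9 x 2 matrix of (row, col) pixel positions, in definition order.
#' @export
atlas_landmark_pixels <- function(atlas, defs, ccs) {
  stopifnot(inherits(atlas, "region_atlas"), inherits(defs, "landmark_defs"))
  px <- mm_to_px(ccs, cbind(defs$x_mm, defs$y_mm))
  h <- nrow(atlas$label_image); w <- ncol(atlas$label_image)
  bad <- px[, 1] < 1 | px[, 1] > h | px[, 2] < 1 | px[, 2] > w
  if (any(bad)) {
    stop("landmarks outside atlas bounds: ",
         paste(defs$name[bad], collapse = ", "))
  }
  rownames(px) <- defs$name
  px
}

# ---- the bundled synthetic atlas -------------------------------------------

#' The bundled synthetic test atlas
#'
#' A programmatically drawn, exactly mirror-symmetric two-hemisphere
#' parcellation (20 regions, 10 per hemisphere) on a 256 x 256 canvas. The
#' cortex is an ellipse split at the vertical midline (between columns 128
#' and 129); each hemisphere is divided into an anterior motor strip, a
#' somatosensory block, visual and retrosplenial sectors, arranged so the
#' mirrored geometry and landmark set mimic the dorsal-cortex top view used
#' in mesoscale imaging. It stands in for the Allen-derived parcellation so
#' that tests and examples need no external file; a real atlas is loaded
#' with [load_atlas()].
#'
#' @param mm_per_px scale of the synthetic frame (default 0.05 mm/px).
#' @return list with `atlas` ([region_atlas()]), `ccs` ([coord_system()]),
#'   `defs` ([landmark_defs()]) and `landmarks_px` (9 x 2 matrix).
#' @export
synthetic_atlas <- function(mm_per_px = 0.05) {
  h <- 256L; w <- 256L
  cr <- 128.5; cc <- 128.5          # ellipse center
  a <- 100; b <- 78                 # row / col semi-axes
  grid <- pixel_grid(h, w)
  er <- (grid[, 1] - cr) / a
  ec <- (grid[, 2] - cc) / b
  inside <- er^2 + ec^2 <= 1
  lab <- integer(h * w)
  rows <- grid[, 1]; cols <- grid[, 2]
  left <- cols <= 128
  # left-hemisphere parcellation: anterior-posterior bands split medio-lateral
  band <- cut(rows, breaks = c(-Inf, 70, 110, 150, 190, Inf), labels = FALSE)
  med <- abs(cols - cc) <= 39       # medial vs lateral half of the hemisphere
  sector <- (band - 1L) * 2L + ifelse(med, 1L, 2L)   # 1..10
  lab[inside & left] <- sector[inside & left]
  # mirror to the right: right id = left id + 10 at the mirrored column
  m <- matrix(lab, h, w)
  ml <- m[, 1:128]
  m[, 129:256] <- ifelse(ml[, 128:1] > 0L, ml[, 128:1] + 10L, 0L)
  base <- c("MO-a", "MO-l", "SSp-m", "SSp-bfd", "SSp-tr",
            "SSp-ll", "RSP-a", "VIS-l", "RSP-p", "VIS-p")
  regions <- data.frame(
    id = 1:20,
    acronym = c(paste0(base, "-L"), paste0(base, "-R")),
    name = c(paste("left", base), paste("right", base)),
    hemisphere = rep(c("left", "right"), each = 10),
    stringsAsFactors = FALSE)
  atlas <- region_atlas(m, regions)
  ccs <- coord_system(bregma_px = c(140, 128.5), mm_per_px = mm_per_px)
  # geometric landmark positions on this canvas (row, col)
  px <- rbind(
    left_lateral  = c(128.5, 51),
    left_front    = c(48, 96),
    left_rsp_tip  = c(205, 114),
    top_center    = c(40, 128.5),
    bregma        = c(140, 128.5),
    lambda        = c(216, 128.5),
    right_lateral = c(128.5, 206),
    right_front   = c(48, 161),
    right_rsp_tip = c(205, 143))
  mm <- px_to_mm(ccs, px)
  defs <- landmark_defs(
    index = 1:9,
    name = rownames(px),
    x_mm = mm[, 1], y_mm = mm[, 2],
    hemisphere_role = c("left", "left", "left", "midline", "midline",
                        "midline", "right", "right", "right"))
  list(atlas = atlas, ccs = ccs, defs = defs,
       landmarks_px = atlas_landmark_pixels(atlas, defs, ccs))
}
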