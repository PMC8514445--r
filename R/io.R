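# File I/O for images, masks, label images, movies and landmark tables.
# Grayscale images travel as plain numeric matrices (rows = image rows);
# movies as T x H x W arrays.

read_gray <- function(path) {
  x <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}

#' Read / write a grayscale image
#'
#' PNG and TIFF are supported (chosen by file extension). Intensities are
#' written as 16-bit PNG or 32-bit float TIFF after scaling by `max_value`;
#' reading inverts the scaling.
#'
#' @param path file path (`.png` or `.tif`/`.tiff`).
#' @param image numeric matrix.
#' @param max_value intensity corresponding to full scale (default 255).
#' @return `read_image` returns a numeric matrix on the `[0, max_value]`
#'   scale.
#' @export
read_image <- function(path, max_value = 255) {
  read_gray(path) * max_value
}

#' @rdname read_image
#' @export
write_image <- function(image, path, max_value = 255) {
  x <- pmin(pmax(image / max_value, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(x, path)
  } else {
    tiff::writeTIFF(x, path, bits.per.sample = 32L)
  }
  invisible(path)
}

# Integer label images: PNG stores id/255 in 8-bit (<= 255 regions); TIFF
# stores ids directly (read with as.is).
read_label_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) x <- x[, , 1]
    m <- round(x * 255)
  } else {
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1]
  }
  storage.mode(m) <- "integer"
  m
}

write_label_image <- function(labels, path) {
  if (max(labels) > 255) stop("label PNG export supports at most 255 regions")
  png::writePNG(labels / 255, path)
  invisible(path)
}

write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  (x > 0.5) * 1L
}

#' Read / write an activity movie as a multi-page TIFF
#'
#' Frames are stored as 32-bit float pages scaled by `max_value`.
#'
#' @param movie T x H x W numeric array.
#' @param path file path.
#' @param max_value full-scale intensity used for scaling (default 1).
#' @return `read_movie_tiff` returns a T x H x W array.
#' @export
write_movie_tiff <- function(movie, path, max_value = 1) {
  stopifnot(length(dim(movie)) == 3L)
  pages <- lapply(seq_len(dim(movie)[1]), function(t) {
    pmin(pmax(movie[t, , ] / max_value, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, max_value = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]] * max_value
  arr
}

#' Read / write landmark observations as CSV
#'
#' CSV header: `index,name,row,col,confidence`.
#' @param obs a data.frame of landmark observations (see
#'   [landmark_observations()]).
#' @param path CSV path.
#' @return `read_landmarks_csv` returns a landmark-observation data.frame.
#' @export
write_landmarks_csv <- function(obs, path) {
  utils::write.csv(obs[, c("index", "name", "row", "col", "confidence")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  landmark_observations(d$index, d$name, cbind(d$row, d$col), d$confidence)
}
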