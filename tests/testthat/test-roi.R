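# ROI extraction: dilation, contours, pole of inaccessibility, labeling
# methods, spatial numbering and export.

test_that("dilate_once grows regions into background with the lower-ID tie rule", {
  m <- matrix(0L, 9, 9); m[5, 5] <- 3L
  d <- dilate_once(m)
  expect_true(all(d[4:6, 4:6] == 3L))
  expect_equal(sum(d > 0), 9)

  expect_identical(dilate_once(matrix(0L, 4, 4)), matrix(0L, 4, 4))

  # pixel-level oracle on a random label image
  set.seed(51)
  m <- matrix(sample(0:3, 144, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
              12, 12)
  storage.mode(m) <- "integer"
  d <- dilate_once(m)
  for (r in 1:12) for (c in 1:12) {
    if (m[r, c] > 0) {
      expect_identical(d[r, c], m[r, c])  # regions never overwritten
    } else {
      nbr <- c()
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if ((dr | dc) && rr >= 1 && rr <= 12 && cc >= 1 && cc <= 12 &&
              m[rr, cc] > 0) nbr <- c(nbr, m[rr, cc])
      }
      expect_identical(d[r, c], if (length(nbr)) min(nbr) else 0L)
    }
  }
})

test_that("contours enclose exactly the component pixels, outer boundary only", {
  m <- matrix(0L, 20, 20); m[5:14, 4:9] <- 1L
  ct <- extract_contours(m)
  expect_length(ct, 1)
  poly <- ct[[1]]
  expect_equal(range(poly[, 1]), c(4.5, 14.5))
  expect_equal(range(poly[, 2]), c(3.5, 9.5))
  expect_gt(mesomap:::polygon_area(poly), 0)   # counter-clockwise

  m[17:19, 15:18] <- 1L
  expect_length(extract_contours(m), 2)

  donut <- matrix(0L, 15, 15); donut[3:12, 3:12] <- 1L; donut[6:9, 6:9] <- 0L
  ct <- extract_contours(donut)
  expect_length(ct, 1)
  expect_equal(range(ct[[1]][, 1]), c(2.5, 12.5))  # outer boundary only
})

test_that("pole of inaccessibility matches closed forms and the grid oracle", {
  sq <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  p <- pole_of_inaccessibility(sq, 0.01)
  expect_lt(max(abs(p$point - c(0.5, 0.5))), 0.01)
  expect_equal(p$clearance, 0.5, tolerance = 0.01)

  ang <- seq(0, 2 * pi, length.out = 65)[-65]
  circle <- cbind(3 * sin(ang) + 1, 3 * cos(ang) - 2)
  p <- pole_of_inaccessibility(circle, 0.05)
  expect_lt(max(abs(p$point - c(1, -2))), 0.1)
  expect_equal(p$clearance, 3 * cos(pi / 64), tolerance = 0.05)

  lshape <- rbind(c(0, 0), c(4, 0), c(4, 2), c(2, 2), c(2, 4), c(0, 4))
  p <- pole_of_inaccessibility(lshape, 0.01)
  oracle <- grid_pole(lshape, 0.01)
  expect_equal(p$clearance, oracle$clearance, tolerance = 0.02)

  set.seed(52)
  for (i in 1:5) {
    poly <- random_simple_polygon(10)
    p <- pole_of_inaccessibility(poly, 0.05)
    oracle <- grid_pole(poly, 0.02)
    expect_equal(p$clearance, oracle$clearance, tolerance = 0.06)
    expect_true(mesomap:::point_in_polygon(poly, rbind(p$point)))
    # the pole is a maximizer: at least the centroid's clearance
    centroid <- colMeans(poly)
    expect_gte(p$clearance + 1e-9,
               mesomap:::signed_distance(poly, rbind(centroid)))
  }
  expect_error(pole_of_inaccessibility(rbind(c(0, 0), c(1, 1), c(2, 2)), 0.1),
               "degenerate")
})

test_that("label_by_id yields one ROI per visible region component", {
  ref <- ref_atlas
  mask <- (ref$atlas$label_image > 0) * 1L
  rois <- label_by_id(ref$atlas$label_image, mask, ref$atlas$regions)
  expect_equal(sort(unique(vapply(rois, `[[`, integer(1), "region_id"))),
               ref$atlas$regions$id)
  for (r in rois) {
    ctr <- round(r$center)
    expect_true(r$pixel_mask[ctr[1], ctr[2]])
    expect_equal(r$acronym,
                 ref$atlas$regions$acronym[ref$atlas$regions$id == r$region_id])
  }

  # a mask hiding one region removes exactly that ID
  hide <- mask
  hide[ref$atlas$label_image == 7L] <- 0L
  rois2 <- label_by_id(ref$atlas$label_image, hide, ref$atlas$regions)
  expect_false(7L %in% vapply(rois2, `[[`, integer(1), "region_id"))

  # a mask splitting a region in two gives two ROIs sharing the region_id
  lab <- matrix(0L, 20, 20); lab[3:17, 3:17] <- 1L
  split_mask <- matrix(1L, 20, 20); split_mask[, 10:11] <- 0L
  tab <- data.frame(id = 1L, acronym = "Z", name = "z", hemisphere = "midline")
  rois3 <- label_by_id(lab, split_mask, tab)
  expect_length(rois3, 2)
  expect_equal(vapply(rois3, `[[`, integer(1), "region_id"), c(1L, 1L))
})

test_that("spatial numbering follows the column-chain rule and ignores input order", {
  mk <- function(center, id) {
    structure(list(roi_number = id, region_id = id, acronym = "x",
                   contour = rbind(center + c(-1, -1), center + c(-1, 1),
                                   center + c(1, 1), center + c(1, -1)),
                   center = center, clearance = 1,
                   pixel_mask = matrix(TRUE, 1, 1)),
              class = "region_roi")
  }
  # same column: top first
  rois <- list(mk(c(30, 20), 1L), mk(c(10, 20), 2L))
  ord <- order_spatial(rois, bregma_col = 100)
  expect_equal(vapply(ord, function(r) r$center[1], numeric(1)), c(10, 30))

  # columns 20 and 24 (delta < 5): treated as aligned, sorted by row
  rois <- list(mk(c(10, 24), 1L), mk(c(40, 20), 2L))
  ord <- order_spatial(rois, 100)
  expect_equal(vapply(ord, function(r) r$center[2], numeric(1)), c(24, 20))

  # chained alignment: cols 20, 24, 28 form one group
  rois <- list(mk(c(30, 24), 1L), mk(c(10, 28), 2L), mk(c(50, 20), 3L))
  ord <- order_spatial(rois, 100)
  expect_equal(vapply(ord, function(r) r$center[1], numeric(1)), c(10, 30, 50))

  # hemisphere split + permutation invariance
  set.seed(53)
  rois <- lapply(1:12, function(i) {
    mk(c(runif(1, 1, 100), runif(1, 1, 200)), as.integer(i))
  })
  ord1 <- order_spatial(rois, 100)
  for (perm in 1:5) {
    ord2 <- order_spatial(sample(rois), 100)
    expect_equal(lapply(ord2, `[[`, "center"), lapply(ord1, `[[`, "center"))
  }
  left_n <- sum(vapply(ord1, function(r) r$center[2] < 100, logical(1)))
  firsts <- vapply(ord1[seq_len(left_n)], function(r) r$center[2], numeric(1))
  expect_true(all(firsts < 100))   # left hemisphere numbered first
})

test_that("ROI export round-trips through JSON and MAT", {
  lab <- matrix(0L, 16, 16); lab[2:7, 3:9] <- 1L; lab[10:14, 5:12] <- 2L
  tab <- data.frame(id = 1:2, acronym = c("A", "B"), name = c("a", "b"),
                    hemisphere = c("left", "right"))
  rois <- label_by_id(lab, matrix(1L, 16, 16), tab)
  jp <- withr::local_tempfile(fileext = ".json")
  export_rois(rois, jp, "json")
  back <- read_rois_json(jp)
  expect_length(back, length(rois))
  for (i in seq_along(rois)) {
    expect_equal(back[[i]]$roi_number, rois[[i]]$roi_number)
    expect_equal(back[[i]]$region_id, rois[[i]]$region_id)
    expect_equal(unname(back[[i]]$center), unname(rois[[i]]$center))
    expect_equal(back[[i]]$pixel_mask, rois[[i]]$pixel_mask)
    expect_equal(unname(back[[i]]$contour), unname(rois[[i]]$contour))
  }
  # empty set stays a valid container
  ep <- withr::local_tempfile(fileext = ".json")
  export_rois(list(), ep, "json")
  expect_length(read_rois_json(ep), 0)

  mp <- withr::local_tempfile(fileext = ".mat")
  export_rois(rois, mp, "matfile")
  mats <- read_mat5(mp)
  expect_equal(names(mats), c("roi_1", "roi_2"))
  for (i in 1:2) {
    expect_identical(mats[[sprintf("roi_%d", i)]] > 0, rois[[i]]$pixel_mask)
  }
})
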