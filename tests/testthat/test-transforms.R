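# Affine / similarity / piecewise-affine fitting and warping.

test_that("three-point affine fit is exact and rejects degenerate input", {
  src <- rbind(c(0, 0), c(0, 1), c(1, 0))
  expect_equal(fit_affine_three(src, src)$m, cbind(diag(2), c(0, 0)))

  # 90 degree rotation about the origin in the (row, col) plane:
  # (r, c) -> (-c, r)
  dst <- cbind(-src[, 2], src[, 1])
  m <- fit_affine_three(src, dst)$m
  expect_equal(m, cbind(matrix(c(0, 1, -1, 0), 2, 2), c(0, 0)),
               tolerance = 1e-12)

  set.seed(11)
  for (i in 1:20) {
    s <- matrix(rnorm(6, sd = 50), 3, 2)
    if (mesomap:::is_collinear(s)) next
    d <- matrix(rnorm(6, sd = 50), 3, 2)
    # independent oracle: solve the stacked 6x6 linear system directly
    a6 <- matrix(0, 6, 6)
    for (k in 1:3) {
      a6[2 * k - 1, 1:3] <- c(s[k, ], 1)
      a6[2 * k, 4:6] <- c(s[k, ], 1)
    }
    coefs <- solve(a6, as.vector(t(d)))
    m_oracle <- rbind(coefs[1:3], coefs[4:6])
    fit <- fit_affine_three(s, d)
    expect_equal(fit$m, m_oracle, tolerance = 1e-6)
    expect_points_equal(affine_apply(fit, s), d, 1e-9)
  }
  expect_error(fit_affine_three(rbind(c(0, 0), c(1, 1), c(2, 2)), src),
               "collinear")
})

test_that("two-point similarity fit has uniform scale and no reflection", {
  f <- fit_similarity_two(rbind(c(0, 0), c(0, 1)), rbind(c(0, 0), c(0, 2)))
  expect_equal(f$m[, 1:2], 2 * diag(2), tolerance = 1e-12)

  # (0,0),(0,1) -> (0,0),(1,0): quarter-turn, scale 1
  f <- fit_similarity_two(rbind(c(0, 0), c(0, 1)), rbind(c(0, 0), c(1, 0)))
  sv <- svd(f$m[, 1:2])$d
  expect_equal(sv, c(1, 1), tolerance = 1e-12)

  set.seed(12)
  for (i in 1:100) {
    s <- matrix(rnorm(4, sd = 20), 2, 2)
    d <- matrix(rnorm(4, sd = 20), 2, 2)
    f <- fit_similarity_two(s, d)
    expect_points_equal(affine_apply(f, s), d, 1e-8)
    sv <- svd(f$m[, 1:2])$d
    expect_lt(abs(sv[1] - sv[2]), 1e-9 * max(sv))      # uniform scale
    expect_gt(det(f$m[, 1:2]), 0)                      # no reflection
  }
  expect_error(fit_similarity_two(rbind(c(1, 1), c(1, 1)),
                                  rbind(c(0, 0), c(1, 1))), "coincide")
})

test_that("multi-point affine fit is least squares and matches the 3-point fit", {
  set.seed(13)
  truth <- affine_map(cbind(matrix(c(1.2, 0.3, -0.2, 0.9), 2, 2), c(5, -3)))
  src <- matrix(rnorm(16, sd = 30), 8, 2)
  dst <- affine_apply(truth, src)
  fit <- fit_affine_multi(src, dst)
  expect_equal(fit$m, truth$m, tolerance = 1e-9)

  s3 <- src[1:3, ]; d3 <- dst[1:3, ] + matrix(rnorm(6), 3, 2)
  expect_equal(fit_affine_multi(s3, d3)$m, fit_affine_three(s3, d3)$m,
               tolerance = 1e-9)

  # randomized optimality: no perturbed affine does better on noisy data
  dn <- dst + matrix(rnorm(16, sd = 2), 8, 2)
  fit <- fit_affine_multi(src, dn)
  resid <- sum((affine_apply(fit, src) - dn)^2)
  for (i in 1:1000) {
    cand <- affine_map(fit$m + matrix(rnorm(6, sd = 0.01), 2, 3))
    expect_gte(sum((affine_apply(cand, src) - dn)^2), resid - 1e-9)
  }
  expect_error(fit_affine_multi(cbind(1:4, 1:4), cbind(1:4, 2 * (1:4))),
               "collinear")
})

test_that("affine fits are equivariant under rigid conjugation", {
  set.seed(14)
  rig <- similarity_map(rotation_deg = 33, scale = 1, translation = c(4, -7))
  src <- matrix(rnorm(10, sd = 20), 5, 2)
  dst <- matrix(rnorm(10, sd = 20), 5, 2)
  f <- fit_affine_multi(src, dst)
  g <- fit_affine_multi(affine_apply(rig, src), affine_apply(rig, dst))
  conj <- affine_compose(rig, affine_compose(f, affine_invert(rig)))
  expect_equal(g$m, conj$m, tolerance = 1e-8)
})

test_that("compose and invert follow matrix algebra", {
  a <- similarity_map(25, 1.3, c(3, 4))
  b <- affine_map(cbind(matrix(c(0.9, -0.2, 0.1, 1.1), 2, 2), c(-2, 6)))
  ident <- affine_compose(a, affine_invert(a))
  expect_equal(ident$m, affine_identity()$m, tolerance = 1e-9)
  expect_equal(affine_compose(affine_identity(), a)$m, a$m)
  # invert(rotation theta) = rotation -theta
  expect_equal(affine_invert(similarity_map(40))$m, similarity_map(-40)$m,
               tolerance = 1e-12)
  # direct matrix product oracle
  m3 <- rbind(a$m, c(0, 0, 1)) %*% rbind(b$m, c(0, 0, 1))
  expect_equal(affine_compose(a, b)$m, m3[1:2, ], tolerance = 1e-12)
})

test_that("piecewise-affine map is exact at control points and per-triangle affine", {
  src <- rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0))
  pw <- fit_piecewise_affine(src, src)
  probe <- rbind(c(2, 3), c(7, 8), c(5, 5))
  expect_points_equal(piecewise_apply(pw, probe), probe, 1e-9)

  # three pairs: equals the single affine everywhere inside the triangle
  s3 <- rbind(c(0, 0), c(0, 8), c(8, 0))
  d3 <- rbind(c(1, 1), c(0, 10), c(9, -1))
  pw3 <- fit_piecewise_affine(s3, d3)
  f3 <- fit_affine_three(s3, d3)
  inner <- rbind(c(1, 1), c(2, 4), c(5, 1))
  expect_points_equal(piecewise_apply(pw3, inner), affine_apply(f3, inner),
                      1e-9)

  # square with one displaced corner: probe each triangle against the
  # independently fitted per-triangle affine
  dst <- src; dst[3, ] <- c(13, 12)
  pw <- fit_piecewise_affine(src, dst)
  expect_points_equal(piecewise_apply(pw, src), dst, 1e-9)
  for (k in seq_len(nrow(pw$triangles))) {
    tri <- pw$triangles[k, ]
    centroid <- colMeans(src[tri, ])
    oracle <- fit_affine_three(src[tri, ], dst[tri, ])
    expect_points_equal(piecewise_apply(pw, centroid),
                        affine_apply(oracle, centroid), 1e-9)
  }
  expect_error(fit_piecewise_affine(cbind(0:3, 0:3), cbind(0:3, 0:3)),
               "collinear")
})

test_that("deformation fields reproduce shifts and affine warps", {
  img <- matrix(runif(30 * 30), 30, 30)
  zf <- deformation_field(matrix(0, 30, 30), matrix(0, 30, 30))
  expect_equal(apply_deformation(zf, img), img)

  # constant field (5, 0): out(p) = in(p + 5 rows) = image shifted up;
  # equivalently the content moves 5 rows towards lower indices
  cf <- deformation_field(matrix(5, 30, 30), matrix(0, 30, 30))
  out <- apply_deformation(cf, img)
  expect_equal(out[1:25, ], img[6:30, ])
  expect_true(all(out[26:30, ] == 0))

  # a field sampled from an affine map reproduces the affine warp
  lab <- matrix(0L, 40, 40); lab[10:20, 8:30] <- 1L; lab[25:35, 15:25] <- 2L
  map <- similarity_map(10, 1.05, c(2, -1), center = c(20, 20))
  inv <- affine_invert(map)
  grid <- mesomap:::pixel_grid(40, 40)
  srcpts <- affine_apply(inv, grid)
  field <- deformation_field(matrix(srcpts[, 1] - grid[, 1], 40, 40),
                             matrix(srcpts[, 2] - grid[, 2], 40, 40))
  via_field <- apply_deformation(field, lab, "nearest")
  via_affine <- warp_affine(lab, map, interpolation = "nearest")
  expect_lt(mean(via_field != via_affine), 0.01)
  expect_error(apply_deformation(zf, matrix(0, 10, 10)), "shape")
})

test_that("deformation-field TIFF round-trips including negative displacements", {
  f <- deformation_field(matrix(-2.5, 8, 8), matrix(1.25, 8, 8))
  path <- withr::local_tempfile(fileext = ".tif")
  write_deformation_tiff(f, path)
  f2 <- read_deformation_tiff(path)
  expect_lt(max(abs(f2$drow - f$drow)), 1e-4)
  expect_lt(max(abs(f2$dcol - f$dcol)), 1e-4)
})
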