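# Shared fixtures: the bundled atlas (computed once), small canonical
# phantoms, and small random-geometry helpers.

ref_atlas <- synthetic_atlas()

canonical_phantom <- function(size = 256L, noise_sigma = 0, vessel_count = 0L,
                              seed = 1L) {
  s <- size / 256
  make_phantom(phantom_spec(image_size = c(size, size),
                            semi_axes = c(100, 78) * s,
                            noise_sigma = noise_sigma,
                            vessel_count = vessel_count, seed = seed))
}

small_phantom <- function(...) canonical_phantom(size = 64L, ...)

# random simple (star-shaped) polygon around the origin
random_simple_polygon <- function(n = 8, r_range = c(2, 6)) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  rad <- stats::runif(n, r_range[1], r_range[2])
  cbind(rad * sin(ang), rad * cos(ang))
}

# dense-grid brute-force pole of inaccessibility (independent oracle)
grid_pole <- function(poly, step = 0.01) {
  rs <- seq(min(poly[, 1]), max(poly[, 1]), by = step)
  cs <- seq(min(poly[, 2]), max(poly[, 2]), by = step)
  pts <- as.matrix(expand.grid(rs, cs))
  inside <- mesomap:::point_in_polygon(poly, pts)
  pts <- pts[inside, , drop = FALSE]
  d <- mesomap:::dist_to_boundary(poly, pts)
  list(point = pts[which.max(d), ], clearance = max(d))
}

expect_points_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
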