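# Convolutional NMF, motif images, templates, matching and MBFMs.

test_that("convnmf handles degenerate input and keeps factors nonnegative", {
  X0 <- matrix(0, 20, 30)
  ms <- convnmf(X0, K = 2, L = 3, n_iter = 5)
  expect_true(all(ms$W == 0))
  expect_true(all(ms$H == 0))
  expect_equal(mesomap:::convnmf_reconstruct(ms$W, ms$H), X0)

  set.seed(71)
  X <- matrix(runif(20 * 40), 20, 40)
  ms <- convnmf(X, K = 2, L = 4, n_iter = 30)
  expect_true(all(ms$W >= 0))
  expect_true(all(ms$H >= 0))
  expect_warning(convnmf(X - 0.5, K = 1, L = 2, n_iter = 2), "clipped")
  expect_error(convnmf(matrix(c(1, NA), 2, 2), 1, 1), "finite")
})

test_that("convnmf objective is non-increasing and recovers a planted motif", {
  sc <- small_phantom()
  sim <- motif_sim_spec(n_motifs = 1, motif_len = 5, movie_len = 200,
                        occurrences = 10, footprints = list(c(1, 11)),
                        noise_sigma = 0, seed = 2)
  act <- simulate_activity(sc, sim)
  X <- movie_to_matrix(act$movie, sc$true_mask)
  ms <- convnmf(X, K = 1, L = 5, n_iter = 100, seed = 1)
  expect_lt(convnmf_error(ms, X), 0.05)
  d <- diff(ms$objective)
  expect_true(all(d <= 1e-6 * pmax(abs(ms$objective[-length(ms$objective)]), 1)))
  # determinism
  ms2 <- convnmf(X, K = 1, L = 5, n_iter = 100, seed = 1)
  expect_identical(ms$W, ms2$W)
})

test_that("the cross-orthogonality penalty shrinks redundant motifs", {
  sc <- small_phantom()
  sim <- motif_sim_spec(n_motifs = 1, motif_len = 4, movie_len = 150,
                        occurrences = 8, footprints = list(c(4, 14)),
                        noise_sigma = 0, seed = 3)
  act <- simulate_activity(sc, sim)
  X <- movie_to_matrix(act$movie, sc$true_mask)
  # with K=2 > true K=1 and a penalty, the energy concentrates in one motif
  ms <- convnmf(X, K = 2, L = 4, lambda = 0.1, n_iter = 150, seed = 1)
  energy <- vapply(1:2, function(k) sum(ms$W[, k, ]^2 %o% 1) *
                     sum(ms$H[k, ]^2), numeric(1))
  expect_gt(max(energy) / max(sum(energy), 1e-12), 0.9)
})

test_that("motif images are masked, max-projected and normalized", {
  mask <- matrix(0L, 6, 6); mask[2:5, 2:5] <- 1L
  mot <- array(0, c(3, 6, 6))
  mot[1, 3, 3] <- 2; mot[3, 4, 5] <- 1; mot[2, 1, 1] <- 5   # outside mask
  img <- motif_image(mot, mask)
  expect_equal(max(img), 1)
  expect_equal(img[3, 3], 1)
  expect_equal(img[1, 1], 0)
  # pointwise max oracle inside the mask (before normalization, up to scale)
  raw <- apply(mot, c(2, 3), max); raw[mask == 0] <- 0
  expect_equal(img, (raw - min(raw)) / (max(raw) - min(raw)) * (mask > 0))

  single <- array(c(0.2, 0.8), c(1, 1, 2))
  got <- motif_image(array(single, c(1, 2, 1)), matrix(1L, 2, 1))
  expect_equal(as.vector(got), c(0, 1))

  zero <- motif_image(array(0, c(2, 4, 4)), matrix(1L, 4, 4))
  expect_true(all(zero == 0))
})

test_that("MBFM is the pointwise max and idempotent on one image", {
  a <- matrix(runif(16), 4, 4)
  expect_equal(unclass(make_mbfm(list(a))), a, ignore_attr = TRUE)
  b <- matrix(runif(16), 4, 4)
  m <- make_mbfm(list(a, b))
  expect_equal(unclass(m), pmax(a, b), ignore_attr = TRUE)
  expect_true(all(m >= a) && all(m >= b))
  expect_equal(attr(m, "n_motifs"), 2)
})

test_that("templates average the central motifs of the largest clusters", {
  set.seed(72)
  base <- matrix(runif(64), 8, 8)
  identical_cluster <- lapply(1:4, function(i) base)
  other <- lapply(1:2, function(i) matrix(runif(64), 8, 8))
  images <- c(identical_cluster, other)
  labels <- c(1, 1, 1, 1, 2, 3)
  expect_warning(tpl <- make_templates(images, labels, n_templates = 6),
                 "3 clusters")
  expect_length(tpl$templates, 3)
  expect_equal(tpl$templates[[1]], base)         # largest cluster first
  expect_equal(tpl$cluster_ids[1], "1")
  for (t in tpl$templates) expect_true(all(tpl$mbfm >= t))

  # ranking: counts (10, 5, 2), n = 2 keeps clusters 1 and 2
  imgs <- c(lapply(1:10, function(i) base + 0.01 * i),
            lapply(1:5, function(i) other[[1]] + 0.01 * i),
            lapply(1:2, function(i) other[[2]]))
  labs <- rep(c("a", "b", "c"), c(10, 5, 2))
  tpl <- make_templates(imgs, labs, n_templates = 2)
  expect_equal(sort(tpl$cluster_ids), c("a", "b"))
})

test_that("motif matching assigns by thresholded correlation, scale-invariantly", {
  set.seed(73)
  templates <- lapply(1:3, function(i) matrix(runif(100), 10, 10))
  res <- match_motifs(list(templates[[2]]), templates, 0.5)
  expect_equal(res$assignment$template_id, 2L)
  expect_equal(res$assignment$r, 1)

  # orthogonal-ish motif stays unassigned
  noise <- matrix(runif(100), 10, 10)
  while (max(abs(cor(as.vector(noise),
                     sapply(templates, as.vector)))) >= 0.5) {
    noise <- matrix(runif(100), 10, 10)
  }
  res <- match_motifs(list(noise), templates, 0.5)
  expect_true(is.na(res$assignment$template_id))

  # exhaustive-correlation oracle + scale invariance
  motifs <- lapply(1:6, function(i) {
    0.7 * templates[[(i - 1) %% 3 + 1]] + 0.3 * matrix(runif(100), 10, 10)
  })
  res <- match_motifs(motifs, templates, 0.3)
  for (i in 1:6) {
    rs <- vapply(templates, function(t) {
      cor(as.vector(motifs[[i]]), as.vector(t))
    }, numeric(1))
    expect_equal(res$assignment$template_id[i],
                 if (max(rs) >= 0.3) which.max(rs) else NA_integer_)
  }
  scaled <- lapply(motifs, function(m) 7.3 * m)
  res2 <- match_motifs(scaled, templates, 0.3)
  expect_equal(res2$assignment$template_id, res$assignment$template_id)

  # zero-variance motif warns and stays unassigned
  expect_warning(res <- match_motifs(list(matrix(1, 10, 10)), templates, 0.5),
                 "variance")
  expect_true(is.na(res$assignment$template_id))
  # MBFM of the matched averages is their pointwise max
  res <- match_motifs(motifs, templates, 0.3)
  have <- which(!vapply(res$matched, is.null, logical(1)))
  expect_equal(unclass(res$mbfm),
               Reduce(pmax, res$matched[have]), ignore_attr = TRUE)
})

test_that("planted motifs are recovered at realistic noise over seeds", {
  sc <- small_phantom()
  hits <- 0
  for (seed in 1:2) {
    sim <- motif_sim_spec(n_motifs = 3, motif_len = 5, movie_len = 300,
                          occurrences = 12, noise_sigma = 0.2, seed = seed)
    act <- simulate_activity(sc, sim)
    X <- movie_to_matrix(act$movie, sc$true_mask)
    ms <- convnmf(X, K = 3, L = 5, n_iter = 80, seed = seed)
    imgs <- motif_images(ms, sc$true_mask)
    planted <- lapply(1:3, function(k) motif_image(act$motifs[k, , , ],
                                                   sc$true_mask))
    rbest <- vapply(planted, function(p) {
      max(vapply(imgs, function(i) {
        cor(i[sc$true_mask > 0], p[sc$true_mask > 0])
      }, numeric(1)))
    }, numeric(1))
    if (all(rbest >= 0.8)) hits <- hits + 1
  }
  expect_equal(hits, 2)
})
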