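# Triple selection, per-hemisphere atlas-to-brain warping and
# brain-to-atlas normalization.

obs_at_atlas <- function(conf = rep(1, 9)) {
  landmark_observations(1:9, rownames(ref_atlas$landmarks_px),
                        ref_atlas$landmarks_px, conf)
}

test_that("triple selection follows the default, confidence and tie rules", {
  # equal confidences: confidence mode agrees with the default triples
  obs <- obs_at_atlas()
  d <- select_triples(obs, "default")
  cfd <- select_triples(obs, "confidence")
  expect_equal(sort(d$left), sort(cfd$left))
  expect_equal(sort(d$right), sort(cfd$right))
  expect_equal(sort(d$left), c(1, 4, 6))
  expect_equal(sort(d$right), c(4, 6, 7))

  # a zero-confidence landmark is excluded by confidence mode
  conf <- rep(1, 9); conf[4] <- 0
  cfd <- select_triples(obs_at_atlas(conf), "confidence", min_confidence = 0)
  expect_false(4 %in% cfd$left)
  expect_false(4 %in% cfd$right)

  # exhaustive-search oracle over all usable left-pool triples
  set.seed(31)
  conf <- runif(9, 0.5, 1)
  obs <- obs_at_atlas(conf)
  got <- select_triples(obs, "confidence")$left
  pool <- 1:6
  cands <- combn(pool, 3, simplify = FALSE)
  ok <- vapply(cands, function(tr) {
    !mesomap:::is_collinear(ref_atlas$landmarks_px[tr, ])
  }, logical(1))
  scores <- vapply(cands, function(tr) sum(conf[tr]), numeric(1))
  scores[!ok] <- -Inf
  expect_equal(sum(conf[got]), max(scores), tolerance = 1e-12)

  # fewer than three usable observations per hemisphere signals fallback
  two <- obs_at_atlas()[c(5, 6), ]
  expect_null(select_triples(two, "default")$left)
})

test_that("atlas-to-brain with observations at atlas positions is the identity", {
  ref <- ref_atlas
  sc <- canonical_phantom()
  obs <- obs_at_atlas()
  fit <- atlas_to_brain(ref$atlas, obs, ref$defs, ref$ccs, sc$true_mask)
  inside <- sc$true_mask == 1
  expect_identical(fit$labels[inside], ref$atlas$label_image[inside])
  expect_true(all(fit$labels[!inside] == 0))

  # all-zero mask -> all-zero output
  zero <- atlas_to_brain(ref$atlas, obs, ref$defs, ref$ccs,
                         matrix(0L, 256, 256))
  expect_true(all(zero$labels == 0))
  expect_error(atlas_to_brain(ref$atlas, obs_at_atlas(rep(0, 9)), ref$defs,
                              ref$ccs, sc$true_mask),
               "usable")
})

test_that("atlas-to-brain recovers labels on a misaligned phantom", {
  ref <- ref_atlas
  sc <- canonical_phantom()
  p <- perturb_alignment(sc, misalignment_spec(c(-25, 25), c(0.85, 1.15),
                                               c(-15, 15), seed = 8))
  obs <- mock_landmarks(p, 0, 0, 1)
  fit <- atlas_to_brain(ref$atlas, obs, ref$defs, ref$ccs, p$true_mask)
  agree <- sum(vapply(1:9, function(i) {
    pt <- round(p$true_landmarks[i, ])
    fit$labels[pt[1], pt[2]] == p$true_labels[pt[1], pt[2]]
  }, logical(1)))
  expect_gte(agree, 8)
})

test_that("brain-to-atlas registers phantoms back to the canonical frame", {
  ref <- ref_atlas
  sc <- canonical_phantom()
  obs <- mock_landmarks(sc, 0, 0, 1)
  reg <- brain_to_atlas(sc$image, obs, ref$defs, ref$ccs, sc$true_mask,
                        atlas = ref$atlas)
  pts <- register_points(sc$true_landmarks, obs, reg$maps, ref$landmarks_px)
  expect_lt(max(sqrt(rowSums((pts - ref$landmarks_px)^2))), 0.5)

  # known rotation 17 degrees, scale 1.1
  p <- perturb_alignment(sc, misalignment_spec(c(17, 17), c(1.1, 1.1),
                                               c(4, 4), seed = 2))
  obs <- mock_landmarks(p, 0, 0, 1)
  reg <- brain_to_atlas(p$image, obs, ref$defs, ref$ccs, p$true_mask,
                        atlas = ref$atlas)
  pts <- register_points(p$true_landmarks, obs, reg$maps, ref$landmarks_px)
  rmse <- sqrt(mean(rowSums((pts - ref$landmarks_px)^2)))
  expect_lt(rmse, 1)
  # the registered mask should land on the canonical cortex
  expect_gt(sum(reg$mask & sc$true_mask) / sum(sc$true_mask | reg$mask), 0.95)

  # round-trip: registering then warping back restores landmark positions
  back <- register_points(pts, obs_at_atlas(),
                          atlas_to_brain(ref$atlas, obs, ref$defs, ref$ccs,
                                         p$true_mask)$maps,
                          ref$landmarks_px)
  expect_lt(max(sqrt(rowSums((back - p$true_landmarks)^2))), 1)
})

test_that("hemispheres register independently", {
  ref <- ref_atlas
  sc <- canonical_phantom()
  obs <- obs_at_atlas()
  fit1 <- atlas_to_brain(ref$atlas, obs, ref$defs, ref$ccs, sc$true_mask)
  # perturb only right-hemisphere observations (indices 7-9)
  obs2 <- obs
  sel <- obs2$index %in% 7:9
  obs2$row[sel] <- obs2$row[sel] + 4
  obs2$col[sel] <- obs2$col[sel] + 3
  fit2 <- atlas_to_brain(ref$atlas, obs2, ref$defs, ref$ccs, sc$true_mask)
  bcol <- floor(ref$ccs$bregma_px[2])
  expect_identical(fit1$labels[, 1:(bcol - 1)], fit2$labels[, 1:(bcol - 1)])
  expect_false(identical(fit1$labels, fit2$labels))
})

test_that("two-landmark observations fall back to a similarity registration", {
  ref <- ref_atlas
  sc <- canonical_phantom()
  p <- perturb_alignment(sc, misalignment_spec(c(10, 10), c(1.05, 1.05),
                                               c(3, 3), seed = 6))
  obs <- mock_landmarks(p, 0, 0, 1)[c(5, 6), ]   # bregma + lambda only
  reg <- brain_to_atlas(p$image, obs, ref$defs, ref$ccs, p$true_mask,
                        atlas = ref$atlas)
  # a pure similarity perturbation is exactly undone by two points
  pts <- register_points(p$true_landmarks, obs, reg$maps, ref$landmarks_px)
  expect_lt(max(sqrt(rowSums((pts - ref$landmarks_px)^2))), 0.5)
})

test_that("an olfactory-bulb mask is carried along with its hemisphere", {
  ref <- ref_atlas
  sc <- canonical_phantom()
  ob <- matrix(0L, 256, 256)
  ob[12:24, 110:125] <- 1L   # a blob anterior to the left frontal pole
  img <- sc$image
  img[ob == 1L] <- 150
  obs <- obs_at_atlas()
  reg <- brain_to_atlas(img, obs, ref$defs, ref$ccs, sc$true_mask,
                        atlas = ref$atlas, ob_mask = ob)
  # identity alignment: the bulb must reappear at its own pixels
  expect_gt(mean(reg$mask[ob == 1L]), 0.95)
  reg0 <- brain_to_atlas(img, obs, ref$defs, ref$ccs, sc$true_mask,
                         atlas = ref$atlas)
  expect_true(all(reg0$mask[ob == 1L] == 0))
})
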