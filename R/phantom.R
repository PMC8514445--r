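# Synthetic phantom scenes: cortical frames with two bright hemispheres, a
# midline, dark vessel curves, nine ground-truth landmarks, misaligned
# variants with a recorded similarity transform, mock landmark detections,
# and activity movies with planted spatio-temporal motifs.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic cortical phantom
#'
#' @param image_size `(H, W)` in pixels.
#' @param semi_axes `(row, col)` semi-axes of the cortex ellipse in pixels.
#' @param midline_col column of the midline (may be fractional).
#' @param vessel_count number of dark vessel curves drawn inside the cortex.
#' @param vessel_width stroke width of vessels in pixels.
#' @param noise_sigma sd of additive Gaussian intensity noise (0-255 scale).
#' @param intensity `(background, cortex)` intensity levels in `[0, 255]`.
#' @param seed RNG seed; phantoms are pure functions of their spec.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(256L, 256L), semi_axes = c(100, 78),
                         midline_col = (image_size[2] + 1) / 2,
                         vessel_count = 6L, vessel_width = 3,
                         noise_sigma = 5, intensity = c(20, 200), seed = 1L) {
  stopifnot(noise_sigma >= 0, vessel_count >= 0,
            all(intensity >= 0), all(intensity <= 255),
            semi_axes[1] <= image_size[1] / 2,
            semi_axes[2] <= image_size[2] / 2)
  structure(list(image_size = as.integer(image_size), semi_axes = semi_axes,
                 midline_col = midline_col, vessel_count = vessel_count,
                 vessel_width = vessel_width, noise_sigma = noise_sigma,
                 intensity = intensity, seed = seed),
            class = "phantom_spec")
}

#' Generate a phantom cortical scene
#'
#' The scene geometry is the bundled [synthetic_atlas()] parcellation scaled
#' into the requested frame (rows by `semi_axes[1]/100`, columns by
#' `semi_axes[2]/78`, centered on the midline). The image is a two-level
#' cortex-on-background frame with optional dark vessel curves and additive
#' Gaussian noise; ground truth (mask, labels, the nine landmark pixels, and
#' the atlas-to-scene affine) is carried alongside.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_scene` with fields `image`, `true_mask`,
#'   `true_labels`, `true_landmarks` (9 x 2), `true_transform` (identity for
#'   a canonical scene), `atlas_map` (atlas frame -> scene frame) and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  ref <- synthetic_atlas()
  h <- spec$image_size[1]; w <- spec$image_size[2]
  sr <- spec$semi_axes[1] / 100
  sc <- spec$semi_axes[2] / 78
  center <- c((h + 1) / 2, spec$midline_col)
  lin <- diag(c(sr, sc))
  atlas_map <- affine_map(cbind(lin, center - lin %*% c(128.5, 128.5)))
  labels <- warp_affine(ref$atlas$label_image, atlas_map, c(h, w), "nearest")
  storage.mode(labels) <- "integer"
  mask <- (labels > 0) * 1L
  landmarks <- affine_apply(atlas_map, ref$landmarks_px)
  img <- matrix(spec$intensity[1], h, w)
  img[mask == 1L] <- spec$intensity[2]
  with_seed(spec$seed, {
    if (spec$vessel_count > 0) {
      vm <- draw_vessels(mask, spec$vessel_count, spec$vessel_width)
      img[vm & mask == 1L] <- spec$intensity[1] +
        0.45 * (spec$intensity[2] - spec$intensity[1])
    }
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
      img <- pmin(pmax(img, 0), 255)
    }
  })
  structure(list(image = img, true_mask = mask, true_labels = labels,
                 true_landmarks = landmarks,
                 true_transform = affine_identity(),
                 atlas_map = atlas_map, spec = spec),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  ident <- all(x$true_transform$m == affine_identity()$m)
  cat(sprintf("phantom scene: %d x %d px, %s alignment\n",
              nrow(x$image), ncol(x$image),
              if (ident) "canonical" else "perturbed"))
  invisible(x)
}

# Random smooth dark curves (quadratic Bezier strokes) inside the mask.
draw_vessels <- function(mask, count, width) {
  h <- nrow(mask); w <- ncol(mask)
  inside <- which(mask == 1L)
  vm <- matrix(FALSE, h, w)
  rad <- max(width / 2, 0.5)
  for (i in seq_len(count)) {
    pts <- arrayInd(sample(inside, 3L), c(h, w))
    tt <- seq(0, 1, length.out = 4L * max(h, w))
    br <- (1 - tt)^2 * pts[1, 1] + 2 * tt * (1 - tt) * pts[2, 1] + tt^2 * pts[3, 1]
    bc <- (1 - tt)^2 * pts[1, 2] + 2 * tt * (1 - tt) * pts[2, 2] + tt^2 * pts[3, 2]
    for (dr in seq(-floor(rad), floor(rad))) {
      for (dc in seq(-floor(rad), floor(rad))) {
        if (dr^2 + dc^2 > rad^2) next
        rr <- round(br) + dr; cc <- round(bc) + dc
        ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
        vm[cbind(rr[ok], cc[ok])] <- TRUE
      }
    }
  }
  vm
}

#' Specification of a random misalignment
#'
#' Misalignments are similarity transforms (rotation + uniform scale +
#' translation) about the image center, matching how misaligned test data
#' are produced by rotating and resizing the frames.
#'
#' @param rotation_deg `(min, max)` rotation range in degrees.
#' @param scale `(min, max)` uniform-scale range (> 0).
#' @param translation_px `(min, max)` per-axis translation range in pixels.
#' @param seed RNG seed.
#' @return list of class `misalignment_spec`.
#' @export
misalignment_spec <- function(rotation_deg = c(-30, 30), scale = c(0.8, 1.2),
                              translation_px = c(-20, 20), seed = 1L) {
  stopifnot(all(scale > 0))
  structure(list(rotation_deg = rotation_deg, scale = scale,
                 translation_px = translation_px, seed = seed),
            class = "misalignment_spec")
}

#' Apply a random similarity misalignment to a phantom scene
#'
#' One similarity transform is sampled from the spec ranges and applied to
#' the image (bilinear), mask and labels (nearest) and landmarks (exact);
#' `true_transform` records the sampled map so registration can be scored
#' against ground truth.
#'
#' @param scene a canonical (identity-transform) `phantom_scene`.
#' @param mis a [misalignment_spec()].
#' @return the perturbed `phantom_scene`.
#' @export
perturb_alignment <- function(scene, mis) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(mis, "misalignment_spec"))
  if (any(scene$true_transform$m != affine_identity()$m)) {
    stop("scene is already perturbed; start from a canonical scene")
  }
  h <- nrow(scene$image); w <- ncol(scene$image)
  map <- with_seed(mis$seed, {
    similarity_map(
      rotation_deg = stats::runif(1, mis$rotation_deg[1], mis$rotation_deg[2]),
      scale = stats::runif(1, mis$scale[1], mis$scale[2]),
      translation = stats::runif(2, mis$translation_px[1], mis$translation_px[2]),
      center = c((h + 1) / 2, (w + 1) / 2))
  })
  out <- scene
  out$image <- warp_affine(scene$image, map, c(h, w), "bilinear")
  out$true_mask <- warp_affine(scene$true_mask, map, c(h, w), "nearest")
  storage.mode(out$true_mask) <- "integer"
  out$true_labels <- warp_affine(scene$true_labels, map, c(h, w), "nearest")
  storage.mode(out$true_labels) <- "integer"
  out$true_landmarks <- affine_apply(map, scene$true_landmarks)
  out$true_transform <- map
  out$atlas_map <- affine_compose(map, scene$atlas_map)
  out
}

#' Mock landmark detections on a phantom scene
#'
#' Emulates a trained landmark detector: ground-truth landmark positions get
#' isotropic Gaussian jitter, a per-landmark confidence
#' `exp(-d^2 / (2 sigma^2))` (`d` = sampled displacement; 1 when
#' `jitter_sigma = 0`), and Bernoulli dropout. At least two landmarks are
#' always retained (the lowest-index ones are put back if dropout removes
#' too many).
#'
#' @param scene a `phantom_scene`.
#' @param jitter_sigma per-axis Gaussian jitter sd in pixels.
#' @param dropout probability in `[0, 1)` that a landmark is missed.
#' @param seed RNG seed.
#' @return a landmark-observation data.frame (see [landmark_observations()]).
#' @export
mock_landmarks <- function(scene, jitter_sigma = 0, dropout = 0, seed = 1L) {
  stopifnot(inherits(scene, "phantom_scene"), dropout >= 0, dropout < 1)
  lm <- scene$true_landmarks
  with_seed(seed, {
    jit <- matrix(stats::rnorm(18, 0, max(jitter_sigma, 0)), 9, 2)
    keep <- stats::runif(9) >= dropout
    if (sum(keep) < 2L) keep[order(!keep)[1:2]] <- TRUE
    d2 <- rowSums(jit^2)
    conf <- if (jitter_sigma > 0) {
      pmin(pmax(exp(-d2 / (2 * jitter_sigma^2)), 0), 1)
    } else rep(1, 9)
    obs <- landmark_observations(
      index = 1:9, name = rownames(lm),
      px = lm + jit, confidence = conf)
    obs[keep, , drop = FALSE]
  })
}

#' Specification of a planted-motif activity simulation
#'
#' @param n_motifs number of distinct motifs K.
#' @param motif_len motif length L in frames (must be < `movie_len`).
#' @param movie_len movie length T in frames.
#' @param occurrences onsets per motif (overlaps allowed).
#' @param footprints list of K integer vectors of region IDs from the scene's
#'   label image; each motif activates its region group.
#' @param amplitude peak motif amplitude in dF/F units.
#' @param noise_sigma sd of additive Gaussian noise.
#' @param seed RNG seed.
#' @return list of class `motif_sim_spec`.
#' @export
motif_sim_spec <- function(n_motifs = 3L, motif_len = 5L, movie_len = 300L,
                           occurrences = 10L,
                           footprints = list(c(1, 11), c(4, 14), c(9, 10, 19, 20)),
                           amplitude = 1, noise_sigma = 0.2, seed = 1L) {
  stopifnot(n_motifs >= 1, motif_len >= 1, motif_len < movie_len,
            occurrences >= 1, length(footprints) == n_motifs)
  structure(list(n_motifs = as.integer(n_motifs),
                 motif_len = as.integer(motif_len),
                 movie_len = as.integer(movie_len),
                 occurrences = as.integer(occurrences),
                 footprints = footprints, amplitude = amplitude,
                 noise_sigma = noise_sigma, seed = seed),
            class = "motif_sim_spec")
}

#' Simulate an activity movie with planted spatio-temporal motifs
#'
#' Each motif k is its region-group footprint modulated by a half-sine
#' temporal envelope over L frames, with a lateral sweep (the active columns
#' shift over the motif) so motifs have genuine spatio-temporal structure.
#' The movie is the sum of each motif convolved with its onset train, plus
#' Gaussian noise, clipped at zero.
#'
#' @param scene a `phantom_scene` providing `true_labels` and `true_mask`.
#' @param sim a [motif_sim_spec()].
#' @return list with `movie` (T x H x W), `motifs` (K x L x H x W planted
#'   motifs), `onsets` (list of onset frames per motif) and `noiseless`
#'   (movie before noise).
#' @export
simulate_activity <- function(scene, sim) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(sim, "motif_sim_spec"))
  labs <- scene$true_labels
  h <- nrow(labs); w <- ncol(labs)
  K <- sim$n_motifs; L <- sim$motif_len; Tn <- sim$movie_len
  present <- unique(as.vector(labs))
  motifs <- array(0, c(K, L, h, w))
  for (k in seq_len(K)) {
    ids <- sim$footprints[[k]]
    missing <- setdiff(ids, present)
    if (length(missing)) {
      stop("footprint region IDs absent from scene labels: ",
           paste(missing, collapse = ", "))
    }
    fp <- matrix(as.numeric(labs %in% ids), h, w)
    env <- sin(pi * seq_len(L) / (L + 1))
    colw <- col(fp) / w
    for (l in seq_len(L)) {
      # lateral sweep: weight columns by a moving window across the motif
      sweep_w <- exp(-((colw - l / (L + 1))^2) / 0.18)
      motifs[k, l, , ] <- sim$amplitude * env[l] * fp * sweep_w
    }
  }
  out <- with_seed(sim$seed, {
    onsets <- lapply(seq_len(K), function(k) {
      sort(sample.int(Tn - L + 1L, sim$occurrences, replace = TRUE))
    })
    clean <- array(0, c(Tn, h, w))
    for (k in seq_len(K)) {
      for (t0 in onsets[[k]]) {
        idx <- t0:(t0 + L - 1L)
        clean[idx, , ] <- clean[idx, , ] + motifs[k, , , ]
      }
    }
    movie <- clean
    if (sim$noise_sigma > 0) {
      movie <- movie + array(stats::rnorm(length(movie), 0, sim$noise_sigma),
                             dim(movie))
      movie[movie < 0] <- 0
    }
    list(movie = movie, onsets = onsets, noiseless = clean)
  })
  list(movie = out$movie, motifs = motifs, onsets = out$onsets,
       noiseless = out$noiseless, spec = sim)
}

#' Save a phantom scene to a directory
#'
#' Writes `image.tiff`, `mask.png`, `labels.png`, `landmarks.csv` and
#' `transform.json` (2x3 row-major affine).
#'
#' @param scene a `phantom_scene`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
save_phantom <- function(scene, dir) {
  stopifnot(inherits(scene, "phantom_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(scene$image, file.path(dir, "image.tiff"))
  write_mask_png(scene$true_mask, file.path(dir, "mask.png"))
  write_label_image(scene$true_labels, file.path(dir, "labels.png"))
  obs <- landmark_observations(1:9, rownames(scene$true_landmarks),
                               scene$true_landmarks, rep(1, 9))
  write_landmarks_csv(obs, file.path(dir, "landmarks.csv"))
  write_affine_json(scene$true_transform, file.path(dir, "transform.json"))
  invisible(dir)
}
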