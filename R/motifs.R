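# Convolutional NMF motif discovery, motif images, template construction,
# motif matching and motif-based functional maps (MBFMs).

# shift a K x T matrix right (later in time) by s frames, zero-filling
shift_right <- function(m, s) {
  if (s == 0) return(m)
  Tn <- ncol(m)
  cbind(matrix(0, nrow(m), s), m[, seq_len(Tn - s), drop = FALSE])
}

shift_left <- function(m, s) {
  if (s == 0) return(m)
  Tn <- ncol(m)
  cbind(m[, (s + 1):Tn, drop = FALSE], matrix(0, nrow(m), s))
}

convnmf_reconstruct <- function(W, H) {
  L <- dim(W)[3]
  xhat <- matrix(0, dim(W)[1], ncol(H))
  for (l in seq_len(L)) {
    xhat <- xhat + W[, , l] %*% shift_right(H, l - 1)
  }
  xhat
}

# (W (*) X)_{k,t} = sum_l W[, k, l]' X[, t + l - 1]: temporal correlation of
# each motif with the data, used in the H update and the cross-orthogonality
# penalty.
conv_wtx <- function(W, X) {
  K <- dim(W)[2]; L <- dim(W)[3]
  out <- matrix(0, K, ncol(X))
  for (l in seq_len(L)) {
    out <- out + t(W[, , l]) %*% shift_left(X, l - 1)
  }
  out
}

# banded temporal smoothing: M %*% S with S the (2L-1)-wide ones band
smooth_band <- function(m, L) {
  out <- m
  for (s in seq_len(L - 1)) {
    out <- out + shift_left(m, s) + shift_right(m, s)
  }
  out
}

#' Convolutional NMF motif discovery
#'
#' Factorizes a nonnegative pixels-by-time matrix `X` into `K` motifs of
#' length `L` frames with nonnegative temporal weights, by multiplicative
#' updates minimizing `0.5 * ||X - sum_k W_k (*) h_k||_F^2` plus an optional
#' cross-factor orthogonality penalty (weight `lambda`) that discourages
#' different motifs from explaining the same data and thereby favors
#' repeated sequences.
#'
#' @param X nonnegative `N_pixels x T` matrix (negative entries are clipped
#'   at 0 with a warning).
#' @param K number of motifs (>= 1).
#' @param L motif length in frames (>= 1, < T).
#' @param lambda cross-orthogonality penalty weight (default 0).
#' @param n_iter multiplicative-update iterations (default 100).
#' @param seed RNG seed for the nonnegative random initialization.
#' @param eps numerical floor for denominators.
#' @return object of class `motif_set`: `W` (`N x K x L` motif array), `H`
#'   (`K x T` temporal weights), `lambda`, `iterations`, and `objective`
#'   (per-iteration trace of the objective).
#' @export
convnmf <- function(X, K, L, lambda = 0, n_iter = 100, seed = 1L,
                    eps = 1e-12) {
  stopifnot(K >= 1, L >= 1, L < ncol(X), n_iter >= 1)
  if (!all(is.finite(X))) stop("X contains non-finite values")
  if (any(X < 0)) {
    warning("negative entries in X clipped at 0")
    X[X < 0] <- 0
  }
  N <- nrow(X); Tn <- ncol(X)
  scale0 <- sqrt(mean(X) / (K * L) + eps)
  init <- with_seed(seed, {
    list(W = array(stats::runif(N * K * L), c(N, K, L)) * scale0,
         H = matrix(stats::runif(K * Tn), K, Tn) * scale0)
  })
  W <- init$W; H <- init$H
  not_eye <- 1 - diag(K)
  objective <- numeric(n_iter)
  obj <- function(xhat) {
    o <- 0.5 * sum((X - xhat)^2)
    if (lambda > 0) {
      o <- o + lambda * sum(not_eye * (conv_wtx(W, X) %*%
                                         t(smooth_band(H, L))))
    }
    o
  }
  for (it in seq_len(n_iter)) {
    # W update (all lags simultaneously, H fixed)
    xhat <- convnmf_reconstruct(W, H)
    if (lambda > 0) xs <- smooth_band(X, L)
    for (l in seq_len(L)) {
      hs <- shift_right(H, l - 1)
      num <- X %*% t(hs)
      den <- xhat %*% t(hs)
      if (lambda > 0) den <- den + lambda * (xs %*% t(hs)) %*% not_eye
      W[, , l] <- W[, , l] * num / pmax(den, eps)
    }
    # H update (W fixed)
    xhat <- convnmf_reconstruct(W, H)
    num <- conv_wtx(W, X)
    den <- conv_wtx(W, xhat)
    if (lambda > 0) den <- den + lambda * not_eye %*% smooth_band(num, L)
    H <- H * num / pmax(den, eps)
    objective[it] <- obj(convnmf_reconstruct(W, H))
  }
  structure(list(W = W, H = H, K = K, L = L, lambda = lambda,
                 iterations = n_iter, objective = objective),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("motif set: K = %d motifs of %d frames, %d pixels, %d iterations\n",
              x$K, x$L, nrow(x$W), x$iterations))
  cat(sprintf("final objective: %.6g\n", utils::tail(x$objective, 1)))
  invisible(x)
}

#' Relative reconstruction error of a motif set
#'
#' `||X - X_hat||_F / ||X||_F`.
#' @param ms a `motif_set`.
#' @param X the factorized matrix.
#' @return scalar.
#' @export
convnmf_error <- function(ms, X) {
  xhat <- convnmf_reconstruct(ms$W, ms$H)
  sqrt(sum((X - xhat)^2)) / sqrt(sum(X^2))
}

#' Flatten a movie to the pixels-by-time matrix used by [convnmf()]
#'
#' @param movie T x H x W array.
#' @param mask binary H x W matrix; only in-mask pixels are kept.
#' @return `N_pixels x T` matrix with attribute `mask`.
#' @export
movie_to_matrix <- function(movie, mask = NULL) {
  Tn <- dim(movie)[1]
  flat <- matrix(aperm(movie, c(2, 3, 1)), ncol = Tn)
  if (!is.null(mask)) flat <- flat[as.vector(mask > 0), , drop = FALSE]
  attr(flat, "mask") <- mask
  flat
}

# unflatten one motif lag (or image) back onto the frame
unflatten <- function(v, mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  out[mask > 0] <- v
  out
}

#' Per-motif maximum-projection image
#'
#' Max over the motif's frames, zeroed outside the brain mask and min-max
#' normalized to `[0, 1]` (an all-zero motif stays zero).
#'
#' @param motif L x H x W array, or (for factorization output) an `N x L`
#'   matrix of masked pixels with `mask` supplied.
#' @param mask binary H x W brain mask.
#' @return H x W matrix in `[0, 1]`.
#' @export
motif_image <- function(motif, mask) {
  if (is.matrix(motif)) {
    mx <- apply(motif, 1, max)
    img <- unflatten(mx, mask)
  } else {
    img <- apply(motif, c(2, 3), max)
    img[mask == 0] <- 0
  }
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  img[mask == 0] <- 0
  img
}

#' Motif images of every motif in a factorization
#'
#' @param ms a `motif_set` factorized from [movie_to_matrix()] output.
#' @param mask the brain mask used for the flattening.
#' @return list of H x W motif images.
#' @export
motif_images <- function(ms, mask) {
  lapply(seq_len(ms$K), function(k) motif_image(ms$W[, k, ], mask))
}

#' Maximum-projection motif-based functional map (MBFM)
#'
#' The pointwise maximum of the given normalized motif images.
#'
#' @param images list of H x W motif images in `[0, 1]`.
#' @return object of class `mbfm`: H x W matrix with attribute `n_motifs`.
#' @export
make_mbfm <- function(images) {
  stopifnot(length(images) >= 1L)
  out <- Reduce(pmax, images)
  attr(out, "n_motifs") <- length(images)
  class(out) <- c("mbfm", class(out))
  out
}

pearson_masked <- function(a, b, mask = NULL) {
  va <- if (is.null(mask)) as.vector(a) else a[mask > 0]
  vb <- if (is.null(mask)) as.vector(b) else b[mask > 0]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}

#' Build template motifs and the template MBFM from clustered motif images
#'
#' Clusters are ranked by member count and the `n_templates` largest are
#' kept. Within each cluster the "center" motifs — the members whose mean
#' correlation with the rest of the cluster is in the top `center_quantile`
#' fraction — are averaged into the template. The template MBFM is the
#' maximum projection of the templates.
#'
#' @param images list of motif images.
#' @param cluster_labels integer cluster label per image.
#' @param n_templates number of templates to keep (default 6; fewer with a
#'   warning when there are fewer clusters).
#' @param center_quantile fraction of most-central members averaged
#'   (default 0.5).
#' @param mask optional mask restricting the correlations.
#' @return list with `templates` (list of images), `cluster_ids` (source
#'   cluster of each template), `mbfm` (template MBFM).
#' @export
make_templates <- function(images, cluster_labels, n_templates = 6,
                           center_quantile = 0.5, mask = NULL) {
  stopifnot(length(images) == length(cluster_labels))
  sizes <- sort(table(cluster_labels), decreasing = TRUE)
  if (length(sizes) < n_templates) {
    warning(sprintf("only %d clusters available; returning %d templates",
                    length(sizes), length(sizes)))
    n_templates <- length(sizes)
  }
  keep <- names(sizes)[seq_len(n_templates)]
  templates <- list(); cluster_ids <- c()
  for (cl in keep) {
    member_ix <- which(as.character(cluster_labels) == cl)
    if (!length(member_ix)) next
    if (length(member_ix) == 1L) {
      templates[[length(templates) + 1L]] <- images[[member_ix]]
      cluster_ids <- c(cluster_ids, cl)
      next
    }
    cm <- vapply(member_ix, function(i) {
      others <- setdiff(member_ix, i)
      mean(vapply(others, function(j) {
        r <- pearson_masked(images[[i]], images[[j]], mask)
        if (is.na(r)) 0 else r
      }, numeric(1)))
    }, numeric(1))
    cutoff <- stats::quantile(cm, 1 - center_quantile, names = FALSE)
    centers <- member_ix[cm >= cutoff]
    templates[[length(templates) + 1L]] <-
      Reduce(`+`, images[centers]) / length(centers)
    cluster_ids <- c(cluster_ids, cl)
  }
  list(templates = templates, cluster_ids = cluster_ids,
       mbfm = make_mbfm(templates))
}

#' Match new motifs against template motifs and build the new MBFM
#'
#' Each new motif image is assigned to its best-correlated template if the
#' Pearson correlation reaches `r_threshold` (ties go to the lower template
#' index); otherwise it stays unassigned. Matched motifs are averaged per
#' template, and the new MBFM is the maximum projection of those averages.
#'
#' @param new_images list of motif images (normalized to `[0, 1]`).
#' @param templates list of template images.
#' @param r_threshold matching threshold in `(-1, 1)` (default 0.5).
#' @param mask optional mask restricting the correlations.
#' @return list with `assignment` (data.frame `motif_id, template_id, r`;
#'   `template_id` is `NA` for unassigned motifs), `matched` (per-template
#'   averaged images, NULL where no motif matched) and `mbfm`.
#' @export
match_motifs <- function(new_images, templates, r_threshold = 0.5,
                         mask = NULL) {
  stopifnot(length(templates) >= 1L, r_threshold > -1, r_threshold < 1)
  n <- length(new_images); m <- length(templates)
  rmat <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      rmat[i, j] <- pearson_masked(new_images[[i]], templates[[j]], mask)
    }
  }
  assignment <- data.frame(motif_id = seq_len(n),
                           template_id = NA_integer_, r = NA_real_)
  for (i in seq_len(n)) {
    ri <- rmat[i, ]
    if (all(is.na(ri))) {
      warning(sprintf("motif %d has zero variance; left unassigned", i))
      next
    }
    best <- which(ri == max(ri, na.rm = TRUE))[1]   # ties -> lower index
    assignment$r[i] <- ri[best]
    if (ri[best] >= r_threshold) assignment$template_id[i] <- best
  }
  matched <- vector("list", m)
  for (j in seq_len(m)) {
    ix <- which(assignment$template_id == j)
    if (length(ix)) matched[[j]] <- Reduce(`+`, new_images[ix]) / length(ix)
  }
  have <- !vapply(matched, is.null, logical(1))
  mbfm <- if (any(have)) make_mbfm(matched[have]) else NULL
  list(assignment = assignment, matched = matched, mbfm = mbfm,
       r_matrix = rmat)
}
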