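# PhenoGraph-style clustering of motif images: k-nearest-neighbor graph with
# shared-neighbor (Jaccard) edge weights, Louvain community detection, and
# silhouette scoring.

#' Shared-nearest-neighbor (Jaccard) kNN graph
#'
#' Finds each point's k nearest neighbors (Euclidean distance), then weights
#' the edge between two points by the Jaccard overlap of their neighbor
#' sets; pairs with no shared neighborhood structure get no edge.
#'
#' @param vectors n x d numeric matrix (rows = points).
#' @param k neighborhood size (k < n).
#' @return object of class `motif_graph`: an undirected weighted
#'   [igraph::graph] with vertex attribute `id`, plus attributes `k` and
#'   `knn` (n x k neighbor-index matrix).
#' @export
knn_graph <- function(vectors, k) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (k >= n) stop("k must be smaller than the number of points")
  stopifnot(k >= 1)
  d <- as.matrix(stats::dist(vectors))
  diag(d) <- Inf
  knn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  nbr <- lapply(seq_len(n), function(i) knn[i, ])
  edges <- c(); weights <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- length(intersect(nbr[[i]], nbr[[j]]))
      if (inter == 0) next
      wt <- inter / length(union(nbr[[i]], nbr[[j]]))
      edges <- c(edges, i, j)
      weights <- c(weights, wt)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, edges, weight = weights)
  }
  igraph::V(g)$id <- seq_len(n)
  structure(list(graph = g, k = k, knn = knn), class = "motif_graph")
}

#' @export
print.motif_graph <- function(x, ...) {
  cat(sprintf("shared-neighbor graph: %d nodes, %d weighted edges (k = %d)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$k))
  invisible(x)
}

#' Louvain community detection on a motif graph
#'
#' Greedy modularity optimization; communities are relabeled by descending
#' size (label 1 = largest). Deterministic for a fixed seed.
#'
#' @param graph a `motif_graph` (or an igraph graph).
#' @param seed RNG seed controlling tie-breaking.
#' @return object of class `cluster_result`: `labels` (integer per node),
#'   `modularity`, `n_clusters`.
#' @export
louvain <- function(graph, seed = 1L) {
  g <- if (inherits(graph, "motif_graph")) graph$graph else graph
  if (igraph::vcount(g) == 0) stop("empty graph")
  memb <- with_seed(seed, {
    if (igraph::ecount(g) == 0) {
      seq_len(igraph::vcount(g))
    } else {
      igraph::membership(igraph::cluster_louvain(g))
    }
  })
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- as.integer(relabel[as.character(memb)])
  mod <- if (igraph::ecount(g) == 0) 0 else {
    igraph::modularity(g, labels, weights = igraph::E(g)$weight)
  }
  structure(list(labels = labels, modularity = mod,
                 n_clusters = length(sizes)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("clustering: %d communities, modularity %.4f%s\n",
              x$n_clusters, x$modularity,
              if (!is.null(x$silhouette)) {
                sprintf(", silhouette %.4f", x$silhouette)
              } else ""))
  invisible(x)
}

#' Mean silhouette score
#'
#' Mean over points of `(b - a) / max(a, b)` with Euclidean distances, where
#' `a` is the mean within-cluster distance and `b` the mean distance to the
#' closest other cluster; members of singleton clusters score 0.
#'
#' @param vectors n x d matrix.
#' @param labels integer cluster labels (>= 2 distinct values required).
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_score <- function(vectors, labels) {
  if (length(unique(labels)) < 2L) {
    stop("silhouette requires at least two clusters")
  }
  s <- cluster::silhouette(as.integer(factor(labels)),
                           stats::dist(as.matrix(vectors)))
  mean(s[, "sil_width"])
}

#' Cluster motif images (PhenoGraph-style)
#'
#' Flattens each motif image over the mask, builds the shared-neighbor kNN
#' graph, runs Louvain, and averages the member images per cluster.
#'
#' @param images list of H x W motif images.
#' @param mask binary H x W mask (default: all pixels).
#' @param k neighborhood size (default 15, truncated to n - 1).
#' @param seed RNG seed for Louvain tie-breaking.
#' @return `cluster_result` with extra fields `cluster_means` (list of
#'   per-cluster mean images) and `silhouette` (NA when a single cluster is
#'   found).
#' @export
cluster_motifs <- function(images, mask = NULL, k = 15, seed = 1L) {
  n <- length(images)
  stopifnot(n >= 2L)
  if (is.null(mask)) mask <- matrix(1, nrow(images[[1]]), ncol(images[[1]]))
  vectors <- t(vapply(images, function(im) im[mask > 0],
                      numeric(sum(mask > 0))))
  k <- min(k, n - 1L)
  g <- knn_graph(vectors, k)
  res <- louvain(g, seed)
  res$cluster_means <- lapply(seq_len(res$n_clusters), function(cl) {
    ix <- which(res$labels == cl)
    Reduce(`+`, images[ix]) / length(ix)
  })
  res$silhouette <- if (res$n_clusters >= 2L) {
    silhouette_score(vectors, res$labels)
  } else NA_real_
  res$graph <- g
  res
}
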