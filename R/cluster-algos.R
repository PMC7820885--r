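# Classical clustering on latent features. k-means, Ward agglomerative and
# Gaussian mixtures are delegated to stats/mclust; DBSCAN and OPTICS are
# compact O(n^2) distance-matrix implementations (no R implementation is
# available in the dependency set), returning 0-based labels with -1 noise.

#' Density-based spatial clustering (DBSCAN)
#'
#' @param z Numeric matrix of points.
#' @param eps Neighbourhood radius.
#' @param min_pts Minimum neighbourhood size (self included) for a core
#'   point.
#' @return Integer labels, 0-based; noise points get `-1`.
#' @export
dbscan_fit <- function(z, eps, min_pts = 5) {
  z <- check_matrix(z, "z")
  eps <- check_number(eps, "eps", min = 0, strict_min = TRUE)
  min_pts <- check_count(min_pts, "min_pts")
  n <- nrow(z)
  d <- as.matrix(stats::dist(z))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, 1L) >= min_pts
  labels <- rep(-2L, n)  # -2 = unvisited
  cl <- -1L
  for (i in seq_len(n)) {
    if (labels[i] != -2L) next
    if (!core[i]) { labels[i] <- -1L; next }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbrs[[i]], i)
    while (length(queue) > 0L) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (labels[j] == -1L) labels[j] <- cl        # border point
      if (labels[j] != -2L) next
      labels[j] <- cl
      if (core[j]) queue <- c(queue, setdiff(nbrs[[j]], j))
    }
  }
  labels
}

#' OPTICS ordering and cluster extraction
#'
#' Computes the OPTICS reachability ordering (core distance = distance to
#' the `min_pts`-th nearest neighbour, self included) and extracts clusters
#' by cutting the reachability profile at `eps_cl`: a point whose
#' reachability exceeds the cut starts a new cluster if its own core
#' distance is within the cut, and is noise otherwise. This threshold
#' extraction is equivalent to DBSCAN at radius `eps_cl` up to border-point
#' assignment.
#'
#' @param z Numeric matrix of points.
#' @param min_pts Core-point neighbourhood size.
#' @param eps Maximum radius considered (default `Inf`).
#' @param eps_cl Extraction cut; defaults to `eps`.
#' @return Integer labels (0-based, `-1` noise) with the visit `order` and
#'   `reachability` attached as attributes.
#' @export
optics_fit <- function(z, min_pts = 5, eps = Inf, eps_cl = eps) {
  z <- check_matrix(z, "z")
  min_pts <- check_count(min_pts, "min_pts")
  n <- nrow(z)
  if (!is.finite(eps_cl)) dc_stop("`eps_cl` must be finite for cluster extraction")
  d <- as.matrix(stats::dist(z))
  core_dist <- apply(d, 1L, function(row) sort(row)[min(min_pts, n)])
  core_dist[core_dist > eps] <- Inf
  reach <- rep(Inf, n)
  processed <- rep(FALSE, n)
  ord <- integer(n)
  for (pos in seq_len(n)) {
    i <- if (all(is.infinite(reach[!processed]))) {
      which(!processed)[1L]
    } else {
      cand <- which(!processed)
      cand[which.min(reach[cand])]
    }
    processed[i] <- TRUE
    ord[pos] <- i
    if (is.finite(core_dist[i])) {
      nb <- which(d[i, ] <= eps & !processed)
      newreach <- pmax(core_dist[i], d[i, nb])
      upd <- newreach < reach[nb]
      reach[nb[upd]] <- newreach[upd]
    }
  }
  # threshold extraction along the ordering
  labels <- rep(-1L, n)
  cl <- -1L
  for (pos in seq_len(n)) {
    i <- ord[pos]
    if (reach[i] > eps_cl) {
      if (core_dist[i] <= eps_cl) {
        cl <- cl + 1L
        labels[i] <- cl
      }  # else noise
    } else if (cl >= 0L) {
      labels[i] <- cl
    }
  }
  structure(labels, order = ord, reachability = reach)
}

#' Initialize cluster centroids on latent features
#'
#' Runs a centroid-capable base algorithm on Z and returns K centroids:
#' k-means centres, or the group means of a Ward agglomerative cut, or
#' Gaussian-mixture component means. Deterministic given `seed`. When
#' `n == K` every point is its own centroid regardless of algorithm.
#' Density-based algorithms have no centroids; use [pipeline_cluster()].
#'
#' @param z Latent matrix (n x d).
#' @param k Number of clusters (2 <= K <= n).
#' @param algorithm `"kmeans"`, `"agglomerative"` or `"gmm"`.
#' @param seed Integer seed.
#' @return K x d centroid matrix.
#' @export
init_centroids <- function(z, k, algorithm = c("kmeans", "agglomerative", "gmm"),
                           seed = 1) {
  z <- check_matrix(z, "z")
  k <- check_count(k, "k")
  if (identical(algorithm, "dbscan") || identical(algorithm, "optics")) {
    dc_stop("density-based algorithms have no centroids; use pipeline_cluster()")
  }
  algorithm <- match.arg(algorithm)
  if (k > nrow(z)) dc_stop("K = %d exceeds the number of samples (%d)", k, nrow(z))
  if (k == nrow(z)) return(unname(z))
  group_means <- function(lab) {
    t(vapply(sort(unique(lab)),
             function(g) colMeans(z[lab == g, , drop = FALSE]),
             numeric(ncol(z))))
  }
  with_seed(seed, switch(algorithm,
    kmeans = unname(stats::kmeans(z, centers = k, nstart = 10,
                                  iter.max = 100)$centers),
    agglomerative = {
      hc <- stats::hclust(stats::dist(z), method = "ward.D2")
      group_means(stats::cutree(hc, k = k))
    },
    gmm = {
      mclustBIC <- mclust::mclustBIC  # Mclust looks this up in the caller
      fit <- mclust::Mclust(z, G = k, verbose = FALSE)
      if (is.null(fit)) dc_stop("GMM fit failed")
      t(fit$parameters$mean)
    }
  ))
}

#' Pipeline-mode clustering on latent features
#'
#' Extract-then-cluster: runs a conventional algorithm directly on the
#' latent matrix. Supports `kmeans`, `agglomerative` (Ward), `gmm` (full
#' covariance), `dbscan` and `optics`; the density-based pair may emit the
#' noise label `-1`.
#'
#' @param z Latent matrix.
#' @param algorithm Algorithm name.
#' @param params List of algorithm parameters: `k` (partition algorithms),
#'   `eps`, `min_pts`, `eps_cl` (density-based).
#' @param seed Integer seed.
#' @return Integer labels, 0-based (`-1` = noise).
#' @export
pipeline_cluster <- function(z, algorithm = c("kmeans", "agglomerative", "gmm",
                                              "dbscan", "optics"),
                             params = list(), seed = 1) {
  z <- check_matrix(z, "z")
  if (any(!is.finite(z))) dc_stop("`z` must be finite")
  algorithm <- match.arg(algorithm)
  if (algorithm %in% c("kmeans", "agglomerative", "gmm")) {
    k <- params$k
    if (is.null(k)) dc_stop("`params$k` is required for %s", algorithm)
    k <- check_count(k, "k")
    mclustBIC <- mclust::mclustBIC  # Mclust looks this up in the caller
    labels <- with_seed(seed, switch(algorithm,
      kmeans = stats::kmeans(z, centers = k, nstart = 10, iter.max = 100)$cluster,
      agglomerative = stats::cutree(stats::hclust(stats::dist(z),
                                                  method = "ward.D2"), k = k),
      gmm = mclust::Mclust(z, G = k, verbose = FALSE)$classification
    ))
    return(relabel_from_zero(as.integer(labels)))
  }
  min_pts <- if (is.null(params$min_pts)) 5L else params$min_pts
  if (algorithm == "dbscan") {
    if (is.null(params$eps)) dc_stop("`params$eps` is required for dbscan")
    return(dbscan_fit(z, params$eps, min_pts))
  }
  eps <- if (is.null(params$eps)) Inf else params$eps
  eps_cl <- if (is.null(params$eps_cl)) eps else params$eps_cl
  as.integer(optics_fit(z, min_pts, eps, eps_cl))
}
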