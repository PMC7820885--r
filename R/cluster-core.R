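#' Student's-t soft cluster assignment
#'
#' Computes the soft assignment matrix Q with a Student's-t kernel on latent
#' distances:
#' `q_ij = (1 + ||z_i - mu_j||^2 / alpha)^(-(alpha+1)/2) / sum_j' (...)`.
#' With the default `alpha = 1` this is the similarity kernel also used by
#' t-SNE; learning `alpha` adds nothing in the unsupervised setting, so it is
#' fixed by default and merely exposed for experimentation.
#'
#' @param z Latent matrix (n x d), rows are embedded samples.
#' @param centroids Centroid matrix (K x d), rows are cluster centres.
#' @param alpha Degrees of freedom of the kernel (> 0), default 1.
#' @return An n x K matrix Q; every row sums to 1 and every entry is in (0, 1).
#' @examples
#' soft_assign(matrix(c(0, 0), 1), rbind(c(0, 0), c(2, 0)))  # (5/6, 1/6)
#' @export
soft_assign <- function(z, centroids, alpha = 1) {
  z <- check_matrix(z, "z")
  centroids <- check_matrix(centroids, "centroids")
  alpha <- check_number(alpha, "alpha", min = 0, strict_min = TRUE)
  if (ncol(z) != ncol(centroids)) {
    dc_stop("latent dimension of `z` (%d) != centroid dimension (%d)",
            ncol(z), ncol(centroids))
  }
  d2 <- pairwise_sqdist(z, centroids)
  log_un <- -(alpha + 1) / 2 * log1p(d2 / alpha)
  # normalize in log space for numerical safety at large distances
  m <- apply(log_un, 1L, max)
  un <- exp(log_un - m)
  un / rowSums(un)
}

# squared Euclidean distances between rows of a (n x d) and rows of b (K x d)
pairwise_sqdist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Auxiliary target distribution
#'
#' Sharpens a soft assignment Q into the self-training target
#' `p_ij = (q_ij^2 / f_j) / sum_j' (q_ij'^2 / f_j')` with soft cluster
#' frequencies `f_j = sum_i q_ij`. Squaring emphasizes confident assignments;
#' dividing by the frequency guards against large clusters swallowing the
#' target mass.
#'
#' @param q Soft assignment matrix (rows sum to 1).
#' @return Matrix P of the same shape; rows sum to 1.
#' @export
target_distribution <- function(q) {
  q <- check_matrix(q, "q")
  f <- colSums(q)
  if (any(f <= 0)) dc_stop("zero cluster frequency: cannot form the target distribution")
  # q * (q / f) rather than q^2 / f: algebraically identical, and exact in
  # the single-sample case where f = q so P reduces to Q
  w <- q * sweep(q, 2L, f, "/")
  w / rowSums(w)
}

#' Kullback-Leibler clustering loss
#'
#' `L = KL(P || Q) = sum_ij p_ij log(p_ij / q_ij)` in natural-log units, with
#' the convention `0 * log(0/q) = 0`. Non-negative; zero iff P equals Q.
#'
#' @param p Target distribution matrix.
#' @param q Soft assignment matrix (strictly positive wherever `p > 0`).
#' @return Scalar loss (sum over all samples and clusters).
#' @export
kld_loss <- function(p, q) {
  p <- check_matrix(p, "p")
  q <- check_matrix(q, "q")
  if (!all(dim(p) == dim(q))) dc_stop("`p` and `q` shapes differ")
  pos <- p > 0
  if (any(q[pos] <= 0)) {
    dc_stop("q_ij = 0 where p_ij > 0: KL divergence is infinite",
            class = "deepclust_infinite_kld")
  }
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Analytic gradients of the clustering loss
#'
#' Gradients of `KL(P || Q)` (P held fixed) with respect to the embedded
#' points and the centroids:
#' `dL/dz_i =  ((alpha+1)/alpha) * sum_j (1 + ||z_i - mu_j||^2/alpha)^-1 (p_ij - q_ij)(z_i - mu_j)`
#' `dL/dmu_j = -((alpha+1)/alpha) * sum_i (1 + ||z_i - mu_j||^2/alpha)^-1 (p_ij - q_ij)(z_i - mu_j)`.
#' The z-gradients are what gets backpropagated into the encoder. By
#' translation invariance of the loss, the z- and centroid-gradients sum to
#' the zero vector.
#'
#' @param z Latent matrix (n x d).
#' @param centroids Centroid matrix (K x d).
#' @param p Target distribution (n x K).
#' @param q Soft assignments (n x K).
#' @param alpha Student's-t degrees of freedom.
#' @return List with `dz` (n x d) and `dmu` (K x d).
#' @export
clustering_gradients <- function(z, centroids, p, q, alpha = 1) {
  z <- check_matrix(z, "z")
  centroids <- check_matrix(centroids, "centroids")
  p <- check_matrix(p, "p")
  q <- check_matrix(q, "q")
  alpha <- check_number(alpha, "alpha", min = 0, strict_min = TRUE)
  n <- nrow(z); k <- nrow(centroids)
  if (ncol(z) != ncol(centroids)) dc_stop("dimension mismatch between `z` and `centroids`")
  if (!all(dim(p) == c(n, k)) || !all(dim(q) == c(n, k))) {
    dc_stop("`p`/`q` must be %d x %d", n, k)
  }
  d2 <- pairwise_sqdist(z, centroids)
  w <- ((alpha + 1) / alpha) * (p - q) / (1 + d2 / alpha)   # n x K weights
  rs <- rowSums(w)
  dz <- rs * z - w %*% centroids
  dmu <- -(crossprod(w, z) - colSums(w) * centroids)
  list(dz = dz, dmu = dmu)
}

#' Combined training objective
#'
#' `L = sigma * L_clustering + (1 - sigma) * L_nonclustering`, the convex
#' combination weighting the cluster-hardening KLD term against the
#' autoencoder reconstruction term. The default schedule trains with
#' `sigma = 0` in the representation-learning phase and `sigma = 1` in the
#' hardening phase; a constant `0 < sigma < 1` gives joint training.
#'
#' @param l_clustering Clustering (KLD) loss value.
#' @param l_nonclustering Non-clustering (reconstruction) loss value.
#' @param sigma Weight in `[0, 1]`.
#' @return Scalar combined loss.
#' @export
combined_loss <- function(l_clustering, l_nonclustering, sigma) {
  sigma <- check_number(sigma, "sigma", min = 0, max = 1)
  l_clustering <- check_number(l_clustering, "l_clustering")
  l_nonclustering <- check_number(l_nonclustering, "l_nonclustering")
  sigma * l_clustering + (1 - sigma) * l_nonclustering
}
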