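#' Clustering-quality metrics
#'
#' @description
#' External validation metrics comparing a predicted clustering `c` against
#' ground-truth labels `y`: normalized mutual information, Rand and adjusted
#' Rand indices, unsupervised clustering accuracy (best one-to-one
#' cluster-to-class mapping via the Hungarian algorithm), homogeneity and
#' completeness; plus internal criteria (within-cluster sum of squares, the
#' Elbow knee rule) and the generalizability ratio G.
#'
#' All label-pair metrics are invariant to bijective relabeling of either
#' argument. Density-based noise labels (`-1`) are by default treated as
#' singleton clusters (one per noise point); set `noise = "drop"` to exclude
#' noise points instead.
#'
#' @name metrics
NULL

# Validate a label pair and resolve the noise-handling policy.
# Returns a list(y, c) of integer vectors, equal length, no -1 left.
prepare_labels <- function(y, c, noise = c("singleton", "drop")) {
  noise <- match.arg(noise)
  if (length(y) != length(c)) dc_stop("`y` and `c` must have equal length")
  if (length(y) == 0L) dc_stop("empty label vectors")
  y <- as.integer(y)
  c <- as.integer(c)
  if (anyNA(y) || anyNA(c)) dc_stop("labels must not contain NA")
  is_noise <- c == -1L | y == -1L
  if (any(is_noise)) {
    if (noise == "drop") {
      y <- y[!is_noise]
      c <- c[!is_noise]
      if (length(y) == 0L) dc_stop("all points are noise")
    } else {
      # each noise point becomes its own singleton cluster
      nxt_c <- max(c[c != -1L], 0L) + 1L
      idx <- which(c == -1L)
      c[idx] <- nxt_c + seq_along(idx) - 1L
      nxt_y <- max(y[y != -1L], 0L) + 1L
      idx <- which(y == -1L)
      y[idx] <- nxt_y + seq_along(idx) - 1L
    }
  }
  list(y = y, c = c)
}

contingency_table <- function(y, c) {
  uy <- sort(unique(y))
  uc <- sort(unique(c))
  iy <- match(y, uy)
  ic <- match(c, uc)
  m <- matrix(tabulate(iy + (ic - 1L) * length(uy),
                       nbins = length(uy) * length(uc)),
              length(uy), length(uc))
  dimnames(m) <- list(as.character(uy), as.character(uc))
  m
}

entropy_nats <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Normalized mutual information between two labelings
#'
#' `NMI(y, c) = I(y, c) / ((H(y) + H(c)) / 2)` with natural-log entropies
#' (the ratio is base-invariant). When both partitions are trivial (a single
#' cluster each) the value is defined as 1 by convention.
#'
#' @param y Ground-truth labels.
#' @param c Predicted labels (`-1` allowed for noise).
#' @param noise Noise-label policy: `"singleton"` (default) or `"drop"`.
#' @return A number in `[0, 1]`.
#' @examples
#' nmi(c(0, 0, 1, 1), c(0, 0, 0, 1))
#' @export
nmi <- function(y, c, noise = "singleton") {
  lp <- prepare_labels(y, c, noise)
  tab <- contingency_table(lp$y, lp$c)
  n <- sum(tab)
  hy <- entropy_nats(rowSums(tab))
  hc <- entropy_nats(colSums(tab))
  if (hy == 0 && hc == 0) return(1)
  pj <- rowSums(tab) / n
  pc <- colSums(tab) / n
  pij <- tab / n
  expected <- outer(pj, pc)
  pos <- pij > 0
  mi <- sum(pij[pos] * log(pij[pos] / expected[pos]))
  val <- mi / ((hy + hc) / 2)
  min(max(val, 0), 1)
}

# Pair counts (over all n(n-1)/2 sample pairs) from the contingency table.
pair_confusion <- function(y, c) {
  tab <- contingency_table(y, c)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  tp <- sum(choose2(tab))                    # same cluster in both
  same_y <- sum(choose2(rowSums(tab)))
  same_c <- sum(choose2(colSums(tab)))
  fn <- same_y - tp                          # same in y, split in c
  fp <- same_c - tp                          # same in c, split in y
  total <- choose2(n)
  tn <- total - tp - fp - fn
  list(TP = tp, TN = tn, FP = fp, FN = fn, total = total)
}

#' Rand index
#'
#' Fraction of sample pairs on which the two partitions agree:
#' `RI = (TP + TN) / (TP + FP + FN + TN)` where the counts run over all
#' `n(n-1)/2` pairs.
#'
#' @inheritParams nmi
#' @return A number in `[0, 1]`; 1 iff the partitions are identical up to
#'   relabeling.
#' @examples
#' rand_index(c(0, 0, 0, 1, 1, 1), c(0, 0, 1, 1, 1, 1))  # 10/15
#' @export
rand_index <- function(y, c, noise = "singleton") {
  lp <- prepare_labels(y, c, noise)
  if (length(lp$y) < 2L) dc_stop("rand_index needs at least 2 samples")
  pc <- pair_confusion(lp$y, lp$c)
  (pc$TP + pc$TN) / pc$total
}

#' Adjusted Rand index
#'
#' The Rand index corrected for chance under the permutation model with fixed
#' cluster-size marginals; 1 for identical partitions, ~0 for independent
#' labelings, can be negative. Degenerate case (both partitions a single
#' cluster) is defined as 1.
#'
#' @inheritParams nmi
#' @return A number in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(y, c, noise = "singleton") {
  lp <- prepare_labels(y, c, noise)
  if (length(lp$y) < 2L) dc_stop("adjusted_rand_index needs at least 2 samples")
  tab <- contingency_table(lp$y, lp$c)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions degenerate
  (sum_ij - expected) / (max_index - expected)
}

#' Unsupervised clustering accuracy
#'
#' Best achievable label-match fraction over all one-to-one mappings `m`
#' between predicted clusters and ground-truth classes:
#' `ACC = max_m (1/n) * sum_i 1{y_i = m(c_i)}`, solved exactly with the
#' Hungarian algorithm on the (square-padded) negated contingency table.
#'
#' @inheritParams nmi
#' @return A number in `(0, 1]`; invariant to any relabeling of `c`.
#' @examples
#' unsupervised_accuracy(c(0, 1, 0, 1), c(0, 0, 0, 1))  # 0.75
#' @export
unsupervised_accuracy <- function(y, c, noise = "singleton") {
  lp <- prepare_labels(y, c, noise)
  tab <- unclass(contingency_table(lp$y, lp$c))
  n <- sum(tab)
  k <- max(dim(tab))
  counts <- matrix(0, k, k)
  counts[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  # maximize matched counts == minimize (max - counts)
  m <- solve_assignment(max(counts) - counts)
  sum(counts[cbind(seq_len(k), m)]) / n
}

#' Homogeneity and completeness
#'
#' Conditional-entropy criteria: homogeneity `= 1 - H(y|c)/H(y)` is 1 when
#' every cluster contains members of a single class; completeness
#' `= 1 - H(c|y)/H(c)` is 1 when all members of each class land in one
#' cluster. Each is defined as 1 when its reference entropy is 0.
#'
#' @inheritParams nmi
#' @return Named numeric vector `c(homogeneity =, completeness =)`.
#' @export
homogeneity_completeness <- function(y, c, noise = "singleton") {
  lp <- prepare_labels(y, c, noise)
  tab <- contingency_table(lp$y, lp$c)
  n <- sum(tab)
  hy <- entropy_nats(rowSums(tab))
  hc <- entropy_nats(colSums(tab))
  # H(y|c) = sum_c p(c) H(y | C = c)
  h_y_given_c <- sum(apply(tab, 2, function(col) sum(col) / n * entropy_nats(col)))
  h_c_given_y <- sum(apply(tab, 1, function(row) sum(row) / n * entropy_nats(row)))
  hom <- if (hy == 0) 1 else 1 - h_y_given_c / hy
  com <- if (hc == 0) 1 else 1 - h_c_given_y / hc
  c(homogeneity = min(max(hom, 0), 1), completeness = min(max(com, 0), 1))
}

#' Generalizability ratio
#'
#' `G = L_train / L_validation`. Values well below 1 (training loss much
#' smaller than validation loss) indicate overfitting of the representation.
#'
#' @param l_train Training loss (non-negative).
#' @param l_validation Validation loss (strictly positive).
#' @return The ratio `G`.
#' @export
generalizability <- function(l_train, l_validation) {
  l_train <- check_number(l_train, "l_train", min = 0)
  l_validation <- check_number(l_validation, "l_validation", min = 0, strict_min = TRUE)
  l_train / l_validation
}

#' Within-cluster sum of squares
#'
#' `WCSS = sum_i || z_i - centroid(label_i) ||^2`, the Elbow method's cost.
#' Noise points (label `-1`) are skipped.
#'
#' @param z Numeric matrix of points (rows = samples).
#' @param labels Integer cluster label per row; every non-noise label must
#'   index a centroid row (0-based labels map to centroid rows 1-based).
#' @param centroids Numeric matrix of centroids (rows = clusters).
#' @return Non-negative scalar.
#' @export
wcss <- function(z, labels, centroids) {
  z <- check_matrix(z, "z")
  centroids <- check_matrix(centroids, "centroids")
  labels <- as.integer(labels)
  if (length(labels) != nrow(z)) dc_stop("`labels` length must match rows of `z`")
  keep <- labels != -1L
  if (!all(labels[keep] >= 0L & labels[keep] < nrow(centroids))) {
    dc_stop("label without a matching centroid")
  }
  if (!any(keep)) return(0)
  d <- z[keep, , drop = FALSE] - centroids[labels[keep] + 1L, , drop = FALSE]
  sum(d^2)
}

#' Elbow rule for selecting the number of clusters
#'
#' Given WCSS at contiguous values of K, returns the interior K maximizing
#' the discrete second difference `WCSS(K-1) - 2 WCSS(K) + WCSS(K+1)` (the
#' knee). Ties break toward smaller K.
#'
#' @param wcss_by_k Named numeric vector: names are K values (contiguous
#'   integers), values are WCSS.
#' @return The selected K (integer).
#' @examples
#' elbow_select(c(`2` = 100, `3` = 20, `4` = 18, `5` = 17))  # 3
#' @export
elbow_select <- function(wcss_by_k) {
  if (length(wcss_by_k) < 3L) dc_stop("elbow_select needs at least 3 K values")
  ks <- as.integer(names(wcss_by_k))
  if (anyNA(ks)) dc_stop("`wcss_by_k` must have integer K names")
  o <- order(ks)
  ks <- ks[o]
  w <- as.numeric(wcss_by_k[o])
  if (!all(diff(ks) == 1L)) dc_stop("K values must be contiguous")
  second_diff <- w[-c(1L, length(w))] * -2 + w[-c(length(w) - 1L, length(w))] +
    w[-c(1L, 2L)]
  ks[-c(1L, length(ks))][which.max(second_diff)]
}

#' Full metrics report for a clustering run
#'
#' Convenience wrapper computing every external metric at once.
#'
#' @inheritParams nmi
#' @return A list of class `"deepclust_metrics"` with elements `acc`, `nmi`,
#'   `ri`, `ari`, `homogeneity`, `completeness`.
#' @export
metrics_report <- function(y, c, noise = "singleton") {
  hc <- homogeneity_completeness(y, c, noise)
  structure(list(
    acc = unsupervised_accuracy(y, c, noise),
    nmi = nmi(y, c, noise),
    ri = rand_index(y, c, noise),
    ari = adjusted_rand_index(y, c, noise),
    homogeneity = unname(hc["homogeneity"]),
    completeness = unname(hc["completeness"])
  ), class = "deepclust_metrics")
}

#' @export
print.deepclust_metrics <- function(x, ...) {
  cat("Clustering quality:\n")
  for (k in names(x)) cat(sprintf("  %-13s %.4f\n", k, x[[k]]))
  invisible(x)
}
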