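#' Synthetic labeled datasets with planted cluster structure
#'
#' @description
#' Seeded generators producing datasets whose ground truth is unambiguous,
#' so every downstream stage (representation learning, cluster hardening,
#' metrics) can be tested without external downloads. Class-conditional
#' structure is always planted in disjoint feature blocks (latent Gaussian
#' components, signature-gene blocks, texture families, vocabulary ranges).
#' Every generator is a pure function of its parameters and `seed`:
#' regenerating with identical arguments reproduces values bit-identically.
#'
#' @name synthetic_data
NULL

new_labeled_dataset <- function(values, labels, modality, seed, generator_params) {
  structure(list(values = values, labels = as.integer(labels),
                 modality = modality, seed = as.integer(seed),
                 generator_params = generator_params),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  n <- if (is.list(x$values) && !is.data.frame(x$values)) length(x$values)
       else dim(x$values)[1L]
  cat(sprintf("<labeled_dataset: %s>  n=%d  classes=%d  seed=%d\n",
              x$modality, n, length(unique(x$labels)), x$seed))
  invisible(x)
}

#' Gaussian latent blobs pushed through a random nonlinear map
#'
#' Draws `n_clusters` Gaussian components in a `latent_dim`-dimensional
#' latent space, with centroids scaled so that the minimum pairwise centroid
#' distance is `separation * noise_sd` (or `separation` alone when
#' `noise_sd = 0`), then maps points to `ambient_dim` dimensions through a
#' fixed random orthonormal linear map followed by the elementwise
#' nonlinearity `g(x) = x + tanh(x)`. The map is bi-Lipschitz (the slope of
#' `g` lies in `(1, 2)`), so the planted cluster separation survives in the
#' ambient space — the invariant every downstream recovery test relies on —
#' while the embedding stays genuinely nonlinear. `map = "identity"` skips
#' the map; it requires `ambient_dim == latent_dim`.
#'
#' @param n_per_class Samples per cluster.
#' @param n_clusters Number of clusters K (>= 2).
#' @param latent_dim Latent dimensionality.
#' @param ambient_dim Observed dimensionality (>= `latent_dim`).
#' @param separation Centroid spacing in units of `noise_sd`.
#' @param noise_sd Within-cluster standard deviation.
#' @param seed Integer seed.
#' @param map `"random"` (default) or `"identity"`.
#' @return A `labeled_dataset` (modality `"tabular"`); `generator_params`
#'   records the latent coordinates, centroids and the ambient map.
#' @export
make_blob_dataset <- function(n_per_class, n_clusters, latent_dim = 2,
                              ambient_dim = 10, separation = 8, noise_sd = 1,
                              seed = 1, map = c("random", "identity")) {
  n_per_class <- check_count(n_per_class, "n_per_class")
  n_clusters <- check_count(n_clusters, "n_clusters", min = 2L)
  latent_dim <- check_count(latent_dim, "latent_dim")
  ambient_dim <- check_count(ambient_dim, "ambient_dim")
  separation <- check_number(separation, "separation", min = 0, strict_min = TRUE)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  map <- match.arg(map)
  if (ambient_dim < latent_dim) dc_stop("`ambient_dim` must be >= `latent_dim`")
  if (map == "identity" && ambient_dim != latent_dim) {
    dc_stop("identity map requires ambient_dim == latent_dim")
  }
  target_sep <- separation * if (noise_sd > 0) noise_sd else 1

  with_seed(seed, {
    centroids <- matrix(stats::rnorm(n_clusters * latent_dim), n_clusters)
    min_d <- min(stats::dist(centroids))
    if (min_d == 0) centroids <- centroids + stats::rnorm(length(centroids), sd = 1e-3)
    centroids <- centroids * (target_sep / min(stats::dist(centroids)))
    labels <- rep(0:(n_clusters - 1L), each = n_per_class)
    n <- length(labels)
    latent <- centroids[labels + 1L, , drop = FALSE] +
      matrix(stats::rnorm(n * latent_dim, sd = noise_sd), n)
    if (map == "identity") {
      w <- diag(latent_dim)
      values <- latent
    } else {
      w <- qr.Q(qr(matrix(stats::rnorm(ambient_dim * latent_dim), ambient_dim)))
      proj <- latent %*% t(w)
      values <- proj + tanh(proj)
    }
  })
  colnames(values) <- sprintf("f%03d", seq_len(ncol(values)))
  new_labeled_dataset(values, labels, "tabular", seed,
                      list(centroids = centroids, latent = latent, map = w,
                           map_kind = map, separation = separation,
                           noise_sd = noise_sd))
}

#' FPKM-like expression matrix with signature-gene blocks
#'
#' Emulates an RNA-seq expression matrix with subtype structure: each
#' subtype up-regulates its own disjoint block of `n_signature` signature
#' genes (about +4 on the log2 scale); background genes carry
#' subtype-independent variation wide enough to pass the low-information
#' filter; and exactly `n_low_info` genes are constructed to FAIL the filter
#' (half near-zero expression, post-log mean < 0.4; half near-constant,
#' post-log SD < 0.75). Values are non-negative FPKM-like intensities; apply
#' [log_transform_expression()] before filtering or modeling.
#'
#' @param n_per_class Samples per subtype.
#' @param n_subtypes Number of subtypes (1 allowed: degenerate, no signature
#'   structure).
#' @param n_genes Total gene count.
#' @param n_signature Signature genes per subtype.
#' @param n_low_info Genes planted to fail the low-information filter.
#' @param seed Integer seed.
#' @return A `labeled_dataset` (modality `"expression"`); `generator_params`
#'   records `signature_genes` (per subtype), `low_info_genes` and the
#'   filter thresholds the low-information block is built against.
#' @export
make_expression_dataset <- function(n_per_class, n_subtypes = 3, n_genes = 200,
                                    n_signature = 10, n_low_info = 10, seed = 1) {
  n_per_class <- check_count(n_per_class, "n_per_class", min = 2L)
  n_subtypes <- check_count(n_subtypes, "n_subtypes")
  n_genes <- check_count(n_genes, "n_genes")
  n_signature <- check_count(n_signature, "n_signature")
  n_low_info <- check_count(n_low_info, "n_low_info", min = 0L)
  if (n_signature * n_subtypes + n_low_info > n_genes) {
    dc_stop("n_signature * n_subtypes + n_low_info exceeds n_genes")
  }
  mean_min <- 0.4; sd_min <- 0.75
  n <- n_per_class * n_subtypes
  labels <- rep(0:(n_subtypes - 1L), each = n_per_class)

  with_seed(seed, {
    # gene index bookkeeping: signature blocks first, then low-info, then background
    sig_idx <- split(seq_len(n_signature * n_subtypes),
                     rep(seq_len(n_subtypes), each = n_signature))
    low_idx <- if (n_low_info > 0) n_signature * n_subtypes + seq_len(n_low_info) else integer(0)

    # log2-scale baseline per gene, wide sample noise so background passes the filter
    base_mean <- stats::runif(n_genes, 2, 6)
    base_sd <- stats::runif(n_genes, 1.1, 1.6)
    logv <- matrix(stats::rnorm(n * n_genes), n) *
      rep(base_sd, each = n) + rep(base_mean, each = n)
    # subtype up-regulation of the signature block
    if (n_subtypes > 1) {
      for (s in seq_len(n_subtypes)) {
        logv[labels == s - 1L, sig_idx[[s]]] <- logv[labels == s - 1L, sig_idx[[s]]] + 4
      }
    }
    # deterministic fix-up: guarantee informative genes pass the filter even
    # under unlucky sampling (spread about the mean, floor the mean)
    keep_cols <- setdiff(seq_len(n_genes), low_idx)
    for (g in keep_cols) {
      m <- mean(logv[, g]); s_ <- stats::sd(logv[, g])
      if (s_ < sd_min + 0.15) {
        logv[, g] <- m + (logv[, g] - m) * ((sd_min + 0.2) / max(s_, 1e-8))
      }
      if (mean(logv[, g]) < mean_min + 0.2) {
        logv[, g] <- logv[, g] + (mean_min + 0.3 - mean(logv[, g]))
      }
    }
    values <- pmax(2^logv - 1, 0)
    # planted low-information genes: half near-silent, half near-constant
    if (n_low_info > 0) {
      n_silent <- ceiling(n_low_info / 2)
      for (j in seq_along(low_idx)) {
        g <- low_idx[j]
        if (j <= n_silent) {
          values[, g] <- stats::runif(n, 0, 0.2)        # post-log mean <= log2(1.2) < 0.4
        } else {
          values[, g] <- 10 + stats::runif(n, 0, 0.5)   # post-log SD ~ 0.02 < 0.75
        }
      }
    }
  })
  colnames(values) <- sprintf("gene%04d", seq_len(n_genes))
  new_labeled_dataset(values, labels, "expression", seed,
                      list(signature_genes = if (n_subtypes > 1) sig_idx else list(),
                           low_info_genes = low_idx,
                           mean_min = mean_min, sd_min = sd_min))
}

#' Class-textured image set
#'
#' Small procedural RGB images (`[0, 1]` intensities, channels-last) in
#' which each class carries a distinct texture family (horizontal stripes,
#' vertical stripes, checkerboard, blobs, diagonal gradient — cycled) on a
#' class-specific base intensity, so classes are separable by local pixel
#' statistics. `generator_params$class_mean_margin` records the smallest
#' between-class difference of mean intensity.
#'
#' @param n_per_class Images per class.
#' @param n_classes Number of classes.
#' @param height,width Image size in pixels (>= 16).
#' @param seed Integer seed.
#' @return A `labeled_dataset` (modality `"image"`) whose `values` is an
#'   array of shape `(n_per_class * n_classes, height, width, 3)`.
#' @export
make_image_dataset <- function(n_per_class, n_classes = 3, height = 64,
                               width = 64, seed = 1) {
  n_per_class <- check_count(n_per_class, "n_per_class")
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  height <- check_count(height, "height", min = 16L)
  width <- check_count(width, "width", min = 16L)
  n <- n_per_class * n_classes
  labels <- rep(0:(n_classes - 1L), each = n_per_class)
  values <- array(0, c(n, height, width, 3L))
  ii <- matrix(seq_len(height), height, width)
  jj <- matrix(seq_len(width), height, width, byrow = TRUE)

  with_seed(seed, {
    base <- seq(0.2, 0.8, length.out = n_classes)
    for (img in seq_len(n)) {
      k <- labels[img]
      fam <- k %% 5L
      period <- 4L + k %/% 5L
      pattern <- switch(as.character(fam),
        "0" = (ii %/% period) %% 2L,
        "1" = (jj %/% period) %% 2L,
        "2" = ((ii %/% period) + (jj %/% period)) %% 2L,
        "3" = {
          cx <- stats::runif(1, 0.25, 0.75) * height
          cy <- stats::runif(1, 0.25, 0.75) * width
          1 * (((ii - cx)^2 + (jj - cy)^2) < (min(height, width) / 4)^2)
        },
        "4" = ((ii + jj) %/% period) %% 2L
      )
      for (ch in 1:3) {
        noise <- matrix(stats::rnorm(height * width, sd = 0.03), height)
        channel_gain <- 0.8 + 0.1 * ch / 3
        px <- base[k + 1L] * channel_gain + 0.15 * pattern + noise
        values[img, , , ch] <- pmin(pmax(px, 0), 1)
      }
    }
  })
  class_means <- vapply(0:(n_classes - 1L),
                        function(k) mean(values[labels == k, , , , drop = FALSE]),
                        numeric(1))
  margin <- min(abs(outer(class_means, class_means, "-"))[upper.tri(diag(n_classes))])
  new_labeled_dataset(values, labels, "image", seed,
                      list(class_means = class_means, class_mean_margin = margin))
}

#' Token sequences with class-specific vocabulary blocks
#'
#' Three classes of variable-length token sequences: each class draws 80% of
#' its tokens from its own disjoint vocabulary block and 20% from a shared
#' block; token id 0 is reserved for padding. Ratings (1-10) are sampled so
#' that the rating-to-polarity thresholds reproduce the class labels exactly
#' (class 0: ratings 1-4, class 1: 5-7, class 2: 8-10).
#'
#' @param n_per_class Documents per class.
#' @param vocab_size Vocabulary size (>= 30 so each class gets its own block).
#' @param max_length Maximum sequence length (lengths vary in
#'   `[3, max_length]`, or are all 1 when `max_length = 1`).
#' @param seed Integer seed.
#' @return A list of class `"sequence_dataset"` with `token_ids` (list of
#'   integer vectors), `ratings`, `labels`, `vocab_size`, `seed`,
#'   `generator_params`.
#' @export
make_text_dataset <- function(n_per_class, vocab_size = 60, max_length = 20,
                              seed = 1) {
  n_per_class <- check_count(n_per_class, "n_per_class")
  vocab_size <- check_count(vocab_size, "vocab_size")
  max_length <- check_count(max_length, "max_length")
  if (vocab_size < 30L) dc_stop("`vocab_size` must be >= 30 (3 class blocks of >= 10)")
  n_classes <- 3L
  n <- n_per_class * n_classes
  labels <- rep(0:(n_classes - 1L), each = n_per_class)
  block <- (vocab_size * 3L) %/% 4L %/% n_classes   # per-class block width
  shared_lo <- block * n_classes + 1L

  with_seed(seed, {
    token_ids <- vector("list", n)
    ratings <- integer(n)
    rating_range <- list(1:4, 5:7, 8:10)
    for (i in seq_len(n)) {
      k <- labels[i]
      len <- if (max_length == 1L) 1L else {
        lo <- if (max_length > 4L) 3L else 1L
        sample(lo:max_length, 1L)
      }
      own <- (k * block + 1L):((k + 1L) * block)
      shared <- shared_lo:vocab_size
      from_own <- stats::runif(len) < 0.8
      toks <- integer(len)
      toks[from_own] <- sample(own, sum(from_own), replace = TRUE)
      toks[!from_own] <- sample(shared, sum(!from_own), replace = TRUE)
      token_ids[[i]] <- toks
      ratings[i] <- sample(rating_range[[k + 1L]], 1L)
    }
  })
  structure(list(token_ids = token_ids, ratings = ratings,
                 labels = as.integer(labels), vocab_size = vocab_size,
                 max_length = max_length, seed = as.integer(seed),
                 generator_params = list(block_width = block,
                                         shared_block = c(shared_lo, vocab_size))),
            class = "sequence_dataset")
}

#' @export
print.sequence_dataset <- function(x, ...) {
  cat(sprintf("<sequence_dataset>  n=%d  vocab=%d  classes=%d  seed=%d\n",
              length(x$token_ids), x$vocab_size, length(unique(x$labels)), x$seed))
  invisible(x)
}
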