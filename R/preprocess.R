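#' Log-transform FPKM expression values
#'
#' Replaces each entry of a non-negative expression matrix by
#' `log2(value + 1)`, modeling proportional rather than additive expression
#' changes. Shape and dimnames are preserved.
#'
#' @param fpkm Non-negative numeric matrix (samples x genes).
#' @return Matrix of the same shape.
#' @examples
#' log_transform_expression(matrix(c(0, 1, 3, 7), 2))
#' @export
log_transform_expression <- function(fpkm) {
  fpkm <- check_matrix(fpkm, "fpkm")
  if (any(fpkm < 0)) dc_stop("FPKM values must be non-negative")
  log2(fpkm + 1)
}

#' Filter genes with low information burden
#'
#' Removes features whose post-log mean or sample standard deviation falls
#' below the thresholds: a gene is KEPT iff `mean >= mean_min` AND
#' `sd >= sd_min` (equivalently, removed when `mean < mean_min` OR
#' `sd < sd_min`). The SD uses the n-1 denominator, the standard convention
#' for expression QC. Filtering is idempotent.
#'
#' @param logged Log-transformed expression matrix (>= 2 samples, so the SD
#'   is defined).
#' @param mean_min Mean threshold (default 0.4).
#' @param sd_min SD threshold (default 0.75).
#' @return List with `values` (the matrix restricted to kept genes) and
#'   `report`, a `"filter_report"` carrying `kept_mask`, `per_feature_mean`,
#'   `per_feature_sd` and the thresholds.
#' @export
filter_low_information_genes <- function(logged, mean_min = 0.4, sd_min = 0.75) {
  logged <- check_matrix(logged, "logged")
  if (nrow(logged) < 2L) dc_stop("at least 2 samples required (SD undefined)")
  mean_min <- check_number(mean_min, "mean_min")
  sd_min <- check_number(sd_min, "sd_min")
  mu <- colMeans(logged)
  sd_ <- apply(logged, 2L, stats::sd)
  kept <- mu >= mean_min & sd_ >= sd_min
  report <- structure(list(kept_mask = kept, per_feature_mean = mu,
                           per_feature_sd = sd_,
                           thresholds = c(mean_min = mean_min, sd_min = sd_min)),
                      class = "filter_report")
  list(values = logged[, kept, drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> kept %d / %d genes (mean >= %.2f & SD >= %.2f)\n",
              sum(x$kept_mask), length(x$kept_mask),
              x$thresholds["mean_min"], x$thresholds["sd_min"]))
  invisible(x)
}

#' Map a 10-star rating to a sentiment polarity label
#'
#' Ratings up to and including 4 are negative, 5-7 neutral, 8 and above
#' positive. The three bands partition 1..10 with no gaps or overlaps.
#'
#' @param rating Integer vector with values in 1..10.
#' @return Factor with levels `negative`, `neutral`, `positive`.
#' @examples
#' rating_to_polarity(c(4, 5, 7, 8, 10))
#' @export
rating_to_polarity <- function(rating) {
  if (!is.numeric(rating) || anyNA(rating) ||
      any(rating < 1 | rating > 10 | rating != floor(rating))) {
    dc_stop("`rating` must contain integers in 1..10")
  }
  cut(rating, breaks = c(0, 4, 7, 10),
      labels = c("negative", "neutral", "positive"))
}

#' Per-sample latent normalization statistic
#'
#' Diagnostic for the assumption that cluster-hardening input is normalized:
#' returns `(1/d) * ||z_i||^2` for each row of Z, which should sit near 1
#' for well-scaled latent spaces. A diagnostic only, not a transform.
#'
#' @param z Latent matrix (n x d, d >= 1, n >= 1).
#' @return Numeric vector of length n.
#' @examples
#' latent_norm_statistic(rbind(c(3, 4)))  # 12.5
#' @export
latent_norm_statistic <- function(z) {
  z <- check_matrix(z, "z")
  if (nrow(z) == 0L || ncol(z) == 0L) dc_stop("`z` must be non-empty")
  rowSums(z^2) / ncol(z)
}

#' Rescale an image to a target size
#'
#' Bilinear interpolation on a channels-last `[0, 1]` image (height x width
#' x channels, row-major with top-left origin). Grayscale matrices are
#' treated as a single channel and returned as height x width x 1.
#'
#' @param image Numeric array `h x w x c` (or matrix `h x w`).
#' @param target_hw Integer vector `c(height, width)`.
#' @return Array `target_h x target_w x c` with intensities still in `[0, 1]`.
#' @export
rescale_image <- function(image, target_hw) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (!is.array(image) || length(dim(image)) != 3L || !is.numeric(image)) {
    dc_stop("`image` must be a numeric h x w x c array")
  }
  th <- check_count(target_hw[1L], "target height")
  tw <- check_count(target_hw[2L], "target width")
  d <- dim(image)
  if (th == d[1L] && tw == d[2L]) return(image)
  # sample positions of output pixel centres in input coordinates
  yi <- if (th == 1L) rep(1, 1L) else seq(1, d[1L], length.out = th)
  xi <- if (tw == 1L) rep(1, 1L) else seq(1, d[2L], length.out = tw)
  y0 <- pmin(floor(yi), d[1L] - 1L); x0 <- pmin(floor(xi), d[2L] - 1L)
  if (d[1L] == 1L) y0 <- rep(1, th)
  if (d[2L] == 1L) x0 <- rep(1, tw)
  wy <- yi - y0; wx <- xi - x0
  out <- array(0, c(th, tw, d[3L]))
  for (ch in seq_len(d[3L])) {
    sl <- image[, , ch]
    y1 <- pmin(y0 + 1L, d[1L]); x1 <- pmin(x0 + 1L, d[2L])
    a <- sl[y0, x0, drop = FALSE]; b <- sl[y0, x1, drop = FALSE]
    cc <- sl[y1, x0, drop = FALSE]; dd <- sl[y1, x1, drop = FALSE]
    top <- a * (1 - wx)[col(a)] + b * wx[col(b)]
    bot <- cc * (1 - wx)[col(cc)] + dd * wx[col(dd)]
    out[, , ch] <- top * (1 - wy)[row(top)] + bot * wy[row(bot)]
  }
  pmin(pmax(out, 0), 1)
}

#' Build a token embedding table
#'
#' Randomly initialized Gaussian embedding table over a vocabulary (token id
#' 0 is the padding token and maps to the zero vector). User-supplied
#' vectors in word2vec text format can be loaded with [read_word2vec()] and
#' passed to [vectorize_tokens()] instead.
#'
#' @param vocab_size Number of real tokens (ids 1..vocab_size).
#' @param embed_dim Embedding width (default 300).
#' @param seed Integer seed.
#' @return `(vocab_size + 1) x embed_dim` matrix; row 1 is the padding row.
#' @export
make_embedding <- function(vocab_size, embed_dim = 300, seed = 1) {
  vocab_size <- check_count(vocab_size, "vocab_size")
  embed_dim <- check_count(embed_dim, "embed_dim")
  tab <- with_seed(seed,
    matrix(stats::rnorm((vocab_size + 1L) * embed_dim, sd = 0.1),
           vocab_size + 1L, embed_dim))
  tab[1L, ] <- 0
  tab
}

#' Read word vectors in word2vec text format
#'
#' First line `"<n> <dim>"`, then one token per line: `token v1 v2 ... vdim`.
#'
#' @param path File path.
#' @return List with `tokens` (character) and `vectors` (n x dim matrix).
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) dc_stop("word2vec file too short")
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  parts <- strsplit(trimws(lines[-1L]), "\\s+")
  tokens <- vapply(parts, `[[`, character(1), 1L)
  vectors <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(hdr[2L])))
  list(tokens = tokens, vectors = vectors)
}

#' Embed token sequences as real-vector sequences
#'
#' Maps every document of a [make_text_dataset()]-style corpus to a sequence
#' of `embed_dim`-dimensional vectors through an embedding table (trainable/
#' random by default; supply `embedding` for pretrained vectors). Optional
#' padding/truncation to `pad_to` timesteps uses the reserved token id 0,
#' whose embedding is the zero vector; the applied length is recorded in the
#' result's `"pad_to"` attribute.
#'
#' @param corpus A `"sequence_dataset"`.
#' @param embed_dim Embedding width (default 300).
#' @param embedding Optional `(vocab_size + 1) x embed_dim` table.
#' @param pad_to Optional fixed length.
#' @param seed Seed for the random table when `embedding` is NULL.
#' @return List of `L x embed_dim` matrices, one per document.
#' @export
vectorize_tokens <- function(corpus, embed_dim = 300, embedding = NULL,
                             pad_to = NULL, seed = 1) {
  if (!inherits(corpus, "sequence_dataset")) dc_stop("`corpus` must be a sequence_dataset")
  if (is.null(embedding)) {
    embedding <- make_embedding(corpus$vocab_size, embed_dim, seed)
  }
  if (nrow(embedding) < corpus$vocab_size + 1L) {
    dc_stop("embedding table smaller than vocabulary")
  }
  out <- lapply(corpus$token_ids, function(toks) {
    if (length(toks) == 0L) dc_stop("empty document")
    if (any(toks < 0L | toks >= corpus$vocab_size + 1L)) {
      dc_stop("token id outside [0, vocab_size)")
    }
    if (!is.null(pad_to)) {
      toks <- if (length(toks) >= pad_to) toks[seq_len(pad_to)]
              else c(toks, rep(0L, pad_to - length(toks)))
    }
    embedding[toks + 1L, , drop = FALSE]
  })
  attr(out, "pad_to") <- pad_to
  out
}
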