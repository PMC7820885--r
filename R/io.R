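#' Read a delimited sample-by-feature matrix
#'
#' Expects a header row of feature ids and a first column of sample ids; an
#' optional `label` column is extracted and removed from the values. The
#' delimiter is auto-detected among tab and comma and recorded in the
#' result.
#'
#' @param path File path.
#' @return List with `values` (numeric matrix, rownames = sample ids),
#'   `sample_ids`, `labels` (or NULL) and `delimiter`.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) dc_stop("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) dc_stop("empty file: %s", path)
  delim <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = delim, check.names = FALSE,
                          stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(df) == 0L || ncol(df) < 2L) dc_stop("matrix file has no data: %s", path)
  sample_ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  labels <- NULL
  lab_col <- which(tolower(names(df)) == "label")
  if (length(lab_col) == 1L) {
    labels <- as.integer(df[[lab_col]])
    df <- df[, -lab_col, drop = FALSE]
  }
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v) & !anyNA(df[[j]])) {
      bad <- which(is.na(v))[1L]
      dc_stop("non-numeric cell at row %d, column '%s'", bad, names(df)[j])
    }
    if (anyNA(v)) dc_stop("missing value in column '%s'", names(df)[j])
    df[[j]] <- v
  }
  values <- as.matrix(df)
  rownames(values) <- sample_ids
  list(values = values, sample_ids = sample_ids, labels = labels,
       delimiter = delim)
}

#' Write a sample-by-feature matrix as delimited text
#'
#' Inverse of [read_matrix()]: first column `sample_id`, then feature
#' columns, then an optional `label` column.
#'
#' @param values Numeric matrix (rownames used as sample ids when present).
#' @param path Output path.
#' @param labels Optional integer labels.
#' @param delimiter `"\t"` (default) or `","`.
#' @export
write_matrix <- function(values, path, labels = NULL, delimiter = "\t") {
  values <- check_matrix(values, "values")
  ids <- rownames(values)
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(nrow(values)))
  df <- data.frame(sample_id = ids, values, check.names = FALSE)
  if (!is.null(labels)) df$label <- as.integer(labels)
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a directory of images
#'
#' Reads PNG/TIFF images as a channels-last float tensor in `[0, 1]`.
#' Grayscale images broadcast to 3 channels; alpha channels are dropped.
#' Ordering follows the manifest when given (TSV with columns `filename`
#' and `label`), otherwise lexicographic filename order.
#'
#' @param path Directory of `.png`/`.tif`/`.tiff` files.
#' @param manifest Optional manifest TSV path.
#' @param rescale_to Optional `c(height, width)`; required when the images
#'   have mixed sizes.
#' @return A `labeled_dataset` (modality `"image"`); labels are from the
#'   manifest or all zero.
#' @export
read_image_dir <- function(path, manifest = NULL, rescale_to = NULL) {
  if (!dir.exists(path)) dc_stop("directory not found: %s", path)
  if (!is.null(manifest)) {
    mf <- utils::read.table(manifest, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    files <- file.path(path, mf$filename)
    labels <- as.integer(mf$label)
  } else {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    labels <- rep(0L, length(files))
  }
  if (length(files) == 0L) dc_stop("no images found in %s", path)
  imgs <- lapply(files, function(f) {
    if (!file.exists(f)) dc_stop("unreadable image: %s", f)
    img <- tryCatch({
      if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
      else tiff::readTIFF(f)
    }, error = function(e) dc_stop("unreadable image: %s (%s)", f, conditionMessage(e)))
    if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
    if (dim(img)[3L] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
    if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]
    if (!is.null(rescale_to)) img <- rescale_image(img, rescale_to)
    img
  })
  sizes <- vapply(imgs, function(i) dim(i)[1:2], integer(2))
  if (any(sizes[1, ] != sizes[1, 1]) || any(sizes[2, ] != sizes[2, 1])) {
    dc_stop("images have mixed sizes; pass `rescale_to = c(h, w)`")
  }
  h <- sizes[1, 1]; w <- sizes[2, 1]
  values <- array(0, c(length(imgs), h, w, 3L))
  for (i in seq_along(imgs)) values[i, , , ] <- imgs[[i]]
  new_labeled_dataset(values, labels, "image", 0L,
                      list(files = basename(files)))
}

#' Save / load a backbone checkpoint
#'
#' Single-file native container (RDS) embedding the spec, parameters and
#' input shape.
#'
#' @param model A `"backbone"`.
#' @param path Checkpoint path.
#' @return `load_backbone` returns the model.
#' @export
save_backbone <- function(model, path) {
  if (!inherits(model, "backbone")) dc_stop("`model` must be a backbone")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_backbone
#' @export
load_backbone <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "backbone")) dc_stop("not a backbone checkpoint: %s", path)
  model
}

#' Write the full output bundle of a clustering run
#'
#' Writes, into `out_dir`: `labels.tsv` (sample_id, label), `q_matrix.tsv`,
#' `centroids.tsv`, `loss_history.csv` (iteration, L_AE, L_KLD, combined,
#' pct_changed), `metrics.json` (when ground truth supplied), `config.json`
#' (the fully resolved configuration, so a re-run reproduces the outputs
#' for deterministic stages), and `run_log.txt`.
#'
#' @param fit A `"deep_clustering_fit"`.
#' @param out_dir Output directory (created if needed).
#' @param sample_ids Optional sample ids (default `s0001`, ...).
#' @param truth Optional ground-truth labels for the metrics report.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(fit, out_dir, sample_ids = NULL, truth = NULL) {
  if (!inherits(fit, "deep_clustering_fit")) {
    dc_stop("`fit` must be a deep_clustering_fit")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) dc_stop("cannot create output directory %s", out_dir)
  n <- length(fit$labels)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(n))
  paths <- c(
    labels = file.path(out_dir, "labels.tsv"),
    q = file.path(out_dir, "q_matrix.tsv"),
    centroids = file.path(out_dir, "centroids.tsv"),
    loss = file.path(out_dir, "loss_history.csv"),
    config = file.path(out_dir, "config.json"),
    log = file.path(out_dir, "run_log.txt")
  )
  utils::write.table(data.frame(sample_id = sample_ids, label = fit$labels),
                     paths["labels"], sep = "\t", quote = FALSE, row.names = FALSE)
  q <- fit$state$Q
  colnames(q) <- sprintf("q%d", seq_len(ncol(q)) - 1L)
  utils::write.table(data.frame(sample_id = sample_ids, q), paths["q"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cen <- fit$state$centroids
  utils::write.table(data.frame(cluster = seq_len(nrow(cen)) - 1L, cen),
                     paths["centroids"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(fit$loss_history, paths["loss"], row.names = FALSE)
  cfg <- unclass(fit$config)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    paths <- c(paths, metrics = file.path(out_dir, "metrics.json"))
    m <- metrics_report(truth, fit$labels)
    jsonlite::write_json(c(unclass(m), list(G = fit$G)), paths["metrics"],
                         auto_unbox = TRUE, digits = NA)
  }
  log_lines <- c(
    sprintf("deepclust run: K=%d n=%d", fit$state$K, n),
    sprintf("sigma=%g tol=%g%% update_interval=%d seed=%d",
            fit$config$sigma, fit$config$tol, fit$config$update_interval,
            fit$config$seed),
    sprintf("iterations_run=%d converged=%s G=%s", fit$iterations_run,
            fit$converged, format(fit$G)),
    utils::capture.output(print(fit$loss_history))
  )
  writeLines(log_lines, paths["log"])
  invisible(paths)
}
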