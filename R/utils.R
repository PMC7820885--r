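#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards. Every stochastic operation in
#' the package funnels through this helper so that identical (params, seed)
#' pairs reproduce results bit-identically.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Classed error helper: all argument-validation failures carry class
# "deepclust_invalid_argument" so callers and tests can catch them uniformly.
dc_stop <- function(msg, ..., class = "deepclust_invalid_argument") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    dc_stop("`%s` must be a single integer >= %d (got %s)", name, min,
            paste(format(x), collapse = ","))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    dc_stop("`%s` must be a single number", name)
  }
  if (x < min || x > max || (strict_min && x <= min)) {
    dc_stop("`%s` = %g is outside the allowed range", name, x)
  }
  as.numeric(x)
}

check_matrix <- function(x, name) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    dc_stop("`%s` must be a numeric matrix", name)
  }
  if (anyNA(x)) dc_stop("`%s` contains missing values", name)
  x
}

#' @keywords internal
relabel_from_zero <- function(labels) {
  # map arbitrary labels to 0..K-1 preserving first-appearance order;
  # noise label -1 is passed through untouched
  out <- integer(length(labels))
  noise <- labels == -1L
  u <- unique(labels[!noise])
  out[!noise] <- match(labels[!noise], u) - 1L
  out[noise] <- -1L
  out
}
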