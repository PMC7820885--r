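# Independent brute-force oracles for the metric suite. These never call the
# package's own implementations.

# All set partitions of n items into at most max_blocks blocks, as 0-based
# label vectors (restricted-growth-string enumeration).
enumerate_partitions <- function(n, max_blocks) {
  out <- list()
  recurse <- function(prefix, used) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (b in seq_len(min(used + 1L, max_blocks))) {
      recurse(c(prefix, b - 1L), max(used, b))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Rand index by explicit enumeration of all n(n-1)/2 pairs.
ri_pair_oracle <- function(y, c) {
  n <- length(y)
  agree <- 0L
  total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      total <- total + 1L
      same_y <- y[i] == y[j]
      same_c <- c[i] == c[j]
      if (same_y == same_c) agree <- agree + 1L
    }
  }
  agree / total
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

# Unsupervised accuracy by exhaustive search over all K! one-to-one
# cluster-to-class mappings (square-padded).
acc_brute_oracle <- function(y, c) {
  uy <- sort(unique(y))
  uc <- sort(unique(c))
  k <- max(length(uy), length(uc))
  counts <- matrix(0L, k, k)
  for (i in seq_along(y)) {
    counts[match(c[i], uc), match(y[i], uy)] <- counts[match(c[i], uc), match(y[i], uy)] + 1L
  }
  best <- 0L
  for (p in all_permutations(k)) {
    matched <- sum(counts[cbind(seq_len(k), p)])
    if (matched > best) best <- matched
  }
  best / length(y)
}

# NMI straight from the contingency-table definition with natural logs.
nmi_table_oracle <- function(y, c) {
  n <- length(y)
  uy <- sort(unique(y)); uc <- sort(unique(c))
  tab <- matrix(0, length(uy), length(uc))
  for (i in seq_len(n)) {
    tab[match(y[i], uy), match(c[i], uc)] <- tab[match(y[i], uy), match(c[i], uc)] + 1
  }
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hy <- ent(rowSums(tab) / n)
  hc <- ent(colSums(tab) / n)
  if (hy == 0 && hc == 0) return(1)
  mi <- 0
  for (a in seq_along(uy)) {
    for (b in seq_along(uc)) {
      pij <- tab[a, b] / n
      if (pij > 0) mi <- mi + pij * log(pij / ((sum(tab[a, ]) / n) * (sum(tab[, b]) / n)))
    }
  }
  mi / ((hy + hc) / 2)
}

# random label vector with at most k distinct values
random_labels <- function(n, k) sample.int(k, n, replace = TRUE) - 1L

# random valid soft-assignment state for property tests
random_cluster_state <- function(n, k, d) {
  z <- matrix(stats::rnorm(n * d), n)
  mu <- matrix(stats::rnorm(k * d), k)
  q <- soft_assign(z, mu)
  list(z = z, mu = mu, q = q)
}
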