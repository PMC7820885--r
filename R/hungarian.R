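#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the linear assignment problem for a square cost matrix: finds a
#' permutation `m` minimizing `sum(cost[i, m[i]])`. Used by
#' [unsupervised_accuracy()] to find the best one-to-one mapping between
#' predicted clusters and ground-truth classes.
#'
#' Implementation: the O(n^3) shortest-augmenting-path formulation with row
#' and column potentials.
#'
#' @param cost Square numeric cost matrix.
#' @return Integer vector `m` of length `nrow(cost)`; row `i` is assigned to
#'   column `m[i]`.
#' @examples
#' solve_assignment(matrix(c(4, 1, 3, 2, 0, 5, 3, 2, 2), 3, byrow = TRUE))
#' @export
solve_assignment <- function(cost) {
  cost <- check_matrix(cost, "cost")
  n <- nrow(cost)
  if (ncol(cost) != n) dc_stop("`cost` must be square")
  if (any(!is.finite(cost))) dc_stop("`cost` must be finite")

  # Columns are indexed 1..n+1 where column 1 is a virtual column; real
  # column j lives at index j+1. p[j] is the row matched to column j (0 = free).
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)
  way <- integer(n + 1L)

  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 1L:(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }

  m <- integer(n)
  for (j in 2L:(n + 1L)) m[p[j]] <- j - 1L
  m
}
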