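test_that("soft assignment follows the Student's-t kernel", {
  # equidistant point splits mass evenly
  q <- soft_assign(matrix(c(1, 0), 1), rbind(c(0, 0), c(2, 0)))
  expect_equal(as.numeric(q), c(0.5, 0.5))
  # direct kernel evaluation: (1+0)^-1 vs (1+4)^-1, normalized
  q <- soft_assign(matrix(c(0, 0), 1), rbind(c(0, 0), c(2, 0)))
  expect_equal(as.numeric(q), c(5 / 6, 1 / 6))
  # translation invariance: distances are all that matter
  set.seed(2)
  z <- matrix(rnorm(12), 4)
  mu <- matrix(rnorm(9), 3)
  shift <- matrix(rnorm(3), 1)
  expect_equal(soft_assign(z, mu),
               soft_assign(sweep(z, 2, -shift), sweep(mu, 2, -shift)),
               tolerance = 1e-12)
  # rows sum to one, entries strictly inside (0, 1)
  q <- soft_assign(z, mu)
  expect_equal(rowSums(q), rep(1, 4))
  expect_true(all(q > 0 & q < 1))
  expect_error(soft_assign(z, matrix(0, 2, 5)), "dimension")
})

test_that("target distribution squares and frequency-normalizes Q", {
  q <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.3, 0.7))
  p <- target_distribution(q)
  expect_equal(p, rbind(c(0.98182, 0.01818), c(0.6, 0.4), c(0.10909, 0.89091)),
               tolerance = 1e-4)
  expect_equal(rowSums(p), rep(1, 3))
  # single sample: P reduces to Q identically
  q1 <- matrix(c(0.25, 0.75), 1)
  expect_identical(target_distribution(q1), q1)
  # uniform Q stays uniform
  qu <- matrix(1 / 3, 5, 3)
  expect_equal(target_distribution(qu), qu)
  expect_error(target_distribution(rbind(c(1, 0), c(1, 0))), "zero cluster frequency")
})

test_that("squaring sharpens: row entropies of P do not exceed those of Q when frequencies are equal", {
  set.seed(8)
  ent <- function(m) -rowSums(m * log(m))
  for (r in 1:10) {
    # build a Q with exactly equal cluster frequencies by symmetrizing
    q <- random_cluster_state(6, 3, 2)$q
    q <- rbind(q, q[, c(2, 3, 1)], q[, c(3, 1, 2)])  # cyclic copies equalize colSums
    p <- target_distribution(q)
    expect_true(all(ent(p) <= ent(q) + 1e-12))
  }
})

test_that("KL divergence is non-negative, zero iff P = Q, with the ln-2 example", {
  expect_equal(kld_loss(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)), log(2))
  set.seed(4)
  for (r in 1:20) {
    st <- random_cluster_state(5, 3, 2)
    p <- target_distribution(st$q)
    expect_gte(kld_loss(p, st$q), 0)
    expect_equal(kld_loss(st$q, st$q), 0)
  }
  expect_error(kld_loss(matrix(c(1, 0), 1), matrix(c(0, 1), 1)), "infinite")
})

test_that("analytic clustering gradients match finite differences and sum to zero", {
  set.seed(21)
  for (r in 1:10) {
    n <- sample(2:8, 1); k <- sample(2:3, 1); d <- sample(1:4, 1)
    st <- random_cluster_state(n, k, d)
    p <- target_distribution(st$q)
    g <- clustering_gradients(st$z, st$mu, p, st$q)
    f <- function(flat) {
      z2 <- matrix(flat[1:(n * d)], n)
      mu2 <- matrix(flat[-(1:(n * d))], k)
      kld_loss(p, soft_assign(z2, mu2))
    }
    num <- numeric_gradient(f, c(as.numeric(st$z), as.numeric(st$mu)), h = 1e-6)
    ana <- c(as.numeric(g$dz), as.numeric(g$dmu))
    expect_lt(max(abs(ana - num)) / max(abs(num)), 1e-6)
    expect_lt(max(abs(colSums(g$dz) + colSums(g$dmu))), 1e-9)
  }
  # P = Q: the (p - q) factor kills every gradient exactly
  st <- random_cluster_state(4, 2, 2)
  g <- clustering_gradients(st$z, st$mu, st$q, st$q)
  expect_true(all(g$dz == 0) && all(g$dmu == 0))
})

test_that("combined loss is the sigma-weighted convex combination", {
  expect_equal(combined_loss(2, 4, 0), 4)
  expect_equal(combined_loss(2, 4, 1), 2)
  expect_equal(combined_loss(2, 4, 0.5), 3)
  expect_error(combined_loss(1, 1, 1.5), "outside the allowed range")
})

test_that("repeated KLD evaluation on the same state is bit-identical", {
  st <- random_cluster_state(6, 3, 2)
  p <- target_distribution(st$q)
  expect_identical(kld_loss(p, st$q), kld_loss(target_distribution(st$q), st$q))
})
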