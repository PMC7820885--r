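test_that("NMI matches hand-computed and limiting cases", {
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(nmi(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)       # relabeling
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)       # independent
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 0, 0, 1)), 0.343711, tolerance = 1e-6)
  expect_equal(nmi(c(0, 0, 0), c(1, 1, 1)), 1)             # both trivial
})

test_that("Rand index matches the pair-count example and bounds", {
  expect_equal(rand_index(c(0, 0, 0, 1, 1, 1), c(0, 0, 1, 1, 1, 1)), 10 / 15)
  expect_equal(rand_index(c(0, 1, 2), c(2, 0, 1)), 1)
  expect_equal(rand_index(c(0, 0), c(0, 1)), 0)            # single disagreeing pair
  expect_error(rand_index(0, 0), "at least 2")
})

test_that("ARI is 1 on identity, ~0 on random permutations, and chance-corrected", {
  y <- rep(0:2, each = 10)
  expect_equal(adjusted_rand_index(y, y), 1)
  expect_equal(adjusted_rand_index(y, (y + 1) %% 3), 1)
  set.seed(71)
  null_vals <- replicate(2000, adjusted_rand_index(y, sample(y)))
  expect_lt(abs(mean(null_vals)), 0.02)
  expect_equal(adjusted_rand_index(c(0, 0, 0), c(0, 0, 0)), 1)  # degenerate
})

test_that("unsupervised accuracy solves the best one-to-one mapping", {
  expect_equal(unsupervised_accuracy(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(unsupervised_accuracy(c(0, 1, 0, 1), c(0, 0, 0, 1)), 0.75)
  # more predicted clusters than classes and vice versa (padded matching)
  expect_equal(unsupervised_accuracy(c(0, 0, 1, 1), c(0, 1, 2, 2)), 0.75)
  expect_equal(unsupervised_accuracy(c(0, 1, 2, 2), c(0, 0, 1, 1)), 0.75)
})

test_that("homogeneity/completeness limiting cases and duality hold", {
  hc <- homogeneity_completeness(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(unname(hc), c(1, 1))
  hc <- homogeneity_completeness(c(0, 0, 1, 1), c(0, 0, 0, 0))
  expect_equal(unname(hc), c(0, 1))
  # singleton clusters: perfectly homogeneous; completeness is the
  # conditional-entropy ratio 1 - ln2/ln4 = 0.5 of the V-measure definition
  hc <- homogeneity_completeness(c(0, 0, 1, 1), c(0, 1, 2, 3))
  expect_equal(unname(hc), c(1, 0.5))
  set.seed(5)
  for (r in 1:20) {
    y <- random_labels(12, 3)
    c_ <- random_labels(12, 4)
    expect_equal(homogeneity_completeness(y, c_)[["homogeneity"]],
                 homogeneity_completeness(c_, y)[["completeness"]])
  }
})

test_that("label-pair metrics are invariant to bijective relabeling", {
  set.seed(11)
  for (r in 1:25) {
    n <- sample(5:15, 1)
    k <- sample(2:4, 1)
    y <- random_labels(n, k)
    c_ <- random_labels(n, k)
    perm <- sample.int(k) - 1L
    c2 <- perm[c_ + 1L]
    expect_equal(nmi(y, c_), nmi(y, c2))
    expect_equal(rand_index(y, c_), rand_index(y, c2))
    expect_equal(adjusted_rand_index(y, c_), adjusted_rand_index(y, c2))
    expect_equal(unsupervised_accuracy(y, c_), unsupervised_accuracy(y, c2))
  }
})

test_that("noise labels become singletons by default and can be dropped", {
  y <- c(0, 0, 1, 1, 1)
  c_ <- c(0, 0, 1, 1, -1)
  # singleton policy: the noise point is its own cluster, hurting completeness
  expect_lt(homogeneity_completeness(y, c_)[["completeness"]], 1)
  # drop policy: remaining points agree perfectly
  expect_equal(nmi(y, c_, noise = "drop"), 1)
  expect_equal(unsupervised_accuracy(y, c_, noise = "drop"), 1)
})

test_that("generalizability is the train/validation loss ratio", {
  expect_equal(generalizability(1, 1), 1)
  expect_equal(generalizability(0.5, 1.0), 0.5)
  expect_error(generalizability(1, 0), "outside the allowed range")
})

test_that("WCSS sums squared distances to own centroids", {
  z <- rbind(c(0, 0), c(2, 0))
  expect_equal(wcss(z, c(0, 0), rbind(c(1, 0))), 2)
  expect_equal(wcss(z, c(0, 1), z), 0)                      # K = n
  # splitting a cluster and refitting centroids never increases WCSS
  set.seed(3)
  z <- matrix(rnorm(40), 20)
  one <- wcss(z, rep(0L, 20), rbind(colMeans(z)))
  lab2 <- as.integer(z[, 1] > median(z[, 1]))
  cen2 <- rbind(colMeans(z[lab2 == 0, ]), colMeans(z[lab2 == 1, ]))
  expect_lte(wcss(z, lab2, cen2), one)
  expect_error(wcss(z, rep(3L, 20), cen2), "centroid")
})

test_that("elbow rule picks the max second difference with ties toward small K", {
  expect_equal(elbow_select(c(`2` = 100, `3` = 20, `4` = 18, `5` = 17)), 3)
  # linear decline: no curvature anywhere, tie broken at the smallest interior K
  expect_equal(elbow_select(c(`2` = 40, `3` = 30, `4` = 20, `5` = 10)), 3)
  # insertion order must not matter
  expect_equal(elbow_select(c(`4` = 18, `2` = 100, `5` = 17, `3` = 20)), 3)
  expect_error(elbow_select(c(`2` = 1, `3` = 2)), "at least 3")
})

test_that("the assignment solver matches exhaustive search on random costs", {
  set.seed(9)
  for (r in 1:30) {
    k <- sample(2:5, 1)
    cost <- matrix(runif(k * k), k)
    m <- solve_assignment(cost)
    got <- sum(cost[cbind(seq_len(k), m)])
    best <- min(vapply(all_permutations(k),
                       function(p) sum(cost[cbind(seq_len(k), p)]), numeric(1)))
    expect_equal(got, best)
    expect_equal(sort(m), seq_len(k))
  }
})

test_that("metrics_report aggregates all external metrics", {
  y <- rep(0:1, each = 5)
  m <- metrics_report(y, y)
  expect_s3_class(m, "deepclust_metrics")
  expect_true(all(unlist(m) == 1))
})
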