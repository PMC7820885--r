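blob600 <- function(seed) {
  make_blob_dataset(200, 3, latent_dim = 2, ambient_dim = 50, separation = 8,
                    noise_sd = 1, seed = seed)
}

small_dense <- function(d, seed) {
  build_backbone(backbone_spec("stacked_denoising", layer_sizes = c(64, 32),
                               latent_dim = 5), d, seed = seed)
}

test_that("centroid initialization handles the degenerate and separable cases", {
  z <- rbind(c(0, 0), c(10, 0), c(0, 10))
  for (alg in c("kmeans", "agglomerative", "gmm")) {
    cen <- init_centroids(z, 3, alg, seed = 1)
    expect_equal(cen[order(cen[, 1], cen[, 2]), ], z[order(z[, 1], z[, 2]), ])
  }
  # two well-separated pairs: 2-means optimum is the pair midpoints
  z <- rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0))
  cen <- init_centroids(z, 2, "kmeans", seed = 1)
  expect_equal(cen[order(cen[, 1]), ], rbind(c(0.5, 0), c(10.5, 0)))
  cen <- init_centroids(z, 2, "agglomerative", seed = 1)
  expect_equal(cen[order(cen[, 1]), ], rbind(c(0.5, 0), c(10.5, 0)))
  expect_identical(init_centroids(z, 2, "kmeans", seed = 3),
                   init_centroids(z, 2, "kmeans", seed = 3))
  expect_error(init_centroids(z, 5, "kmeans"), "exceeds")
  expect_error(init_centroids(z, 2, "dbscan"), "pipeline_cluster")
})

test_that("pipeline clustering recovers separable groups for every algorithm", {
  set.seed(6)
  z <- rbind(matrix(rnorm(60, 0, 0.3), 30), matrix(rnorm(60, 8, 0.3), 30))
  truth <- rep(0:1, each = 30)
  for (alg in c("kmeans", "agglomerative", "gmm")) {
    lab <- pipeline_cluster(z, alg, list(k = 2), seed = 2)
    expect_equal(unsupervised_accuracy(truth, lab), 1)
  }
  lab <- pipeline_cluster(z, "dbscan", list(eps = 1.5, min_pts = 4), seed = 2)
  expect_equal(unsupervised_accuracy(truth, lab), 1)
  lab <- pipeline_cluster(z, "optics", list(eps = 3, eps_cl = 1.5, min_pts = 4), seed = 2)
  expect_equal(unsupervised_accuracy(truth, lab), 1)
  # determinism
  expect_identical(pipeline_cluster(z, "kmeans", list(k = 2), seed = 9),
                   pipeline_cluster(z, "kmeans", list(k = 2), seed = 9))
  # radius below all pairwise distances: everything is noise
  expect_true(all(dbscan_fit(z, eps = 1e-12, min_pts = 3) == -1L))
  expect_error(pipeline_cluster(z, "kmeans"), "params\\$k")
})

test_that("a fixed point converges within two target refreshes", {
  # data exactly at K separated centroids with an identity-like encoder
  z <- rbind(matrix(rep(c(0, 0), 50), ncol = 2, byrow = TRUE),
             matrix(rep(c(20, 0), 50), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 20), 50), ncol = 2, byrow = TRUE))
  spec <- backbone_spec("dense", layer_sizes = 2, latent_dim = 2)
  m <- build_backbone(spec, 2, seed = 1)
  eye <- diag(2)
  m$params$enc <- list(list(W = eye, b = c(0, 0)), list(W = eye, b = c(0, 0)))
  m$params$dec <- list(list(W = eye, b = c(0, 0)), list(W = eye, b = c(0, 0)))
  cfg <- deep_clustering_config(pretrain = FALSE, tol = 0.1, update_interval = 20,
                                max_iters = 200, lr = 1e-4, seed = 1)
  fit <- fit_deep_clustering(m, z, 3, cfg)
  expect_true(fit$converged)
  expect_lte(nrow(fit$loss_history), 3)   # initial refresh + at most one more
  expect_equal(fit$loss_history$pct_changed[nrow(fit$loss_history)], 0)
  expect_equal(sort(unique(fit$labels)), 0:2)
})

test_that("joint deep clustering recovers planted blob labels", {
  ds <- blob600(1)
  cfg <- deep_clustering_config(sigma = 1, tol = 0.1, update_interval = 140,
                                max_iters = 1400, base_algorithm = "kmeans",
                                pretrain = TRUE, pretrain_epochs = 5, seed = 1)
  fit <- fit_deep_clustering(small_dense(50, 1), ds$values, 3, cfg)
  expect_gte(unsupervised_accuracy(ds$labels, fit$labels), 0.95)
  expect_gte(nmi(ds$labels, fit$labels), 0.90)
  expect_true(fit$converged)
  lh <- fit$loss_history
  expect_lte(lh$L_KLD[nrow(lh)], lh$L_KLD[1])
  expect_true(all(is.finite(unlist(lh[, c("L_AE", "L_KLD", "combined")]))))
  # Q and P row sums hold at the final state
  expect_equal(rowSums(fit$state$Q), rep(1, 600), tolerance = 1e-9)
  expect_equal(rowSums(fit$state$P), rep(1, 600), tolerance = 1e-9)
  expect_true(all(fit$state$cluster_frequencies > 0))
  expect_gt(fit$G, 0)
})

test_that("sigma = 0 disables the clustering loss: centroids receive no update signal", {
  ds <- make_blob_dataset(30, 2, ambient_dim = 10, seed = 2)
  m <- small_dense(10, 2)
  z <- encode(m, ds$values)
  mu <- init_centroids(z, 2, "kmeans", seed = 2)
  q <- soft_assign(z, mu)
  p <- target_distribution(q)
  g <- clustering_gradients(z, mu, p, q)
  sigma <- 0
  expect_true(all(sigma * g$dmu == 0))
})

test_that("density-based and recurrent requests are rejected in joint mode", {
  ds <- make_blob_dataset(20, 2, ambient_dim = 6, seed = 3)
  m <- small_dense(6, 3)
  cfg <- deep_clustering_config(base_algorithm = "dbscan")
  expect_error(fit_deep_clustering(m, ds$values, 2, cfg), "pipeline_cluster")
  mr <- build_backbone(backbone_spec("recurrent", latent_dim = 2), 2, 1)
  expect_error(fit_deep_clustering(mr, list(matrix(0, 2, 2)), 2,
                                   deep_clustering_config()), "recurrent")
})

test_that("K sweep emits the elbow table with NMI only when truth is supplied", {
  ds <- blob600(1)
  cfg <- deep_clustering_config(pretrain = TRUE, pretrain_epochs = 5,
                                max_iters = 280, seed = 1)
  m <- small_dense(50, 1)
  tab <- sweep_k(m, ds$values, 2:6, cfg, labels = ds$labels)
  expect_identical(tab$K, 2:6)
  expect_true(all(tab$WCSS >= 0))
  expect_true(all(is.finite(tab$NMI)))
  expect_identical(attr(tab, "elbow_k"), 3L)
  tab2 <- sweep_k(m, ds$values, 3:5, cfg)          # no labels: NMI empty
  expect_true(all(is.na(tab2$NMI)))
  expect_error(sweep_k(m, ds$values, integer(0), cfg), "non-empty")
})

test_that("joint mode also works through a variational encoder", {
  ds <- make_blob_dataset(60, 2, latent_dim = 2, ambient_dim = 12,
                          separation = 8, seed = 5)
  spec <- backbone_spec("variational", layer_sizes = 16, latent_dim = 2)
  m <- build_backbone(spec, 12, seed = 5)
  cfg <- deep_clustering_config(pretrain = TRUE, pretrain_epochs = 15,
                                update_interval = 40, max_iters = 400, seed = 5)
  fit <- fit_deep_clustering(m, ds$values, 2, cfg)
  expect_gte(unsupervised_accuracy(ds$labels, fit$labels), 0.95)
})
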