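test_that("blob generator is deterministic and honours the zero-noise identity case", {
  a <- make_blob_dataset(20, 3, seed = 4)
  b <- make_blob_dataset(20, 3, seed = 4)
  expect_identical(a$values, b$values)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$values, make_blob_dataset(20, 3, seed = 5)$values))
  # zero noise + identity map: points sit exactly at the two centroids
  d <- make_blob_dataset(1, 2, latent_dim = 2, ambient_dim = 2, separation = 10,
                         noise_sd = 0, seed = 1, map = "identity")
  expect_identical(d$labels, c(0L, 1L))
  expect_equal(unname(d$values), unname(d$generator_params$centroids))
  expect_error(make_blob_dataset(0, 2), "must be a single integer")
  expect_error(make_blob_dataset(5, 2, latent_dim = 4, ambient_dim = 2), ">=")
})

test_that("blob latent coordinates are recoverable by best-of-10 k-means", {
  ds <- make_blob_dataset(200, 3, latent_dim = 2, ambient_dim = 10,
                          separation = 8, noise_sd = 1, seed = 6)
  km <- with(ds$generator_params,
             stats::kmeans(latent, centers = 3, nstart = 10))
  expect_gte(unsupervised_accuracy(ds$labels, km$cluster), 0.99)
  # centroid spacing respects the separation contract
  expect_gte(min(stats::dist(ds$generator_params$centroids)), 8 * 1 - 1e-9)
})

test_that("expression generator plants signatures and flags exactly the low-information genes", {
  ds <- make_expression_dataset(15, 3, n_genes = 120, n_signature = 8,
                                n_low_info = 7, seed = 2)
  expect_true(all(ds$values >= 0))
  logged <- log_transform_expression(ds$values)
  fl <- filter_low_information_genes(logged)
  expect_identical(which(!fl$report$kept_mask),
                   stats::setNames(ds$generator_params$low_info_genes,
                                   colnames(ds$values)[ds$generator_params$low_info_genes]))
  # signature genes are up-regulated in their own subtype
  gp <- ds$generator_params
  for (s in 1:3) {
    own <- colMeans(logged[ds$labels == s - 1L, gp$signature_genes[[s]], drop = FALSE])
    other <- colMeans(logged[ds$labels != s - 1L, gp$signature_genes[[s]], drop = FALSE])
    expect_true(all(own > other))
  }
  expect_identical(ds$values, make_expression_dataset(15, 3, n_genes = 120,
                                                      n_signature = 8,
                                                      n_low_info = 7, seed = 2)$values)
  expect_error(make_expression_dataset(10, 5, n_genes = 20, n_signature = 10),
               "exceeds")
})

test_that("single-subtype expression data is degenerate by construction", {
  ds <- make_expression_dataset(10, 1, n_genes = 50, n_signature = 5,
                                n_low_info = 4, seed = 3)
  expect_true(all(ds$labels == 0L))
  expect_length(ds$generator_params$signature_genes, 0)
})

test_that("image generator meets the shape, range and class-margin contracts", {
  ds <- make_image_dataset(4, 3, height = 16, width = 16, seed = 9)
  expect_equal(dim(ds$values), c(12, 16, 16, 3))
  expect_true(all(ds$values >= 0 & ds$values <= 1))
  expect_gt(ds$generator_params$class_mean_margin, 0.05)
  expect_identical(ds$values,
                   make_image_dataset(4, 3, height = 16, width = 16, seed = 9)$values)
  expect_error(make_image_dataset(4, 3, height = 8, width = 16), ">=")
})

test_that("text generator ties ratings to labels and varies sequence lengths", {
  ds <- make_text_dataset(30, vocab_size = 60, max_length = 15, seed = 5)
  expect_identical(as.integer(rating_to_polarity(ds$ratings)) - 1L, ds$labels)
  lens <- lengths(ds$token_ids)
  expect_gt(length(unique(lens)), 1)
  expect_true(all(unlist(ds$token_ids) >= 1 & unlist(ds$token_ids) <= 60))
  expect_identical(ds$token_ids,
                   make_text_dataset(30, vocab_size = 60, max_length = 15, seed = 5)$token_ids)
  expect_error(make_text_dataset(10, vocab_size = 20), ">= 30")
})

test_that("generators restore the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_blob_dataset(5, 2, seed = 99))
  invisible(make_text_dataset(5, seed = 99))
  expect_identical(.Random.seed, before)
})
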