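#' Configuration for deep-clustering training
#'
#' @param sigma Weight of the clustering (KLD) loss in the hardening phase,
#'   in `[0, 1]`. The default 1 is the hard schedule (reconstruction-only
#'   pretraining, then pure cluster hardening); any `0 < sigma < 1` gives
#'   constant-weight joint training of both losses.
#' @param tol Stopping threshold, in PERCENT: training stops when fewer than
#'   `tol`% of points change hard assignment between two consecutive target
#'   refreshes (default 0.1).
#' @param max_iters Maximum number of optimizer steps in the hardening phase.
#' @param update_interval Optimizer steps between target-distribution
#'   refreshes (default 140).
#' @param base_algorithm Centroid initializer: `"kmeans"`, `"agglomerative"`
#'   or `"gmm"` (density-based algorithms are pipeline-only).
#' @param alpha Student's-t degrees of freedom (default 1).
#' @param batch_size,lr Minibatch size and Adam learning rate.
#' @param pretrain Run representation-learning phase 1 inside the fit
#'   (greedy layer-wise for dense families, plain training otherwise). Set
#'   to `FALSE` when the supplied model is already pretrained.
#' @param pretrain_epochs Epochs for phase 1.
#' @param validation_fraction Held-out fraction for the generalizability
#'   ratio G (default 0.1).
#' @param seed Integer seed driving the split, initialization and batching.
#' @return A list of class `"deep_clustering_config"`.
#' @export
deep_clustering_config <- function(sigma = 1, tol = 0.1, max_iters = 2000,
                                   update_interval = 140,
                                   base_algorithm = "kmeans", alpha = 1,
                                   batch_size = 32, lr = 1e-3,
                                   pretrain = TRUE, pretrain_epochs = 10,
                                   validation_fraction = 0.1, seed = 1) {
  structure(list(
    sigma = check_number(sigma, "sigma", min = 0, max = 1),
    tol = check_number(tol, "tol", min = 0, strict_min = TRUE),
    max_iters = check_count(max_iters, "max_iters"),
    update_interval = check_count(update_interval, "update_interval"),
    base_algorithm = base_algorithm,
    alpha = check_number(alpha, "alpha", min = 0, strict_min = TRUE),
    batch_size = check_count(batch_size, "batch_size"),
    lr = check_number(lr, "lr", min = 0, strict_min = TRUE),
    pretrain = isTRUE(pretrain),
    pretrain_epochs = check_count(pretrain_epochs, "pretrain_epochs", min = 0L),
    validation_fraction = check_number(validation_fraction, "validation_fraction",
                                       min = 0, max = 0.5),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "deep_clustering_config")
}

# ---- encoder forward/backward hooks used by joint training -----------------

zeros_like <- function(p) {
  if (is.numeric(p)) return(p * 0)
  lapply(p, zeros_like)
}

encode_with_cache <- function(model, x) UseMethod("encode_with_cache")

#' @keywords internal
#' @export
encode_with_cache.backbone_dense <- function(model, x) {
  f <- dense_forward(zip_layers(model$params$enc, model$arch$enc_acts), x)
  list(z = f$out, cache = f$cache)
}

#' @keywords internal
#' @export
encode_with_cache.backbone_stacked_denoising <- encode_with_cache.backbone_dense

#' @keywords internal
#' @export
encode_with_cache.backbone_variational <- function(model, x) {
  f <- dense_forward(zip_layers(model$params$trunk, model$arch$trunk_acts), x)
  z <- sweep(f$out %*% model$params$mu_head$W, 2L, model$params$mu_head$b, "+")
  list(z = z, cache = list(h = f$out, trunk_cache = f$cache))
}

#' @keywords internal
#' @export
encode_with_cache.backbone_convolutional <- function(model, x) {
  f <- conv_encode_forward(model, x)
  list(z = f$z, cache = f)
}

# Parameter gradients from an upstream latent gradient dz; params-shaped,
# zero for decoder blocks.
encoder_backward_params <- function(model, cache, dz, x) {
  g <- zeros_like(model$params)
  if (inherits(model, "backbone_dense") ||
      inherits(model, "backbone_stacked_denoising")) {
    enc <- zip_layers(model$params$enc, model$arch$enc_acts)
    g$enc <- dense_backward(enc, cache$cache, dz)$grads
  } else if (inherits(model, "backbone_variational")) {
    h <- cache$cache$h
    g$mu_head <- list(W = crossprod(h, dz), b = colSums(dz))
    dh <- tcrossprod(dz, model$params$mu_head$W)
    trunk <- zip_layers(model$params$trunk, model$arch$trunk_acts)
    g$trunk <- dense_backward(trunk, cache$cache$trunk_cache, dh)$grads
  } else if (inherits(model, "backbone_convolutional")) {
    be <- conv_encode_backward(model, cache$cache, dz, dim(x)[1L])
    g$enc <- be$grads$enc
    g$fc_enc <- be$grads$fc_enc
  } else {
    dc_stop("joint deep clustering is not implemented for the %s family; use pipeline_cluster()",
            model$spec$family)
  }
  g
}

# ---- the two-phase fit ------------------------------------------------------

#' Fit deep embedded clustering
#'
#' The two-phase procedure. Phase 1 learns the representation: either the
#' supplied model is already pretrained, or (with `config$pretrain = TRUE`)
#' it is pretrained here on the training split — greedy layer-wise denoising
#' for dense families, plain reconstruction training otherwise. Phase 2
#' hardens the clusters: centroids are initialized by a base algorithm on
#' the encoded features, then Adam alternates between (a) refreshing the
#' auxiliary target distribution P every `update_interval` steps and (b)
#' minibatch steps on the combined loss
#' `sigma * KL(P || Q) + (1 - sigma) * L_AE`, backpropagating the analytic
#' clustering gradients through the encoder and updating the centroids as
#' free parameters. Training stops when fewer than `tol` percent of points
#' change hard assignment between consecutive refreshes, or at `max_iters`.
#'
#' If a centroid's hard-assignment count drops to zero at a refresh, it is
#' re-seeded at the sample with the least-confident assignment, keeping K
#' fixed.
#'
#' @param model A `"backbone"` (dense, stacked-denoising, variational or
#'   convolutional families support joint training).
#' @param x Data in the model's input layout.
#' @param k Number of clusters.
#' @param config A [deep_clustering_config()].
#' @return An object of class `"deep_clustering_fit"`: `labels` (0-based
#'   hard assignments), `state` (centroids, Q, P, frequencies, alpha),
#'   `loss_history` (per-refresh data frame with `L_AE`, `L_KLD`, `combined`
#'   and percent changed), `G`, `iterations_run`, `converged`, the trained
#'   `model` and the resolved `config`.
#' @export
fit_deep_clustering <- function(model, x, k, config = deep_clustering_config()) {
  if (!inherits(model, "backbone")) dc_stop("`model` must be a backbone")
  if (!inherits(config, "deep_clustering_config")) {
    dc_stop("`config` must be a deep_clustering_config")
  }
  if (config$base_algorithm %in% c("dbscan", "optics")) {
    dc_stop(paste("density-based base algorithms have no centroid update rule;",
                  "use pipeline_cluster() on encode(model, x)"))
  }
  if (model$spec$family == "recurrent") {
    dc_stop(paste("joint deep clustering is not implemented for the recurrent",
                  "family; run pipeline_cluster() on encode(model, x)"))
  }
  k <- check_count(k, "k", min = 2L)
  n <- n_items(model, x)
  if (k > n) dc_stop("K exceeds the sample count")

  # held-out split for the generalizability ratio
  val_idx <- integer(0)
  if (config$validation_fraction > 0 && n >= 10L) {
    val_idx <- with_seed(config$seed + 7L,
                         sort(sample.int(n, max(1L, round(config$validation_fraction * n)))))
  }
  train_idx <- setdiff(seq_len(n), val_idx)

  # ---- phase 1: representation learning (sigma = 0) ----
  if (config$pretrain && config$pretrain_epochs > 0L) {
    xtr <- slice_items(model, x, train_idx)
    model <- if (inherits(model, "backbone_dense") ||
                 inherits(model, "backbone_stacked_denoising")) {
      pretrain_greedy_layerwise(model, xtr, epochs_per_layer = config$pretrain_epochs,
                                batch_size = config$batch_size, lr = config$lr,
                                seed = config$seed)
    } else {
      train_backbone(model, xtr, epochs = config$pretrain_epochs,
                     batch_size = config$batch_size, lr = config$lr,
                     seed = config$seed)
    }
  }

  # ---- phase 2: cluster hardening ----
  z <- encode(model, x)
  mu <- init_centroids(z, k, config$base_algorithm, seed = config$seed)
  flat_theta <- flatten_params(model$params)
  st_theta <- adam_init(length(flat_theta))
  st_mu <- adam_init(length(mu))
  flat_mu <- as.numeric(mu)

  hist_rows <- list()
  prev_hard <- NULL
  p_full <- NULL
  converged <- FALSE
  steps_done <- 0L

  refresh <- function(model, mu) {
    z <- encode(model, x)
    q <- soft_assign(z, mu, config$alpha)
    list(z = z, q = q, p = target_distribution(q),
         hard = max.col(q, ties.method = "first") - 1L)
  }
  full_ae_loss <- function(model) {
    if (model$spec$family == "recurrent") lstm_ae_loss(x, model)$loss_value
    else if (model$spec$family == "variational") vae_loss(x, model, seed = config$seed)$loss_value
    else reconstruction_loss_any(model, x)
  }

  with_seed(config$seed + 13L, {
    repeat {
      # ---- refresh target distribution / convergence check ----
      rf <- refresh(model, mu)
      p_full <- rf$p
      # empty-cluster re-seeding keeps K fixed
      counts <- tabulate(rf$hard + 1L, nbins = k)
      if (any(counts == 0L)) {
        weakest <- which.min(apply(rf$q, 1L, max))
        for (j in which(counts == 0L)) {
          mu[j, ] <- rf$z[weakest, ] + stats::rnorm(ncol(mu), sd = 1e-4)
        }
        flat_mu <- as.numeric(mu)
        rf <- refresh(model, mu)
        p_full <- rf$p
      }
      l_kld <- kld_loss(p_full, rf$q) / n
      l_ae <- full_ae_loss(model)
      pct <- if (is.null(prev_hard)) NA_real_ else 100 * mean(rf$hard != prev_hard)
      hist_rows[[length(hist_rows) + 1L]] <- data.frame(
        iteration = steps_done, L_AE = l_ae, L_KLD = l_kld,
        combined = combined_loss(l_kld, l_ae, config$sigma),
        pct_changed = pct)
      if (!is.null(prev_hard) && !is.na(pct) && pct < config$tol) {
        converged <- TRUE
        break
      }
      prev_hard <- rf$hard
      if (steps_done >= config$max_iters) break

      # ---- update_interval optimizer steps against the frozen P ----
      n_steps <- min(config$update_interval, config$max_iters - steps_done)
      ord <- sample.int(n)
      pos <- 1L
      for (s in seq_len(n_steps)) {
        if (pos > n) { ord <- sample.int(n); pos <- 1L }
        idx <- ord[pos:min(pos + config$batch_size - 1L, n)]
        pos <- pos + config$batch_size
        xb <- slice_items(model, x, idx)
        nb <- length(idx)

        ec <- encode_with_cache(model, xb)
        qb <- soft_assign(ec$z, mu, config$alpha)
        cg <- clustering_gradients(ec$z, mu, p_full[idx, , drop = FALSE], qb,
                                   config$alpha)
        g_theta <- encoder_backward_params(model, ec, config$sigma * cg$dz / nb, xb)
        g_mu <- config$sigma * cg$dmu / nb
        if (config$sigma < 1) {
          rg <- backbone_loss_grads(model, xb)
          g_theta <- accumulate_grads(g_theta, scale_grads(rg$grads, 1 - config$sigma))
        }
        stp <- adam_step(st_theta, flat_theta, flatten_params(g_theta), lr = config$lr)
        st_theta <- stp$state
        flat_theta <- stp$params
        model$params <- assign_flat(model$params, flat_theta)$value
        stp <- adam_step(st_mu, flat_mu, as.numeric(g_mu), lr = config$lr)
        st_mu <- stp$state
        flat_mu <- stp$params
        mu <- matrix(flat_mu, k)
        steps_done <- steps_done + 1L
      }
    }
  })

  rf <- refresh(model, mu)
  g_ratio <- NA_real_
  if (length(val_idx) > 0L) {
    l_tr <- recon_loss_subset(model, x, train_idx, config)
    l_va <- recon_loss_subset(model, x, val_idx, config)
    if (l_va > 0) g_ratio <- generalizability(l_tr, l_va)
  }
  structure(list(
    labels = rf$hard,
    state = list(K = k, centroids = mu, Q = rf$q, P = rf$p,
                 cluster_frequencies = colSums(rf$q), alpha = config$alpha,
                 hard_labels = rf$hard),
    loss_history = do.call(rbind, hist_rows),
    G = g_ratio,
    iterations_run = steps_done,
    converged = converged,
    model = model,
    config = config,
    validation_index = val_idx
  ), class = "deep_clustering_fit")
}

reconstruction_loss_any <- function(model, x) {
  if (model$spec$family == "recurrent") return(lstm_ae_loss(x, model)$loss_value)
  xhat <- reconstruct(model, x)
  if (length(dim(x)) == 4L) return(sum((x - xhat)^2) / dim(x)[1L])
  reconstruction_loss(x, xhat)$loss_value
}

recon_loss_subset <- function(model, x, idx, config) {
  xs <- slice_items(model, x, idx)
  if (model$spec$family == "variational") {
    vae_loss(xs, model, seed = config$seed)$loss_value
  } else {
    reconstruction_loss_any(model, xs)
  }
}

#' @export
print.deep_clustering_fit <- function(x, ...) {
  cat(sprintf("<deep_clustering_fit>  K=%d  n=%d  steps=%d  converged=%s\n",
              x$state$K, length(x$labels), x$iterations_run, x$converged))
  if (!is.na(x$G)) cat(sprintf("  generalizability G = %.3f\n", x$G))
  invisible(x)
}

#' Sweep the cluster count K
#'
#' Pretrains the backbone once (phase 1), then runs one hardening fit per K
#' in `k_range` from the shared pretrained parameters, recording the
#' within-cluster sum of squares of the final latent space, NMI against
#' ground truth when labels are supplied, and the generalizability ratio G.
#' The Elbow choice (max second difference of WCSS) is attached as
#' `attr(result, "elbow_k")` when the range has at least 3 contiguous
#' values.
#'
#' @param model A `"backbone"`.
#' @param x Data in the model's input layout.
#' @param k_range Integer vector of K values (each in `[2, n - 1]`).
#' @param config A [deep_clustering_config()].
#' @param labels Optional ground-truth labels.
#' @return Data frame with columns `K`, `WCSS`, `NMI` (NA without labels),
#'   `G`.
#' @export
sweep_k <- function(model, x, k_range, config = deep_clustering_config(),
                    labels = NULL) {
  if (length(k_range) == 0L) dc_stop("`k_range` must be non-empty")
  n <- n_items(model, x)
  k_range <- vapply(k_range, check_count, integer(1), name = "k_range")
  if (any(k_range < 2L | k_range > n - 1L)) dc_stop("each K must lie in [2, n-1]")

  if (config$pretrain && config$pretrain_epochs > 0L) {
    model <- if (inherits(model, "backbone_dense") ||
                 inherits(model, "backbone_stacked_denoising")) {
      pretrain_greedy_layerwise(model, x, epochs_per_layer = config$pretrain_epochs,
                                batch_size = config$batch_size, lr = config$lr,
                                seed = config$seed)
    } else {
      train_backbone(model, x, epochs = config$pretrain_epochs,
                     batch_size = config$batch_size, lr = config$lr,
                     seed = config$seed)
    }
  }
  cfg <- config
  cfg$pretrain <- FALSE

  # WCSS is evaluated in the shared pretrained latent space (cluster centres =
  # group means of each K's fitted labels there): the hardening phase rescales
  # each run's latent space differently, so per-run WCSS values would not be
  # comparable across K and the Elbow curve would lose its meaning.
  z0 <- encode(model, x)
  rows <- lapply(k_range, function(k) {
    fit <- fit_deep_clustering(model, x, k, cfg)
    centres <- t(vapply(sort(unique(fit$labels)),
                        function(g) colMeans(z0[fit$labels == g, , drop = FALSE]),
                        numeric(ncol(z0))))
    data.frame(
      K = k,
      WCSS = wcss(z0, match(fit$labels, sort(unique(fit$labels))) - 1L, centres),
      NMI = if (is.null(labels)) NA_real_ else nmi(labels, fit$labels),
      G = fit$G
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$K), , drop = FALSE]
  if (nrow(out) >= 3L && all(diff(out$K) == 1L)) {
    attr(out, "elbow_k") <- elbow_select(stats::setNames(out$WCSS, out$K))
  }
  out
}
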