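#' Describe an autoencoder backbone
#'
#' A `backbone_spec` captures the architecture of one of the five supported
#' autoencoder families before any parameters exist:
#' \describe{
#'   \item{dense}{plain multilayer dense autoencoder; `layer_sizes` are the
#'     hidden encoder widths (the decoder mirrors them).}
#'   \item{stacked_denoising}{same architecture as `dense`, but intended for
#'     greedy layer-wise denoising pretraining ([pretrain_greedy_layerwise()]).}
#'   \item{variational}{dense trunk with Gaussian mean/log-variance heads of
#'     width `latent_dim` and a mirrored decoder; trained on the negative
#'     evidence lower bound ([vae_loss()]).}
#'   \item{convolutional}{conv/max-pool encoder and upsample/deconv decoder
#'     for channels-last image tensors; `layer_sizes` is a list of
#'     `(channels, kernel, pool)` triples.}
#'   \item{recurrent}{LSTM encoder-decoder for variable-length sequences of
#'     feature vectors; the encoder's final hidden state (width
#'     `latent_dim`) is the representation and the decoder reconstructs the
#'     sequence in reverse order.}
#' }
#'
#' @param family One of `"dense"`, `"stacked_denoising"`, `"convolutional"`,
#'   `"variational"`, `"recurrent"`.
#' @param layer_sizes Hidden widths (dense families), list of
#'   `(channels, kernel, pool)` triples (convolutional), ignored for
#'   recurrent (the single LSTM layer has `latent_dim` units).
#' @param latent_dim Width of the latent representation Z.
#' @param activation Hidden activation name (default `"relu"`).
#' @param corruption_rate Dropout corruption probability in `[0, 1)` used by
#'   denoising training (default 0.2, the rate the architecture presets use).
#' @param batch_norm Logical; reserved switch for batch normalization
#'   (presets record it; the desk-scale implementation trains without it).
#' @return An object of class `"backbone_spec"`.
#' @export
backbone_spec <- function(family = c("dense", "stacked_denoising",
                                     "convolutional", "variational", "recurrent"),
                          layer_sizes = c(64, 32),
                          latent_dim = 10,
                          activation = "relu",
                          corruption_rate = 0.2,
                          batch_norm = FALSE) {
  family <- match.arg(family)
  latent_dim <- check_count(latent_dim, "latent_dim")
  corruption_rate <- check_number(corruption_rate, "corruption_rate", min = 0)
  if (corruption_rate >= 1) dc_stop("`corruption_rate` must be < 1")
  act_fun(activation)  # validates the name
  if (family == "convolutional") {
    if (!is.list(layer_sizes) || !all(vapply(layer_sizes, length, 1L) == 3L)) {
      dc_stop("convolutional `layer_sizes` must be a list of (channels, kernel, pool) triples")
    }
  } else if (family != "recurrent") {
    if (!is.numeric(layer_sizes) || length(layer_sizes) < 1L || any(layer_sizes < 1)) {
      dc_stop("`layer_sizes` must be positive hidden widths")
    }
    layer_sizes <- as.integer(layer_sizes)
  }
  structure(list(family = family, layer_sizes = layer_sizes,
                 latent_dim = latent_dim, activation = activation,
                 corruption_rate = corruption_rate, batch_norm = batch_norm),
            class = "backbone_spec")
}

#' Named architecture presets
#'
#' Presets mirroring the published layer schedules at a configurable scale:
#' `"bach_cae_24layer"` (4-stage convolutional autoencoder with 2x2
#' max-pooling per stage; full-scale channels 127/64/32/32), `"ge_vae_12layer"`
#' (dense variational autoencoder 256-32 trunk with a 2-dimensional latent
#' code), and `"review_lstm_ae"` (LSTM autoencoder over 300-dimensional token
#' embeddings with a 128-unit representation).
#'
#' @param name Preset name.
#' @param scale Multiplier in `(0, 1]` applied to channel/unit counts for
#'   desk-scale runs (default 1 reproduces the printed schedule).
#' @return A [backbone_spec()].
#' @export
backbone_preset <- function(name = c("bach_cae_24layer", "ge_vae_12layer",
                                     "review_lstm_ae"),
                            scale = 1) {
  name <- match.arg(name)
  scale <- check_number(scale, "scale", min = 0, max = 1, strict_min = TRUE)
  sc <- function(x) max(2L, as.integer(round(x * scale)))
  switch(name,
    bach_cae_24layer = backbone_spec(
      family = "convolutional",
      layer_sizes = list(c(sc(127), 3, 2), c(sc(64), 3, 2),
                         c(sc(32), 3, 2), c(sc(32), 3, 2)),
      latent_dim = sc(32), corruption_rate = 0.2, batch_norm = TRUE
    ),
    ge_vae_12layer = backbone_spec(
      family = "variational",
      layer_sizes = c(sc(256), sc(32)),
      latent_dim = 2, corruption_rate = 0.2, batch_norm = TRUE
    ),
    review_lstm_ae = backbone_spec(
      family = "recurrent",
      layer_sizes = integer(0),
      latent_dim = sc(128), corruption_rate = 0.2, batch_norm = TRUE
    )
  )
}

#' Build a randomly initialized backbone model
#'
#' @param spec A [backbone_spec()].
#' @param input_shape Input dimensionality: a single integer D (dense,
#'   variational), `c(height, width, channels)` (convolutional), or the
#'   per-timestep feature width (recurrent).
#' @param seed Integer seed; identical seeds give identical initial
#'   parameters.
#' @return An object of class `"backbone"` holding the parameter set.
#' @export
build_backbone <- function(spec, input_shape, seed = 1) {
  if (!inherits(spec, "backbone_spec")) dc_stop("`spec` must be a backbone_spec")
  with_seed(seed, {
    model <- switch(spec$family,
      dense = ,
      stacked_denoising = build_dense_model(spec, input_shape),
      variational = build_vae_model(spec, input_shape),
      convolutional = build_conv_model(spec, input_shape),
      recurrent = build_lstm_model(spec, input_shape)
    )
  })
  model$spec <- spec
  model$input_shape <- input_shape
  model$seed <- as.integer(seed)
  class(model) <- c(paste0("backbone_", spec$family), "backbone")
  model
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone: %s>  latent_dim=%d  n_params=%d\n",
              x$spec$family, x$spec$latent_dim, length(flatten_params(x$params))))
  invisible(x)
}

# ---- dense & stacked-denoising ---------------------------------------------

# Encoder widths input -> hidden... -> latent; decoder mirrors. Hidden layers
# use the spec activation; the latent layer and the reconstruction layer are
# linear (the convention greedy layer-wise pretraining also produces).
build_dense_model <- function(spec, input_shape) {
  d <- check_count(input_shape[1L], "input_shape")
  widths <- c(d, spec$layer_sizes, spec$latent_dim)
  n_enc <- length(widths) - 1L
  enc <- dec <- vector("list", n_enc)
  enc_acts <- c(rep(spec$activation, n_enc - 1L), "linear")
  dec_widths <- rev(widths)
  dec_acts <- c(rep(spec$activation, n_enc - 1L), "linear")
  for (l in seq_len(n_enc)) {
    enc[[l]] <- init_dense_layer(widths[l], widths[l + 1L])[c("W", "b")]
    dec[[l]] <- init_dense_layer(dec_widths[l], dec_widths[l + 1L])[c("W", "b")]
  }
  list(params = list(enc = enc, dec = dec),
       arch = list(widths = widths, enc_acts = enc_acts, dec_acts = dec_acts))
}

# zip numeric params with stored activation names
zip_layers <- function(param_layers, acts) {
  Map(function(p, a) list(W = p$W, b = p$b, act = a), param_layers, acts)
}

# ---- variational ------------------------------------------------------------

build_vae_model <- function(spec, input_shape) {
  d <- check_count(input_shape[1L], "input_shape")
  trunk_widths <- c(d, spec$layer_sizes)
  n_tr <- length(trunk_widths) - 1L
  trunk <- vector("list", n_tr)
  for (l in seq_len(n_tr)) {
    trunk[[l]] <- init_dense_layer(trunk_widths[l], trunk_widths[l + 1L])[c("W", "b")]
  }
  h <- trunk_widths[length(trunk_widths)]
  dec_widths <- c(spec$latent_dim, rev(spec$layer_sizes), d)
  n_dec <- length(dec_widths) - 1L
  dec <- vector("list", n_dec)
  for (l in seq_len(n_dec)) {
    dec[[l]] <- init_dense_layer(dec_widths[l], dec_widths[l + 1L])[c("W", "b")]
  }
  # log-variance head starts near zero output (small weights) so early
  # training is not dominated by the KL term
  logvar <- init_dense_layer(h, spec$latent_dim)[c("W", "b")]
  logvar$W <- logvar$W * 0.01
  list(params = list(trunk = trunk,
                     mu_head = init_dense_layer(h, spec$latent_dim)[c("W", "b")],
                     logvar_head = logvar,
                     dec = dec),
       arch = list(trunk_acts = rep(spec$activation, n_tr),
                   dec_acts = c(rep(spec$activation, n_dec - 1L), "linear")))
}

# ---- shared ops -------------------------------------------------------------

#' Extract latent features
#'
#' Applies only the encoder of a backbone: `Z = f_theta(X)`. Deterministic
#' given the parameters; the variational family returns the posterior mean
#' (sampling happens only inside training), so repeated calls agree exactly.
#'
#' @param model A `"backbone"` model.
#' @param x Input batch in the family's layout (matrix with samples as rows;
#'   `n x h x w x c` array for convolutional; list of `L x d` matrices for
#'   recurrent).
#' @return Latent matrix Z with one row per sample and `latent_dim` columns.
#' @export
encode <- function(model, x) UseMethod("encode")

#' @export
encode.backbone_dense <- function(model, x) {
  x <- check_matrix(x, "x")
  if (ncol(x) != model$arch$widths[1L]) dc_stop("input width mismatch")
  dense_forward(zip_layers(model$params$enc, model$arch$enc_acts), x,
                keep_cache = FALSE)$out
}

#' @export
encode.backbone_stacked_denoising <- encode.backbone_dense

#' @export
encode.backbone_variational <- function(model, x) {
  x <- check_matrix(x, "x")
  h <- dense_forward(zip_layers(model$params$trunk, model$arch$trunk_acts), x,
                     keep_cache = FALSE)$out
  sweep(h %*% model$params$mu_head$W, 2L, model$params$mu_head$b, "+")
}

#' Reconstruct inputs through the full autoencoder
#'
#' @inheritParams encode
#' @return Reconstruction in the same layout as `x` (the variational family
#'   decodes the posterior mean).
#' @export
reconstruct <- function(model, x) UseMethod("reconstruct")

#' @export
reconstruct.backbone_dense <- function(model, x) {
  z <- encode(model, x)
  dense_forward(zip_layers(model$params$dec, model$arch$dec_acts), z,
                keep_cache = FALSE)$out
}

#' @export
reconstruct.backbone_stacked_denoising <- reconstruct.backbone_dense

#' @export
reconstruct.backbone_variational <- function(model, x) {
  z <- encode(model, x)
  dense_forward(zip_layers(model$params$dec, model$arch$dec_acts), z,
                keep_cache = FALSE)$out
}

#' Squared-error reconstruction loss
#'
#' `L_AE = sum_i || x_i - xhat_i ||^2`, reported per sample and reduced by
#' the package's convention: mean over samples, sum over features.
#'
#' @param x Original data matrix.
#' @param xhat Reconstructed matrix of the same shape.
#' @param loss_kind Label recorded in the report.
#' @return A list of class `"reconstruction_report"` with `loss_value` (the
#'   mean-over-samples reduction), `per_sample_losses`, and `loss_kind`.
#' @export
reconstruction_loss <- function(x, xhat, loss_kind = "squared_error") {
  x <- check_matrix(x, "x")
  xhat <- check_matrix(xhat, "xhat")
  if (!all(dim(x) == dim(xhat))) dc_stop("`x` and `xhat` shapes differ")
  per <- rowSums((x - xhat)^2)
  structure(list(loss_value = mean(per), per_sample_losses = per,
                 loss_kind = loss_kind),
            class = "reconstruction_report")
}

#' Dropout corruption
#'
#' Independently zeroes each coordinate with probability `rate`. Surviving
#' coordinates are NOT rescaled: this is the masking-noise corruption of the
#' denoising autoencoder formulation, not inverted dropout.
#'
#' @param x Numeric vector or matrix.
#' @param rate Corruption probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Corrupted copy of `x`.
#' @export
corrupt <- function(x, rate, seed = 1) {
  rate <- check_number(rate, "rate", min = 0)
  if (rate >= 1) dc_stop("`rate` must be < 1")
  if (rate == 0) return(x)
  with_seed(seed, x * (stats::runif(length(x)) >= rate))
}

#' Denoising reconstruction loss
#'
#' Corrupts the input with dropout masking, encodes the corrupted copy, and
#' scores the reconstruction against the clean input with squared error
#' (mean over samples, sum over features). At `rate = 0` this reduces to the
#' plain reconstruction loss.
#'
#' @param x Input matrix (rows = samples).
#' @param model A dense-family backbone.
#' @param seed Integer seed for the corruption mask.
#' @param rate Corruption probability; defaults to the spec's
#'   `corruption_rate`.
#' @return Scalar loss.
#' @export
denoising_loss <- function(x, model, seed = 1, rate = NULL) {
  if (!inherits(model, "backbone")) dc_stop("`model` must be a backbone")
  x <- check_matrix(x, "x")
  if (is.null(rate)) rate <- model$spec$corruption_rate
  xt <- corrupt(x, rate, seed)
  reconstruction_loss(x, reconstruct(model, xt), loss_kind = "denoising")$loss_value
}

# ---- loss + gradients per family (training workhorse) ----------------------

# Returns list(loss, grads) with grads mirroring model$params. `x` is the
# clean batch; `x_in` the (possibly corrupted) encoder input.
dense_loss_grads <- function(model, x, x_in = x) {
  enc <- zip_layers(model$params$enc, model$arch$enc_acts)
  dec <- zip_layers(model$params$dec, model$arch$dec_acts)
  fe <- dense_forward(enc, x_in)
  fd <- dense_forward(dec, fe$out)
  n <- nrow(x)
  diff <- fd$out - x
  loss <- sum(diff^2) / n
  d_out <- 2 * diff / n
  bd <- dense_backward(dec, fd$cache, d_out)
  be <- dense_backward(enc, fe$cache, bd$d_input)
  list(loss = loss, grads = list(enc = be$grads, dec = bd$grads))
}

#' Negative evidence lower bound of a variational autoencoder
#'
#' Computes the per-batch negative ELBO: squared-error reconstruction term
#' from a single reparameterized sample `z = mu + exp(logvar/2) * eps`, plus
#' the closed-form KL divergence of the diagonal-Gaussian posterior from the
#' standard-normal prior, `KL = 1/2 sum(mu^2 + sigma^2 - 1 - log sigma^2)`.
#' Both terms are means over the batch; the KL term is reported separately
#' and is always non-negative.
#'
#' @param x Input batch (matrix, rows = samples).
#' @param model A variational-family backbone.
#' @param seed Integer seed for the reparameterization noise.
#' @return A `"reconstruction_report"` with `loss_value` (negative ELBO),
#'   `per_sample_losses`, `recon_term`, `kl_term`, `loss_kind =
#'   "negative_elbo"`.
#' @export
vae_loss <- function(x, model, seed = 1) {
  if (!inherits(model, "backbone_variational")) {
    dc_stop("`model` must be a variational backbone")
  }
  x <- check_matrix(x, "x")
  r <- with_seed(seed, vae_loss_grads(model, x, want_grads = FALSE))
  structure(list(loss_value = r$loss, per_sample_losses = r$per_sample,
                 recon_term = r$recon, kl_term = r$kl,
                 loss_kind = "negative_elbo"),
            class = "reconstruction_report")
}

# core VAE computation; caller controls seeding. eps drawn from the current RNG.
vae_loss_grads <- function(model, x, want_grads = TRUE) {
  p <- model$params
  trunk <- zip_layers(p$trunk, model$arch$trunk_acts)
  dec <- zip_layers(p$dec, model$arch$dec_acts)
  ft <- dense_forward(trunk, x)
  h <- ft$out
  n <- nrow(x)
  k <- ncol(p$mu_head$W)
  mu <- sweep(h %*% p$mu_head$W, 2L, p$mu_head$b, "+")
  logvar <- sweep(h %*% p$logvar_head$W, 2L, p$logvar_head$b, "+")
  eps <- matrix(stats::rnorm(n * k), n, k)
  sd_ <- exp(0.5 * logvar)
  z <- mu + sd_ * eps
  fd <- dense_forward(dec, z)
  diff <- fd$out - x
  per_recon <- rowSums(diff^2)
  per_kl <- 0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
  recon <- mean(per_recon)
  kl <- mean(per_kl)
  out <- list(loss = recon + kl, recon = recon, kl = kl,
              per_sample = per_recon + per_kl)
  if (!want_grads) return(out)

  d_out <- 2 * diff / n
  bd <- dense_backward(dec, fd$cache, d_out)
  dz <- bd$d_input
  dmu <- dz + mu / n
  dlogvar <- dz * eps * 0.5 * sd_ + 0.5 * (exp(logvar) - 1) / n
  g_mu_head <- list(W = crossprod(h, dmu), b = colSums(dmu))
  g_lv_head <- list(W = crossprod(h, dlogvar), b = colSums(dlogvar))
  dh <- tcrossprod(dmu, p$mu_head$W) + tcrossprod(dlogvar, p$logvar_head$W)
  bt <- dense_backward(trunk, ft$cache, dh)
  out$grads <- list(trunk = bt$grads, mu_head = g_mu_head,
                    logvar_head = g_lv_head, dec = bd$grads)
  out
}

# dispatcher used by the generic training loop; each branch must consume RNG
# only through the current stream (the loop seeds once).
backbone_loss_grads <- function(model, batch, corruption_rate = 0) {
  switch(model$spec$family,
    dense = ,
    stacked_denoising = {
      x_in <- if (corruption_rate > 0) {
        batch * (matrix(stats::runif(length(batch)), nrow(batch)) >= corruption_rate)
      } else batch
      dense_loss_grads(model, batch, x_in)
    },
    variational = vae_loss_grads(model, batch),
    convolutional = conv_loss_grads(model, batch),
    recurrent = lstm_loss_grads(model, batch)
  )
}

#' Train a backbone by minibatch gradient descent
#'
#' Runs Adam (default learning rate 1e-3, batch size 32) on the family's
#' reconstruction objective: squared error (dense/stacked-denoising, with
#' optional dropout corruption of the encoder input), negative ELBO
#' (variational), masked squared error over reversed targets (recurrent), or
#' image squared error (convolutional).
#'
#' @param model A `"backbone"` model.
#' @param x Training data in the family's layout.
#' @param epochs Number of passes over the data.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param corruption_rate Dropout corruption of the encoder input during
#'   training (dense families only).
#' @param seed Integer seed covering shuffling, corruption and VAE sampling.
#' @return The trained model; per-epoch mean losses are attached as
#'   `attr(model, "loss_history")`.
#' @export
train_backbone <- function(model, x, epochs = 20, batch_size = 32, lr = 1e-3,
                           corruption_rate = 0, seed = 1) {
  if (!inherits(model, "backbone")) dc_stop("`model` must be a backbone")
  epochs <- check_count(epochs, "epochs", min = 0L)
  if (epochs == 0L) return(model)
  n <- n_items(model, x)
  flat <- flatten_params(model$params)
  state <- adam_init(length(flat))
  history <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        lg <- backbone_loss_grads(model, slice_items(model, x, idx),
                                  corruption_rate = corruption_rate)
        flat_g <- flatten_params(lg$grads)
        stp <- adam_step(state, flat, flat_g, lr = lr)
        state <- stp$state
        flat <- stp$params
        model$params <- assign_flat(model$params, flat)$value
        ep_loss <- ep_loss + lg$loss
        nb <- nb + 1L
      }
      history[ep] <- ep_loss / nb
    }
  })
  attr(model, "loss_history") <- history
  model
}

n_items <- function(model, x) {
  if (model$spec$family == "recurrent") length(x)
  else if (model$spec$family == "convolutional") dim(x)[1L]
  else nrow(x)
}

slice_items <- function(model, x, idx) {
  if (model$spec$family == "recurrent") x[idx]
  else if (model$spec$family == "convolutional") x[idx, , , , drop = FALSE]
  else x[idx, , drop = FALSE]
}
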