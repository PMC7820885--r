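#' Greedy layer-wise denoising pretraining
#'
#' Pretrains a dense or stacked-denoising backbone one encoder/decoder pair
#' at a time, the initialization strategy of the deep-embedded-clustering
#' family. Each pair is trained as a two-layer denoising autoencoder on the
#' previous layer's (clean) output: the input is corrupted by dropout
#' masking, encoded, the hidden code corrupted again, decoded, and the
#' least-squares loss `||x - y||^2` against the clean input is minimized.
#' Activations are ReLU for every encoder/decoder pair except the decoder of
#' the first pair and the encoder of the last pair, which are linear (so the
#' latent code and the final reconstruction are unconstrained).
#'
#' After all pairs are trained, encoder layers are concatenated in training
#' order and decoder layers in reverse training order, forming the deep
#' autoencoder, which is then fine-tuned end-to-end on clean inputs.
#'
#' @param model A dense or stacked-denoising backbone.
#' @param x Data matrix (rows = samples).
#' @param epochs_per_layer Pretraining epochs per pair; `0` returns the
#'   model unchanged.
#' @param corruption_rate Dropout corruption probability (default: the
#'   spec's `corruption_rate`).
#' @param finetune_epochs End-to-end fine-tuning epochs (default: same as
#'   `epochs_per_layer`).
#' @param batch_size,lr Minibatch size and Adam learning rate.
#' @param seed Integer seed.
#' @return The pretrained (and fine-tuned) model.
#' @export
pretrain_greedy_layerwise <- function(model, x, epochs_per_layer = 10,
                                      corruption_rate = NULL,
                                      finetune_epochs = epochs_per_layer,
                                      batch_size = 32, lr = 1e-3, seed = 1) {
  if (!inherits(model, "backbone_dense") &&
      !inherits(model, "backbone_stacked_denoising")) {
    dc_stop("greedy layer-wise pretraining requires a dense-family backbone")
  }
  x <- check_matrix(x, "x")
  epochs_per_layer <- check_count(epochs_per_layer, "epochs_per_layer", min = 0L)
  if (epochs_per_layer == 0L) return(model)
  if (is.null(corruption_rate)) corruption_rate <- model$spec$corruption_rate
  corruption_rate <- check_number(corruption_rate, "corruption_rate", min = 0)

  n_pairs <- length(model$params$enc)
  h <- x
  with_seed(seed, {
    for (l in seq_len(n_pairs)) {
      enc_act <- model$arch$enc_acts[l]
      # decoder of pair l reconstructs the layer-(l-1) representation; it sits
      # at position n_pairs - l + 1 of the assembled decoder stack
      dec_pos <- n_pairs - l + 1L
      dec_act <- model$arch$dec_acts[dec_pos]
      pair <- train_dae_pair(model$params$enc[[l]], model$params$dec[[dec_pos]],
                             enc_act, dec_act, h, epochs_per_layer,
                             corruption_rate, batch_size, lr)
      model$params$enc[[l]] <- pair$enc
      model$params$dec[[dec_pos]] <- pair$dec
      h <- act_fun(enc_act)$f(sweep(h %*% pair$enc$W, 2L, pair$enc$b, "+"))
    }
  })
  if (finetune_epochs > 0L) {
    model <- train_backbone(model, x, epochs = finetune_epochs,
                            batch_size = batch_size, lr = lr,
                            corruption_rate = 0, seed = seed + 1L)
  }
  model
}

# Two-layer denoising autoencoder: corrupt input, encode, corrupt code,
# decode, least-squares loss against the clean input. Caller seeds the RNG.
train_dae_pair <- function(enc, dec, enc_act, dec_act, x, epochs,
                           rate, batch_size, lr) {
  n <- nrow(x)
  fe <- act_fun(enc_act); fd <- act_fun(dec_act)
  params <- list(enc = enc, dec = dec)
  flat <- flatten_params(params)
  state <- adam_init(length(flat))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      m <- length(idx)
      xt <- if (rate > 0) xb * (matrix(stats::runif(length(xb)), m) >= rate) else xb
      pre1 <- sweep(xt %*% params$enc$W, 2L, params$enc$b, "+")
      hid <- fe$f(pre1)
      ht <- if (rate > 0) hid * (matrix(stats::runif(length(hid)), m) >= rate) else hid
      pre2 <- sweep(ht %*% params$dec$W, 2L, params$dec$b, "+")
      y <- fd$f(pre2)
      diff <- y - xb
      dpre2 <- (2 * diff / m) * fd$df(pre2, y)
      gdec <- list(W = crossprod(ht, dpre2), b = colSums(dpre2))
      dht <- tcrossprod(dpre2, params$dec$W)
      dhid <- if (rate > 0) dht * (ht != 0 | hid == 0) else dht
      dpre1 <- dhid * fe$df(pre1, hid)
      genc <- list(W = crossprod(xt, dpre1), b = colSums(dpre1))
      stp <- adam_step(state, flat, flatten_params(list(enc = genc, dec = gdec)), lr = lr)
      state <- stp$state
      flat <- stp$params
      params <- assign_flat(params, flat)$value
    }
  }
  params
}
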