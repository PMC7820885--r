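# LSTM encoder-decoder for variable-length sequences of feature vectors.
# The encoder's final hidden state (latent_dim units) is the fixed-width
# representation; it also seeds the decoder, which is trained (teacher
# forced) to reproduce the input sequence in REVERSE order: at step t the
# decoder receives x^(L-t+2) (a zero vector at t = 1) and predicts x^(L-t+1).
# Sequences are processed one at a time (no padding needed); losses are the
# per-sequence sum over timesteps and features, averaged over the batch.

build_lstm_model <- function(spec, input_shape) {
  d <- check_count(input_shape[1L], "input_shape")
  h <- spec$latent_dim
  cell_init <- function(d_in) {
    s <- sqrt(1 / max(d_in, h))
    list(Wx = matrix(stats::rnorm(d_in * 4L * h, sd = s), d_in, 4L * h),
         Wh = matrix(stats::rnorm(h * 4L * h, sd = s), h, 4L * h),
         b = numeric(4L * h))
  }
  list(params = list(enc = cell_init(d), dec = cell_init(d),
                     out = init_dense_layer(h, d)[c("W", "b")]),
       arch = list(d = d, h = h))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One LSTM step. x: 1 x d row; h_prev/c_prev: 1 x h. Gate order [i, f, o, g].
lstm_step <- function(cell, x, h_prev, c_prev, h) {
  gates <- x %*% cell$Wx + h_prev %*% cell$Wh
  gates <- gates + rep(cell$b, each = nrow(gates))
  i <- sigmoid(gates[, 1:h, drop = FALSE])
  f <- sigmoid(gates[, (h + 1):(2 * h), drop = FALSE])
  o <- sigmoid(gates[, (2 * h + 1):(3 * h), drop = FALSE])
  g <- tanh(gates[, (3 * h + 1):(4 * h), drop = FALSE])
  c_new <- f * c_prev + i * g
  tc <- tanh(c_new)
  list(h = o * tc, c = c_new, i = i, f = f, o = o, g = g, tc = tc,
       x = x, h_prev = h_prev, c_prev = c_prev)
}

# Backward through one step given dh, dc (1 x h each). Returns gate-level
# parameter grads plus dh_prev, dc_prev, dx.
lstm_step_backward <- function(cell, st, dh, dc, h) {
  dc <- dc + dh * st$o * (1 - st$tc^2)
  do_ <- dh * st$tc
  di <- dc * st$g
  dg <- dc * st$i
  df <- dc * st$c_prev
  dc_prev <- dc * st$f
  dgates <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  do_ * st$o * (1 - st$o),
                  dg * (1 - st$g^2))
  list(dWx = crossprod(st$x, dgates),
       dWh = crossprod(st$h_prev, dgates),
       db = as.numeric(dgates),
       dh_prev = dgates %*% t(cell$Wh),
       dc_prev = dc_prev,
       dx = dgates %*% t(cell$Wx))
}

check_sequence <- function(x, d) {
  if (!is.matrix(x)) x <- matrix(x, ncol = d)
  if (nrow(x) == 0L) dc_stop("empty sequence")
  if (ncol(x) != d) dc_stop("sequence feature width %d != model input %d", ncol(x), d)
  x
}

lstm_encode_one <- function(model, x, keep_cache = FALSE) {
  h <- model$arch$h
  x <- check_sequence(x, model$arch$d)
  hs <- matrix(0, 1L, h); cs <- matrix(0, 1L, h)
  cache <- if (keep_cache) vector("list", nrow(x)) else NULL
  for (t in seq_len(nrow(x))) {
    st <- lstm_step(model$params$enc, x[t, , drop = FALSE], hs, cs, h)
    hs <- st$h; cs <- st$c
    if (keep_cache) cache[[t]] <- st
  }
  list(h = hs, c = cs, cache = cache)
}

#' @export
encode.backbone_recurrent <- function(model, x) {
  if (is.matrix(x)) x <- list(x)
  if (!is.list(x)) dc_stop("recurrent input must be a list of L x d matrices")
  out <- matrix(0, length(x), model$arch$h)
  for (i in seq_along(x)) out[i, ] <- lstm_encode_one(model, x[[i]])$h
  out
}

# forward + (optionally) backward for one sequence; returns loss contribution
# and parameter grads (NULL when want_grads = FALSE)
lstm_seq_loss_grads <- function(model, x, want_grads = TRUE) {
  p <- model$params
  h <- model$arch$h; d <- model$arch$d
  x <- check_sequence(x, d)
  L <- nrow(x)
  enc <- lstm_encode_one(model, x, keep_cache = want_grads)
  # decoder teacher-forced inputs and reverse-order targets
  dec_in <- rbind(matrix(0, 1L, d), x[rev(seq_len(L)), , drop = FALSE][-L, , drop = FALSE])
  targets <- x[rev(seq_len(L)), , drop = FALSE]
  hs <- enc$h; cs <- enc$c
  dcache <- vector("list", L)
  preds <- matrix(0, L, d)
  for (t in seq_len(L)) {
    st <- lstm_step(p$dec, dec_in[t, , drop = FALSE], hs, cs, h)
    hs <- st$h; cs <- st$c
    preds[t, ] <- st$h %*% p$out$W + p$out$b
    if (want_grads) dcache[[t]] <- st
  }
  diff <- preds - targets
  loss <- sum(diff^2)
  if (!want_grads) return(list(loss = loss, preds = preds))

  zero4 <- function(cell) list(Wx = cell$Wx * 0, Wh = cell$Wh * 0, b = cell$b * 0)
  g_dec <- zero4(p$dec); g_enc <- zero4(p$enc)
  g_out <- list(W = p$out$W * 0, b = p$out$b * 0)
  dh <- matrix(0, 1L, h); dc <- matrix(0, 1L, h)
  for (t in rev(seq_len(L))) {
    dpred <- 2 * diff[t, , drop = FALSE]
    g_out$W <- g_out$W + crossprod(dcache[[t]]$h, dpred)
    g_out$b <- g_out$b + as.numeric(dpred)
    dh <- dh + dpred %*% t(p$out$W)
    bk <- lstm_step_backward(p$dec, dcache[[t]], dh, dc, h)
    g_dec$Wx <- g_dec$Wx + bk$dWx
    g_dec$Wh <- g_dec$Wh + bk$dWh
    g_dec$b <- g_dec$b + bk$db
    dh <- bk$dh_prev; dc <- bk$dc_prev
  }
  # decoder initial state = encoder final state: pass gradients through
  for (t in rev(seq_len(L))) {
    bk <- lstm_step_backward(p$enc, enc$cache[[t]], dh, dc, h)
    g_enc$Wx <- g_enc$Wx + bk$dWx
    g_enc$Wh <- g_enc$Wh + bk$dWh
    g_enc$b <- g_enc$b + bk$db
    dh <- bk$dh_prev; dc <- bk$dc_prev
  }
  list(loss = loss, grads = list(enc = g_enc, dec = g_dec, out = g_out))
}

lstm_loss_grads <- function(model, batch) {
  if (is.matrix(batch)) batch <- list(batch)
  n <- length(batch)
  if (n == 0L) dc_stop("empty batch")
  total <- 0
  acc <- NULL
  for (i in seq_len(n)) {
    r <- lstm_seq_loss_grads(model, batch[[i]])
    total <- total + r$loss
    acc <- if (is.null(acc)) r$grads else accumulate_grads(acc, r$grads)
  }
  list(loss = total / n, grads = scale_grads(acc, 1 / n))
}

accumulate_grads <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  for (i in seq_along(a)) a[[i]] <- accumulate_grads(a[[i]], b[[i]])
  a
}

scale_grads <- function(g, s) {
  if (is.numeric(g)) return(g * s)
  for (i in seq_along(g)) g[[i]] <- scale_grads(g[[i]], s)
  g
}

#' Sequence-reversal reconstruction loss of the LSTM autoencoder
#'
#' For each sequence `X = (x^(1), ..., x^(L))` the encoder compresses the
#' sequence into its final hidden state, the decoder is seeded with that
#' state and the loss is `sum_i || x^(i) - x'^(i) ||^2` with reconstruction
#' targets taken in reverse input order. Reported as per-sequence sums,
#' reduced as the mean over the batch.
#'
#' @param batch A list of `L x d` matrices (or a single matrix).
#' @param model A recurrent-family backbone.
#' @return A `"reconstruction_report"` with `loss_kind = "sequence_reverse"`.
#' @export
lstm_ae_loss <- function(batch, model) {
  if (!inherits(model, "backbone_recurrent")) {
    dc_stop("`model` must be a recurrent backbone")
  }
  if (is.matrix(batch)) batch <- list(batch)
  per <- vapply(batch, function(s) lstm_seq_loss_grads(model, s, want_grads = FALSE)$loss,
                numeric(1))
  structure(list(loss_value = mean(per), per_sample_losses = per,
                 loss_kind = "sequence_reverse"),
            class = "reconstruction_report")
}

#' @export
reconstruct.backbone_recurrent <- function(model, x) {
  if (is.matrix(x)) {
    return(lstm_seq_loss_grads(model, x, want_grads = FALSE)$preds)
  }
  lapply(x, function(s) lstm_seq_loss_grads(model, s, want_grads = FALSE)$preds)
}
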