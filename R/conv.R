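# Convolutional autoencoder for channels-last image tensors (n, h, w, c).
# Encoder stages: same-padding stride-1 convolution (odd kernels), ReLU,
# non-overlapping max-pooling; then a linear dense map to the latent code.
# Decoder mirrors with nearest-neighbour upsampling + convolution per stage
# and a sigmoid output layer keeping intensities in [0, 1].
# Convolutions are evaluated as matrix products through an im2col index map;
# backward passes are hand-written and finite-difference checked in tests.

build_conv_model <- function(spec, input_shape) {
  if (length(input_shape) != 3L) {
    dc_stop("convolutional input_shape must be c(height, width, channels)")
  }
  h <- check_count(input_shape[1L], "height")
  w <- check_count(input_shape[2L], "width")
  cin <- check_count(input_shape[3L], "channels")
  stages <- spec$layer_sizes
  geom <- vector("list", length(stages))
  ch <- cin; hh <- h; ww <- w
  for (s in seq_along(stages)) {
    co <- as.integer(stages[[s]][1L])
    k <- as.integer(stages[[s]][2L])
    p <- as.integer(stages[[s]][3L])
    if (k %% 2L == 0L) dc_stop("convolution kernels must be odd-sized")
    if (hh %% p != 0L || ww %% p != 0L) {
      dc_stop("spatial size %dx%d not divisible by pool %d at stage %d", hh, ww, p, s)
    }
    geom[[s]] <- list(h = hh, w = ww, cin = ch, cout = co, k = k, pool = p,
                      idx = im2col_index(hh, ww, ch, k))
    ch <- co; hh <- hh %/% p; ww <- ww %/% p
  }
  flat <- hh * ww * ch
  nstg <- length(stages)
  conv_init <- function(g) {
    kk <- g$k * g$k * g$cin
    list(W = matrix(stats::rnorm(kk * g$cout, sd = sqrt(2 / kk)), kk, g$cout),
         b = numeric(g$cout))
  }
  enc <- lapply(geom, conv_init)
  # decoder geometry: reverse stages; stage s of the decoder upsamples by the
  # pool of encoder stage (nstg - s + 1) and convolves back to that stage's
  # input channel count (the last one lands on the original image channels)
  dgeom <- vector("list", nstg)
  dh <- hh; dw <- ww; dch <- ch
  for (s in seq_len(nstg)) {
    g_enc <- geom[[nstg - s + 1L]]
    dh <- dh * g_enc$pool; dw <- dw * g_enc$pool
    dgeom[[s]] <- list(h = dh, w = dw, cin = dch, cout = g_enc$cin,
                       k = g_enc$k, pool = g_enc$pool,
                       idx = im2col_index(dh, dw, dch, g_enc$k))
    dch <- g_enc$cin
  }
  dec <- lapply(dgeom, conv_init)
  list(params = list(enc = enc,
                     fc_enc = init_dense_layer(flat, spec$latent_dim)[c("W", "b")],
                     fc_dec = init_dense_layer(spec$latent_dim, flat)[c("W", "b")],
                     dec = dec),
       arch = list(h = h, w = w, cin = cin, geom = geom, dgeom = dgeom,
                   flat = flat, flat_h = hh, flat_w = ww, flat_c = ch))
}

# Index map from output-pixel x kernel-element to positions in the padded
# per-sample slice (hp * wp * c values). Rows ordered row-index fastest.
im2col_index <- function(h, w, c, k) {
  pad <- (k - 1L) %/% 2L
  hp <- h + 2L * pad; wp <- w + 2L * pad
  oi <- rep(seq_len(h), times = w)            # output row, fastest
  oj <- rep(seq_len(w), each = h)
  di <- rep(seq_len(k), times = k)
  dj <- rep(seq_len(k), each = k)
  # offsets for one channel
  base <- outer(oi - 1L, di - 1L, "+") + hp * outer(oj - 1L, dj - 1L, "+")  # (hw, k*k)
  idx <- matrix(0L, h * w, k * k * c)
  for (ci in seq_len(c)) {
    idx[, ((ci - 1L) * k * k + 1L):(ci * k * k)] <- base + hp * wp * (ci - 1L) + 1L
  }
  idx
}

pad_images <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L], d[2L] + 2L * pad, d[3L] + 2L * pad, d[4L]))
  out[, (pad + 1L):(pad + d[2L]), (pad + 1L):(pad + d[3L]), ] <- x
  out
}

unpad_images <- function(x, pad, h, w) {
  if (pad == 0L) return(x)
  x[, (pad + 1L):(pad + h), (pad + 1L):(pad + w), , drop = FALSE]
}

# forward convolution; returns list(out (n,h,w,cout), cols ((n*hw) x K))
conv_apply <- function(x, par, g) {
  n <- dim(x)[1L]
  pad <- (g$k - 1L) %/% 2L
  xp <- pad_images(x, pad)
  dim(xp) <- c(n, length(xp) / n)
  cols <- xp[, as.vector(g$idx), drop = FALSE]
  dim(cols) <- c(n * g$h * g$w, ncol(g$idx))
  out <- sweep(cols %*% par$W, 2L, par$b, "+")
  dim(out) <- c(n, g$h, g$w, g$cout)
  list(out = out, cols = cols)
}

# backward convolution: returns grads and d_input
conv_backward <- function(d_out, cols, par, g, n) {
  dim(d_out) <- c(n * g$h * g$w, g$cout)
  gW <- crossprod(cols, d_out)
  gb <- colSums(d_out)
  dcols <- d_out %*% t(par$W)           # (n*hw) x K
  pad <- (g$k - 1L) %/% 2L
  hp <- g$h + 2L * pad; wp <- g$w + 2L * pad
  dxp <- matrix(0, n, hp * wp * g$cin)
  dim(dcols) <- c(n, g$h * g$w, ncol(g$idx))
  for (k in seq_len(ncol(g$idx))) {
    cols_k <- g$idx[, k]
    dxp[, cols_k] <- dxp[, cols_k] + dcols[, , k]
  }
  dim(dxp) <- c(n, hp, wp, g$cin)
  list(W = gW, b = gb,
       d_input = unpad_images(dxp, pad, g$h, g$w))
}

# non-overlapping p x p max pooling with argmax memo
maxpool_apply <- function(x, p) {
  d <- dim(x)
  ho <- d[2L] %/% p; wo <- d[3L] %/% p
  best <- array(-Inf, c(d[1L], ho, wo, d[4L]))
  which_k <- array(1L, c(d[1L], ho, wo, d[4L]))
  k <- 0L
  for (pw in seq_len(p)) {
    for (ph in seq_len(p)) {
      k <- k + 1L
      cand <- x[, seq(ph, d[2L], by = p), seq(pw, d[3L], by = p), , drop = FALSE]
      better <- cand > best
      best[better] <- cand[better]
      which_k[better] <- k
    }
  }
  list(out = best, which_k = which_k)
}

maxpool_backward <- function(d_out, which_k, p, h, w) {
  d <- dim(d_out)
  dx <- array(0, c(d[1L], h, w, d[4L]))
  k <- 0L
  for (pw in seq_len(p)) {
    for (ph in seq_len(p)) {
      k <- k + 1L
      mask <- which_k == k
      tmp <- array(0, d)
      tmp[mask] <- d_out[mask]
      dx[, seq(ph, h, by = p), seq(pw, w, by = p), ] <- tmp
    }
  }
  dx
}

upsample_apply <- function(x, p) {
  d <- dim(x)
  x[, rep(seq_len(d[2L]), each = p), rep(seq_len(d[3L]), each = p), , drop = FALSE]
}

upsample_backward <- function(d_out, p) {
  d <- dim(d_out)
  ho <- d[2L] %/% p; wo <- d[3L] %/% p
  acc <- array(0, c(d[1L], ho, wo, d[4L]))
  for (pw in seq_len(p)) {
    for (ph in seq_len(p)) {
      acc <- acc + d_out[, seq(ph, d[2L], by = p), seq(pw, d[3L], by = p), , drop = FALSE]
    }
  }
  acc
}

conv_encode_forward <- function(model, x) {
  a <- model$arch
  caches <- vector("list", length(a$geom))
  cur <- x
  for (s in seq_along(a$geom)) {
    g <- a$geom[[s]]
    cv <- conv_apply(cur, model$params$enc[[s]], g)
    act <- pmax(cv$out, 0)
    pl <- maxpool_apply(act, g$pool)
    caches[[s]] <- list(cols = cv$cols, pre = cv$out, which_k = pl$which_k,
                        act_dim = dim(act))
    cur <- pl$out
  }
  n <- dim(x)[1L]
  flat <- cur
  dim(flat) <- c(n, a$flat)
  z <- sweep(flat %*% model$params$fc_enc$W, 2L, model$params$fc_enc$b, "+")
  list(z = z, flat = flat, caches = caches)
}

conv_encode_backward <- function(model, fwd, dz, n) {
  a <- model$arch
  g_fc <- list(W = crossprod(fwd$flat, dz), b = colSums(dz))
  dflat <- dz %*% t(model$params$fc_enc$W)
  cur <- dflat
  dim(cur) <- c(n, a$flat_h, a$flat_w, a$flat_c)
  g_enc <- vector("list", length(a$geom))
  for (s in rev(seq_along(a$geom))) {
    g <- a$geom[[s]]
    cc <- fwd$caches[[s]]
    d_act <- maxpool_backward(cur, cc$which_k, g$pool, g$h, g$w)
    d_pre <- d_act * (cc$pre > 0)
    bk <- conv_backward(d_pre, cc$cols, model$params$enc[[s]], g, n)
    g_enc[[s]] <- list(W = bk$W, b = bk$b)
    cur <- bk$d_input
  }
  list(grads = list(enc = g_enc, fc_enc = g_fc), d_input = cur)
}

conv_decode_forward <- function(model, z) {
  a <- model$arch
  n <- nrow(z)
  pre_fc <- sweep(z %*% model$params$fc_dec$W, 2L, model$params$fc_dec$b, "+")
  hflat <- pmax(pre_fc, 0)
  cur <- hflat
  dim(cur) <- c(n, a$flat_h, a$flat_w, a$flat_c)
  caches <- vector("list", length(a$dgeom))
  for (s in seq_along(a$dgeom)) {
    g <- a$dgeom[[s]]
    up <- upsample_apply(cur, g$pool)
    cv <- conv_apply(up, model$params$dec[[s]], g)
    last <- s == length(a$dgeom)
    out <- if (last) 1 / (1 + exp(-cv$out)) else pmax(cv$out, 0)
    caches[[s]] <- list(cols = cv$cols, pre = cv$out, out = out, last = last)
    cur <- out
  }
  list(out = cur, pre_fc = pre_fc, caches = caches)
}

conv_decode_backward <- function(model, fwd, d_out, z, n) {
  a <- model$arch
  g_dec <- vector("list", length(a$dgeom))
  cur <- d_out
  for (s in rev(seq_along(a$dgeom))) {
    g <- a$dgeom[[s]]
    cc <- fwd$caches[[s]]
    d_pre <- if (cc$last) cur * cc$out * (1 - cc$out) else cur * (cc$pre > 0)
    bk <- conv_backward(d_pre, cc$cols, model$params$dec[[s]], g, n)
    g_dec[[s]] <- list(W = bk$W, b = bk$b)
    cur <- upsample_backward(bk$d_input, g$pool)
  }
  dim(cur) <- c(n, a$flat)
  d_hflat <- cur * (fwd$pre_fc > 0)
  g_fc <- list(W = crossprod(z, d_hflat), b = colSums(d_hflat))
  dz <- d_hflat %*% t(model$params$fc_dec$W)
  list(grads = list(fc_dec = g_fc, dec = g_dec), dz = dz)
}

conv_loss_grads <- function(model, x) {
  n <- dim(x)[1L]
  fe <- conv_encode_forward(model, x)
  fd <- conv_decode_forward(model, fe$z)
  diff <- fd$out - x
  loss <- sum(diff^2) / n
  d_out <- 2 * diff / n
  bd <- conv_decode_backward(model, fd, d_out, fe$z, n)
  be <- conv_encode_backward(model, fe, bd$dz, n)
  list(loss = loss,
       grads = list(enc = be$grads$enc, fc_enc = be$grads$fc_enc,
                    fc_dec = bd$grads$fc_dec, dec = bd$grads$dec))
}

check_image_batch <- function(model, x) {
  if (length(dim(x)) != 4L) dc_stop("convolutional input must be a 4-d array (n, h, w, c)")
  a <- model$arch
  if (!all(dim(x)[2:4] == c(a$h, a$w, a$cin))) {
    dc_stop("image shape %s does not match model input %dx%dx%d",
            paste(dim(x)[2:4], collapse = "x"), a$h, a$w, a$cin)
  }
  invisible(x)
}

#' @export
encode.backbone_convolutional <- function(model, x) {
  check_image_batch(model, x)
  conv_encode_forward(model, x)$z
}

#' @export
reconstruct.backbone_convolutional <- function(model, x) {
  check_image_batch(model, x)
  conv_decode_forward(model, conv_encode_forward(model, x)$z)$out
}
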