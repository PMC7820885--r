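# Minimal dense-network machinery: layers are lists(W, b, act) with W stored
# input x output so a batch (rows = samples) propagates as A %*% W + b.
# Backpropagation and Adam are hand-written; every loss in the package is
# validated against central finite differences in the test suite.

ACTIVATIONS <- list(
  linear  = list(f = function(x) x,            df = function(x, a) matrix(1, nrow(x), ncol(x))),
  relu    = list(f = function(x) pmax(x, 0),   df = function(x, a) (x > 0) * 1),
  sigmoid = list(f = function(x) 1 / (1 + exp(-x)), df = function(x, a) a * (1 - a)),
  tanh    = list(f = tanh,                     df = function(x, a) 1 - a^2)
)

act_fun <- function(name) {
  a <- ACTIVATIONS[[name]]
  if (is.null(a)) dc_stop("unknown activation '%s'", name)
  a
}

# He-scaled Gaussian initialization; caller is responsible for seeding.
init_dense_layer <- function(n_in, n_out, act = "relu") {
  sd <- sqrt(2 / n_in)
  list(
    W = matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out),
    b = numeric(n_out),
    act = act
  )
}

# Forward through a stack of dense layers. Returns list(out, cache) where
# cache holds per-layer pre-activations and activations for backprop.
dense_forward <- function(layers, x, keep_cache = TRUE) {
  a <- x
  cache <- if (keep_cache) vector("list", length(layers)) else NULL
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    pre <- sweep(a %*% ly$W, 2L, ly$b, "+")
    a_new <- act_fun(ly$act)$f(pre)
    if (keep_cache) cache[[l]] <- list(input = a, pre = pre, out = a_new)
    a <- a_new
  }
  list(out = a, cache = cache)
}

# Backward pass: given upstream gradient d_out on the stack output, returns
# list(grads = per-layer list(W, b), d_input = gradient w.r.t. the input).
dense_backward <- function(layers, cache, d_out) {
  grads <- vector("list", length(layers))
  delta <- d_out
  for (l in rev(seq_along(layers))) {
    ly <- layers[[l]]
    cc <- cache[[l]]
    dpre <- delta * act_fun(ly$act)$df(cc$pre, cc$out)
    grads[[l]] <- list(W = crossprod(cc$input, dpre), b = colSums(dpre))
    delta <- tcrossprod(dpre, ly$W)
  }
  list(grads = grads, d_input = delta)
}

# ---- flat parameter plumbing (shared by all families) ----------------------

# Parameters are addressed as nested lists of numeric arrays; these helpers
# flatten/unflatten for the optimizer and for finite-difference checks.
flatten_params <- function(p) {
  if (is.numeric(p)) return(as.numeric(p))
  unlist(lapply(p, flatten_params), use.names = FALSE)
}

assign_flat <- function(p, flat, offset = 0L) {
  if (is.numeric(p)) {
    k <- length(p)
    pnew <- p
    pnew[] <- flat[(offset + 1L):(offset + k)]
    return(list(value = pnew, offset = offset + k))
  }
  for (i in seq_along(p)) {
    r <- assign_flat(p[[i]], flat, offset)
    p[[i]] <- r$value
    offset <- r$offset
  }
  list(value = p, offset = offset)
}

# ---- Adam optimizer --------------------------------------------------------

adam_init <- function(flat_len) {
  list(m = numeric(flat_len), v = numeric(flat_len), t = 0L)
}

adam_step <- function(state, flat_params, flat_grads, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * flat_grads
  state$v <- beta2 * state$v + (1 - beta2) * flat_grads^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state,
       params = flat_params - lr * mhat / (sqrt(vhat) + eps))
}

# ---- finite differences (test oracle support) ------------------------------

#' Central finite-difference gradient of a scalar function
#'
#' Numerical gradient used as the independent oracle for every analytic
#' gradient in the package.
#'
#' @param f Function taking a flat numeric vector, returning a scalar.
#' @param x Flat numeric vector at which to differentiate.
#' @param h Step size.
#' @return Numeric gradient vector of `length(x)`.
#' @export
numeric_gradient <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
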