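# Minimal neural-net primitives (forward + hand-derived backward) used by
# the convolutional backbone. Elementwise and reduction kernels live in
# src/nnops.cpp; this file holds the parameter/state bookkeeping. All state
# is plain R arrays so checkpoints and deterministic replay are trivial.

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# --- batch normalization over columns of a (n x F) matrix -------------------
# One column per feature map; rows are the normalization axis (batch x time).
bn_init <- function(F) {
  list(gamma = rep(1, F), beta = rep(0, F),
       run_mean = rep(0, F), run_var = rep(1, F))
}

bn_fwd <- function(p, x, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    core <- bn_fwd_core(x, p$gamma, p$beta, eps)
    mu <- as.vector(core$mu)
    v <- as.vector(core$var)
    n <- nrow(x)
    p$run_mean <- (1 - momentum) * p$run_mean + momentum * mu
    p$run_var <- (1 - momentum) * p$run_var +
      momentum * v * n / max(1, n - 1)
  } else {
    core <- bn_fwd_eval(x, p$run_mean, p$run_var, p$gamma, p$beta, eps)
    v <- p$run_var
  }
  list(y = core$y, p = p,
       cache = list(xhat = core$xhat, inv_sd = 1 / sqrt(v + eps),
                    training = training))
}

bn_bwd <- function(p, cache, dy) {
  out <- bn_bwd_core(dy, cache$xhat, p$gamma, cache$inv_sd, cache$training)
  list(dx = out$dx, dgamma = as.vector(out$dgamma),
       dbeta = as.vector(out$dbeta))
}

# --- ELU --------------------------------------------------------------------
elu_fwd <- function(x) {
  y <- elu_fwd_cpp(x)
  attributes(y) <- attributes(x)
  list(y = y, cache = list(y = y))
}

elu_bwd <- function(cache, dy) {
  g <- elu_bwd_cpp(cache$y, dy)
  attributes(g) <- attributes(dy)
  g
}

# --- average pooling along the 2nd dim of an (M, T, B) array ----------------
avgpool_fwd <- function(x, p) {
  d <- dim(x)
  if (p == 1) return(x)
  stopifnot(d[2] %% p == 0)
  y <- avgpool_fwd_cpp(x, d[1], d[2], d[3], p)
  dim(y) <- c(d[1], d[2] %/% p, d[3])
  y
}

avgpool_bwd <- function(dy, p, T_in) {
  if (p == 1) return(dy)
  d <- dim(dy)
  dx <- avgpool_bwd_cpp(dy, d[1], d[2], d[3], p)
  dim(dx) <- c(d[1], T_in, d[3])
  dx
}

# --- dropout (inverted scaling; mask drawn from the R RNG) ------------------
dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- array(stats::runif(length(x)) >= rate, dim = dim(x)) / (1 - rate)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(mask, dy) {
  if (is.null(mask)) dy else dy * mask
}

# --- Adam optimizer ---------------------------------------------------------
# params/grads are flat named lists of numeric arrays.
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
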