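#' Channel-projection (ResizeNet) parameters
#'
#' A learnable linear channel-mixing layer applied per time sample: a
#' `C_out x C_in` weight matrix (equivalently a width-1 temporal convolution
#' across channels) mapping a higher-channel montage onto a lower-channel
#' one so heterogeneous domains share one input space. Initialized to the
#' channel-selection matrix (first `C_out` channels), so training starts at
#' the truncation baseline. No nonlinearity; bias optional and off by
#' default.
#'
#' @param c_in,c_out Input/output channel counts, `c_out <= c_in`.
#' @param bias Logical, include a per-output-channel bias.
#' @return An object of class `resizenet_params` with fields `weight`
#'   (`c_out x c_in`) and `bias` (`NULL` or length-`c_out`).
#' @export
resizenet_params <- function(c_in, c_out, bias = FALSE) {
  if (c_out > c_in) {
    stop("projection must reduce channels: c_out <= c_in", call. = FALSE)
  }
  W <- diag(1, nrow = c_out, ncol = c_in)
  structure(list(weight = W, bias = if (bias) rep(0, c_out) else NULL),
            class = "resizenet_params")
}

#' Project a signal through the channel projection
#'
#' `output = weight %*% signal` (plus per-row bias if present); linear in
#' the input.
#'
#' @param params A [resizenet_params()].
#' @param signal `C_in x T` matrix.
#' @return `C_out x T` matrix.
#' @export
resize_project <- function(params, signal) {
  if (nrow(signal) != ncol(params$weight)) {
    stop("shape error: signal has ", nrow(signal), " rows, projection expects ",
         ncol(params$weight), call. = FALSE)
  }
  out <- params$weight %*% signal
  if (!is.null(params$bias)) out <- out + params$bias
  out
}

#' Channel-truncation baseline
#'
#' Unifies montages by keeping the first `c_out` channels and discarding the
#' rest — the channel-selection strategy the projection is initialized to
#' and distilled against.
#'
#' @param signal `C_in x T` matrix.
#' @param c_out Number of channels to keep (`1 <= c_out <= C_in`).
#' @return `c_out x T` matrix holding the first `c_out` rows.
#' @export
truncate_channels <- function(signal, c_out) {
  if (c_out < 1 || c_out > nrow(signal)) {
    stop("parameter error: c_out must be in [1, ", nrow(signal), "]",
         call. = FALSE)
  }
  signal[seq_len(c_out), , drop = FALSE]
}

#' Backbone configuration
#'
#' Hyperparameters of the compact convolutional EEG backbone (the EEGNet-8,2
#' standard): `F1` temporal filters of length `kernel_samples`, a depthwise
#' spatial filter with depth multiplier `D`, a separable temporal stage with
#' `F2 = F1 * D` filters, two average-pooling stages, ELU activations, batch
#' normalization and dropout.
#'
#' @param F1 Temporal filter count (default 8).
#' @param D Depth multiplier of the spatial stage (default 2).
#' @param F2 Separable filter count; the `F1 * D` convention is enforced.
#' @param kernel_samples Temporal kernel length in samples (the convention
#'   is half the sampling rate).
#' @param sep_kernel Separable-stage temporal kernel length (default 16).
#' @param pool1,pool2 Average pooling widths (defaults 4 and 8).
#' @param dropout Dropout probability in `[0, 1)` (default 0.25).
#' @param n_classes Output classes (2: seizure vs non-seizure).
#' @return An object of class `eegnet_config`.
#' @export
eegnet_config <- function(F1 = 8, D = 2, F2 = F1 * D, kernel_samples = 128,
                          sep_kernel = 16, pool1 = 4, pool2 = 8,
                          dropout = 0.25, n_classes = 2) {
  if (F2 != F1 * D) stop("convention F2 = F1 * D is enforced", call. = FALSE)
  if (kernel_samples < 2) stop("kernel_samples must be >= 2", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0,1)",
                                        call. = FALSE)
  structure(list(F1 = F1, D = D, F2 = F2, kernel_samples = kernel_samples,
                 sep_kernel = sep_kernel, pool1 = pool1, pool2 = pool2,
                 dropout = dropout, n_classes = n_classes),
            class = "eegnet_config")
}

#' Initialize backbone parameters
#'
#' Glorot-uniform convolution/dense weights (drawn from the current R RNG
#' stream, so results are reproducible under `set.seed()`), unit-gamma batch
#' norms. The time dimension must be divisible by `pool1 * pool2`.
#'
#' @param cfg An [eegnet_config()].
#' @param n_channels Input channel count the backbone is built at.
#' @param n_samples Input clip length in samples.
#' @return An object of class `eegnet_model` holding trainable `params`,
#'   batch-norm running `state`, and geometry.
#' @export
eegnet_init <- function(cfg, n_channels, n_samples) {
  C <- n_channels; T <- n_samples
  if (T %% (cfg$pool1 * cfg$pool2) != 0) {
    stop("n_samples must be divisible by pool1 * pool2 = ",
         cfg$pool1 * cfg$pool2, call. = FALSE)
  }
  M <- cfg$F1 * cfg$D
  T5 <- T / (cfg$pool1 * cfg$pool2)
  Fdim <- cfg$F2 * T5
  params <- list(
    W1 = glorot_uniform(cfg$kernel_samples, cfg$F1,
                        c(cfg$kernel_samples, cfg$F1)),
    g1 = rep(1, cfg$F1), b1 = rep(0, cfg$F1),
    Wd = glorot_uniform(C, cfg$D, c(cfg$D, C, cfg$F1)),
    g2 = rep(1, M), b2 = rep(0, M),
    W2 = glorot_uniform(cfg$sep_kernel, M, c(cfg$sep_kernel, M)),
    Wp = glorot_uniform(M, cfg$F2, c(cfg$F2, M)),
    g3 = rep(1, cfg$F2), b3 = rep(0, cfg$F2),
    Wc = glorot_uniform(Fdim, cfg$n_classes, c(Fdim, cfg$n_classes)),
    bc = rep(0, cfg$n_classes)
  )
  state <- list(bn1 = bn_init(cfg$F1), bn2 = bn_init(M), bn3 = bn_init(cfg$F2))
  structure(list(cfg = cfg, n_channels = C, n_samples = T,
                 feature_dim = Fdim, params = params, state = state),
            class = "eegnet_model")
}

#' Number of trainable parameters
#' @param model An [eegnet_model()] from [eegnet_init()].
#' @return Integer count of trainable scalars (batch-norm running statistics
#'   excluded).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# Full forward pass. Xb is a (B, C, T) array. Returns features, logits, the
# cache required for backward, and the model (batch-norm running statistics
# are updated in training mode).
eegnet_forward <- function(model, Xb, training = FALSE) {
  cfg <- model$cfg
  B <- dim(Xb)[1]; C <- dim(Xb)[2]; T <- dim(Xb)[3]
  if (C != model$n_channels || T != model$n_samples) {
    stop("shape error: backbone built for ", model$n_channels, " x ",
         model$n_samples, ", got ", C, " x ", T, call. = FALSE)
  }
  p <- model$params; st <- model$state
  M <- cfg$F1 * cfg$D
  T4 <- T / cfg$pool1; T5 <- T4 / cfg$pool2

  # temporal convolution: F1 filters on every channel
  st$bn1$gamma <- p$g1; st$bn1$beta <- p$b1
  st$bn2$gamma <- p$g2; st$bn2$beta <- p$b2
  st$bn3$gamma <- p$g3; st$bn3$beta <- p$b3

  X1 <- matrix(aperm(Xb, c(3, 2, 1)), nrow = T)          # T x (C*B)
  Y1 <- conv1d_same_fwd(X1, p$W1)                        # (T, CB, F1)
  M1 <- matrix(Y1, ncol = cfg$F1)                        # (T*CB) x F1
  bn1 <- bn_fwd(st$bn1, M1, training); st$bn1 <- bn1$p

  # depthwise spatial filter: D filters across channels, per temporal map
  A <- array(bn1$y, c(T, C, B, cfg$F1))
  Zm <- array(0, c(M, T, B))
  Pf <- vector("list", cfg$F1)
  for (f in seq_len(cfg$F1)) {
    Af <- array(A[, , , f], c(T, C, B))
    P <- matrix(aperm(Af, c(2, 1, 3)), nrow = C)
    Pf[[f]] <- P                                          # C x (T*B)
    Zm[((f - 1) * cfg$D + 1):(f * cfg$D), , ] <-
      array(p$Wd[, , f] %*% P, c(cfg$D, T, B))
  }
  Z2 <- t(matrix(Zm, nrow = M))                           # (T*B) x M
  bn2 <- bn_fwd(st$bn2, Z2, training); st$bn2 <- bn2$p
  e2 <- elu_fwd(bn2$y)
  P1 <- avgpool_fwd(array(t(e2$y), c(M, T, B)), cfg$pool1) # (M, T4, B)
  dp1 <- dropout_fwd(P1, cfg$dropout, training)

  # separable stage: depthwise temporal conv then pointwise mixing
  X2 <- matrix(aperm(dp1$y, c(2, 1, 3)), nrow = T4)       # T4 x (M*B)
  Y2 <- dwconv1d_same_fwd(X2, p$W2, M)                    # T4 x (M*B)
  Pm <- matrix(aperm(array(Y2, c(T4, M, B)), c(2, 1, 3)), nrow = M)
  Pw <- p$Wp %*% Pm                                       # F2 x (T4*B)
  Z3 <- t(Pw)                                             # (T4*B) x F2
  bn3 <- bn_fwd(st$bn3, Z3, training); st$bn3 <- bn3$p
  e3 <- elu_fwd(bn3$y)
  P2 <- avgpool_fwd(array(t(e3$y), c(cfg$F2, T4, B)), cfg$pool2) # (F2,T5,B)
  dp2 <- dropout_fwd(P2, cfg$dropout, training)

  feats <- t(matrix(dp2$y, nrow = cfg$F2 * T5))           # B x F
  logits <- feats %*% p$Wc + matrix(p$bc, B, cfg$n_classes, byrow = TRUE)

  model$state <- st
  cache <- list(B = B, C = C, T = T, T4 = T4, T5 = T5, M = M,
                X1 = X1, bn1 = bn1$cache, Pf = Pf,
                bn2 = bn2$cache, e2 = e2$cache, mask1 = dp1$mask,
                X2 = X2, Pm = Pm, bn3 = bn3$cache, e3 = e3$cache,
                mask2 = dp2$mask, feats = feats)
  list(feats = feats, logits = logits, cache = cache, model = model)
}

# Backward pass: dlogits (B x K) and optional dfeats (B x F) flow back to
# gradients for every trainable parameter and to the input (B, C, T).
eegnet_backward <- function(model, cache, dlogits, dfeats = NULL) {
  cfg <- model$cfg; p <- model$params
  B <- cache$B; C <- cache$C; T <- cache$T
  T4 <- cache$T4; T5 <- cache$T5; M <- cache$M

  dWc <- crossprod(cache$feats, dlogits)
  dbc <- colSums(dlogits)
  dfe <- tcrossprod(dlogits, p$Wc)                        # B x F
  if (!is.null(dfeats)) dfe <- dfe + dfeats

  dP2 <- array(t(dfe), c(cfg$F2, T5, B))
  dP2 <- dropout_bwd(cache$mask2, dP2)
  dE3 <- avgpool_bwd(dP2, cfg$pool2, T4)                  # (F2, T4, B)
  dy3 <- elu_bwd(cache$e3, t(matrix(dE3, nrow = cfg$F2))) # (T4*B) x F2
  b3 <- bn_bwd(list(gamma = p$g3), cache$bn3, dy3)
  dPw <- t(b3$dx)                                         # F2 x (T4*B)
  dWp <- tcrossprod(dPw, cache$Pm)
  dPm <- crossprod(p$Wp, dPw)                             # M x (T4*B)
  dY2 <- matrix(aperm(array(dPm, c(M, T4, B)), c(2, 1, 3)), nrow = T4)
  dW2 <- dwconv1d_same_bwd_w(cache$X2, dY2, M, cfg$sep_kernel)
  dX2 <- dwconv1d_same_bwd_x(dY2, p$W2, M)                # T4 x (M*B)
  dP1 <- aperm(array(dX2, c(T4, M, B)), c(2, 1, 3))       # (M, T4, B)
  dP1 <- dropout_bwd(cache$mask1, dP1)
  dE2 <- avgpool_bwd(dP1, cfg$pool1, T)                   # (M, T, B)
  dy2 <- elu_bwd(cache$e2, t(matrix(dE2, nrow = M)))      # (T*B) x M
  b2 <- bn_bwd(list(gamma = p$g2), cache$bn2, dy2)
  dZm <- array(t(b2$dx), c(M, T, B))

  dA <- array(0, c(T, C, B, cfg$F1))
  dWd <- array(0, dim = dim(p$Wd))
  for (f in seq_len(cfg$F1)) {
    rows <- ((f - 1) * cfg$D + 1):(f * cfg$D)
    dZf <- matrix(dZm[rows, , ], nrow = cfg$D)            # D x (T*B)
    dWd[, , f] <- tcrossprod(dZf, cache$Pf[[f]])
    dPc <- crossprod(p$Wd[, , f], dZf)                    # C x (T*B)
    dA[, , , f] <- aperm(array(dPc, c(C, T, B)), c(2, 1, 3))
  }
  dM1 <- matrix(dA, ncol = cfg$F1)
  b1 <- bn_bwd(list(gamma = p$g1), cache$bn1, dM1)
  dY1 <- as.vector(b1$dx)
  cb <- conv1d_same_bwd(cache$X1, dY1, p$W1)
  dW1 <- cb$dW
  dXb <- aperm(array(cb$dX, c(T, C, B)), c(3, 2, 1))

  grads <- list(W1 = dW1, g1 = b1$dgamma, b1 = b1$dbeta,
                Wd = dWd, g2 = b2$dgamma, b2 = b2$dbeta,
                W2 = dW2, Wp = dWp, g3 = b3$dgamma, b3 = b3$dbeta,
                Wc = dWc, bc = dbc)
  list(grads = grads, dX = dXb)
}

#' Features and logits for a batch of trials
#'
#' Deterministic evaluation-mode forward pass through the backbone and
#' classifier.
#'
#' @param model An [eegnet_model()].
#' @param batch `(B, C, T)` array of clips.
#' @return A list with `features` (`B x F`) and `logits` (`B x n_classes`).
#' @export
eegnet_logits <- function(model, batch) {
  out <- eegnet_forward(model, batch, training = FALSE)
  list(features = out$feats, logits = out$logits)
}

#' Save / load a model checkpoint
#'
#' Single-file serialized checkpoint (versioned schema) embedding the
#' architecture configuration, trainable parameters and batch-norm state.
#'
#' @param model An [eegnet_model()] or [msa_model()].
#' @param path Checkpoint file path.
#' @return `path` invisibly (`save_checkpoint`); the restored model
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(schema = "seizalign-checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "seizalign-checkpoint")) {
    stop("not a seizalign checkpoint", call. = FALSE)
  }
  obj$model
}
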