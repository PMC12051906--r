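#' Loss weights for the multi-space objective
#'
#' The composite objective is
#' `classification + lambda_kd * distillation + beta_da * adaptation`,
#' with both trade-off weights defaulting to 1 (the setting used throughout;
#' performance is robust over a wide range). Temperatures soften the softmax
#' in the distillation (`tau_kd`, conventional 2) and class-confusion
#' (`tau_mcc`, 2.5) terms.
#'
#' @param lambda_kd Distillation weight, >= 0.
#' @param beta_da Domain-adaptation weight, >= 0.
#' @param tau_kd,tau_mcc Temperatures, > 0.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_kd = 1, beta_da = 1, tau_kd = 2,
                         tau_mcc = 2.5) {
  if (lambda_kd < 0 || beta_da < 0) stop("weights must be >= 0", call. = FALSE)
  if (tau_kd <= 0 || tau_mcc <= 0) stop("temperatures must be > 0",
                                        call. = FALSE)
  structure(list(lambda_kd = lambda_kd, beta_da = beta_da,
                 tau_kd = tau_kd, tau_mcc = tau_mcc),
            class = "loss_weights")
}

# Row-wise softmax with guard against overflow.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Softmax cross-entropy on labeled logits
#'
#' Mean over the batch of `-log p_true`. Returns the scalar; with
#' `grad = TRUE` also the gradient with respect to the logits.
#'
#' @param logits `B x K` matrix.
#' @param labels Integer vector in `0..K-1`.
#' @param grad Return the gradient as well?
#' @return Scalar loss, or `list(value, grad)`.
#' @export
cross_entropy_loss <- function(logits, labels, grad = FALSE) {
  B <- nrow(logits); K <- ncol(logits)
  P <- softmax_rows(logits)
  idx <- cbind(seq_len(B), as.integer(labels) + 1L)
  value <- -mean(log(pmax(P[idx], 1e-300)))
  if (!grad) return(value)
  G <- P
  G[idx] <- G[idx] - 1
  list(value = value, grad = G / B)
}

#' Knowledge-distillation loss (temperature-scaled KL)
#'
#' Output-space alignment: the Kullback-Leibler divergence from the
#' teacher's softened class distribution to the student's,
#' `mean_b KL(softmax(t/tau) || softmax(s/tau)) * tau^2`. The teacher is
#' treated as a constant (no gradient flows into it).
#'
#' @param student_logits,teacher_logits `B x K` matrices.
#' @param tau Temperature (> 0).
#' @param grad Also return the gradient with respect to the student logits?
#' @return Scalar loss >= 0, or `list(value, grad)`.
#' @export
kd_loss <- function(student_logits, teacher_logits, tau = 2, grad = FALSE) {
  if (ncol(student_logits) < 2) {
    stop("parameter error: need at least 2 classes", call. = FALSE)
  }
  stopifnot(all(dim(student_logits) == dim(teacher_logits)))
  B <- nrow(student_logits)
  Ps <- softmax_rows(student_logits / tau)
  Pt <- softmax_rows(teacher_logits / tau)
  value <- mean(rowSums(Pt * (log(pmax(Pt, 1e-300)) -
                              log(pmax(Ps, 1e-300))))) * tau^2
  if (!grad) return(value)
  list(value = value, grad = tau * (Ps - Pt) / B)
}

#' Channel-wise distillation loss
#'
#' Variant of the distillation term operating on the unified input
#' representation rather than logits: each channel's samples are softened by
#' a softmax over time, and the KL divergence from the teacher's per-channel
#' distribution to the student's is averaged over channels and clips.
#'
#' @param student,teacher `(B, C, T)` arrays (teacher constant).
#' @param tau Temperature.
#' @param grad Also return the gradient with respect to `student`?
#' @return Scalar loss >= 0, or `list(value, grad)`.
#' @export
kd_channelwise_loss <- function(student, teacher, tau = 2, grad = FALSE) {
  d <- dim(student)
  Sm <- matrix(aperm(student, c(3, 1, 2)), nrow = d[3])   # T x (B*C)
  Tm <- matrix(aperm(teacher, c(3, 1, 2)), nrow = d[3])
  Ps <- softmax_rows(t(Sm) / tau)                         # (B*C) x T
  Pt <- softmax_rows(t(Tm) / tau)
  value <- mean(rowSums(Pt * (log(pmax(Pt, 1e-300)) -
                              log(pmax(Ps, 1e-300))))) * tau^2
  if (!grad) return(value)
  g <- tau * (Ps - Pt) / nrow(Ps)                         # (B*C) x T
  garr <- aperm(array(t(g), c(d[3], d[1], d[2])), c(2, 3, 1))
  list(value = value, grad = garr)
}

# Pairwise squared Euclidean distances between rows of A and rows of B.
pdist2 <- function(A, B) {
  an <- rowSums(A * A)
  bn <- rowSums(B * B)
  d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d, 0)
}

#' Multi-kernel maximum mean discrepancy
#'
#' Feature-space alignment: the biased MMD^2 estimate between source and
#' target feature batches, averaged over Gaussian kernels
#' `k(x, y) = exp(-||x-y||^2 / (2 h m))` with base bandwidth `h` set by the
#' median heuristic (median off-diagonal squared distance of the pooled
#' sample) and multipliers `m`. Zero when the batches are identical;
#' symmetric in its arguments.
#'
#' @param source_feats,target_feats `n x F` and `m x F` matrices (n, m >= 2).
#' @param bandwidth_multipliers Kernel bandwidth multipliers.
#' @param bandwidth Base bandwidth `h` (squared-distance scale); `NULL` for
#'   the median heuristic. Treated as a constant in gradients.
#' @param grad Also return gradients with respect to both feature sets?
#' @return Scalar >= 0 (up to estimator noise), or
#'   `list(value, grad_source, grad_target)`.
#' @export
mmd_loss <- function(source_feats, target_feats,
                     bandwidth_multipliers = c(0.25, 0.5, 1, 2, 4),
                     bandwidth = NULL, grad = FALSE) {
  Xs <- as.matrix(source_feats); Xt <- as.matrix(target_feats)
  n <- nrow(Xs); m <- nrow(Xt)
  if (n < 2 || m < 2) {
    stop("parameter error: need at least 2 samples per domain", call. = FALSE)
  }
  Dss <- pdist2(Xs, Xs); Dtt <- pdist2(Xt, Xt); Dst <- pdist2(Xs, Xt)
  if (is.null(bandwidth)) {
    pooled <- c(Dss[upper.tri(Dss)], Dtt[upper.tri(Dtt)], as.vector(Dst))
    bandwidth <- stats::median(pooled)
    if (bandwidth <= 0) bandwidth <- 1
  }
  value <- 0
  Gs <- matrix(0, n, ncol(Xs)); Gt <- matrix(0, m, ncol(Xt))
  for (mult in bandwidth_multipliers) {
    h <- bandwidth * mult
    Kss <- exp(-Dss / (2 * h)); Ktt <- exp(-Dtt / (2 * h))
    Kst <- exp(-Dst / (2 * h))
    value <- value + mean(Kss) + mean(Ktt) - 2 * mean(Kst)
    if (grad) {
      # d k(x_i, x_j) / d x_i = -k * (x_i - x_j) / h
      wss <- Kss / (n * n * h)
      wtt <- Ktt / (m * m * h)
      wst <- Kst / (n * m * h)
      Gs <- Gs - 2 * (rowSums(wss) * Xs - wss %*% Xs) +
        2 * (rowSums(wst) * Xs - wst %*% Xt)
      Gt <- Gt - 2 * (rowSums(wtt) * Xt - wtt %*% Xt) +
        2 * (colSums(wst) * Xt - t(wst) %*% Xs)
    }
  }
  nm <- length(bandwidth_multipliers)
  value <- value / nm
  if (!grad) return(value)
  list(value = value, grad_source = Gs / nm, grad_target = Gt / nm)
}

#' Minimum class confusion loss
#'
#' Feature-space alignment signal computed on unlabeled target logits:
#' class probabilities are softened by `tau`, examples are weighted by
#' prediction certainty (higher entropy, lower weight; weights normalized to
#' sum to the batch size), the weighted class-correlation matrix
#' `C = Y' W Y` is row-normalized, and the loss is the mean off-diagonal
#' (between-class confusion) mass, `sum_{j != j'} C_{jj'} / K`. Bounded in
#' `[0, (K-1)/K]`; zero for perfectly one-hot predictions.
#'
#' @param target_logits `B x K` matrix, B >= 2.
#' @param tau Temperature (default 2.5).
#' @param grad Also return the gradient with respect to the logits?
#' @return Scalar loss, or `list(value, grad)`.
#' @export
mcc_loss <- function(target_logits, tau = 2.5, grad = FALSE) {
  B <- nrow(target_logits); K <- ncol(target_logits)
  if (B < 2) stop("parameter error: need a batch of at least 2", call. = FALSE)
  Y <- softmax_rows(target_logits / tau)
  logY <- log(pmax(Y, 1e-300))
  H <- -rowSums(Y * logY)
  E <- 1 + exp(-H)
  S <- sum(E)
  w <- B * E / S
  Cc <- crossprod(Y, w * Y)                       # K x K, = Y' diag(w) Y
  r <- rowSums(Cc)
  value <- sum(Cc / r) - sum(diag(Cc) / r)
  value <- value / K
  if (!grad) return(value)

  # loss = 1 - (1/K) sum_j Cc_jj / r_j ; G = d loss / d Cc
  G <- matrix(rep(diag(Cc) / r^2, K) * -1, K, K)  # off-diagonal entries
  diag(G) <- (r - diag(Cc)) / r^2
  G <- -G / K
  # through Cc = Y' W Y
  dY <- (w * Y) %*% (G + t(G))
  dw <- rowSums((Y %*% G) * Y)                    # diag(Y G Y') per example
  dE <- (B / S) * dw - (B / S^2) * sum(dw * E)
  dH <- dE * (-exp(-H))
  dY <- dY + dH * (-(logY + 1))
  # softmax Jacobian with temperature
  dZ <- (Y * (dY - rowSums(dY * Y))) / tau
  list(value = value, grad = dZ)
}

#' Total multi-space alignment objective
#'
#' `ce + lambda_kd * kd + beta_da * da`: classification plus weighted
#' output-space (distillation) and feature-space (adaptation) terms. With
#' both weights zero this reduces to plain cross-entropy.
#'
#' @param ce,kd,da Scalar component losses (finite).
#' @param w A [loss_weights()].
#' @return Scalar total loss.
#' @export
msa_total_loss <- function(ce, kd, da, w = loss_weights()) {
  stopifnot(is.finite(ce), is.finite(kd), is.finite(da))
  ce + w$lambda_kd * kd + w$beta_da * da
}
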