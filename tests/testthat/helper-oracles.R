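# Independent brute-force oracles for the defining formulas, written
# directly from the definitions (loops, no shared code with the package).

oracle_softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# KL-based distillation: mean_b KL(p_t || p_s) * tau^2 on softened logits.
oracle_kd <- function(s_logits, t_logits, tau) {
  B <- nrow(s_logits)
  acc <- 0
  for (b in seq_len(B)) {
    ps <- oracle_softmax(s_logits[b, ] / tau)
    pt <- oracle_softmax(t_logits[b, ] / tau)
    acc <- acc + sum(pt * (log(pt) - log(ps)))
  }
  acc / B * tau^2
}

# Biased multi-kernel MMD^2 by explicit kernel sums.
oracle_mmd <- function(Xs, Xt, bandwidth, multipliers = 1) {
  n <- nrow(Xs); m <- nrow(Xt)
  k <- function(a, b, h) exp(-sum((a - b)^2) / (2 * h))
  total <- 0
  for (mult in multipliers) {
    h <- bandwidth * mult
    ss <- 0; tt <- 0; st <- 0
    for (i in 1:n) for (j in 1:n) ss <- ss + k(Xs[i, ], Xs[j, ], h)
    for (i in 1:m) for (j in 1:m) tt <- tt + k(Xt[i, ], Xt[j, ], h)
    for (i in 1:n) for (j in 1:m) st <- st + k(Xs[i, ], Xt[j, ], h)
    total <- total + ss / n^2 + tt / m^2 - 2 * st / (n * m)
  }
  total / length(multipliers)
}

# Minimum class confusion, evaluated stepwise from the definition.
oracle_mcc <- function(logits, tau) {
  B <- nrow(logits); K <- ncol(logits)
  Y <- t(apply(logits / tau, 1, oracle_softmax))
  H <- apply(Y, 1, function(p) -sum(p * log(p)))
  E <- 1 + exp(-H)
  w <- B * E / sum(E)
  Cc <- matrix(0, K, K)
  for (i in seq_len(B)) Cc <- Cc + w[i] * outer(Y[i, ], Y[i, ])
  Cn <- Cc / rowSums(Cc)
  off <- sum(Cn) - sum(diag(Cn))
  off / K
}

# Approximate entropy by the defining double sum (self-matches included,
# Chebyshev distance).
oracle_apen <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    n <- N - mm + 1
    total <- 0
    for (i in seq_len(n)) {
      cnt <- 0
      for (j in seq_len(n)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      total <- total + log(cnt / n)
    }
    total / n
  }
  phi(m) - phi(m + 1)
}

# AUC by exhaustive pair counting with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  acc <- 0
  for (i in pos) for (j in neg) {
    acc <- acc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  acc / (length(pos) * length(neg))
}
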