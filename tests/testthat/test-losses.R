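test_that("distillation loss matches the closed-form KL", {
  S <- matrix(c(1, -1, 0.5, 2), 2, 2)
  expect_equal(kd_loss(S, S, tau = 2), 0, tolerance = 1e-12)

  # B=1, K=2, teacher (2, 0), student (0, 0), tau=1:
  # KL( Bernoulli(sigma(2)) || Bernoulli(0.5) )
  p <- exp(2) / (1 + exp(2))
  expected <- p * log(p / 0.5) + (1 - p) * log((1 - p) / 0.5)
  got <- kd_loss(matrix(c(0, 0), 1), matrix(c(2, 0), 1), tau = 1)
  expect_equal(got, expected, tolerance = 1e-9)

  set.seed(61)
  for (i in 1:5) {
    a <- matrix(rnorm(8), 4, 2); b <- matrix(rnorm(8), 4, 2)
    expect_gte(kd_loss(a, b, tau = 2), 0)
  }
  expect_error(kd_loss(matrix(1, 2, 1), matrix(1, 2, 1), 1),
               "parameter error")
})

test_that("distillation decreases toward the teacher on a grid", {
  teacher <- matrix(c(1.5, -0.5), 1)
  deltas <- seq(3, 0, by = -0.5)
  vals <- vapply(deltas, function(d)
    kd_loss(teacher + c(d, -d), teacher, tau = 2), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[length(vals)], 0, tolerance = 1e-12)
})

test_that("MMD matches a brute-force kernel sum and is symmetric", {
  X <- matrix(rnorm(10), 5, 2)
  expect_lt(abs(mmd_loss(X, X)), 1e-9)

  # n=m=2, F=1, single kernel, fixed bandwidth 1, points {0,1} vs {2,3}
  Xs <- matrix(c(0, 1), 2, 1); Xt <- matrix(c(2, 3), 2, 1)
  got <- mmd_loss(Xs, Xt, bandwidth_multipliers = 1, bandwidth = 1)
  expect_equal(got, oracle_mmd(Xs, Xt, bandwidth = 1), tolerance = 1e-9)

  # multi-kernel case against the same oracle
  set.seed(62)
  A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(18), 6, 3)
  mult <- c(0.5, 1, 2)
  got2 <- mmd_loss(A, B, bandwidth_multipliers = mult, bandwidth = 1.7)
  expect_equal(got2, oracle_mmd(A, B, 1.7, mult), tolerance = 1e-9)

  expect_equal(mmd_loss(A, B), mmd_loss(B, A), tolerance = 1e-12)
  expect_error(mmd_loss(matrix(1, 1, 2), B), "parameter error")
})

test_that("MMD separates shifted distributions", {
  set.seed(63)
  same <- numeric(100); diff_ <- numeric(100)
  for (i in 1:100) {
    a <- matrix(rnorm(64), 64, 1)
    b <- matrix(rnorm(64), 64, 1)
    c_ <- matrix(rnorm(64, mean = 3), 64, 1)
    same[i] <- mmd_loss(a, b)
    diff_[i] <- mmd_loss(a, c_)
  }
  expect_gte(mean(diff_ > same), 0.95)
})

test_that("class-confusion loss matches a stepwise oracle and its bounds", {
  # strongly one-hot logits leave no off-diagonal confusion
  hot <- matrix(c(20, -20, -20, 20, 20, -20), 3, 2, byrow = TRUE)
  expect_lte(mcc_loss(hot, tau = 2.5), 1e-6)

  # uniform logits evaluated stepwise by the oracle implementation
  unif <- matrix(0, 4, 2)
  expect_equal(mcc_loss(unif, tau = 2.5), oracle_mcc(unif, 2.5),
               tolerance = 1e-9)

  set.seed(64)
  for (i in 1:5) {
    L <- matrix(rnorm(8, sd = 2), 4, 2)
    expect_equal(mcc_loss(L, tau = 2.5), oracle_mcc(L, 2.5),
                 tolerance = 1e-9)
    v <- mcc_loss(L, tau = 2.5)
    expect_gte(v, 0)
    expect_lte(v, 1 / 2)                    # (K-1)/K for K = 2
    # permuting class columns consistently leaves the loss unchanged
    expect_equal(mcc_loss(L[, c(2, 1)], tau = 2.5), v, tolerance = 1e-12)
  }
  L3 <- matrix(rnorm(12), 4, 3)
  expect_lte(mcc_loss(L3, 2.5), 2 / 3)
  expect_error(mcc_loss(matrix(1, 1, 2), 2.5), "parameter error")
})

test_that("cross-entropy equals -log p_true and total loss composes", {
  lg <- matrix(c(1.2, -0.7), 1)
  p <- exp(lg) / sum(exp(lg))
  expect_equal(cross_entropy_loss(lg, 1L), -log(p[2]), tolerance = 1e-12)

  expect_equal(msa_total_loss(3.5, 7, 11, loss_weights(0, 0)), 3.5)
  expect_equal(msa_total_loss(1, 2, 3, loss_weights()), 6)   # both weights 1
  expect_equal(msa_total_loss(1, 2, 3, loss_weights(0.5, 2)), 8.0)
  expect_error(loss_weights(tau_kd = 0), "temperatures")
  expect_error(loss_weights(lambda_kd = -1), "weights")
})

test_that("loss gradients agree with finite differences", {
  set.seed(65)
  eps <- 1e-6
  # KD
  S <- matrix(rnorm(8), 4, 2); Tt <- matrix(rnorm(8), 4, 2)
  g <- kd_loss(S, Tt, tau = 2, grad = TRUE)
  for (i in sample(8, 3)) {
    Sp <- S; Sp[i] <- Sp[i] + eps; Sm <- S; Sm[i] <- Sm[i] - eps
    fd <- (kd_loss(Sp, Tt, 2) - kd_loss(Sm, Tt, 2)) / (2 * eps)
    expect_lt(abs(fd - g$grad[i]), 1e-6)
  }
  # MCC
  L <- matrix(rnorm(8), 4, 2)
  gm <- mcc_loss(L, tau = 2.5, grad = TRUE)
  for (i in sample(8, 3)) {
    Lp <- L; Lp[i] <- Lp[i] + eps; Lm <- L; Lm[i] <- Lm[i] - eps
    fd <- (mcc_loss(Lp, 2.5) - mcc_loss(Lm, 2.5)) / (2 * eps)
    expect_lt(abs(fd - gm$grad[i]), 1e-6)
  }
  # MMD (fixed bandwidth so the heuristic does not move)
  A <- matrix(rnorm(8), 4, 2); B <- matrix(rnorm(10), 5, 2)
  gd <- mmd_loss(A, B, bandwidth = 1.3, grad = TRUE)
  for (i in sample(8, 3)) {
    Ap <- A; Ap[i] <- Ap[i] + eps; Am <- A; Am[i] <- Am[i] - eps
    fd <- (mmd_loss(Ap, B, bandwidth = 1.3) -
           mmd_loss(Am, B, bandwidth = 1.3)) / (2 * eps)
    expect_lt(abs(fd - gd$grad_source[i]), 1e-6)
  }
  # channel-wise distillation
  Sa <- array(rnorm(2 * 3 * 5), c(2, 3, 5))
  Ta <- array(rnorm(2 * 3 * 5), c(2, 3, 5))
  gc_ <- kd_channelwise_loss(Sa, Ta, tau = 2, grad = TRUE)
  for (i in sample(30, 3)) {
    Sp <- Sa; Sp[i] <- Sp[i] + eps; Sm <- Sa; Sm[i] <- Sm[i] - eps
    fd <- (kd_channelwise_loss(Sp, Ta, 2) -
           kd_channelwise_loss(Sm, Ta, 2)) / (2 * eps)
    expect_lt(abs(fd - gc_$grad[i]), 1e-6)
  }
})
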