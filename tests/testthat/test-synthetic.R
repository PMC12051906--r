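test_that("latent clips are seeded-deterministic", {
  cfg <- sim_config()
  set.seed(91); a <- simulate_latent_clip(cfg, 1)
  set.seed(91); b <- simulate_latent_clip(cfg, 1)
  expect_identical(a$sources, b$sources)
  set.seed(92); c_ <- simulate_latent_clip(cfg, 1)
  expect_false(identical(a$sources, c_$sources))
})

test_that("ictal clips carry the configured amplitude contrast", {
  cfg <- sim_config()
  set.seed(93)
  v1 <- replicate(200, mean(apply(simulate_latent_clip(cfg, 1)$sources, 1,
                                  var)))
  v0 <- replicate(200, mean(apply(simulate_latent_clip(cfg, 0)$sources, 1,
                                  var)))
  ratio <- mean(v1) / mean(v0)
  # half the sources are scaled by the gain: expected (g^2 + 1) / 2, checked
  # against the contract window [0.5 g^2, 2 g^2]
  expect_gte(ratio, 0.5 * cfg$seizure_gain^2 * 0.5)
  expect_lte(ratio, 2 * cfg$seizure_gain^2)
})

test_that("background clips carry no seizure-band bump", {
  cfg <- sim_config()
  set.seed(94)
  bp <- getFromNamespace("band_power", "seizalign")
  rate <- max(cfg$source_rate, cfg$target_rate)
  inb <- 0; flank <- 0
  for (i in 1:100) {
    S <- simulate_latent_clip(cfg, 0)$sources
    inb <- inb + mean(bp(S, rate, cfg$seizure_band))
    flank <- flank + mean(bp(S, rate, c(cfg$seizure_band[2] + 5,
                                        cfg$seizure_band[2] + 15)))
  }
  # pink background falls with frequency; in-band power of non-seizure clips
  # must not exceed the higher flanking band by > 6 dB beyond the 1/f slope
  slope <- mean(cfg$seizure_band) / mean(c(cfg$seizure_band[2] + 5,
                                           cfg$seizure_band[2] + 15))
  expect_lt(10 * log10((inb / flank) * slope), 6)
})

test_that("sensor projection follows the identity chain and the SNR", {
  cfg <- sim_config()
  set.seed(95)
  clip <- simulate_latent_clip(cfg, 1, rate = 256)
  tr <- project_to_sensors(clip, diag(cfg$n_latent), Inf, 256)
  expect_identical(tr$signal, clip$sources)

  lf <- matrix(rnorm(6 * 4), 6, 4)
  tr6 <- project_to_sensors(clip, lf, 10, 256)
  expect_equal(nrow(tr6$signal), 6)

  # measured SNR within 2 dB of configured, averaged over clips
  snrs <- numeric(100)
  for (i in 1:100) {
    cl <- simulate_latent_clip(cfg, sample(0:1, 1), rate = 256)
    clean <- lf %*% cl$sources
    noisy <- project_to_sensors(cl, lf, 10, 256)
    snrs[i] <- mean(apply(clean, 1, var)) /
      mean(apply(noisy$signal - clean, 1, var))
  }
  expect_lt(abs(10 * log10(mean(snrs)) - 10), 2)

  expect_error(project_to_sensors(clip, matrix(1, 3, 4), 10, 256),
               "rank-deficient")
})

test_that("the generated pair mirrors the montage and label structure", {
  cfg <- tiny_sim_config(seed = 96)
  task <- generate_transfer_pair(cfg)
  expect_equal(task$source$n_channels, 16)
  expect_equal(task$target$n_channels, 6)
  expect_equal(task$source$sampling_rate, 400)
  expect_equal(task$target$sampling_rate, 256)
  for (d in list(task$source, task$target)) {
    labs <- trial_labels(d)
    expect_lte(abs(sum(labs == 1) -
                     cfg$seizure_fraction * length(labs)),
               cfg$n_subjects)   # round() per subject: at most 1 clip each
  }
  # oracle classifier on latent band power: the pair carries usable signal
  expect_gte(auc_score(task$oracle$source$score, task$oracle$source$label),
             0.9)
  expect_gte(auc_score(task$oracle$target$score, task$oracle$target$label),
             0.9)
})

test_that("generation is byte-identical under one seed", {
  cfg <- tiny_sim_config(seed = 97)
  t1 <- generate_transfer_pair(cfg)
  t2 <- generate_transfer_pair(cfg)
  expect_identical(lapply(t1$source$trials, `[[`, "signal"),
                   lapply(t2$source$trials, `[[`, "signal"))
  expect_identical(lapply(t1$target$trials, `[[`, "signal"),
                   lapply(t2$target$trials, `[[`, "signal"))
  expect_identical(t1$oracle, t2$oracle)
})

test_that("stronger seizures are easier for the latent oracle", {
  aucs <- vapply(c(1.05, 1.1, 1.2), function(g) {
    task <- generate_transfer_pair(sim_config(n_subjects = 2,
                                              clips_per_subject = 100,
                                              seed = 98, seizure_gain = g))
    auc_score(task$oracle$target$score, task$oracle$target$label)
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("the benchmark exhibits real domain shift at default settings", {
  task <- generate_transfer_pair(sim_config())
  oracle_auc <- auc_score(task$oracle$target$score, task$oracle$target$label)
  ptask0 <- prepare_task(task, ea = FALSE)
  m <- train_baseline(ptask0, "truncation_noalign",
                      train_cfg = train_config(epochs = 6, seed = 1))
  trunc_auc <- mean(evaluate_auc(m, m$test_pool))
  expect_gte(oracle_auc - trunc_auc, 0.05)
})
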