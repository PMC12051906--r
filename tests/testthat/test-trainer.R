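test_that("chronological split takes the earliest l% per subject and class", {
  # one subject, 10 seizure + 10 non-seizure clips in time order
  trials <- list()
  for (k in 1:20) {
    trials[[k]] <- trial(matrix(rnorm(2 * 8), 2, 8), label = k %% 2L,
                         subject_id = "p1", start_time = k)
  }
  ds <- domain_dataset(trials, 32)
  sp <- chronological_label_split(ds, 20)
  expect_equal(length(sp$labeled$trials), 4)     # 2 + 2
  expect_equal(length(sp$test$trials), 16)
  expect_setequal(c(sp$labeled_idx, sp$test_idx), 1:20)

  for (l in c(5, 10, 15, 20)) {
    s <- chronological_label_split(ds, l)
    expect_equal(length(s$labeled$trials) + length(s$test$trials), 20)
    expect_length(intersect(s$labeled_idx, s$test_idx), 0)
  }
})

test_that("split is a leak-free partition on random data", {
  set.seed(71)
  ds <- noise_dataset(n_subjects = 3, n_trials = 17, C = 2, T = 16,
                      seed = 71)
  for (l in c(5, 10, 15, 20)) {
    sp <- chronological_label_split(ds, l)
    expect_setequal(c(sp$labeled_idx, sp$test_idx),
                    seq_along(ds$trials))
    expect_length(intersect(sp$labeled_idx, sp$test_idx), 0)
    # temporal-leakage guard: per subject and class, every labeled clip
    # starts no later than every test clip
    lab <- sp$labeled; tst <- sp$test
    for (sid in unique(subject_ids(ds))) {
      for (cls in 0:1) {
        lt <- trial_start_times(lab)[subject_ids(lab) == sid &
                                       trial_labels(lab) == cls]
        tt <- trial_start_times(tst)[subject_ids(tst) == sid &
                                       trial_labels(tst) == cls]
        if (length(lt) && length(tt)) expect_lte(max(lt), min(tt))
      }
    }
    # per-class ceil rounding per subject
    for (sid in unique(subject_ids(ds))) {
      for (cls in 0:1) {
        n_cls <- sum(subject_ids(ds) == sid & trial_labels(ds) == cls)
        n_lab <- sum(subject_ids(lab) == sid & trial_labels(lab) == cls)
        expect_equal(n_lab, ceiling(l / 100 * n_cls))
      }
    }
  }
  expect_error(chronological_label_split(ds, 0), "l must be")
})

test_that("AUC follows the rank statistic with tie half-credit", {
  expect_equal(auc_score(c(0.1, 0.9, 0.2, 0.8), c(0, 1, 0, 1)), 1)
  expect_equal(auc_score(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  s <- c(0.2, 0.5, 0.5, 0.8, 0.1, 0.9)
  l <- c(0, 0, 1, 1, 0, 1)
  expect_equal(auc_score(s, l), oracle_auc(s, l), tolerance = 1e-12)
  set.seed(72)
  for (i in 1:5) {
    sc <- sample(seq(0, 1, 0.1), 8, replace = TRUE)
    lb <- sample(0:1, 8, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(lb)) == 2) {
      expect_equal(auc_score(sc, lb), oracle_auc(sc, lb), tolerance = 1e-12)
    }
  }
  expect_true(is.na(auc_score(1:3, c(1, 1, 1))))
})

test_that("training reduces the objective on a separable task", {
  task <- toy_separable_task(seed = 73)
  m <- train_msa(task, model_cfg = toy_model_cfg(),
                 train_cfg = toy_train_cfg(epochs = 8))
  expect_lt(m$history[length(m$history)], m$history[1])
})

test_that("the model learns a separable task as well as a variance oracle", {
  task <- toy_separable_task(seed = 74)
  # independent learnability oracle: logistic model on log clip variance
  tst <- chronological_label_split(task$target, 20)
  vtrain <- log(vapply(tst$labeled$trials, function(t) var(as.vector(t$signal)),
                       numeric(1)))
  vtest <- log(vapply(tst$test$trials, function(t) var(as.vector(t$signal)),
                      numeric(1)))
  fit <- suppressWarnings(
    glm(y ~ v, family = binomial(),
        data = data.frame(y = trial_labels(tst$labeled), v = vtrain)))
  pr <- predict(fit, newdata = data.frame(v = vtest))
  expect_gte(auc_score(pr, trial_labels(tst$test)), 0.95)

  m <- train_msa(task, model_cfg = toy_model_cfg(),
                 train_cfg = toy_train_cfg(epochs = 15))
  auc <- evaluate_auc(m, m$test_pool)
  expect_gte(mean(auc), 0.95)
})

test_that("within baseline learns from the target's own labels", {
  # the l = 20 labeled pool holds only 24 clips, so one optimizer step per
  # epoch: give the run a step budget comparable to the other variants
  task <- toy_separable_task(seed = 75)
  m <- train_baseline(task, "within", model_cfg = toy_model_cfg(),
                      train_cfg = toy_train_cfg(epochs = 100))
  expect_gte(mean(evaluate_auc(m, m$test_pool)), 0.9)
})

test_that("source-only training never reads target labels", {
  task <- toy_separable_task(scenario = "unsupervised", label_fraction = 0,
                             seed = 76, n_clips = 30)
  m1 <- train_baseline(task, "source_only", model_cfg = toy_model_cfg(),
                       train_cfg = toy_train_cfg(epochs = 2))
  flipped <- task
  for (i in seq_along(flipped$target$trials)) {
    flipped$target$trials[[i]]$label <-
      1L - flipped$target$trials[[i]]$label
  }
  m2 <- train_baseline(flipped, "source_only", model_cfg = toy_model_cfg(),
                       train_cfg = toy_train_cfg(epochs = 2))
  expect_identical(m1$backbone$params, m2$backbone$params)
  expect_identical(m1$resizenet, m2$resizenet)
})

test_that("unsupervised MSA is invariant to target label permutation", {
  task <- toy_separable_task(scenario = "unsupervised", label_fraction = 0,
                             seed = 77, n_clips = 30)
  m1 <- train_msa(task, model_cfg = toy_model_cfg(),
                  train_cfg = toy_train_cfg(epochs = 2))
  flipped <- task
  for (i in seq_along(flipped$target$trials)) {
    flipped$target$trials[[i]]$label <-
      1L - flipped$target$trials[[i]]$label
  }
  m2 <- train_msa(flipped, model_cfg = toy_model_cfg(),
                  train_cfg = toy_train_cfg(epochs = 2))
  expect_identical(m1$backbone$params, m2$backbone$params)
})

test_that("comb baseline trains on pools of the expected sizes", {
  task <- toy_separable_task(seed = 78)        # 2 subj x 60 clips per domain
  m <- train_baseline(task, "comb", model_cfg = toy_model_cfg(),
                      train_cfg = toy_train_cfg(epochs = 1))
  expect_equal(m$n_labeled_source, 120)
  expect_equal(m$n_labeled_target, 2 * (ceiling(0.2 * 30) + ceiling(0.2 * 30)))
  expect_equal(m$n_labeled, m$n_labeled_source + m$n_labeled_target)
  expect_equal(length(m$test_pool$trials), 120 - m$n_labeled_target)
})

test_that("config errors are raised for inconsistent scenarios", {
  task <- toy_separable_task(seed = 79, n_clips = 20)
  expect_error(train_baseline(
    transfer_task(task$source, task$target, "unsupervised", 0), "within",
    model_cfg = toy_model_cfg(), train_cfg = toy_train_cfg(epochs = 1)),
    "config error")
  expect_error(transfer_task(task$source, task$target, "unsupervised", 10),
               "config error")
  ut <- transfer_task(task$source, task$target, "unsupervised", 0)
  expect_error(train_msa(ut, model_cfg = toy_model_cfg(),
                         train_cfg = toy_train_cfg(epochs = 1),
                         transductive = FALSE),
               "config error")
})

test_that("deterministic runs are bit-identical; repeats aggregate exactly", {
  task <- toy_separable_task(seed = 80, n_clips = 24)
  cfg <- toy_train_cfg(epochs = 2, seed = 9)
  m1 <- train_msa(task, model_cfg = toy_model_cfg(), train_cfg = cfg)
  m2 <- train_msa(task, model_cfg = toy_model_cfg(), train_cfg = cfg)
  expect_identical(m1$backbone$params, m2$backbone$params)
  expect_identical(m1$resizenet$weight, m2$resizenet$weight)
  expect_identical(m1$history, m2$history)

  r <- run_repeated_experiment(task, method = "within",
                               model_cfg = toy_model_cfg(),
                               train_cfg = toy_train_cfg(epochs = 2,
                                                         repeats = 3))
  expect_equal(r$mean_auc, mean(r$per_repeat), tolerance = 1e-12)
  expect_equal(r$std_auc, sd(r$per_repeat), tolerance = 1e-12)
  expect_equal(r$seeds, 1:3)
  expect_equal(dim(r$per_subject_auc), c(3, 2))

  r1 <- run_repeated_experiment(task, method = "within",
                                model_cfg = toy_model_cfg(),
                                train_cfg = toy_train_cfg(epochs = 2,
                                                          repeats = 1))
  expect_equal(r1$std_auc, 0)
  expect_true(all(r$per_subject_auc >= 0 & r$per_subject_auc <= 1))
})
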