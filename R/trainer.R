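#' A cross-domain transfer task
#'
#' Bundles a labeled source domain, a target domain, the transfer scenario
#' and the target label fraction l. In the unsupervised scenario no target
#' labels are used (l = 0); in the semi-supervised scenario the
#' chronologically first l% of each target subject's clips per class are
#' labeled for training.
#'
#' @param source,target [domain_dataset()]s.
#' @param scenario `"unsupervised"` or `"semi_supervised"`.
#' @param label_fraction Target label percentage, one of 0, 5, 10, 15, 20
#'   (any value in \[0, 100) is accepted).
#' @return An object of class `transfer_task`.
#' @export
transfer_task <- function(source, target,
                          scenario = c("unsupervised", "semi_supervised"),
                          label_fraction = 0) {
  scenario <- match.arg(scenario)
  if (scenario == "unsupervised" && label_fraction != 0) {
    stop("config error: unsupervised scenario requires label_fraction = 0",
         call. = FALSE)
  }
  if (label_fraction < 0 || label_fraction >= 100) {
    stop("label_fraction must be in [0, 100)", call. = FALSE)
  }
  structure(list(source = source, target = target, scenario = scenario,
                 label_fraction = label_fraction),
            class = "transfer_task")
}

#' Training configuration
#'
#' Adam with the conventional settings (learning rate 1e-3, no weight
#' decay), batches of 64 per domain, 50 epochs. With `deterministic = TRUE`
#' the run is fully seeded: two runs with the same seed produce bit-identical
#' parameters.
#'
#' @param epochs Training epochs (>= 1).
#' @param batch_size Mini-batch size per domain (>= 4).
#' @param learning_rate Adam learning rate.
#' @param seed Base RNG seed.
#' @param deterministic Seed the RNG at the start of training?
#' @param repeats Number of repeated runs for [run_repeated_experiment()]
#'   (default 3; repeats use consecutive seeds).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 64, learning_rate = 1e-3,
                         seed = 1, deterministic = TRUE, repeats = 3) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 4) stop("batch_size must be >= 4", call. = FALSE)
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 deterministic = isTRUE(deterministic),
                 repeats = as.integer(repeats)),
            class = "train_config")
}

#' Chronological per-class label split
#'
#' For each target subject and each class, the chronologically first
#' `ceil(l% * n_class)` clips form the labeled pool; the remainder is the
#' test pool. Pools are disjoint and exhaustive, and no test clip of a
#' subject precedes a labeled clip of the same subject and class, guarding
#' against temporal leakage. A subject lacking one class contributes nothing
#' for that class (with a warning).
#'
#' @param dataset A [domain_dataset()].
#' @param l Label percentage in (0, 100).
#' @return A list with `labeled` and `test` (both [domain_dataset()]s, the
#'   labeled pool possibly empty) and the corresponding index vectors
#'   `labeled_idx`, `test_idx`.
#' @export
chronological_label_split <- function(dataset, l) {
  if (l <= 0 || l >= 100) stop("l must be in (0, 100)", call. = FALSE)
  subj <- subject_ids(dataset)
  labs <- trial_labels(dataset)
  st <- trial_start_times(dataset)
  labeled_idx <- integer(0)
  for (sid in unique(subj)) {
    for (cls in c(0L, 1L)) {
      idx <- which(subj == sid & labs == cls)
      if (length(idx) == 0) {
        warning("subject ", sid, " has no trials of class ", cls)
        next
      }
      idx <- idx[order(st[idx])]
      n_lab <- ceiling(l / 100 * length(idx))
      labeled_idx <- c(labeled_idx, idx[seq_len(n_lab)])
    }
  }
  labeled_idx <- sort(labeled_idx)
  test_idx <- setdiff(seq_along(dataset$trials), labeled_idx)
  list(labeled = subset_trials(dataset, labeled_idx),
       test = subset_trials(dataset, test_idx),
       labeled_idx = labeled_idx, test_idx = test_idx)
}

#' Prepare a transfer task for training
#'
#' Brings both domains to the lower of the two sampling rates (see
#' [harmonize_rates()]) and, by default, applies per-subject Euclidean
#' alignment to each domain. Run this once before [train_msa()] /
#' [train_baseline()].
#'
#' @param task A [transfer_task()].
#' @param ea Apply Euclidean alignment?
#' @return The prepared [transfer_task()] (alignment states attached as
#'   `ea_states` when `ea = TRUE`).
#' @export
prepare_task <- function(task, ea = TRUE) {
  h <- harmonize_rates(task$source, task$target)
  task$source <- h$source
  task$target <- h$target
  if (ea) {
    s <- euclidean_align(task$source)
    t <- euclidean_align(task$target)
    task$source <- s$dataset
    task$target <- t$dataset
    task$ea_states <- list(source = s$states, target = t$states)
  }
  task
}

# Test pool of a task: the post-split remainder when target labels are used,
# otherwise the whole target domain.
task_test_pool <- function(task) {
  if (task$label_fraction > 0) {
    chronological_label_split(task$target, task$label_fraction)$test
  } else {
    task$target
  }
}

# Assemble a (B, C_lo, T) batch, adapting higher-channel trials by the
# learnable projection or by truncation. Returns the raw signals of adapted
# rows for the projection gradient.
build_batch <- function(trials, C_lo, rn, matcher) {
  B <- length(trials)
  T <- ncol(trials[[1]]$signal)
  X <- array(0, c(B, C_lo, T))
  hi <- which(vapply(trials, n_channels_of, integer(1)) > C_lo)
  raw <- if (length(hi)) array(0, c(length(hi),
                                    nrow(trials[[hi[1]]]$signal), T)) else NULL
  for (i in seq_len(B)) {
    sig <- trials[[i]]$signal
    if (nrow(sig) > C_lo) {
      X[i, , ] <- if (matcher == "resize") rn$weight %*% sig
                  else sig[seq_len(C_lo), , drop = FALSE]
    } else {
      X[i, , ] <- sig
    }
  }
  if (length(hi)) {
    for (j in seq_along(hi)) raw[j, , ] <- trials[[hi[j]]]$signal
  }
  list(X = X, hi = hi, raw = raw)
}

# Gradient of the projection weight from d(projected signals): stacks the
# adapted rows and contracts over time x batch.
resize_weight_grad <- function(dX_hi, raw) {
  nh <- dim(raw)[1]
  dmat <- matrix(aperm(dX_hi, c(2, 3, 1)), nrow = dim(dX_hi)[2])
  rmat <- matrix(aperm(raw, c(2, 3, 1)), nrow = dim(raw)[2])
  tcrossprod(dmat, rmat)
}

# The shared training engine behind train_msa() and train_baseline().
train_engine <- function(task,
                         include_source = TRUE,
                         matcher = c("resize", "truncate", "none"),
                         da_loss = c("none", "mcc", "mmd"),
                         kd = c("none", "logit", "channelwise"),
                         kd_direction = c("teacher_truncation", "reverse",
                                          "mutual"),
                         model_cfg = NULL,
                         loss_w = loss_weights(),
                         train_cfg = train_config(),
                         transductive = TRUE) {
  matcher <- match.arg(matcher)
  da_loss <- match.arg(da_loss)
  kd <- match.arg(kd)
  kd_direction <- match.arg(kd_direction)
  if (train_cfg$deterministic) set.seed(train_cfg$seed)

  target <- task$target
  source <- if (include_source) task$source else NULL
  l <- task$label_fraction
  if (!is.null(source) && source$sampling_rate != target$sampling_rate) {
    stop("config error: domains must share a sampling rate; run prepare_task()",
         call. = FALSE)
  }
  Ct <- target$n_channels
  Cs <- if (is.null(source)) Ct else source$n_channels
  C_lo <- min(Cs, Ct)
  T <- n_samples_of(target$trials[[1]])

  # labeled pool
  lab_trials <- list()
  if (!is.null(source)) lab_trials <- source$trials
  test_pool <- target
  if (l > 0) {
    sp <- chronological_label_split(target, l)
    lab_trials <- c(lab_trials, sp$labeled$trials)
    test_pool <- sp$test
  }
  if (length(lab_trials) == 0) {
    stop("config error: no labeled data for this variant", call. = FALSE)
  }
  unlab_trials <- if (transductive) target$trials
                  else if (l > 0) chronological_label_split(target, l)$labeled$trials
                  else list()
  if (da_loss != "none" && length(unlab_trials) < 2) {
    stop("config error: no unlabeled target data available for domain ",
         "adaptation", call. = FALSE)
  }

  if (is.null(model_cfg)) {
    model_cfg <- eegnet_config(kernel_samples = round(target$sampling_rate / 2))
  }
  backbone <- eegnet_init(model_cfg, C_lo, T)
  rn <- if (matcher == "resize" && max(Cs, Ct) > C_lo) {
    resizenet_params(max(Cs, Ct), C_lo)
  } else NULL
  use_kd <- kd != "none" && !is.null(rn)

  params <- backbone$params
  if (!is.null(rn)) params$Wr <- rn$weight
  opt <- adam_init(params, lr = train_cfg$learning_rate)

  n_lab <- length(lab_trials)
  bs <- min(train_cfg$batch_size, n_lab)
  n_unlab <- length(unlab_trials)
  lab_labels_all <- vapply(lab_trials, function(t) t$label, integer(1))
  history <- numeric(0)

  for (epoch in seq_len(train_cfg$epochs)) {
    perm <- sample(n_lab)
    ep_loss <- 0
    n_steps <- n_lab %/% bs
    if (n_steps == 0) n_steps <- 1
    for (step in seq_len(n_steps)) {
      bidx <- perm[((step - 1) * bs + 1):min(step * bs, n_lab)]
      btr <- lab_trials[bidx]
      blab <- lab_labels_all[bidx]
      bb <- build_batch(btr, C_lo, rn, matcher)
      backbone$params <- params[names(backbone$params)]
      fw <- eegnet_forward(backbone, bb$X, training = TRUE)
      backbone <- fw$model

      ce <- cross_entropy_loss(fw$logits, blab, grad = TRUE)
      dlogits <- ce$grad
      dfeats <- NULL
      kd_val <- 0
      da_val <- 0
      extra <- list()
      dWr <- if (!is.null(rn)) matrix(0, nrow(rn$weight), ncol(rn$weight))
             else NULL

      if (use_kd && length(bb$hi) > 0 && kd == "logit") {
        Xtr <- array(0, c(length(bb$hi), C_lo, T))
        for (j in seq_along(bb$hi)) {
          Xtr[j, , ] <- bb$raw[j, seq_len(C_lo), ]
        }
        tfw <- eegnet_forward(backbone, Xtr, training = TRUE) # stats discarded
        s_logits <- fw$logits[bb$hi, , drop = FALSE]
        if (kd_direction %in% c("teacher_truncation", "mutual")) {
          kg <- kd_loss(s_logits, tfw$logits, tau = loss_w$tau_kd, grad = TRUE)
          kd_val <- kd_val + kg$value
          dlogits[bb$hi, ] <- dlogits[bb$hi, ] +
            loss_w$lambda_kd * kg$grad
        }
        if (kd_direction %in% c("reverse", "mutual")) {
          kg2 <- kd_loss(tfw$logits, s_logits, tau = loss_w$tau_kd,
                         grad = TRUE)
          kd_val <- kd_val + kg2$value
          extra$trunc <- list(cache = tfw$cache,
                              dlogits = loss_w$lambda_kd * kg2$grad)
        }
      } else if (use_kd && length(bb$hi) > 0 && kd == "channelwise") {
        Xtr <- array(0, c(length(bb$hi), C_lo, T))
        for (j in seq_along(bb$hi)) Xtr[j, , ] <- bb$raw[j, seq_len(C_lo), ]
        kg <- kd_channelwise_loss(bb$X[bb$hi, , , drop = FALSE], Xtr,
                                  tau = loss_w$tau_kd, grad = TRUE)
        kd_val <- kg$value
        dWr <- dWr + loss_w$lambda_kd * resize_weight_grad(
          kg$grad, bb$raw)
      }

      ub <- NULL
      if (da_loss != "none") {
        uidx <- sample.int(n_unlab, min(bs, n_unlab),
                           replace = n_unlab < bs)
        ubb <- build_batch(unlab_trials[uidx], C_lo, rn, matcher)
        ufw <- eegnet_forward(backbone, ubb$X, training = TRUE)
        backbone <- ufw$model
        if (da_loss == "mcc") {
          mg <- mcc_loss(ufw$logits, tau = loss_w$tau_mcc, grad = TRUE)
          da_val <- mg$value
          ub <- eegnet_backward(backbone, ufw$cache,
                                loss_w$beta_da * mg$grad)
        } else {
          src_rows <- if (length(bb$hi)) bb$hi else seq_along(btr)
          mg <- mmd_loss(fw$feats[src_rows, , drop = FALSE], ufw$feats,
                         grad = TRUE)
          da_val <- mg$value
          dfeats <- matrix(0, nrow(fw$feats), ncol(fw$feats))
          dfeats[src_rows, ] <- loss_w$beta_da * mg$grad_source
          ub <- eegnet_backward(backbone, ufw$cache,
                                matrix(0, nrow(ufw$logits), ncol(ufw$logits)),
                                loss_w$beta_da * mg$grad_target)
        }
      }

      lb <- eegnet_backward(backbone, fw$cache, dlogits, dfeats)
      grads <- lb$grads
      if (!is.null(ub)) {
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + ub$grads[[nm]]
      }
      if (!is.null(extra$trunc)) {
        tb <- eegnet_backward(backbone, extra$trunc$cache, extra$trunc$dlogits)
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + tb$grads[[nm]]
      }
      if (!is.null(rn) && length(bb$hi) > 0) {
        dWr <- dWr + resize_weight_grad(
          lb$dX[bb$hi, , , drop = FALSE], bb$raw)
      }
      if (!is.null(rn)) grads$Wr <- dWr

      params <- backbone$params
      if (!is.null(rn)) params$Wr <- rn$weight
      stp <- adam_step(opt, params, grads)
      opt <- stp$opt
      params <- stp$params
      backbone$params <- params[names(backbone$params)]
      if (!is.null(rn)) rn$weight <- params$Wr

      ep_loss <- ep_loss + msa_total_loss(ce$value, kd_val, da_val, loss_w)
    }
    history <- c(history, ep_loss / n_steps)
  }

  structure(list(backbone = backbone, resizenet = rn, matcher = matcher,
                 n_channels = C_lo, loss_weights = loss_w,
                 train_config = train_cfg, da_loss = da_loss, kd = kd,
                 history = history, test_pool = test_pool,
                 n_labeled = n_lab,
                 n_labeled_source = if (is.null(source)) 0L
                                    else length(source$trials),
                 n_labeled_target = n_lab - (if (is.null(source)) 0L
                                             else length(source$trials))),
            class = "msa_model")
}

#' @export
print.msa_model <- function(x, ...) {
  cat(sprintf(
    "<msa_model> backbone %d ch x %d samples (%d params)%s, da=%s, kd=%s\n",
    x$backbone$n_channels, x$backbone$n_samples, n_parameters(x$backbone),
    if (!is.null(x$resizenet))
      sprintf(", projection %dx%d", nrow(x$resizenet$weight),
              ncol(x$resizenet$weight)) else "",
    x$da_loss, x$kd))
  if (length(x$history)) {
    cat(sprintf("  training loss %.4f -> %.4f over %d epochs\n",
                x$history[1], x$history[length(x$history)],
                length(x$history)))
  }
  invisible(x)
}

#' Train the full multi-space alignment model
#'
#' End-to-end training of the channel projection, backbone and classifier
#' under the composite objective: cross-entropy on labeled clips (source,
#' plus the first l% of target clips in the semi-supervised scenario), a
#' distillation term between the truncation-branch and projection-branch
#' logits on the higher-channel domain's batches, and a feature-space
#' adaptation term on unlabeled target batches. The task must be prepared
#' with [prepare_task()] (common sampling rate; Euclidean alignment).
#'
#' @param task A prepared [transfer_task()].
#' @param model_cfg An [eegnet_config()], or `NULL` for the default built at
#'   half-sampling-rate temporal kernels.
#' @param loss_cfg A [loss_weights()].
#' @param train_cfg A [train_config()].
#' @param da_loss Feature-space term: `"mcc"` (default), `"mmd"` or `"none"`.
#' @param kd Output-space term: `"logit"` (default), `"channelwise"` or
#'   `"none"`.
#' @param kd_direction Distillation direction: the truncation branch teaches
#'   the projection branch (default), `"reverse"`, or `"mutual"`.
#' @param transductive Use target clips (labels untouched) as unlabeled data
#'   for adaptation; `FALSE` restricts training to inductive data.
#' @return A trained `msa_model`.
#' @export
train_msa <- function(task, model_cfg = NULL, loss_cfg = loss_weights(),
                      train_cfg = train_config(), da_loss = "mcc",
                      kd = "logit", kd_direction = "teacher_truncation",
                      transductive = TRUE) {
  if (task$scenario == "unsupervised" && task$label_fraction > 0) {
    stop("config error: unsupervised scenario with l > 0", call. = FALSE)
  }
  train_engine(task, include_source = TRUE, matcher = "resize",
               da_loss = da_loss, kd = kd, kd_direction = kd_direction,
               model_cfg = model_cfg, loss_w = loss_cfg,
               train_cfg = train_cfg, transductive = transductive)
}

#' Train a comparison baseline
#'
#' Baselines sharing the backbone, optimizer and epoch budget with
#' [train_msa()] for fair comparison:
#'
#' * `source_only`: all labeled source data, learnable projection, no
#'   adaptation or distillation; target labels are never read.
#' * `within`: only the target's l-percent labeled clips (requires l > 0).
#' * `comb`: the union of source data and the target's labeled clips.
#' * `truncation_noalign`: source only, channels matched by truncation
#'   instead of the learnable projection — run it on a task prepared with
#'   `ea = FALSE` for the fully alignment-free reference.
#'
#' @param task A prepared [transfer_task()].
#' @param variant One of `"source_only"`, `"within"`, `"comb"`,
#'   `"truncation_noalign"`.
#' @param model_cfg,loss_cfg,train_cfg As in [train_msa()].
#' @return A trained `msa_model`.
#' @export
train_baseline <- function(task,
                           variant = c("source_only", "within", "comb",
                                       "truncation_noalign"),
                           model_cfg = NULL, loss_cfg = loss_weights(),
                           train_cfg = train_config()) {
  variant <- match.arg(variant)
  if (variant %in% c("within", "comb") && task$label_fraction == 0) {
    stop("config error: variant '", variant, "' requires l > 0",
         call. = FALSE)
  }
  src_free <- task
  if (variant %in% c("source_only", "truncation_noalign")) {
    # source-only variants never read target labels
    src_free$label_fraction <- 0
  }
  switch(variant,
    source_only = train_engine(src_free, include_source = TRUE,
                               matcher = "resize", da_loss = "none",
                               kd = "none", model_cfg = model_cfg,
                               loss_w = loss_cfg, train_cfg = train_cfg),
    truncation_noalign = train_engine(src_free, include_source = TRUE,
                                      matcher = "truncate", da_loss = "none",
                                      kd = "none", model_cfg = model_cfg,
                                      loss_w = loss_cfg,
                                      train_cfg = train_cfg),
    within = train_engine(task, include_source = FALSE, matcher = "none",
                          da_loss = "none", kd = "none",
                          model_cfg = model_cfg, loss_w = loss_cfg,
                          train_cfg = train_cfg),
    comb = train_engine(task, include_source = TRUE, matcher = "resize",
                        da_loss = "none", kd = "none", model_cfg = model_cfg,
                        loss_w = loss_cfg, train_cfg = train_cfg)
  )
}

# Seizure-class probability for a list of trials (eval mode, batched).
predict_scores <- function(model, trials, batch = 128) {
  n <- length(trials)
  scores <- numeric(n)
  for (s in seq(1, n, by = batch)) {
    idx <- s:min(s + batch - 1, n)
    bb <- build_batch(trials[idx], model$n_channels, model$resizenet,
                      if (model$matcher == "none") "truncate" else model$matcher)
    out <- eegnet_forward(model$backbone, bb$X, training = FALSE)
    P <- softmax_rows(out$logits)
    scores[idx] <- P[, 2]
  }
  scores
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from the Mann-Whitney rank statistic,
#' with half credit for ties.
#'
#' @param scores Numeric scores (higher = more seizure-like).
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  pos <- labels == 1
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Per-subject AUC of a trained model
#'
#' Scores every test clip with the model's seizure-class probability and
#' computes one AUC per subject via the rank statistic. Subjects whose test
#' pool lacks a class are skipped with a warning.
#'
#' @param model A trained `msa_model`.
#' @param test A [domain_dataset()] or list of labeled [trial()]s.
#' @return Named numeric vector mapping subject id to AUC.
#' @export
evaluate_auc <- function(model, test) {
  trials <- if (inherits(test, "domain_dataset")) test$trials else test
  scores <- predict_scores(model, trials)
  labs <- vapply(trials, function(t) t$label, integer(1))
  subj <- vapply(trials, function(t) t$subject_id, character(1))
  out <- c()
  for (sid in unique(subj)) {
    idx <- subj == sid
    a <- auc_score(scores[idx], labs[idx])
    if (is.na(a)) {
      warning("subject ", sid, " lacks one class in the test pool; skipped")
    } else {
      out[sid] <- a
    }
  }
  out
}

#' Repeated seeded training and evaluation
#'
#' Runs train + evaluate `repeats` times with consecutive seeds
#' (`seed + 0 .. repeats - 1`), re-initializing the model each repeat, and
#' reports the mean and standard deviation of the subject-averaged AUC
#' (subjects are averaged within a repeat, then repeats are aggregated).
#'
#' @param task A prepared [transfer_task()].
#' @param method `"msa"` or a [train_baseline()] variant name.
#' @param train_cfg A [train_config()]; `repeats` and base `seed` come from
#'   here.
#' @param ... Passed on to [train_msa()] / [train_baseline()].
#' @return An object of class `eval_result` with fields `per_subject_auc`
#'   (repeats x subjects matrix), `per_repeat` (subject-averaged AUC per
#'   repeat), `mean_auc`, `std_auc`, `seeds`, `method`.
#' @export
run_repeated_experiment <- function(task, method = "msa",
                                    train_cfg = train_config(), ...) {
  seeds <- train_cfg$seed + seq_len(train_cfg$repeats) - 1L
  per_repeat <- numeric(0)
  per_subject <- NULL
  for (s in seeds) {
    cfg_s <- train_cfg
    cfg_s$seed <- s
    model <- if (method == "msa") train_msa(task, train_cfg = cfg_s, ...)
             else train_baseline(task, variant = method, train_cfg = cfg_s, ...)
    auc <- evaluate_auc(model, model$test_pool)
    per_repeat <- c(per_repeat, mean(auc))
    per_subject <- rbind(per_subject, auc)
  }
  rownames(per_subject) <- paste0("seed", seeds)
  structure(list(per_subject_auc = per_subject, per_repeat = per_repeat,
                 mean_auc = mean(per_repeat),
                 std_auc = if (length(per_repeat) > 1) stats::sd(per_repeat)
                           else 0,
                 seeds = seeds, method = method),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: mean AUC %.4f +/- %.4f over %d repeat(s)\n",
              x$method, x$mean_auc, x$std_auc, length(x$seeds)))
  invisible(x)
}

#' @export
as.data.frame.eval_result <- function(x, ...) {
  data.frame(method = x$method, seed = x$seeds, auc = x$per_repeat,
             stringsAsFactors = FALSE)
}

#' Synthetic cross-domain transfer benchmark
#'
#' The package's stand-in for a full cross-species evaluation: for each
#' seed, a fresh two-domain dataset is generated, and the ablation ladder
#' plus the alignment-free reference are trained and evaluated on the
#' unsupervised target pool:
#' `none` (projection only, no alignment), `ea` (+ Euclidean alignment),
#' `ea_da` (+ feature adaptation), `msa` (+ distillation; the full model),
#' and `trunc_source_only` (channel truncation, no alignment — the
#' alignment-free source-only baseline).
#'
#' @param sim_cfg A [sim_config()]; each seed `s` regenerates data with
#'   `sim_config$seed = s`.
#' @param train_cfg A [train_config()] shared by all variants.
#' @param seeds Integer vector of benchmark seeds.
#' @return An object of class `benchmark_result`: a data.frame of
#'   (seed, variant, mean_auc) plus a `summary` attribute.
#' @export
run_transfer_benchmark <- function(sim_cfg = sim_config(),
                                   train_cfg = train_config(epochs = 10),
                                   seeds = 1:3) {
  rows <- NULL
  for (s in seeds) {
    cfg_s <- sim_cfg
    cfg_s$seed <- as.integer(s)
    task <- generate_transfer_pair(cfg_s)
    ptask <- prepare_task(task, ea = TRUE)
    ptask0 <- prepare_task(task, ea = FALSE)
    tc <- train_cfg
    tc$seed <- as.integer(s)
    variants <- list(
      none = function() train_engine(ptask0, matcher = "resize",
                                     da_loss = "none", kd = "none",
                                     train_cfg = tc),
      ea = function() train_engine(ptask, matcher = "resize",
                                   da_loss = "none", kd = "none",
                                   train_cfg = tc),
      ea_da = function() train_engine(ptask, matcher = "resize",
                                      da_loss = "mcc", kd = "none",
                                      train_cfg = tc),
      msa = function() train_msa(ptask, train_cfg = tc),
      trunc_source_only = function() train_baseline(ptask0,
                                                    "truncation_noalign",
                                                    train_cfg = tc)
    )
    for (v in names(variants)) {
      model <- variants[[v]]()
      auc <- evaluate_auc(model, model$test_pool)
      rows <- rbind(rows, data.frame(seed = s, variant = v,
                                     mean_auc = mean(auc),
                                     stringsAsFactors = FALSE))
    }
  }
  agg <- stats::aggregate(mean_auc ~ variant, data = rows,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  summary_df <- data.frame(variant = agg$variant,
                           mean_auc = agg$mean_auc[, "mean"],
                           sd_auc = agg$mean_auc[, "sd"],
                           stringsAsFactors = FALSE)
  structure(rows, summary = summary_df, class = c("benchmark_result",
                                                  "data.frame"))
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(attr(x, "summary"))
  invisible(x)
}
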