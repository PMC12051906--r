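# Small fixture builders shared across test files. Everything is generated
# in code under fixed seeds; nothing is read from disk.

# A small two-domain task: quick to simulate, still carries class signal.
tiny_sim_config <- function(seed = 11, ...) {
  sim_config(n_subjects = 2, clips_per_subject = 40, seed = seed, ...)
}

# A dataset of white-noise trials with controllable per-subject scaling.
noise_dataset <- function(n_subjects = 2, n_trials = 6, C = 3, T = 32,
                          rate = 32, seed = 5, scale = 1) {
  set.seed(seed)
  trials <- list()
  for (s in seq_len(n_subjects)) {
    for (k in seq_len(n_trials)) {
      trials[[length(trials) + 1L]] <- trial(
        scale * matrix(rnorm(C * T), C, T),
        label = (k %% 2L), subject_id = paste0("s", s),
        domain_id = "noise", start_time = (k - 1))
    }
  }
  domain_dataset(trials, sampling_rate = rate, modality = "synthetic",
                 species = "none", domain_id = "noise")
}

# A linearly separable toy task: both "domains" share the montage; class 1
# clips have larger variance. Learnable by variance alone.
toy_separable_task <- function(scenario = "semi_supervised",
                               label_fraction = 20, seed = 3,
                               n_subjects = 2, n_clips = 60, C = 4, T = 64,
                               sd0 = 1, sd1 = 2.5) {
  set.seed(seed)
  mk_domain <- function(domain_id) {
    trials <- list()
    for (s in seq_len(n_subjects)) {
      labs <- sample(rep(c(0L, 1L), length.out = n_clips))
      for (k in seq_len(n_clips)) {
        sdv <- if (labs[k] == 1) sd1 else sd0
        trials[[length(trials) + 1L]] <- trial(
          matrix(rnorm(C * T, sd = sdv), C, T), label = labs[k],
          subject_id = paste0(domain_id, s), domain_id = domain_id,
          start_time = (k - 1))
      }
    }
    domain_dataset(trials, sampling_rate = 64, modality = "synthetic",
                   species = "toy", domain_id = domain_id)
  }
  transfer_task(mk_domain("srcT"), mk_domain("tgtT"), scenario = scenario,
                label_fraction = label_fraction)
}

# Small backbone geometry for fast training in tests.
toy_model_cfg <- function() {
  eegnet_config(F1 = 4, D = 2, F2 = 8, kernel_samples = 16, sep_kernel = 8,
                pool1 = 4, pool2 = 8, dropout = 0.25)
}

toy_train_cfg <- function(epochs = 10, seed = 1, ...) {
  train_config(epochs = epochs, batch_size = 32, seed = seed, ...)
}
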