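#' EEG trial (clip)
#'
#' A `trial` is the unit of classification: one fixed-length multi-channel
#' EEG clip stored as a channels x samples matrix (microvolts), with a binary
#' seizure label, the subject it came from, the recording domain, and the
#' clip's start time within its recording (used for chronological splitting).
#'
#' @param signal Numeric matrix, channels (rows) x samples (columns), in
#'   microvolts. All values must be finite.
#' @param label Integer: 1 = seizure, 0 = non-seizure, -1 = unlabeled.
#' @param subject_id Character scalar identifying the subject.
#' @param domain_id Character scalar identifying the recording domain.
#' @param start_time Non-negative numeric, seconds from recording onset.
#'
#' @return An object of class `trial`.
#' @export
trial <- function(signal, label, subject_id, domain_id = "domain",
                  start_time = 0) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (!all(is.finite(signal))) {
    stop("trial signal contains non-finite values", call. = FALSE)
  }
  if (!label %in% c(-1L, 0L, 1L)) {
    stop("label must be 0 (non-seizure), 1 (seizure) or -1 (unlabeled)",
         call. = FALSE)
  }
  if (start_time < 0) stop("start_time must be >= 0", call. = FALSE)
  structure(
    list(signal = signal, label = as.integer(label),
         subject_id = as.character(subject_id),
         domain_id = as.character(domain_id),
         start_time = as.numeric(start_time)),
    class = "trial"
  )
}

#' @export
print.trial <- function(x, ...) {
  cat(sprintf("<trial> %d ch x %d samples, label=%d, subject=%s, t0=%.2fs\n",
              nrow(x$signal), ncol(x$signal), x$label, x$subject_id,
              x$start_time))
  invisible(x)
}

n_channels_of <- function(x) nrow(x$signal)
n_samples_of <- function(x) ncol(x$signal)

#' EEG domain dataset
#'
#' A homogeneous collection of [trial()]s from one recording domain (one
#' species / device / montage), together with the domain metadata needed by
#' the transfer pipeline: channel count, sampling rate, modality and species.
#' Trials of each subject are kept sorted by `start_time` so chronological
#' label splits are well defined.
#'
#' @param trials List of [trial()] objects, all with the same channel count.
#' @param sampling_rate Sampling rate in Hz.
#' @param modality One of `"iEEG"`, `"sEEG"`, `"synthetic"`.
#' @param species Character scalar (e.g. `"canine"`, `"human"`).
#' @param domain_id Character scalar naming the domain.
#'
#' @return An object of class `domain_dataset` with fields `trials`,
#'   `n_channels`, `sampling_rate`, `modality`, `species`, `domain_id`.
#' @export
domain_dataset <- function(trials, sampling_rate,
                           modality = c("synthetic", "iEEG", "sEEG"),
                           species = "unknown", domain_id = "domain") {
  modality <- match.arg(modality)
  if (length(trials) == 0) {
    stop("empty dataset: a domain_dataset needs at least one trial",
         call. = FALSE)
  }
  ncs <- vapply(trials, n_channels_of, integer(1))
  if (length(unique(ncs)) != 1L) {
    stop("inconsistent channel counts across trials: ",
         paste(unique(ncs), collapse = ", "), call. = FALSE)
  }
  # stable per-subject chronological ordering
  subj <- vapply(trials, function(t) t$subject_id, character(1))
  st <- vapply(trials, function(t) t$start_time, numeric(1))
  ord <- order(subj, st)
  trials <- trials[ord]
  structure(
    list(trials = trials, n_channels = ncs[[1]],
         sampling_rate = as.numeric(sampling_rate),
         modality = modality, species = as.character(species),
         domain_id = as.character(domain_id)),
    class = "domain_dataset"
  )
}

#' @export
print.domain_dataset <- function(x, ...) {
  labs <- trial_labels(x)
  cat(sprintf(
    "<domain_dataset> '%s': %d trials, %d ch @ %g Hz, %s (%s)\n",
    x$domain_id, length(x$trials), x$n_channels, x$sampling_rate,
    x$modality, x$species))
  cat(sprintf("  subjects: %s\n", paste(unique(subject_ids(x)), collapse = ", ")))
  cat(sprintf("  labels: %d seizure / %d non-seizure / %d unlabeled\n",
              sum(labs == 1), sum(labs == 0), sum(labs == -1)))
  invisible(x)
}

#' @export
length.domain_dataset <- function(x) length(x$trials)

#' Subject ids of every trial in a dataset
#' @param dataset A [domain_dataset()].
#' @return Character vector, one entry per trial.
#' @export
subject_ids <- function(dataset) {
  vapply(dataset$trials, function(t) t$subject_id, character(1))
}

#' Labels of every trial in a dataset
#' @param dataset A [domain_dataset()].
#' @return Integer vector, one entry per trial.
#' @export
trial_labels <- function(dataset) {
  vapply(dataset$trials, function(t) t$label, integer(1))
}

#' Start times of every trial in a dataset
#' @param dataset A [domain_dataset()].
#' @return Numeric vector of seconds.
#' @export
trial_start_times <- function(dataset) {
  vapply(dataset$trials, function(t) t$start_time, numeric(1))
}

# Subset keeping metadata (allows empty result; internal use).
subset_trials <- function(dataset, idx) {
  out <- dataset
  out$trials <- dataset$trials[idx]
  out
}

# Stack trials into a (B, C, T) array for model input.
stack_trials <- function(trials) {
  stopifnot(length(trials) > 0)
  C <- nrow(trials[[1]]$signal)
  T <- ncol(trials[[1]]$signal)
  arr <- array(0, dim = c(length(trials), C, T))
  for (i in seq_along(trials)) arr[i, , ] <- trials[[i]]$signal
  arr
}

#' Summarize a dataset as a data frame
#'
#' One row per trial: subject, label, start time, channel count, samples.
#'
#' @param x A [domain_dataset()].
#' @param ... Unused.
#' @return A data.frame.
#' @export
as.data.frame.domain_dataset <- function(x, ...) {
  data.frame(
    domain_id = x$domain_id,
    subject_id = subject_ids(x),
    label = trial_labels(x),
    start_time = trial_start_times(x),
    n_channels = x$n_channels,
    n_samples = vapply(x$trials, n_samples_of, integer(1)),
    stringsAsFactors = FALSE
  )
}
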