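# Fourier-domain resampling of one real series to an arbitrary new length.
# Keeps the min(n_in, n_out) lowest frequencies; the shared Nyquist bin is
# summed on downsampling and split on upsampling so conjugate symmetry (and
# hence realness) is preserved exactly.
fft_resample <- function(x, n_out) {
  N <- length(x)
  M <- as.integer(n_out)
  if (M == N) return(x)
  X <- stats::fft(x)
  Y <- rep(0 + 0i, M)
  N2 <- min(N, M)
  h <- N2 %/% 2L
  Y[1:h] <- X[1:h]
  if (N2 %% 2L == 1L) Y[h + 1L] <- X[h + 1L]
  negn <- if (N2 %% 2L == 0L) h - 1L else h
  if (negn > 0L) Y[(M - negn + 1L):M] <- X[(N - negn + 1L):N]
  if (N2 %% 2L == 0L) {
    if (M < N) {
      Y[h + 1L] <- X[h + 1L] + X[N - h + 1L]
    } else {
      Y[h + 1L] <- X[h + 1L] / 2
      Y[M - h + 1L] <- X[h + 1L] / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / N
}

#' Resample a trial to a new sampling rate
#'
#' Fourier-domain resampling: the spectrum is truncated (downsampling) or
#' zero-padded (upsampling), so sinusoids below the new Nyquist frequency are
#' preserved. The output has exactly `round(T * to_rate / from_rate)` samples.
#'
#' @param x A [trial()].
#' @param from_rate,to_rate Sampling rates in Hz (both positive).
#' @return A [trial()] at the new rate; label and metadata unchanged.
#' @export
resample_trial <- function(x, from_rate, to_rate) {
  if (from_rate <= 0 || to_rate <= 0) {
    stop("parameter error: sampling rates must be positive", call. = FALSE)
  }
  if (from_rate == to_rate) return(x)
  Tn <- ncol(x$signal)
  n_out <- as.integer(round(Tn * to_rate / from_rate))
  out <- t(apply(x$signal, 1, fft_resample, n_out = n_out))
  if (n_out == 1L) out <- matrix(out, nrow = nrow(x$signal))
  x$signal <- out
  x
}

#' Zero-phase band-pass filter a trial
#'
#' Removes each channel's DC offset, then applies a 4th-order Butterworth
#' band-pass (forward-backward, so zero phase) channel by channel, plus an
#' optional 2nd-order mains notch. The signal shape is unchanged.
#'
#' @param x A [trial()].
#' @param cfg A [preprocess_config()] giving band edges and optional notch.
#' @param rate Sampling rate of the trial in Hz.
#' @return The filtered [trial()].
#' @export
bandpass_filter <- function(x, cfg, rate) {
  nyq <- rate / 2
  if (cfg$band_high >= nyq) {
    stop("parameter error: band_high (", cfg$band_high,
         " Hz) must be below the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  }
  bp <- signal::butter(4, c(cfg$band_low, cfg$band_high) / nyq, type = "pass")
  sig <- x$signal - rowMeans(x$signal)
  out <- t(apply(sig, 1, function(row) signal::filtfilt(bp, row)))
  if (!is.null(cfg$notch)) {
    nt <- signal::butter(2, c(cfg$notch - 1, cfg$notch + 1) / nyq,
                         type = "stop")
    out <- t(apply(out, 1, function(row) signal::filtfilt(nt, row)))
  }
  x$signal <- out
  x
}

#' Segment a continuous recording into fixed-length labeled clips
#'
#' Cuts a continuous C x N recording into consecutive non-overlapping clips
#' of `cfg$clip_seconds`; the trailing remainder is dropped. Each clip is
#' labeled by majority overlap with the annotated seizure intervals
#' (half-open `[start_s, end_s)` in seconds); exact ties are labeled seizure
#' to favor sensitivity. Time not covered by any interval counts as
#' non-seizure.
#'
#' @param recording Numeric C x N matrix (continuous multichannel signal).
#' @param annotations List of annotation intervals, each a list/row with
#'   `start_s`, `end_s`, `label` (1 = seizure, 0 = non-seizure).
#' @param cfg A [preprocess_config()].
#' @param rate Sampling rate in Hz.
#' @param subject_id,domain_id Metadata attached to every clip.
#' @return List of [trial()]s, each carrying its `start_time`. A clip length
#'   exceeding the recording yields an empty list with a warning.
#' @export
segment_into_clips <- function(recording, annotations, cfg, rate,
                               subject_id = "subject", domain_id = "domain") {
  recording <- as.matrix(recording)
  N <- ncol(recording)
  clip_len <- as.integer(round(cfg$clip_seconds * rate))
  if (clip_len > N) {
    warning("clip length exceeds recording; returning no clips")
    return(list())
  }
  n_clips <- N %/% clip_len
  seiz <- Filter(function(a) a$label == 1, annotations)
  clips <- vector("list", n_clips)
  for (i in seq_len(n_clips)) {
    s0 <- (i - 1L) * clip_len            # 0-based sample offset
    t0 <- s0 / rate
    t1 <- t0 + cfg$clip_seconds
    ov <- 0
    for (a in seiz) {
      ov <- ov + max(0, min(t1, a$end_s) - max(t0, a$start_s))
    }
    lab <- if (ov >= cfg$clip_seconds / 2) 1L else 0L
    clips[[i]] <- trial(recording[, (s0 + 1):(s0 + clip_len), drop = FALSE],
                        label = lab, subject_id = subject_id,
                        domain_id = domain_id, start_time = t0)
  }
  clips
}

#' Resample every trial of a dataset
#'
#' @param dataset A [domain_dataset()].
#' @param to_rate Target sampling rate in Hz.
#' @return The dataset at `to_rate`.
#' @export
resample_dataset <- function(dataset, to_rate) {
  if (dataset$sampling_rate == to_rate) return(dataset)
  dataset$trials <- lapply(dataset$trials, resample_trial,
                           from_rate = dataset$sampling_rate,
                           to_rate = to_rate)
  dataset$sampling_rate <- as.numeric(to_rate)
  dataset
}

#' Bring two domains to a common sampling rate
#'
#' When domains differ in sampling rate, both are resampled to the LOWER of
#' the two, avoiding fabrication of high-frequency content.
#'
#' @param source,target [domain_dataset()]s.
#' @return A list with elements `source` and `target` at the common rate.
#' @export
harmonize_rates <- function(source, target) {
  common <- min(source$sampling_rate, target$sampling_rate)
  list(source = resample_dataset(source, common),
       target = resample_dataset(target, common))
}
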