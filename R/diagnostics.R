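#' Approximate-entropy parameters
#'
#' Classical regularity statistic settings: embedding dimension `m` and
#' tolerance `r`, the latter either absolute or (the field's default) a
#' multiple of the series' standard deviation. Defaults m = 2, r = 0.2 SD.
#'
#' @param m Embedding dimension (>= 1).
#' @param r Tolerance (> 0).
#' @param r_type `"sd"` (r is a multiple of the SD) or `"absolute"`.
#' @return An object of class `apen_params`.
#' @export
apen_params <- function(m = 2, r = 0.2, r_type = c("sd", "absolute")) {
  r_type <- match.arg(r_type)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (r <= 0) stop("r must be > 0", call. = FALSE)
  structure(list(m = m, r = r, r_type = r_type), class = "apen_params")
}

# Chebyshev-distance template-match counts at embedding dimension m,
# self-matches included (Pincus convention).
phi_m <- function(x, m, r) {
  N <- length(x)
  n <- N - m + 1
  emb <- sapply(seq_len(m), function(j) x[j:(j + n - 1)])
  if (is.null(dim(emb))) emb <- matrix(emb, ncol = m)
  D <- matrix(0, n, n)
  for (j in seq_len(m)) {
    D <- pmax(D, abs(outer(emb[, j], emb[, j], "-")))
  }
  mean(log(rowMeans(D <= r)))
}

#' Approximate entropy
#'
#' Pincus' ApEn: \eqn{\Phi^m(r) - \Phi^{m+1}(r)} with Chebyshev distance and
#' self-matches included. Regular signals (constants, pure tones) score near
#' zero; irregular ones (noise) score higher — the contrast that makes
#' entropy a transferable seizure marker. Invariant to adding a constant;
#' with `r_type = "sd"`, also to rescaling.
#'
#' @param x Numeric series of length N > m + 1.
#' @param p An [apen_params()].
#' @return Scalar ApEn value.
#' @export
approximate_entropy <- function(x, p = apen_params()) {
  N <- length(x)
  if (N <= p$m + 1) {
    stop("parameter error: series length must exceed m + 1", call. = FALSE)
  }
  r <- if (p$r_type == "sd") p$r * stats::sd(x) else p$r
  if (r <= 0) return(0)
  phi_m(x, p$m, r) - phi_m(x, p$m + 1, r)
}

#' PSD spectrogram
#'
#' Consecutive Hann-windowed Fourier transforms of a trial: one-sided power
#' per window in dB (floored at -120 dB), averaged over channels. Frequency
#' bin spacing is `1 / window_seconds`.
#'
#' @param x A [trial()] or a channels x samples matrix.
#' @param rate Sampling rate in Hz.
#' @param window_seconds Window length in seconds (default 1).
#' @param overlap_fraction Overlap between consecutive windows in \[0, 1)
#'   (default 0.5).
#' @return A `windows x bins` matrix of dB power with frequencies as column
#'   names and window start times (s) as row names.
#' @export
psd_spectrogram <- function(x, rate, window_seconds = 1,
                            overlap_fraction = 0.5) {
  sig <- if (inherits(x, "trial")) x$signal else as.matrix(x)
  T <- ncol(sig)
  win <- as.integer(round(window_seconds * rate))
  if (win > T) {
    stop("parameter error: window longer than the trial", call. = FALSE)
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  }
  hop <- max(1L, as.integer(round(win * (1 - overlap_fraction))))
  starts <- seq(1L, T - win + 1L, by = hop)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  nb <- win %/% 2 + 1L
  out <- matrix(0, length(starts), nb)
  for (w in seq_along(starts)) {
    seg <- sig[, starts[w]:(starts[w] + win - 1L), drop = FALSE]
    pw <- 0
    for (ch in seq_len(nrow(seg))) {
      sp <- abs(stats::fft(seg[ch, ] * hann))^2 / win^2
      pw <- pw + sp[seq_len(nb)]
    }
    out[w, ] <- pw / nrow(seg)
  }
  out <- pmax(10 * log10(pmax(out, 0)), -120)
  dimnames(out) <- list(sprintf("%.3f", (starts - 1) / rate),
                        sprintf("%.2f", (seq_len(nb) - 1) / window_seconds))
  out
}

#' Seizure vs background band-power contrast of a dataset
#'
#' Mean in-band power of seizure clips relative to non-seizure clips, in dB
#' — the dataset-level analogue of the ictal power increase visible in PSD
#' spectrograms, used for QC of synthetic and imported data.
#'
#' @param dataset A labeled [domain_dataset()].
#' @param band Frequency band in Hz.
#' @return Scalar dB difference (positive = seizure clips carry more band
#'   power).
#' @export
class_band_contrast <- function(dataset, band = c(15, 25)) {
  labs <- trial_labels(dataset)
  bp <- vapply(dataset$trials, function(tr)
    sum(band_power(tr$signal, dataset$sampling_rate, band)), numeric(1))
  10 * (log10(mean(bp[labs == 1])) - log10(mean(bp[labs == 0])))
}

#' Per-class QC summary of a dataset
#'
#' Approximate entropy (channel-averaged, on up to `max_clips` clips per
#' class) and in-band power by class: the dataset-level counterparts of the
#' time-domain, entropy and frequency-domain seizure signatures.
#'
#' @param dataset A labeled [domain_dataset()].
#' @param band Band of interest in Hz (default 15-25).
#' @param p An [apen_params()].
#' @param max_clips Clips sampled per class for the (quadratic-cost) ApEn.
#' @return A data.frame with one row per class.
#' @export
qc_summary <- function(dataset, band = c(15, 25), p = apen_params(),
                       max_clips = 20) {
  labs <- trial_labels(dataset)
  rows <- NULL
  for (cls in sort(unique(labs))) {
    idx <- which(labs == cls)
    sub <- idx[seq_len(min(max_clips, length(idx)))]
    apens <- vapply(dataset$trials[sub], function(tr)
      mean(apply(tr$signal, 1, approximate_entropy, p = p)), numeric(1))
    bp <- vapply(dataset$trials[idx], function(tr)
      sum(band_power(tr$signal, dataset$sampling_rate, band)), numeric(1))
    rows <- rbind(rows, data.frame(
      label = cls, n_clips = length(idx), mean_apen = mean(apens),
      mean_band_power_db = 10 * log10(mean(bp)),
      stringsAsFactors = FALSE))
  }
  rows
}
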