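#' Per-subject mean trial covariance
#'
#' Computes the reference covariance used by Euclidean alignment:
#' \eqn{\bar R = (1/n) \sum_i X_i X_i^\top} over a subject's trials, then
#' symmetrizes. If the smallest eigenvalue falls below
#' `epsilon * trace / C`, a ridge `epsilon * (trace/C) * I` is added so the
#' result is strictly positive definite even for rank-deficient clip pools.
#'
#' @param trials List of [trial()]s from one subject (same channel count).
#' @param epsilon Relative regularization (default `1e-6`).
#' @return A C x C symmetric positive-definite matrix.
#' @export
mean_covariance <- function(trials, epsilon = 1e-6) {
  if (length(trials) < 1) stop("need at least one trial", call. = FALSE)
  ncs <- vapply(trials, n_channels_of, integer(1))
  if (length(unique(ncs)) != 1L) {
    stop("consistency error: trials have differing channel counts (",
         paste(unique(ncs), collapse = ", "), ")", call. = FALSE)
  }
  C <- ncs[[1]]
  R <- matrix(0, C, C)
  for (tr in trials) R <- R + tcrossprod(tr$signal)
  R <- R / length(trials)
  R <- (R + t(R)) / 2
  scale <- sum(diag(R)) / C
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < epsilon * scale) R <- R + epsilon * scale * diag(C)
  R
}

#' Inverse square root of a symmetric positive-definite matrix
#'
#' Eigendecomposition-based \eqn{M^{-1/2}} with an eigenvalue floor, so that
#' `S %*% M %*% S` is the identity to high accuracy. This is the whitening
#' transform of Euclidean alignment.
#'
#' @param M Symmetric positive-definite matrix.
#' @param floor_rel Eigenvalues below `floor_rel * mean(eigenvalues)` are
#'   floored (guards numerically singular inputs).
#' @return A symmetric positive-definite matrix `S` with `S M S = I`.
#' @export
inv_sqrt_spd <- function(M, floor_rel = 1e-12) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
    stop("inv_sqrt_spd requires a symmetric matrix", call. = FALSE)
  }
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, floor_rel * mean(abs(eg$values)))
  eg$vectors %*% (t(eg$vectors) * (1 / sqrt(ev)))
}

#' Alignment state for one subject
#'
#' Bundles a subject's reference covariance, its inverse square root (the
#' whitener), and the regularization used — enough to reproduce or serialize
#' the alignment.
#'
#' @param mean_cov The subject's mean trial covariance.
#' @param epsilon Relative regularization used.
#' @return An object of class `alignment_state` with fields `mean_cov`,
#'   `whitener`, `epsilon`.
#' @export
alignment_state <- function(mean_cov, epsilon = 1e-6) {
  structure(
    list(mean_cov = mean_cov, whitener = inv_sqrt_spd(mean_cov),
         epsilon = epsilon),
    class = "alignment_state"
  )
}

#' Euclidean alignment of a dataset
#'
#' Input-space alignment: each subject's trials are whitened by the inverse
#' square root of that subject's mean trial covariance, so after alignment
#' every subject's mean covariance is the identity and subjects become
#' directly comparable. The statistic is label-free, so alignment is equally
#' legitimate for unlabeled test subjects. Labels, trial ordering and
#' metadata are unchanged; the operation is idempotent and invariant to
#' per-subject rescaling.
#'
#' @param dataset A [domain_dataset()].
#' @param epsilon Relative covariance regularization (default `1e-6`).
#' @return A list with `dataset` (the aligned [domain_dataset()]) and
#'   `states` (named list mapping subject id to [alignment_state()]).
#' @export
euclidean_align <- function(dataset, epsilon = 1e-6) {
  subj <- subject_ids(dataset)
  states <- list()
  out <- dataset
  for (sid in unique(subj)) {
    idx <- which(subj == sid)
    st <- alignment_state(
      mean_covariance(dataset$trials[idx], epsilon = epsilon),
      epsilon = epsilon)
    states[[sid]] <- st
    for (i in idx) {
      out$trials[[i]]$signal <- st$whitener %*% dataset$trials[[i]]$signal
    }
  }
  list(dataset = out, states = states)
}

# Serialize alignment states to a JSON file (reproducibility sidecar).
#' Write alignment states to JSON
#' @param states Named list of [alignment_state()] (from [euclidean_align()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_alignment_states <- function(states, path) {
  ser <- lapply(states, function(s)
    list(mean_cov = s$mean_cov, whitener = s$whitener, epsilon = s$epsilon))
  jsonlite::write_json(ser, path, digits = NA)
  invisible(path)
}
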