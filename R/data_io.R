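#' Preprocessing configuration
#'
#' Settings for turning continuous recordings into fixed-length labeled clips:
#' clip length, band-pass edges, optional mains notch, optional resampling
#' target. Defaults follow conventional seizure-detection preprocessing:
#' zero-phase 4th-order band-pass 0.5-70 Hz, no notch, 1-second
#' non-overlapping clips.
#'
#' @param clip_seconds Positive clip length in seconds.
#' @param band_low,band_high Band-pass edges in Hz (`0 < band_low < band_high`).
#' @param notch Optional mains frequency in Hz (50 or 60), `NULL` to disable.
#' @param target_rate Optional resampling target in Hz, `NULL` to keep the
#'   native rate. When set, `band_high` must stay below `target_rate / 2`.
#'
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(clip_seconds = 1, band_low = 0.5,
                              band_high = 70, notch = NULL,
                              target_rate = NULL) {
  if (clip_seconds <= 0) stop("clip_seconds must be positive", call. = FALSE)
  if (!(band_low > 0 && band_low < band_high)) {
    stop("need 0 < band_low < band_high", call. = FALSE)
  }
  if (!is.null(target_rate) && band_high >= target_rate / 2) {
    stop("band_high must be below target_rate / 2", call. = FALSE)
  }
  structure(
    list(clip_seconds = clip_seconds, band_low = band_low,
         band_high = band_high, notch = notch, target_rate = target_rate),
    class = "preprocess_config"
  )
}

# ---------------------------------------------------------------------------
# Internal container: one little-endian float64 blob per subject plus a JSON
# metadata sidecar. Sidecar schema (version 1):
#   {
#     "format": "seizalign-dataset", "version": 1,
#     "n_channels": C, "sampling_rate": Hz,
#     "modality": "...", "species": "...", "domain_id": "...",
#     "subjects": [
#       {"subject_id": "...", "file": "<id>.bin",
#        "trials": [{"label": 0|1|-1, "start_time": s, "n_samples": T}, ...]}
#     ]
#   }
# Each blob holds the subject's trials concatenated in sidecar order, each
# stored column-major as a C x n_samples double matrix.
# ---------------------------------------------------------------------------

#' Write a dataset to the internal container format
#'
#' Stores a [domain_dataset()] as a directory holding one binary float64
#' blob per subject plus a `metadata.json` sidecar describing montage,
#' sampling rate and per-trial labels/start times. The round trip through
#' [read_dataset()] is bit-exact.
#'
#' @param dataset A [domain_dataset()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "domain_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  subj <- subject_ids(dataset)
  subjects_meta <- list()
  for (sid in unique(subj)) {
    idx <- which(subj == sid)
    fname <- paste0(make.names(sid), ".bin")
    con <- file(file.path(path, fname), "wb")
    trials_meta <- list()
    for (k in seq_along(idx)) {
      tr <- dataset$trials[[idx[k]]]
      writeBin(as.vector(tr$signal), con, size = 8, endian = "little")
      trials_meta[[k]] <- list(label = tr$label, start_time = tr$start_time,
                               n_samples = ncol(tr$signal))
    }
    close(con)
    subjects_meta[[length(subjects_meta) + 1L]] <-
      list(subject_id = sid, file = fname, trials = trials_meta)
  }
  meta <- list(
    format = "seizalign-dataset", version = 1L,
    n_channels = dataset$n_channels, sampling_rate = dataset$sampling_rate,
    modality = dataset$modality, species = dataset$species,
    domain_id = dataset$domain_id, subjects = subjects_meta
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset from the internal container format
#'
#' Inverse of [write_dataset()]. Signal arrays round-trip bit-exactly.
#'
#' @param path Directory produced by [write_dataset()].
#' @return A [domain_dataset()].
#' @export
read_dataset <- function(path) {
  sidecar <- file.path(path, "metadata.json")
  if (!file.exists(sidecar)) {
    stop("format error: missing metadata.json sidecar in ", path,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar)
  if (is.null(meta$format) || meta$format != "seizalign-dataset") {
    stop("format error: not a seizalign dataset container", call. = FALSE)
  }
  C <- as.integer(meta$n_channels)
  trials <- list()
  for (sm in meta$subjects) {
    blob <- file.path(path, sm$file)
    if (!file.exists(blob)) {
      stop("format error: missing blob ", sm$file, call. = FALSE)
    }
    n_per_trial <- vapply(sm$trials,
                          function(tm) as.integer(tm$n_samples), integer(1))
    total <- C * sum(n_per_trial)
    if (file.size(blob) != 8 * total) {
      stop("consistency error: blob ", sm$file, " holds ",
           file.size(blob) / 8, " doubles but metadata (n_channels=", C,
           ") implies ", total, call. = FALSE)
    }
    con <- file(blob, "rb")
    vals <- readBin(con, "double", n = total, size = 8, endian = "little")
    close(con)
    off <- 0L
    for (k in seq_along(sm$trials)) {
      tm <- sm$trials[[k]]
      Tn <- n_per_trial[k]
      trials[[length(trials) + 1L]] <- trial(
        matrix(vals[(off + 1):(off + C * Tn)], nrow = C, ncol = Tn),
        label = as.integer(tm$label), subject_id = sm$subject_id,
        domain_id = as.character(meta$domain_id),
        start_time = as.numeric(tm$start_time))
      off <- off + C * Tn
    }
  }
  if (length(trials) == 0) {
    stop("empty-dataset error: container holds no trials", call. = FALSE)
  }
  domain_dataset(trials, sampling_rate = as.numeric(meta$sampling_rate),
                 modality = as.character(meta$modality),
                 species = as.character(meta$species),
                 domain_id = as.character(meta$domain_id))
}

# ---------------------------------------------------------------------------
# Optional EDF (European Data Format) import. EDF has a fixed-layout ASCII
# header (256 bytes + 256 per signal) followed by data records of int16
# samples; physical values are reconstructed from the per-signal calibration
# (physical min/max vs digital min/max).
# ---------------------------------------------------------------------------

read_edf_header <- function(con) {
  fld <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  h <- list()
  h$version <- fld(8); h$patient <- fld(80); h$recording <- fld(80)
  h$startdate <- fld(8); h$starttime <- fld(8)
  h$header_bytes <- as.integer(fld(8)); fld(44)
  h$n_records <- as.integer(fld(8))
  h$record_seconds <- as.numeric(fld(8))
  ns <- as.integer(fld(4)); h$ns <- ns
  per <- function(n) vapply(seq_len(ns), function(i) fld(n), character(1))
  h$labels <- per(16); h$transducer <- per(80); h$dim <- per(8)
  h$phys_min <- as.numeric(per(8)); h$phys_max <- as.numeric(per(8))
  h$dig_min <- as.numeric(per(8)); h$dig_max <- as.numeric(per(8))
  h$prefilter <- per(80)
  h$samples_per_record <- as.integer(per(8))
  per(32)
  h
}

#' Import a continuous recording from an EDF file
#'
#' Reads a European Data Format file into a channels x samples matrix of
#' physical values. All channels must share one sampling rate (the usual
#' case for a single montage); annotation channels are not interpreted.
#'
#' @param path Path to an EDF file.
#' @return A list with `signal` (C x N matrix), `sampling_rate` (Hz) and
#'   `channel_labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (length(unique(h$samples_per_record)) != 1L) {
    stop("EDF channels have differing sampling rates; not supported",
         call. = FALSE)
  }
  spr <- h$samples_per_record[[1]]
  rate <- spr / h$record_seconds
  gain <- (h$phys_max - h$phys_min) / (h$dig_max - h$dig_min)
  offset <- h$phys_min - gain * h$dig_min
  sig <- matrix(0, nrow = h$ns, ncol = spr * h$n_records)
  for (r in seq_len(h$n_records)) {
    for (s in seq_len(h$ns)) {
      d <- readBin(con, "integer", n = spr, size = 2, signed = TRUE,
                   endian = "little")
      sig[s, ((r - 1) * spr + 1):(r * spr)] <- gain[s] * d + offset[s]
    }
  }
  list(signal = sig, sampling_rate = rate, channel_labels = h$labels)
}

#' Import an EDF recording plus annotation CSV into the container format
#'
#' Convenience wrapper: reads an EDF file, segments it into clips with
#' [segment_into_clips()] using annotation intervals from a CSV with columns
#' `subject,start_s,end_s,label`, and writes the internal container.
#'
#' @param edf_path Path to the EDF file.
#' @param annotations_csv CSV of `(subject, start_s, end_s, label)` intervals.
#' @param out_dir Output container directory.
#' @param subject_id Subject the recording belongs to.
#' @param cfg A [preprocess_config()].
#' @param species,modality Domain metadata for the container.
#' @return The output path, invisibly.
#' @export
import_edf <- function(edf_path, annotations_csv, out_dir, subject_id,
                       cfg = preprocess_config(), species = "human",
                       modality = "sEEG") {
  rec <- read_edf(edf_path)
  ann <- utils::read.csv(annotations_csv, stringsAsFactors = FALSE)
  ann <- ann[ann$subject == subject_id, , drop = FALSE]
  ivals <- lapply(seq_len(nrow(ann)), function(i)
    list(start_s = ann$start_s[i], end_s = ann$end_s[i], label = ann$label[i]))
  clips <- segment_into_clips(rec$signal, ivals, cfg, rec$sampling_rate,
                              subject_id = subject_id, domain_id = "edf")
  ds <- domain_dataset(clips, sampling_rate = rec$sampling_rate,
                       modality = modality, species = species,
                       domain_id = "edf")
  write_dataset(ds, out_dir)
}
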