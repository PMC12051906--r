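test_that("container round-trip is the identity on every field", {
  ds <- noise_dataset(seed = 21)
  path <- file.path(tempdir(), "rt-ds")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$n_channels, ds$n_channels)
  expect_equal(back$sampling_rate, ds$sampling_rate)
  expect_equal(back$modality, ds$modality)
  expect_equal(back$species, ds$species)
  expect_equal(back$domain_id, ds$domain_id)
  expect_equal(length(back$trials), length(ds$trials))
  for (i in seq_along(ds$trials)) {
    expect_identical(back$trials[[i]]$signal, ds$trials[[i]]$signal)
    expect_identical(back$trials[[i]]$label, ds$trials[[i]]$label)
    expect_identical(back$trials[[i]]$subject_id, ds$trials[[i]]$subject_id)
    expect_identical(back$trials[[i]]$start_time, ds$trials[[i]]$start_time)
  }
  unlink(path, recursive = TRUE)
})

test_that("container errors: missing sidecar, shape mismatch, empty", {
  ds <- noise_dataset(seed = 22)
  path <- file.path(tempdir(), "bad-ds")
  write_dataset(ds, path)

  # metadata claims more channels than the blobs hold
  meta <- jsonlite::read_json(file.path(path, "metadata.json"))
  meta$n_channels <- 16L
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_dataset(path), "consistency error")

  # empty trial list
  meta$n_channels <- 3L
  meta$subjects <- list()
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_dataset(path), "empty-dataset")

  file.remove(file.path(path, "metadata.json"))
  expect_error(read_dataset(path), "format error")
  unlink(path, recursive = TRUE)
})

test_that("resampling preserves length formula, identity and sinusoids", {
  set.seed(1)
  tr <- trial(matrix(rnorm(2 * 4000), 2, 4000), 0, "s1")
  expect_identical(resample_trial(tr, 400, 400), tr)
  out <- resample_trial(tr, 400, 256)
  expect_equal(ncol(out$signal), 2560)

  # 10 Hz sine downsampled 400 -> 200 Hz keeps its spectral peak
  t4 <- seq(0, 10 - 1 / 400, by = 1 / 400)
  sine <- trial(matrix(sin(2 * pi * 10 * t4), 1), 0, "s1")
  ds <- resample_trial(sine, 400, 200)
  sp <- abs(fft(ds$signal[1, ]))[1:1000]
  peak_hz <- (which.max(sp) - 1) / 10        # bin spacing 0.1 Hz
  expect_lt(abs(peak_hz - 10), 0.1 + 1e-9)

  # down-then-up round trip correlates for band-limited input
  bl <- trial(matrix(sin(2 * pi * 30 * t4) + 0.5 * sin(2 * pi * 11 * t4),
                     1), 0, "s1")
  rt <- resample_trial(resample_trial(bl, 400, 256), 256, 400)
  expect_gt(cor(rt$signal[1, ], bl$signal[1, ]), 0.99)

  expect_error(resample_trial(tr, 400, -1), "parameter error")
})

test_that("band-pass filtering attenuates out-of-band content, keeps shape", {
  cfg <- preprocess_config(band_low = 0.5, band_high = 70)
  t4 <- seq(0, 10 - 1 / 400, by = 1 / 400)

  hf <- trial(matrix(sin(2 * pi * 100 * t4), 1), 0, "s1")
  out <- bandpass_filter(hf, cfg, rate = 400)
  expect_lt(sqrt(mean(out$signal^2)), 0.1 * sqrt(mean(hf$signal^2)))

  dc <- trial(matrix(5, 1, 4000), 0, "s1")
  outdc <- bandpass_filter(dc, cfg, rate = 400)
  expect_lt(mean(abs(outdc$signal)), 1e-3 * 5)

  set.seed(2)
  x <- trial(matrix(rnorm(3 * 800), 3, 800), 0, "s1")
  expect_equal(dim(bandpass_filter(x, cfg, rate = 400)$signal), c(3, 800))

  expect_error(bandpass_filter(x, preprocess_config(band_high = 300),
                               rate = 400),
               "parameter error")

  # in-band sinusoid passes, out-of-band is >= 20 dB down relative to it
  inband <- trial(matrix(sin(2 * pi * 20 * t4), 1), 0, "s1")
  rms_in <- sqrt(mean(bandpass_filter(inband, cfg, 400)$signal^2))
  rms_out <- sqrt(mean(out$signal^2))
  expect_gt(20 * log10(rms_in / rms_out), 20)
})

test_that("segmentation counts clips, drops remainders, labels by majority", {
  cfg <- preprocess_config(clip_seconds = 1)
  rec <- matrix(rnorm(2 * 4000), 2)
  ann <- list(list(start_s = 2.0, end_s = 4.0, label = 1))
  clips <- segment_into_clips(rec, ann, cfg, rate = 400, subject_id = "s1")
  expect_length(clips, 10)
  expect_equal(vapply(clips, function(x) x$start_time, numeric(1)), 0:9)
  expect_equal(vapply(clips, function(x) x$label, integer(1)),
               as.integer(seq(0, 9) >= 2 & seq(0, 9) < 4))

  clips2 <- segment_into_clips(matrix(rnorm(4100), 1), list(), cfg, 400)
  expect_length(clips2, 10)

  # majority overlap: 0.6 s seizure wins; exact ties favor seizure
  ann3 <- list(list(start_s = 0.4, end_s = 1.0, label = 1))
  expect_equal(segment_into_clips(matrix(0, 1, 400), ann3, cfg,
                                  400)[[1]]$label, 1L)
  ann4 <- list(list(start_s = 0.5, end_s = 1.0, label = 1))
  expect_equal(segment_into_clips(matrix(0, 1, 400), ann4, cfg,
                                  400)[[1]]$label, 1L)
  ann5 <- list(list(start_s = 0.6, end_s = 1.0, label = 1))
  expect_equal(segment_into_clips(matrix(0, 1, 400), ann5, cfg,
                                  400)[[1]]$label, 0L)

  expect_warning(out <- segment_into_clips(matrix(0, 1, 100), list(), cfg,
                                           400),
                 "clip length exceeds")
  expect_length(out, 0)
})

test_that("clip count equals floor(N / clip samples) for random inputs", {
  cfg <- preprocess_config(clip_seconds = 0.5)
  set.seed(9)
  for (N in sample(300:5000, 5)) {
    clips <- segment_into_clips(matrix(0, 1, N), list(), cfg, rate = 100)
    expect_length(clips, N %/% 50)
  }
})

# An independent minimal EDF writer following the published fixed-layout
# header (256 bytes + 256 per signal, int16 little-endian records).
write_edf_fixture <- function(path, signal, rate, phys_range = 500) {
  ns <- nrow(signal); N <- ncol(signal)
  n_rec <- N %/% rate
  con <- file(path, "wb")
  pad <- function(s, n) {
    s <- substr(s, 1, n)
    writeChar(formatC(s, width = -n), con, eos = NULL)
  }
  pad("0", 8); pad("test patient", 80); pad("test rec", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(as.character(256 * (1 + ns)), 8); pad("", 44)
  pad(as.character(n_rec), 8); pad("1", 8); pad(as.character(ns), 4)
  for (i in 1:ns) pad(sprintf("ch%d", i), 16)
  for (i in 1:ns) pad("transducer", 80)
  for (i in 1:ns) pad("uV", 8)
  for (i in 1:ns) pad(as.character(-phys_range), 8)
  for (i in 1:ns) pad(as.character(phys_range), 8)
  for (i in 1:ns) pad("-32768", 8)
  for (i in 1:ns) pad("32767", 8)
  for (i in 1:ns) pad("", 80)
  for (i in 1:ns) pad(as.character(rate), 8)
  for (i in 1:ns) pad("", 32)
  gain <- (2 * phys_range) / 65535
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- signal[s, ((r - 1) * rate + 1):(r * rate)]
      dig <- as.integer(round((seg - (-phys_range)) / gain + (-32768)))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  close(con)
}

test_that("EDF import recovers signals to quantization accuracy", {
  set.seed(4)
  rate <- 64
  sig <- matrix(rnorm(2 * rate * 4, sd = 50), 2)
  path <- tempfile(fileext = ".edf")
  write_edf_fixture(path, sig, rate)
  edf <- read_edf(path)
  expect_equal(edf$sampling_rate, rate)
  expect_equal(dim(edf$signal), dim(sig))
  # int16 over [-500, 500] quantizes to ~0.0153 uV steps
  expect_lt(max(abs(edf$signal - sig)), 0.02)

  ann <- data.frame(subject = "p1", start_s = 1, end_s = 3, label = 1)
  csv <- tempfile(fileext = ".csv")
  write.csv(ann, csv, row.names = FALSE)
  out_dir <- file.path(tempdir(), "edf-ds")
  import_edf(path, csv, out_dir, subject_id = "p1",
             cfg = preprocess_config(clip_seconds = 1))
  ds <- read_dataset(out_dir)
  expect_equal(length(ds$trials), 4)
  expect_equal(trial_labels(ds), c(0L, 1L, 1L, 0L))
  unlink(c(path, csv)); unlink(out_dir, recursive = TRUE)
})
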