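test_that("crop_or_pad honours the padding and windowing contracts", {
  short <- audio_clip(rep(0.3, 8000), 4000)        # 2 s
  out <- crop_or_pad(short, 5)
  expect_length(out$samples, 20000L)
  expect_identical(out$samples[8001:20000], numeric(12000))

  exact <- audio_clip(runif(20000, -1, 1), 4000)
  expect_identical(crop_or_pad(exact, 5)$samples, exact$samples)

  long <- audio_clip(seq_len(120000) / 120000, 4000)   # 30 s ramp
  # window start uniform over valid offsets, deterministic under a seed
  starts <- vapply(1:200, function(i) {
    set.seed(i)
    crop_or_pad(long, 5)$samples[1] * 120000
  }, numeric(1))
  expect_true(all(starts >= 1 & starts <= 100001))
  expect_gt(diff(range(starts)), 50000)            # actually spread out
  set.seed(99); a <- crop_or_pad(long, 5)
  set.seed(99); b <- crop_or_pad(long, 5)
  expect_identical(a$samples, b$samples)
})

test_that("band-pass filter preserves the pass band and kills the stop band", {
  inband <- sine_clip(500, duration = 2)
  out <- bandpass_filter(inband, 250, 750)
  rms <- function(x) sqrt(mean(x^2))
  trim <- 2001:6000                                # avoid edge transients
  expect_lt(abs(20 * log10(rms(out$samples[trim]) / rms(inband$samples[trim]))), 1)

  low <- sine_clip(50, duration = 2)
  att <- bandpass_filter(low, 250, 750)
  expect_lt(20 * log10(rms(att$samples[trim]) / rms(low$samples[trim])), -40)

  zero <- audio_clip(numeric(4000) + 0, 4000)
  zero$samples[1] <- 0                             # keep non-empty contract
  expect_equal(max(abs(bandpass_filter(zero, 250, 750)$samples)), 0)
  expect_error(bandpass_filter(inband, 750, 250), "f_low < f_high")
})

test_that("log-mel geometry matches the 4 kHz front end", {
  set.seed(3)
  clip <- audio_clip(rnorm(20000), 4000)           # 5 s
  sp <- compute_logmel(clip)
  expect_identical(dim(sp$values), c(32L, 313L))
  expect_equal(sp$frame_rate, 62.5)
  one_sec <- compute_logmel(audio_clip(rnorm(4000), 4000))
  expect_identical(ncol(one_sec$values), 63L)      # floor(4000/64) + 1
  # frame count non-decreasing in length
  t_of <- function(n) ncol(compute_logmel(audio_clip(rnorm(n), 4000))$values)
  lens <- c(300, 1000, 5000, 12000, 20000)
  expect_true(all(diff(vapply(lens, t_of, numeric(1))) >= 0))
})

test_that("zero signal maps to the log floor and the transform is deterministic", {
  zero <- audio_clip(rep(0, 4000), 4000)
  sp <- compute_logmel(zero)
  expect_true(all(abs(sp$values - log(1e-10)) < 1e-9))
  set.seed(4)
  clip <- audio_clip(rnorm(6000), 4000)
  expect_identical(compute_logmel(clip)$values, compute_logmel(clip)$values)
})

test_that("mel filterbank rows are non-negative with contiguous in-band support", {
  fb <- mel_filterbank(32, 256, 4000, 250, 750)
  expect_true(all(fb >= 0))
  freqs <- seq(0, 2000, length.out = ncol(fb))
  for (m in seq_len(nrow(fb))) {
    sup <- which(fb[m, ] > 0)
    expect_gt(length(sup), 0)
    expect_identical(sup, seq(min(sup), max(sup)))  # contiguous
    expect_gte(freqs[min(sup)], 250 - (freqs[2] - freqs[1]))
    expect_lte(freqs[max(sup)], 750 + (freqs[2] - freqs[1]))
  }
})

test_that("per-band normalization standardizes each band independently", {
  set.seed(5)
  specs <- lapply(1:6, function(i) {
    compute_logmel(audio_clip(rnorm(8000, sd = 0.3), 4000))
  })
  st <- fit_band_stats(specs)
  normed <- lapply(specs, apply_band_norm, stats = st)
  pooled <- do.call(cbind, lapply(normed, function(s) s$values))
  expect_true(all(abs(rowMeans(pooled)) < 1e-8))
  expect_true(all(abs(apply(pooled, 1, stats::var) - 1) < 0.05))

  # constant band collapses to ~0, other bands unaffected in their centring
  s1 <- specs[[1]]
  s1$values[3, ] <- 7
  s2 <- specs[[2]]
  s2$values[3, ] <- 7
  st2 <- fit_band_stats(list(s1, s2))
  n1 <- apply_band_norm(s1, st2)
  expect_true(all(abs(n1$values[3, ]) < 1e-3))

  # two bands with different offsets are centred independently
  a <- s1; a$values[1, ] <- a$values[1, ] + 100
  b <- s2; b$values[1, ] <- b$values[1, ] + 100
  st3 <- fit_band_stats(list(a, b))
  expect_equal(st3$mean[1] - st2$mean[1], 100, tolerance = 1e-9)
  expect_equal(st3$mean[2], st2$mean[2], tolerance = 1e-9)
})

test_that("spectrogram configs load from YAML and spectrograms dump as text", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_mels: 16", "f_high: 600"), f)
  cfg <- read_spectrogram_config(f)
  expect_identical(cfg$n_mels, 16L)
  expect_equal(cfg$f_high, 600)
  expect_identical(cfg$window_len, 256L)            # defaults kept
  writeLines("bogus_key: 1", f)
  expect_error(read_spectrogram_config(f), "unknown spectrogram config key")

  sp <- compute_logmel(audio_clip(rnorm(4000), 4000), cfg)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_spectrogram(sp, out)
  back <- as.matrix(utils::read.table(out, sep = "\t", comment.char = "#"))
  expect_equal(unname(back), unname(sp$values), tolerance = 1e-12)
})

test_that("SpecAugment masks behave as counted, deterministic operations", {
  set.seed(6)
  sp <- compute_logmel(audio_clip(rnorm(20000), 4000))
  same <- spec_augment(sp, n_freq_masks = 0, n_time_masks = 0)
  expect_identical(same$values, sp$values)

  set.seed(7)
  one <- spec_augment(sp, n_freq_masks = 0, n_time_masks = 1,
                      max_time_width = 12, fill = 0)
  altered <- which(colSums(one$values != sp$values) > 0)
  expect_gte(length(altered), 1)
  expect_lte(length(altered), 12)
  expect_identical(altered, seq(min(altered), max(altered)))  # contiguous
  expect_true(all(one$values[, altered] == 0))
  untouched <- setdiff(seq_len(ncol(sp$values)), altered)
  expect_identical(one$values[, untouched], sp$values[, untouched])

  set.seed(8); m1 <- spec_augment(sp)
  set.seed(8); m2 <- spec_augment(sp)
  expect_identical(m1$values, m2$values)
})
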