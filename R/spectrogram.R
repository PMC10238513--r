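#' Spectrogram configuration
#'
#' Parameters of the band-limited log-mel front end. Defaults follow the
#' acquisition pipeline: a 256-sample Hann window (64 ms at 4 kHz) with a
#' 64-sample hop (16 ms, i.e. 62.5 frames/s), and 32 mel bands spanning
#' 250-750 Hz. The narrow band reduces interference from background noise.
#'
#' @param window_len STFT window length in samples.
#' @param hop_len Hop length in samples (`<= window_len`).
#' @param n_mels Number of mel bands.
#' @param f_low,f_high Filterbank edges in Hz (`0 <= f_low < f_high`).
#' @param log_floor Positive constant added before the log.
#' @param bandpass If `TRUE`, apply an explicit time-domain band-pass filter
#'   over \[f_low, f_high\] before the transform. Off by default: the mel-range
#'   restriction already band-limits the representation.
#' @return An object of class `spectrogram_config`.
#' @export
spectrogram_config <- function(window_len = 256L, hop_len = 64L, n_mels = 32L,
                               f_low = 250, f_high = 750, log_floor = 1e-10,
                               bandpass = FALSE) {
  if (hop_len > window_len) stop("hop_len must be <= window_len")
  if (f_low < 0 || f_low >= f_high) stop("need 0 <= f_low < f_high")
  if (n_mels < 1L) stop("n_mels must be >= 1")
  if (log_floor <= 0) stop("log_floor must be positive")
  structure(list(window_len = as.integer(window_len),
                 hop_len = as.integer(hop_len), n_mels = as.integer(n_mels),
                 f_low = f_low, f_high = f_high, log_floor = log_floor,
                 bandpass = isTRUE(bandpass)),
            class = "spectrogram_config")
}

#' Read a spectrogram configuration from a YAML file
#'
#' Keys mirror the [spectrogram_config] arguments; missing keys keep their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A [spectrogram_config].
#' @export
read_spectrogram_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(spectrogram_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown spectrogram config key(s): ", paste(unknown, collapse = ", "))
  do.call(spectrogram_config, vals)
}

#' Dump a spectrogram as a delimited text matrix
#'
#' Debug artifact: tab-separated values, one row per mel band, with frame
#' times in the header comment.
#'
#' @param spec A spectrogram.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrogram <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate=%g rate=%g frames=%d", spec$frame_rate,
                     spec$rate, ncol(spec$values)), con)
  utils::write.table(spec$values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Crop or zero-pad a clip to a fixed duration
#'
#' Training requires fixed-size inputs: shorter clips are right-padded with
#' zeros; longer clips yield a contiguous window whose start offset is drawn
#' uniformly from the valid range using R's current random-number stream
#' (seed it with [set.seed()] for reproducibility). Five seconds generally
#' covers at least one full pediatric respiration cycle.
#'
#' @param clip An [audio_clip].
#' @param duration Target duration in seconds (> 0).
#' @return An [audio_clip] of exactly `duration * rate` samples.
#' @export
crop_or_pad <- function(clip, duration = 5) {
  if (duration <= 0) stop("duration must be positive")
  n <- as.integer(round(duration * clip$rate))
  len <- length(clip$samples)
  x <- if (len < n) {
    c(clip$samples, numeric(n - len))
  } else if (len > n) {
    start <- sample.int(len - n + 1L, 1L)
    clip$samples[start:(start + n - 1L)]
  } else clip$samples
  audio_clip(x, clip$rate, patient_id = clip$patient_id, site = clip$site,
             centre = clip$centre)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase). The
#' squared magnitude response gives well over 40 dB attenuation one octave
#' outside the pass-band.
#'
#' @param clip An [audio_clip].
#' @param f_low,f_high Pass-band edges in Hz, `0 < f_low < f_high < rate/2`.
#' @return Filtered [audio_clip].
#' @export
bandpass_filter <- function(clip, f_low = 250, f_high = 750) {
  ny <- clip$rate / 2
  if (f_low <= 0 || f_low >= f_high || f_high >= ny)
    stop("need 0 < f_low < f_high < rate/2")
  bf <- signal::butter(4, c(f_low, f_high) / ny, type = "pass")
  y <- signal::filtfilt(bf, clip$samples)
  audio_clip(y, clip$rate, patient_id = clip$patient_id, site = clip$site,
             centre = clip$centre)
}

#' Mel filterbank restricted to a frequency band
#'
#' Triangular filters with HTK mel spacing (`mel = 2595 log10(1 + f/700)`),
#' endpoints exactly at `f_low` and `f_high`. Rows are non-negative and each
#' has contiguous support inside the band.
#'
#' @param n_mels Number of bands.
#' @param n_fft FFT size (window length).
#' @param rate Sampling rate in Hz.
#' @param f_low,f_high Band edges in Hz.
#' @return Matrix `n_mels x (n_fft/2 + 1)`.
#' @export
mel_filterbank <- function(n_mels = 32L, n_fft = 256L, rate = 4000,
                           f_low = 250, f_high = 750) {
  to_mel <- function(f) 2595 * log10(1 + f / 700)
  from_mel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- from_mel(seq(to_mel(f_low), to_mel(f_high), length.out = n_mels + 2L))
  freqs <- seq(0, rate / 2, length.out = n_fft %/% 2L + 1L)
  fb <- matrix(0, n_mels, length(freqs))
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; ce <- pts[m + 1L]; hi <- pts[m + 2L]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Compute a band-limited log-mel spectrogram
#'
#' Hann-windowed STFT with centred frames (reflect padding), magnitude spectra
#' projected onto the mel filterbank over \[f_low, f_high\], then
#' `log(value + log_floor)`. The frame count is `floor(len / hop) + 1`, so a
#' 5-second clip at 4 kHz yields a 32 x 313 matrix at 62.5 frames/s.
#'
#' @param clip An [audio_clip] (4 kHz in the standard pipeline).
#' @param cfg A [spectrogram_config].
#' @return An object of class `spectrogram`: list with `values`
#'   (`n_mels x T` matrix), `frame_times` (frame centres in seconds),
#'   `frame_rate` (frames/s), `rate` and `cfg`.
#' @export
compute_logmel <- function(clip, cfg = spectrogram_config()) {
  if (cfg$f_high > clip$rate / 2)
    stop("f_high exceeds the Nyquist frequency of the clip")
  x <- clip$samples
  if (isTRUE(cfg$bandpass)) x <- bandpass_filter(clip, cfg$f_low, cfg$f_high)$samples
  wl <- cfg$window_len; hop <- cfg$hop_len
  half <- wl %/% 2L
  xp <- reflect_pad(x, half)
  n_frames <- length(x) %/% hop + 1L
  idx <- outer(seq_len(wl), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(xp[idx], nrow = wl)
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(wl) - 1L) / wl))   # periodic Hann
  spec <- stats::mvfft(frames * win)
  mag <- Mod(spec[seq_len(half + 1L), , drop = FALSE])
  fb <- mel_filterbank(cfg$n_mels, wl, clip$rate, cfg$f_low, cfg$f_high)
  vals <- log(fb %*% mag + cfg$log_floor)
  structure(list(values = vals,
                 frame_times = (seq_len(n_frames) - 1L) * hop / clip$rate,
                 frame_rate = clip$rate / hop, rate = clip$rate, cfg = cfg),
            class = "spectrogram")
}

reflect_pad <- function(x, n) {
  len <- length(x)
  if (len == 1L) return(rep(x, len + 2L * n))
  # mirror without repeating the edge sample, folding if n >= len
  kl <- ((n:1 - 1L) %% (len - 1L)) + 1L
  kr <- ((seq_len(n) - 1L) %% (len - 1L)) + 1L
  c(x[1L + kl], x, x[len - kr])
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d mel bands x %d frames @ %.3g frames/s\n",
              nrow(x$values), ncol(x$values), x$frame_rate))
  invisible(x)
}

#' Fit per-band normalization statistics
#'
#' Each mel band is normalized independently of the others (spectrograms,
#' unlike natural images, are not vertically translation invariant). This is
#' the offline counterpart of the model's input batch-normalization layer:
#' mean and variance per band pooled over all frames of a batch, with an
#' optional learned scale/shift.
#'
#' @param specs A list of [compute_logmel] spectrograms (non-empty).
#' @return An object of class `band_stats` with fields `mean`, `var`,
#'   `scale`, `shift` (one value per band).
#' @export
fit_band_stats <- function(specs) {
  if (!length(specs)) stop("need at least one spectrogram to fit band stats")
  m <- do.call(cbind, lapply(specs, function(s) s$values))
  structure(list(mean = rowMeans(m),
                 var = apply(m, 1L, stats::var) * (ncol(m) - 1) / ncol(m),
                 scale = rep(1, nrow(m)), shift = rep(0, nrow(m))),
            class = "band_stats")
}

#' Apply per-band normalization
#' @param spec A spectrogram.
#' @param stats A `band_stats` object from [fit_band_stats].
#' @param eps Variance clamp for constant bands.
#' @return The normalized spectrogram.
#' @export
apply_band_norm <- function(spec, stats, eps = 1e-5) {
  v <- (spec$values - stats$mean) / sqrt(pmax(stats$var, 0) + eps)
  spec$values <- v * stats$scale + stats$shift
  spec
}

#' SpecAugment time/frequency masking
#'
#' Masks out randomly selected frequency bands and time ranges, the standard
#' augmentation for spectrogram classifiers. Each mask's width is drawn
#' uniformly from 1 to the corresponding maximum; masked cells are set to
#' `fill` (the band-normalized zero by default). Uses R's current RNG stream.
#'
#' @param spec A spectrogram.
#' @param n_freq_masks,n_time_masks Number of masks of each kind.
#' @param max_freq_width,max_time_width Maximum widths (bands / frames).
#' @param fill Value written into masked cells. The default `NULL` fills each
#'   masked cell with its band's mean, the band-normalized zero of the raw
#'   log-mel input.
#' @return The augmented spectrogram.
#' @export
spec_augment <- function(spec, n_freq_masks = 2L, n_time_masks = 2L,
                         max_freq_width = 8L, max_time_width = 32L,
                         fill = NULL) {
  v <- spec$values
  nb <- nrow(v); nt <- ncol(v)
  if (max_freq_width > nb || max_time_width > nt)
    stop("mask width exceeds spectrogram dimension")
  band_fill <- if (is.null(fill)) rowMeans(v) else rep(fill, nb)
  for (i in seq_len(n_freq_masks)) {
    w <- sample.int(max_freq_width, 1L)
    s <- sample.int(nb - w + 1L, 1L)
    v[s:(s + w - 1L), ] <- band_fill[s:(s + w - 1L)]
  }
  for (i in seq_len(n_time_masks)) {
    w <- sample.int(max_time_width, 1L)
    s <- sample.int(nt - w + 1L, 1L)
    v[, s:(s + w - 1L)] <- band_fill
  }
  spec$values <- v
  spec
}
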