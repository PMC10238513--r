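#' Canonical thoracic auscultation sites
#'
#' The eight standard recording positions, one per quadrant of the anterior
#' and posterior thorax. All site-indexed structures in the package
#' (site vectors, file suffixes `_s1` .. `_s8`) follow this fixed ordering.
#'
#' @format Character vector of length 8.
#' @export
ausc_sites <- c(
  "anterior_right_superior", "anterior_left_superior",
  "anterior_right_inferior", "anterior_left_inferior",
  "posterior_right_superior", "posterior_left_superior",
  "posterior_right_inferior", "posterior_left_inferior"
)

#' Diagnostic classes
#'
#' The four patient-level diagnostic categories, in the fixed order used by
#' confusion matrices and the multinomial fusion.
#'
#' @format Character vector of length 4.
#' @export
ausc_diagnoses <- c("control", "pneumonia", "wheezing_disorder", "bronchiolitis")

#' Construct an audio clip
#'
#' A mono waveform with its sampling rate and the linkage metadata used by the
#' patient-level pipeline. Amplitudes are dimensionless with nominal range
#' \[-1, 1\].
#'
#' @param samples Numeric vector of amplitudes (non-empty).
#' @param rate Sampling rate in Hz (> 0).
#' @param patient_id,site,centre Optional linkage metadata; `site` must be one
#'   of [ausc_sites] when given.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, rate, patient_id = NA_character_,
                       site = NA_character_, centre = NA_character_) {
  if (length(samples) == 0L) stop("audio clip must contain at least one sample")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("sampling rate must be a single positive number")
  if (!is.na(site) && !site %in% ausc_sites)
    stop("unknown site '", site, "'; see ausc_sites")
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         patient_id = patient_id, site = site, centre = centre),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d samples @ %g Hz (%.2f s)", length(x$samples),
              x$rate, length(x$samples) / x$rate))
  if (!is.na(x$site)) cat(" site=", x$site, sep = "")
  cat("\n")
  invisible(x)
}

#' Duration of a clip in seconds
#' @param clip An `audio_clip`.
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$rate

#' Construct a respiration-phase annotation
#'
#' Timestamped inspiration/expiration segments for one recording. Segments are
#' sorted by start time; intervals within one phase class must not overlap.
#'
#' @param start,end Numeric vectors of segment boundaries in seconds
#'   (`0 <= start < end`).
#' @param phase Character vector, each `"inspiration"` or `"expiration"`.
#' @return A `phase_annotation`: a data frame with columns start, end, phase.
#' @export
phase_annotation <- function(start = numeric(), end = numeric(),
                             phase = character()) {
  if (length(start) != length(end) || length(start) != length(phase))
    stop("start, end and phase must have equal length")
  phase <- as.character(phase)
  bad <- setdiff(unique(phase), c("inspiration", "expiration"))
  if (length(bad)) stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  if (any(start < 0)) stop("segment start times must be >= 0")
  if (any(end <= start)) stop("every segment must satisfy start < end")
  o <- order(start)
  df <- data.frame(start = as.numeric(start)[o], end = as.numeric(end)[o],
                   phase = phase[o], stringsAsFactors = FALSE)
  for (ph in c("inspiration", "expiration")) {
    sub <- df[df$phase == ph, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)] - 1e-9))
      stop("overlapping ", ph, " segments in annotation")
  }
  class(df) <- c("phase_annotation", "data.frame")
  df
}

#' Construct a patient record
#'
#' One patient's diagnosis, covariates and up to eight site-linked recordings,
#' with optional respiration-phase annotations per site.
#'
#' @param patient_id Identifier.
#' @param diagnosis One of [ausc_diagnoses].
#' @param centre Recording centre identifier.
#' @param age Age in years.
#' @param respiratory_rate Breaths per minute, or `NA` if not recorded.
#' @param clips Named list of [audio_clip]s; names drawn from [ausc_sites],
#'   at most one clip per site.
#' @param annotations Named list of [phase_annotation]s (subset of the clip
#'   sites), or `NULL`.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, diagnosis, centre, age,
                           respiratory_rate = NA_real_, clips = list(),
                           annotations = NULL) {
  if (!diagnosis %in% ausc_diagnoses)
    stop("diagnosis must be one of: ", paste(ausc_diagnoses, collapse = ", "))
  if (length(clips)) {
    if (is.null(names(clips)) || !all(names(clips) %in% ausc_sites))
      stop("clips must be named by canonical site")
    if (anyDuplicated(names(clips))) stop("at most one clip per site")
  }
  structure(
    list(patient_id = patient_id, diagnosis = diagnosis, centre = centre,
         age = age, respiratory_rate = respiratory_rate,
         clips = clips, annotations = annotations),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s: %s (centre %s, age %.1f y), %d clip(s)\n",
              x$patient_id, x$diagnosis, x$centre, x$age, length(x$clips)))
  invisible(x)
}

## ---- WAV I/O ---------------------------------------------------------------
## Minimal RIFF/WAVE reader and writer. Supports integer PCM (8/16/24/32 bit)
## and IEEE float-32; multi-channel audio is averaged to mono on read.

read_wav_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF container: ", path)
  readBin(con, "integer", 1, 4, endian = "little")   # chunk size, unused
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      u16 <- function(i) as.integer(body[i]) + 256L * as.integer(body[i + 1L])
      u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
      fmt <- list(format = u16(1L), channels = u16(3L), rate = u32(5L),
                  bits = u16(15L))
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", size)
    } else {
      seek(con, size + size %% 2L, origin = "current")
      next
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L)
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("missing fmt/data chunk: ", path)
  list(fmt = fmt, data = dat)
}

#' Read a WAV file
#'
#' Reads a RIFF/WAVE container into an [audio_clip]. Integer PCM is scaled to
#' \[-1, 1\]; multi-channel audio is averaged to mono. The acquisition contract
#' of the pipeline is 4 kHz mono: audio at any other rate is resampled on load
#' with a warning (see `enforce_rate`).
#'
#' @param path Path to a `.wav` file.
#' @param enforce_rate Target rate in Hz, or `NULL` to keep the file's rate.
#'   Defaults to `NULL`.
#' @param patient_id,site,centre Optional linkage metadata.
#' @return An [audio_clip].
#' @export
read_wav <- function(path, enforce_rate = NULL, patient_id = NA_character_,
                     site = NA_character_, centre = NA_character_) {
  w <- read_wav_raw(path)
  fmt <- w$fmt
  bytes <- fmt$bits %/% 8L
  n <- length(w$data) %/% (bytes * fmt$channels)
  if (n == 0L) stop("zero-length audio: ", path)
  if (fmt$format == 1L) {           # integer PCM
    if (fmt$bits == 8L) {
      x <- (as.integer(w$data) - 128) / 128
    } else if (fmt$bits == 16L) {
      x <- readBin(w$data, "integer", n * fmt$channels, 2L, signed = TRUE,
                   endian = "little") / 32768
    } else if (fmt$bits == 24L) {
      b <- matrix(as.integer(w$data), nrow = 3L)
      v <- b[1L, ] + 256L * b[2L, ] + 65536 * b[3L, ]
      x <- ifelse(v >= 8388608, v - 16777216, v) / 8388608
    } else if (fmt$bits == 32L) {
      x <- readBin(w$data, "integer", n * fmt$channels, 4L,
                   endian = "little") / 2147483648
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else if (fmt$format == 3L && fmt$bits == 32L) {   # IEEE float
    x <- readBin(w$data, "double", n * fmt$channels, 4L, endian = "little")
  } else stop("unsupported WAVE format code: ", fmt$format)
  if (fmt$channels > 1L)
    x <- colMeans(matrix(x, nrow = fmt$channels))
  clip <- audio_clip(x, fmt$rate, patient_id = patient_id, site = site,
                     centre = centre)
  if (!is.null(enforce_rate) && fmt$rate != enforce_rate) {
    warning(sprintf("resampling %s from %d Hz to %d Hz on load",
                    basename(path), fmt$rate, as.integer(enforce_rate)))
    clip <- resample_clip(clip, enforce_rate)
  }
  clip
}

#' Write a clip as 16-bit PCM WAV
#'
#' Samples are clamped to \[-1, 1\] and quantized to 16-bit PCM, so
#' `write_wav(read_wav(f))` is bit-identical for 16-bit input.
#'
#' @param clip An [audio_clip].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  x <- pmin(pmax(clip$samples, -1), 32767 / 32768)
  pcm <- as.integer(round(x * 32768))
  nbytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  wch <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  w32 <- function(v) writeBin(as.integer(v), con, 4L, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, 2L, endian = "little")
  wch("RIFF"); w32(36L + nbytes); wch("WAVE")
  wch("fmt "); w32(16L); w16(1L); w16(1L)
  w32(as.integer(clip$rate)); w32(as.integer(clip$rate) * 2L)
  w16(2L); w16(16L)
  wch("data"); w32(nbytes)
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}

#' Resample a clip by band-limited interpolation
#'
#' Polyphase FIR resampling (via \pkg{signal}); the output duration matches the
#' input duration to within one sample period.
#'
#' @param clip An [audio_clip].
#' @param target_rate Target sampling rate in Hz (> 0).
#' @return An [audio_clip] at `target_rate`.
#' @export
resample_clip <- function(clip, target_rate) {
  if (target_rate <= 0) stop("target_rate must be positive")
  if (target_rate == clip$rate) return(clip)
  g <- gcd_int(round(target_rate), round(clip$rate))
  p <- round(target_rate) / g
  q <- round(clip$rate) / g
  y <- signal::resample(clip$samples, p, q)
  n_out <- round(length(clip$samples) * target_rate / clip$rate)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, numeric(n_out - length(y)))
  audio_clip(y, target_rate, patient_id = clip$patient_id, site = clip$site,
             centre = clip$centre)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Read a respiration-phase annotation table
#'
#' Expects a UTF-8 CSV with header `start,end,phase` (seconds as decimal
#' floats, phase `inspiration` or `expiration`). Rows are returned sorted by
#' start time. An empty table is a valid (empty) annotation.
#'
#' @param path Path to the CSV file.
#' @return A [phase_annotation].
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "phase")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns start, end, phase: ", path)
  phase_annotation(df$start, df$end, df$phase)
}

#' Write a respiration-phase annotation table
#' @param ann A [phase_annotation].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(as.data.frame(ann)[, c("start", "end", "phase")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- Cohort layout ---------------------------------------------------------
## dir/metadata.csv                          patient_id,diagnosis,centre,age,respiratory_rate
## dir/audio/<patient_id>_s<k>.wav           k = 1..8 in canonical site order
## dir/annotations/<patient_id>_s<k>.csv     optional phase tables

#' Write a cohort to the on-disk layout
#'
#' Writes `metadata.csv`, one WAV per recording under `audio/` (site encoded as
#' the `_s1` .. `_s8` filename suffix in canonical order) and one phase CSV per
#' annotated recording under `annotations/`.
#'
#' @param patients List of [patient_record]s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(patients, dir) {
  dir.create(file.path(dir, "audio"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), showWarnings = FALSE)
  meta <- do.call(rbind, lapply(patients, function(p) {
    data.frame(patient_id = p$patient_id, diagnosis = p$diagnosis,
               centre = p$centre, age = p$age,
               respiratory_rate = p$respiratory_rate,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE,
                   quote = FALSE)
  for (p in patients) {
    for (site in names(p$clips)) {
      k <- match(site, ausc_sites)
      write_wav(p$clips[[site]],
                file.path(dir, "audio", sprintf("%s_s%d.wav", p$patient_id, k)))
      ann <- p$annotations[[site]]
      if (!is.null(ann))
        write_annotations(ann, file.path(dir, "annotations",
                                         sprintf("%s_s%d.csv", p$patient_id, k)))
    }
  }
  invisible(dir)
}

#' Load a cohort from the on-disk layout
#'
#' Inverse of [write_cohort]. Audio is loaded with the 4 kHz contract enforced
#' (other rates resampled with a warning).
#'
#' @param dir Cohort directory.
#' @param rate Target sampling rate (default 4000 Hz).
#' @return List of [patient_record]s, in metadata order.
#' @export
load_cohort <- function(dir, rate = 4000) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    clips <- list(); anns <- list()
    for (k in seq_along(ausc_sites)) {
      f <- file.path(dir, "audio", sprintf("%s_s%d.wav", m$patient_id, k))
      if (file.exists(f)) {
        clips[[ausc_sites[k]]] <- read_wav(
          f, enforce_rate = rate, patient_id = m$patient_id,
          site = ausc_sites[k], centre = m$centre)
        a <- file.path(dir, "annotations", sprintf("%s_s%d.csv", m$patient_id, k))
        if (file.exists(a)) anns[[ausc_sites[k]]] <- read_annotations(a)
      }
    }
    patient_record(m$patient_id, m$diagnosis, m$centre, m$age,
                   respiratory_rate = m$respiratory_rate, clips = clips,
                   annotations = if (length(anns)) anns else NULL)
  })
}
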