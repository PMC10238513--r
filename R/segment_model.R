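#' Segment-model configuration
#'
#' Architecture of the convolutional audio classifier. The standard model has
#' 5 convolutional blocks (two 3x3 convolutions each, batch norm + ReLU),
#' 2x2 average pooling and dropout after the first 4 blocks, channel
#' progression 64-128-256-512-1024, frequency reduction by average pooling,
#' time smoothing (max + average pooling of size 3, stride 1, summed) and a
#' 1024-wide fully connected layer feeding the per-segment sigmoid prediction
#' head and tanh attention head.
#'
#' `rf_frames` is the receptive-field width (in STFT frames) used to map
#' segments to time spans. For the standard 5-block architecture it defaults
#' to the published value of 78 frames (1296 ms at the 4 kHz front end); the
#' analytically traced width of the implemented network is wider (see
#' [analytic_receptive_field] and [measure_receptive_field]) and can be
#' requested by passing `rf_frames = NA`.
#'
#' @param n_blocks Number of convolutional blocks.
#' @param channels Output channels per block (length `n_blocks`).
#' @param dropout Dropout rate after every downsampling and fully connected
#'   stage.
#' @param n_mels Input mel bands.
#' @param fc_width Width of the fully connected layer (defaults to the last
#'   block's channel count).
#' @param rf_frames Receptive-field width in frames for time mapping; `NULL`
#'   picks 78 for the standard architecture and the analytic width otherwise;
#'   `NA` forces the analytic width.
#' @param init_seed Seed for weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_blocks = 5L, channels = c(64L, 128L, 256L, 512L, 1024L),
                         dropout = 0.2, n_mels = 32L, fc_width = NULL,
                         rf_frames = NULL, init_seed = 1L) {
  if (length(channels) != n_blocks) stop("channels must have length n_blocks")
  if (is.null(fc_width)) fc_width <- channels[n_blocks]
  standard <- n_blocks == 5L
  analytic <- analytic_receptive_field(n_blocks)
  if (is.null(rf_frames)) rf_frames <- if (standard) 78L else analytic
  if (is.na(rf_frames)) rf_frames <- analytic
  structure(list(n_blocks = as.integer(n_blocks),
                 channels = as.integer(channels), dropout = dropout,
                 n_mels = as.integer(n_mels), fc_width = as.integer(fc_width),
                 stride_frames = 2L^(as.integer(n_blocks) - 1L),
                 rf_frames = as.integer(rf_frames),
                 init_seed = as.integer(init_seed)),
            class = "model_config")
}

#' Analytic receptive field of the convolutional stack
#'
#' Width in input frames reached by tracing the 3x3 convolutions, the
#' `n_blocks - 1` poolings and the size-3 time smoothing of the architecture.
#'
#' @param n_blocks Number of convolutional blocks.
#' @return Width in STFT frames.
#' @export
analytic_receptive_field <- function(n_blocks = 5L) {
  rf <- 1L; jump <- 1L
  for (i in seq_len(n_blocks)) {
    rf <- rf + 4L * jump          # two 3x3 convolutions
    if (i < n_blocks) {
      rf <- rf + jump             # 2x2 pooling kernel
      jump <- jump * 2L
    }
  }
  rf + 2L * jump                  # time smoothing, size 3 stride 1
}

#' Build a segment model
#'
#' Initializes weights (uniform Kaiming-style bounds) and batch-norm running
#' statistics for the given configuration.
#'
#' @param cfg A [model_config].
#' @return An object of class `segment_model`.
#' @export
build_model <- function(cfg = model_config()) {
  ini <- init_params(cfg)
  structure(list(cfg = cfg, params = ini$params, run = ini$run),
            class = "segment_model")
}

#' @export
print.segment_model <- function(x, ...) {
  cat(sprintf("<segment_model> %d blocks, channels %s, fc %d\n",
              x$cfg$n_blocks, paste(x$cfg$channels, collapse = "-"),
              x$cfg$fc_width))
  invisible(x)
}

#' Segment geometry of a spectrogram under a model
#'
#' Maps segment indices to time: segments stride `2^(n_blocks-1)` frames; each
#' covers one receptive field. With the standard front end (hop 64, window 256
#' at 4 kHz) and the 78-frame receptive field, a segment spans 1296 ms and
#' consecutive segments start 256 ms apart.
#'
#' @param n_frames Frame count of the input spectrogram.
#' @param model_cfg A [model_config].
#' @param spec_cfg A [spectrogram_config].
#' @param rate Sampling rate in Hz.
#' @return A list with `n_segments`, `rf_frames`, `stride_frames`,
#'   `span_sec` (receptive-field duration), `stride_sec` and `duration`.
#' @export
segment_geometry <- function(n_frames, model_cfg, spec_cfg = spectrogram_config(),
                             rate = 4000) {
  stride <- model_cfg$stride_frames
  span <- ((model_cfg$rf_frames - 1L) * spec_cfg$hop_len + spec_cfg$window_len) / rate
  list(n_segments = as.integer(ceiling(n_frames / stride)),
       rf_frames = model_cfg$rf_frames, stride_frames = stride,
       span_sec = span, stride_sec = stride * spec_cfg$hop_len / rate,
       duration = (n_frames - 1L) * spec_cfg$hop_len / rate)
}

#' Time span of one segment
#'
#' Spans have equal width (the receptive-field duration), are centred on the
#' segment's pooled position, stride by `stride_sec`, and are clipped to the
#' clip bounds.
#'
#' @param i Segment index (1-based, `1 <= i <= n_segments`).
#' @param geometry From [segment_geometry].
#' @return Numeric `c(start, end)` in seconds.
#' @export
segment_time_span <- function(i, geometry) {
  if (any(i < 1L) || any(i > geometry$n_segments))
    stop("segment index out of range")
  centre <- (i - 0.5) * geometry$stride_sec
  start <- pmax(0, centre - geometry$span_sec / 2)
  end <- pmin(geometry$duration, centre + geometry$span_sec / 2)
  cbind(start = start, end = end)
}

#' Extract the feature sequence of a spectrogram
#'
#' Runs the convolutional stack in inference mode and returns the sequence of
#' fully connected feature vectors \eqn{x_1, \dots, x_T} together with the
#' segment geometry. `T = ceiling(n_frames / 2^(n_blocks-1))`.
#'
#' @param spec A spectrogram from [compute_logmel].
#' @param model A [build_model] object.
#' @return List with `features` (`fc_width x T` matrix) and `geometry`.
#' @export
forward_features <- function(spec, model) {
  x3 <- array(spec$values, dim = c(dim(spec$values), 1L))
  out <- nn_forward(model, x3, training = FALSE, keep_cache = FALSE)
  geom <- segment_geometry(ncol(spec$values), model$cfg, spec$cfg, spec$rate)
  list(features = matrix(out$features, nrow = model$cfg$fc_width),
       geometry = geom)
}

#' Attention pooling over a feature sequence
#'
#' Applies the two per-segment heads and Eqs. (1)-(2): segment predictions
#' \eqn{p(x_i)} from the sigmoid head, attention logits \eqn{v(x_i)} from the
#' tanh head, attention values \eqn{g(x_i) = \exp v(x_i) / \sum_j \exp v(x_j)},
#' and the clip-level prediction \eqn{p(x) = \sum_i g(x_i) p(x_i)}, a convex
#' combination of the segment predictions.
#'
#' @param features `fc_width x T` feature matrix.
#' @param model A [build_model] object.
#' @return List with `p`, `v`, `g` (length `T`) and `clip_p` (scalar).
#' @export
attention_pool <- function(features, model) {
  pr <- model$params
  zp <- drop(crossprod(pr[["att_p.w"]], features)) + pr[["att_p.b"]]
  zv <- drop(crossprod(pr[["att_v.w"]], features)) + pr[["att_v.b"]]
  p <- 1 / (1 + exp(-zp))
  v <- tanh(zv)
  ev <- exp(v - max(v))
  g <- ev / sum(ev)
  list(p = p, v = v, g = g, clip_p = sum(g * p))
}

#' Score a full recording
#'
#' Inference runs on the entire recording, whatever its duration (no 5-second
#' crop); recordings shorter than one segment stride are zero-padded to the
#' model minimum. Returns segment-level predictions and attention with their
#' time spans, plus the clip-level prediction.
#'
#' @param clip An [audio_clip].
#' @param model A [build_model] object.
#' @param spec_cfg A [spectrogram_config].
#' @return An object of class `segment_outputs`: list with `p`, `v`, `g`,
#'   `clip_p`, `spans` (`T x 2` matrix) and `geometry`.
#' @export
predict_clip <- function(clip, model, spec_cfg = spectrogram_config()) {
  if (length(clip$samples) == 0L) stop("empty clip")
  min_samples <- model$cfg$stride_frames * spec_cfg$hop_len
  if (length(clip$samples) < min_samples)
    clip$samples <- c(clip$samples,
                      numeric(min_samples - length(clip$samples)))
  spec <- compute_logmel(clip, spec_cfg)
  x3 <- array(spec$values, dim = c(dim(spec$values), 1L))
  out <- nn_forward(model, x3, training = FALSE, keep_cache = FALSE)
  geom <- segment_geometry(ncol(spec$values), model$cfg, spec_cfg, clip$rate)
  structure(list(p = drop(out$p), v = drop(out$v), g = drop(out$g),
                 clip_p = unname(out$clip_p),
                 spans = segment_time_span(seq_len(geom$n_segments), geom),
                 geometry = geom),
            class = "segment_outputs")
}

#' Measure the empirical receptive field
#'
#' Backpropagates one interior segment's prediction to the input spectrogram
#' (inference-mode batch norm, no dropout) and reports the number of input
#' frames with non-zero gradient. This is the effective temporal footprint of
#' one segment in the implemented network.
#'
#' @param model A [build_model] object.
#' @param n_frames Input frame count used for the probe.
#' @param tol Gradient magnitude below which a frame counts as untouched.
#' @return Width in frames (integer).
#' @export
measure_receptive_field <- function(model, n_frames = 313L, tol = 1e-12) {
  set.seed(42L)
  x3 <- array(stats::rnorm(model$cfg$n_mels * n_frames), dim = c(model$cfg$n_mels, n_frames, 1L))
  out <- nn_forward(model, x3, training = FALSE, keep_cache = TRUE)
  Tseg <- nrow(out$p)
  i <- (Tseg + 1L) %/% 2L
  dp <- matrix(0, Tseg, 1L); dp[i, 1L] <- 1
  gr <- nn_backward(model, out, dp = dp, want_dx = TRUE)
  frame_mag <- colSums(matrix(abs(gr$dx), nrow = model$cfg$n_mels))
  sum(frame_mag > tol)
}
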