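test_that("segment counts follow the pooling arithmetic", {
  set.seed(10)
  m <- tiny_model5()
  sp5 <- compute_logmel(audio_clip(rnorm(20000), 4000))
  ff <- forward_features(sp5, m)
  # ceil(ceil(ceil(ceil(313/2)/2)/2)/2) = 20
  expect_identical(ncol(ff$features), 20L)
  expect_identical(nrow(ff$features), m$cfg$fc_width)

  sp16 <- compute_logmel(audio_clip(rnorm(15 * 64), 4000))  # 16 frames
  expect_identical(ncol(forward_features(sp16, m)$features), 1L)

  sp10 <- compute_logmel(audio_clip(rnorm(40000), 4000))    # 10 s
  t5 <- ncol(ff$features); t10 <- ncol(forward_features(sp10, m)$features)
  expect_lte(abs(t10 - 2 * t5), 2)                          # within rounding
})

test_that("attention pooling reproduces the softmax-weighted equations", {
  m <- tiny_model2()
  # worked example: v = (ln 2, 0), p = (0.9, 0.3)
  m$params[["att_p.w"]] <- c(stats::qlogis(0.9), stats::qlogis(0.3),
                             numeric(m$cfg$fc_width - 2L))
  m$params[["att_p.b"]] <- 0
  m$params[["att_v.w"]] <- c(atanh(log(2)), 0, numeric(m$cfg$fc_width - 2L))
  m$params[["att_v.b"]] <- 0
  feats <- diag(m$cfg$fc_width)[, 1:2]
  out <- attention_pool(feats, m)
  # independent oracle: direct evaluation of the two equations
  v <- c(log(2), 0); p <- c(0.9, 0.3)
  g_oracle <- exp(v) / sum(exp(v))
  expect_equal(out$p, p, tolerance = 1e-12)
  expect_equal(out$g, g_oracle, tolerance = 1e-12)
  expect_equal(out$g, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(out$clip_p, sum(g_oracle * p), tolerance = 1e-12)
  expect_equal(out$clip_p, 0.7, tolerance = 1e-12)
})

test_that("attention values are a proper convex weighting", {
  m <- tiny_model2()
  set.seed(11)
  for (Tseg in c(1L, 2L, 7L, 40L)) {
    feats <- matrix(rnorm(m$cfg$fc_width * Tseg), m$cfg$fc_width, Tseg)
    out <- attention_pool(feats, m)
    expect_equal(sum(out$g), 1, tolerance = 1e-6)
    expect_true(all(out$p >= 0 & out$p <= 1))
    expect_gte(out$clip_p, min(out$p))
    expect_lte(out$clip_p, max(out$p))
    if (Tseg == 1L) {
      expect_equal(out$g, 1, tolerance = 1e-12)
      expect_equal(out$clip_p, out$p, tolerance = 1e-12)
    }
  }
  # equal attention logits average the segment predictions
  feats <- matrix(rep(rnorm(m$cfg$fc_width), 5), ncol = 5)
  out <- attention_pool(feats, m)
  expect_equal(out$g, rep(0.2, 5), tolerance = 1e-12)
  expect_equal(out$clip_p, mean(out$p), tolerance = 1e-12)
})

test_that("permuting segments permutes outputs and preserves the clip score", {
  m <- tiny_model2()
  set.seed(12)
  feats <- matrix(rnorm(m$cfg$fc_width * 9), m$cfg$fc_width, 9)
  perm <- sample(9)
  a <- attention_pool(feats, m)
  b <- attention_pool(feats[, perm], m)
  expect_equal(b$p, a$p[perm], tolerance = 1e-12)
  expect_equal(b$g, a$g[perm], tolerance = 1e-12)
  expect_equal(b$clip_p, a$clip_p, tolerance = 1e-12)
})

test_that("full-length inference is deterministic and scales with duration", {
  m <- tiny_model5()
  set.seed(13)
  clip30 <- audio_clip(rnorm(120000, sd = 0.2), 4000)
  clip5 <- audio_clip(clip30$samples[1:20000], 4000)
  o30 <- predict_clip(clip30, m)
  o5 <- predict_clip(clip5, m)
  expect_true(o30$clip_p >= 0 && o30$clip_p <= 1)
  expect_lte(abs(length(o30$g) - 6 * length(o5$g)), 6)
  expect_identical(predict_clip(clip30, m)$g, o30$g)   # eval determinism
  expect_equal(sum(o30$g), 1, tolerance = 1e-6)
  expect_error(predict_clip(audio_clip(1, 4000)[-1], m))
})

test_that("segment geometry maps indices to the published time spans", {
  geom <- segment_geometry(1876L, model_config(), spectrogram_config(), 4000)
  expect_equal(geom$span_sec, 1.296)        # (78 - 1) * 64 + 256 samples
  expect_equal(geom$stride_sec, 0.256)      # 16 frames x 16 ms
  spans <- segment_time_span(seq_len(geom$n_segments), geom)
  expect_equal(unname(spans[1, "start"]), 0)  # clamped at the clip start
  inner <- 4:(geom$n_segments - 4)            # receptive field fully inside
  expect_equal(diff(spans[inner, "start"]), rep(0.256, length(inner) - 1),
               tolerance = 1e-12)
  expect_equal(unique(round(spans[inner, "end"] - spans[inner, "start"], 9)),
               1.296)
  expect_error(segment_time_span(0, geom), "out of range")
  expect_error(segment_time_span(geom$n_segments + 1L, geom), "out of range")
})

test_that("the empirical receptive field matches the architectural trace", {
  m <- tiny_model2()
  expect_identical(measure_receptive_field(m, n_frames = 120L),
                   analytic_receptive_field(2L))
  # the standard 5-block architecture is wider than the 78-frame mapping value
  expect_gt(analytic_receptive_field(5L), 78L)
})

test_that("network gradients agree with finite differences", {
  cfg <- model_config(n_blocks = 2L, channels = c(3L, 4L), dropout = 0,
                      n_mels = 6L, init_seed = 3L)
  model <- build_model(cfg)
  set.seed(14)
  x3 <- array(rnorm(6 * 20 * 2), c(6, 20, 2))
  y <- c(1, 0)
  lossf <- function(mo) {
    out <- auscultnet:::nn_forward(mo, x3, training = TRUE, keep_cache = FALSE)
    bce_loss(out$clip_p, y)
  }
  out <- auscultnet:::nn_forward(model, x3, training = TRUE)
  pc <- pmin(pmax(out$clip_p, 1e-7), 1 - 1e-7)
  dclip <- (pc - y) / (pc * (1 - pc)) / length(y)
  gr <- auscultnet:::nn_backward(model, out, dclip = dclip)
  eps <- 1e-6
  for (k in names(model$params)) {
    p <- model$params[[k]]
    for (i in sample(length(p), min(length(p), 3L))) {
      m2 <- model
      m2$params[[k]][i] <- p[i] + eps; l1 <- lossf(m2)
      m2$params[[k]][i] <- p[i] - eps; l0 <- lossf(m2)
      num <- (l1 - l0) / (2 * eps)
      expect_equal(gr[[k]][i], num, tolerance = 1e-4,
                   label = sprintf("analytic grad of %s[%d]", k, i))
    }
  }
})

test_that("batch normalization running statistics drive inference mode", {
  m <- tiny_model2()
  set.seed(15)
  x3 <- array(rnorm(16 * 40 * 4, mean = 2), c(16, 40, 4))
  out <- auscultnet:::nn_forward(m, x3, training = TRUE)
  expect_false(identical(out$run[["bn0.mean"]], m$run[["bn0.mean"]]))
  m$run <- out$run
  e1 <- auscultnet:::nn_forward(m, x3, training = FALSE)
  e2 <- auscultnet:::nn_forward(m, x3, training = FALSE)
  expect_identical(e1$clip_p, e2$clip_p)   # no stochastic path in eval
})
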