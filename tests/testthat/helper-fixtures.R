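# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A sine-wave clip.
sine_clip <- function(freq, duration = 1, rate = 4000, amp = 0.5) {
  audio_clip(amp * sin(2 * pi * freq * seq_len(duration * rate) / rate), rate)
}

# Tiny model for fast structural tests (full 5-block geometry, few channels).
tiny_model5 <- function() fixture("tiny_model5", function() {
  build_model(model_config(n_blocks = 5L, channels = c(2L, 2L, 4L, 4L, 8L),
                           n_mels = 32L, dropout = 0, init_seed = 11L))
})

# Very small 2-block model used where only the head/geometry matters.
tiny_model2 <- function() fixture("tiny_model2", function() {
  build_model(model_config(n_blocks = 2L, channels = c(3L, 4L), n_mels = 16L,
                           dropout = 0, init_seed = 12L))
})

# Desk-scale synthetic cohort: 16 patients (2 per diagnosis x centre), short
# clips, used by the I/O, sweep and interpretation tests. Patient ids run
# class-major: pt001-4 control, pt005-8 pneumonia, pt009-12 wheezing
# disorder, pt013-16 bronchiolitis.
tiny_cohort <- function() fixture("tiny_cohort", function() {
  simulate_cohort(simulation_config(n_per_cell = 2L, clip_duration = 8,
                                    rr_missing_prob = 0, seed = 77L))
})

# Moderate cohort for generator statistics (wheeze/control contrast,
# separability): 6 wheeze + 6 control patients, 15-second clips.
contrast_cohort <- function() fixture("contrast_cohort", function() {
  cfg <- simulation_config(n_per_cell = 3L, clip_duration = 15,
                           rr_missing_prob = 0, seed = 101L)
  simulate_cohort(cfg)
})

# Reference study conditions for the parameter-recovery runs: 120 patients,
# 2 centres, 30-second clips, seed 1234 (the simulator defaults).
acceptance_cohort <- function() fixture("acceptance_cohort", function() {
  simulate_cohort(simulation_config())
})

# Time-domain band-power oracle: zero-phase band-pass the clip once, then
# compare mean squared amplitude across the annotated phases.
phase_band_contrast_db <- function(clip, ann, band = c(350, 650)) {
  y <- bandpass_filter(clip, band[1], band[2])$samples
  pow <- function(phase) {
    iv <- ann[ann$phase == phase, , drop = FALSE]
    mean(unlist(lapply(seq_len(nrow(iv)), function(i) {
      y[(floor(iv$start[i] * clip$rate) + 1L):
          min(length(y), floor(iv$end[i] * clip$rate))]
    }))^2)
  }
  10 * log10(pow("expiration") / pow("inspiration"))
}

# Mean phase contrast over all sites of one patient.
patient_contrast_db <- function(p, band = c(350, 650)) {
  mean(vapply(ausc_sites, function(s) {
    phase_band_contrast_db(p$clips[[s]], p$annotations[[s]], band)
  }, numeric(1)))
}

# Hand-made segment outputs for interpretation tests.
fake_outputs <- function(g, spans, p = rep(0.5, length(g))) {
  structure(list(p = p, v = rep(0, length(g)), g = g, clip_p = sum(g * p),
                 spans = spans,
                 geometry = list(duration = max(spans), stride_sec = 0.256,
                                 span_sec = spans[1, 2] - spans[1, 1],
                                 n_segments = nrow(spans))),
            class = "segment_outputs")
}

regular_spans <- function(n, width = 1.296, stride = 0.256, duration = NULL) {
  centre <- (seq_len(n) - 0.5) * stride
  if (is.null(duration)) duration <- max(centre + width / 2)
  cbind(start = pmax(0, centre - width / 2),
        end = pmin(duration, centre + width / 2))
}
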