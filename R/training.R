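#' Training configuration
#'
#' Defaults follow the standard recipe: batch size 64, AdamW with weight decay
#' 0.005, a 1cycle learning-rate policy peaking at 0.001, 100 epochs with
#' tune-fold model selection (by mean positional AUROC) from epoch 60 onward,
#' and 5-second random crops for fixed-size training inputs.
#'
#' @param batch_size Recordings per batch.
#' @param epochs Training epochs.
#' @param selection_start Epoch from which the tune fold is evaluated every
#'   epoch and the best checkpoint kept (`< epochs`).
#' @param max_lr Peak learning rate of the 1cycle schedule.
#' @param weight_decay AdamW decoupled weight decay.
#' @param crop_duration Training crop length in seconds.
#' @param augment Apply SpecAugment to training crops.
#' @param seed Seed for sampling, cropping, augmentation, dropout and weight
#'   initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, epochs = 100L, selection_start = 60L,
                         max_lr = 1e-3, weight_decay = 5e-3, crop_duration = 5,
                         augment = TRUE, seed = 1L) {
  if (selection_start >= epochs) stop("selection_start must be < epochs")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 selection_start = as.integer(selection_start),
                 max_lr = max_lr, weight_decay = weight_decay,
                 crop_duration = crop_duration, augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Flatten a cohort into a recording table
#'
#' @param patients List of [patient_record]s.
#' @return List with `clips` (list of [audio_clip]) and `meta` (data frame
#'   with patient_id, site, centre, diagnosis, one row per recording).
#' @export
cohort_recordings <- function(patients) {
  clips <- list(); rows <- list()
  for (p in patients) {
    for (site in names(p$clips)) {
      clips[[length(clips) + 1L]] <- p$clips[[site]]
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, site = site, centre = p$centre,
        diagnosis = p$diagnosis, stringsAsFactors = FALSE)
    }
  }
  list(clips = clips, meta = do.call(rbind, rows))
}

#' Balanced sampling plan over diagnosis strata and centres
#'
#' For a one-vs-rest target class, sampling (with replacement) is arranged so
#' that positives and negatives are equiprobable, the negative mass is split
#' equally across the (non-empty) other classes, and within each class the
#' non-empty recording centres are equiprobable. This counters both class
#' imbalance and the hazard of the model learning centre-specific background
#' noise.
#'
#' @param meta Recording table (from [cohort_recordings]).
#' @param target_class Positive class, one of [ausc_diagnoses].
#' @return An object of class `sampling_plan` with per-cell recording indices
#'   and draw probabilities.
#' @export
sampling_plan <- function(meta, target_class) {
  if (!target_class %in% meta$diagnosis)
    stop("configuration error: target class '", target_class,
         "' absent from the dataset")
  cells <- list(); probs <- numeric()
  neg_classes <- intersect(ausc_diagnoses, unique(meta$diagnosis))
  neg_classes <- setdiff(neg_classes, target_class)
  class_prob <- c(stats::setNames(0.5, target_class),
                  stats::setNames(rep(0.5 / length(neg_classes),
                                      length(neg_classes)), neg_classes))
  for (cl in names(class_prob)) {
    centres <- unique(meta$centre[meta$diagnosis == cl])
    for (ce in centres) {
      idx <- which(meta$diagnosis == cl & meta$centre == ce)
      cells[[paste(cl, ce, sep = "|")]] <- idx
      probs[paste(cl, ce, sep = "|")] <- class_prob[cl] / length(centres)
    }
  }
  structure(list(cells = cells, probs = probs, n = nrow(meta),
                 target_class = target_class),
            class = "sampling_plan")
}

#' Draw one epoch of balanced recording indices
#'
#' One epoch draws exactly `n` recordings (by default the total number of
#' recordings in the plan), sampled with replacement according to the plan's
#' cell probabilities. Uses R's current RNG stream.
#'
#' @param plan A [sampling_plan].
#' @param n Number of draws.
#' @return Integer vector of recording indices, length `n`.
#' @export
sample_epoch <- function(plan, n = plan$n) {
  cell_draw <- sample.int(length(plan$cells), n, replace = TRUE,
                          prob = plan$probs)
  vapply(cell_draw, function(ci) {
    idx <- plan$cells[[ci]]
    idx[sample.int(length(idx), 1L)]
  }, integer(1))
}

#' Split an epoch's draws into batches
#'
#' The number of batches per epoch is `ceiling(n / batch_size)`, so that a
#' full epoch presents exactly `n` recordings.
#'
#' @param plan A [sampling_plan].
#' @param batch_size Batch size.
#' @param n Draws per epoch.
#' @return List of integer index vectors.
#' @export
balanced_batches <- function(plan, batch_size = 64L, n = plan$n) {
  idx <- sample_epoch(plan, n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' 1cycle learning-rate schedule
#'
#' A single cosine rise from `max_lr / div_factor` to `max_lr` over the first
#' `pct_start` of training, followed by a cosine fall to
#' `max_lr / (div_factor * final_div_factor)`, far below the initial rate.
#'
#' @param step Step index, `0 <= step < total_steps` (vectorized).
#' @param total_steps Total optimizer steps.
#' @param max_lr Peak learning rate.
#' @param pct_start Fraction of steps spent rising.
#' @param div_factor Initial LR = `max_lr / div_factor`.
#' @param final_div_factor Final LR = initial / `final_div_factor`.
#' @return Learning rate(s).
#' @export
one_cycle_lr <- function(step, total_steps, max_lr = 1e-3, pct_start = 0.3,
                         div_factor = 25, final_div_factor = 1e4) {
  if (any(step < 0 | step >= total_steps)) stop("step out of range")
  initial <- max_lr / div_factor
  final <- initial / final_div_factor
  u <- if (total_steps > 1L) step / (total_steps - 1) else 0.5
  ifelse(u <= pct_start,
         initial + (max_lr - initial) / 2 *
           (1 - cos(pi * u / max(pct_start, 1e-12))),
         final + (max_lr - final) / 2 *
           (1 + cos(pi * (u - pct_start) / (1 - pct_start))))
}

#' Binary cross-entropy on clip-level predictions
#' @param p Predicted probabilities.
#' @param y Binary labels.
#' @param eps Clamp for numerical stability.
#' @return Mean BCE.
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Rank-based AUROC
#'
#' The probability that a random positive outscores a random negative, with
#' half-credit for ties (equivalent to the Mann-Whitney statistic).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop("undefined metric: AUROC needs both classes")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean positional AUROC
#'
#' Recording scores are partitioned by thoracic site, one AUROC is computed
#' per site, and the unweighted mean is returned. A site whose labels are
#' single-class is dropped from the mean with a warning.
#'
#' @param scores Per-recording scores.
#' @param labels Per-recording binary labels.
#' @param sites Per-recording site (values from [ausc_sites]).
#' @return Mean of the per-site AUROCs.
#' @export
mean_positional_auroc <- function(scores, labels, sites) {
  vals <- c()
  for (s in unique(sites)) {
    sel <- sites == s
    y <- as.logical(labels[sel])
    if (length(unique(y)) < 2L) {
      warning("site ", s, " has single-class labels; excluded from the mean")
      next
    }
    vals <- c(vals, auroc(scores[sel], y))
  }
  if (!length(vals)) stop("no site with both classes present")
  mean(vals)
}

## Stack a list of spectrogram matrices with equal frame counts into the
## (n_mels, T, N) array the network consumes.
stack_specs <- function(mats) {
  array(unlist(mats), dim = c(nrow(mats[[1L]]), ncol(mats[[1L]]), length(mats)))
}

#' Score recordings with a trained model
#'
#' Full-length inference-mode scoring, batched over groups of equal frame
#' count for speed.
#'
#' @param model A `segment_model`.
#' @param clips List of [audio_clip]s.
#' @param spec_cfg A [spectrogram_config].
#' @param batch_size Clips per forward pass.
#' @return Numeric vector of clip-level probabilities, one per clip.
#' @export
score_recordings <- function(model, clips, spec_cfg = spectrogram_config(),
                             batch_size = 32L) {
  min_samples <- model$cfg$stride_frames * spec_cfg$hop_len
  mats <- lapply(clips, function(cl) {
    if (length(cl$samples) < min_samples)
      cl$samples <- c(cl$samples, numeric(min_samples - length(cl$samples)))
    compute_logmel(cl, spec_cfg)$values
  })
  scores <- numeric(length(mats))
  frames <- vapply(mats, ncol, integer(1))
  for (tf in unique(frames)) {
    idx <- which(frames == tf)
    for (chunk in split(idx, ceiling(seq_along(idx) / batch_size))) {
      x3 <- stack_specs(mats[chunk])
      out <- nn_forward(model, x3, training = FALSE, keep_cache = FALSE)
      scores[chunk] <- out$clip_p
    }
  }
  scores
}

#' Train one binary segment model
#'
#' Trains the CNN with BCE on clip-level predictions (the clip label is the
#' patient's diagnosis broadcast to all of its recordings), balanced sampling
#' over (stratum x centre) cells, AdamW and the 1cycle schedule. From
#' `selection_start` onward the tune fold's mean positional AUROC is computed
#' every epoch and the best checkpoint is returned. Deterministic given
#' `train_cfg$seed`.
#'
#' @param patients List of [patient_record]s.
#' @param train_ids,tune_ids Patient ids of the train and tune folds.
#' @param target_class Positive class, one of [ausc_diagnoses].
#' @param model_cfg A [model_config].
#' @param train_cfg A [train_config].
#' @param spec_cfg A [spectrogram_config].
#' @param verbose Print per-epoch log lines.
#' @return List with `model` (best checkpoint), `history` (per-epoch loss, LR
#'   and selection metric), `best_epoch` and `best_metric`.
#' @export
train_binary_model <- function(patients, train_ids, tune_ids, target_class,
                               model_cfg = model_config(),
                               train_cfg = train_config(),
                               spec_cfg = spectrogram_config(),
                               verbose = FALSE) {
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (length(intersect(train_ids, tune_ids)))
    stop("train and tune folds overlap")
  train_rec <- cohort_recordings(patients[ids %in% train_ids])
  tune_rec <- cohort_recordings(patients[ids %in% tune_ids])
  if (!nrow(train_rec$meta) || !nrow(tune_rec$meta))
    stop("both folds must be non-empty")
  tune_y <- tune_rec$meta$diagnosis == target_class
  if (length(unique(tune_y)) < 2L)
    stop("selection-metric error: tune fold contains a single class")

  model_cfg$init_seed <- train_cfg$seed
  model <- build_model(model_cfg)
  opt <- adamw_init(model$params)
  plan <- sampling_plan(train_rec$meta, target_class)
  n_epoch_draws <- plan$n
  steps_per_epoch <- ceiling(n_epoch_draws / train_cfg$batch_size)
  total_steps <- steps_per_epoch * train_cfg$epochs

  # tune-fold spectrograms are fixed; compute once
  min_samples <- model_cfg$stride_frames * spec_cfg$hop_len
  tune_mats <- lapply(tune_rec$clips, function(cl) {
    if (length(cl$samples) < min_samples)
      cl$samples <- c(cl$samples, numeric(min_samples - length(cl$samples)))
    compute_logmel(cl, spec_cfg)$values
  })
  tune_frames <- vapply(tune_mats, ncol, integer(1))

  set.seed(train_cfg$seed + 1L)
  history <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                        tune_metric = numeric())
  best <- list(metric = -Inf, params = NULL, run = NULL, epoch = NA_integer_)
  step <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    batches <- balanced_batches(plan, train_cfg$batch_size, n_epoch_draws)
    ep_loss <- 0; ep_n <- 0L
    for (b in batches) {
      lr <- one_cycle_lr(step, total_steps, train_cfg$max_lr)
      mats <- lapply(train_rec$clips[b], function(cl) {
        sp <- compute_logmel(crop_or_pad(cl, train_cfg$crop_duration), spec_cfg)
        if (train_cfg$augment) sp <- spec_augment(sp, fill = NULL)
        sp$values
      })
      x3 <- stack_specs(mats)
      y <- as.numeric(train_rec$meta$diagnosis[b] == target_class)
      out <- nn_forward(model, x3, training = TRUE)
      model$run <- out$run
      pc <- pmin(pmax(out$clip_p, 1e-7), 1 - 1e-7)
      dclip <- (pc - y) / (pc * (1 - pc)) / length(y)
      grads <- nn_backward(model, out, dclip = dclip)
      upd <- adamw_step(model$params, grads, opt, lr,
                        weight_decay = train_cfg$weight_decay)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + bce_loss(out$clip_p, y) * length(y)
      ep_n <- ep_n + length(y)
      step <- step + 1L
    }
    metric <- NA_real_
    if (epoch >= train_cfg$selection_start) {
      sc <- numeric(length(tune_mats))
      for (tf in unique(tune_frames)) {
        idx <- which(tune_frames == tf)
        for (chunk in split(idx, ceiling(seq_along(idx) / train_cfg$batch_size))) {
          out <- nn_forward(model, stack_specs(tune_mats[chunk]),
                            training = FALSE, keep_cache = FALSE)
          sc[chunk] <- out$clip_p
        }
      }
      metric <- mean_positional_auroc(sc, tune_y, tune_rec$meta$site)
      if (metric > best$metric) {
        best$metric <- metric
        best$params <- model$params
        best$run <- model$run
        best$epoch <- epoch
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss / ep_n,
                                         lr = lr, tune_metric = metric))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  lr %.2e  tune mpAUROC %s",
                      epoch, ep_loss / ep_n, lr,
                      ifelse(is.na(metric), "-", sprintf("%.3f", metric))))
  }
  if (is.null(best$params)) {         # selection never ran (shouldn't happen)
    best$params <- model$params; best$run <- model$run
  }
  model$params <- best$params
  model$run <- best$run
  list(model = model, history = history, best_epoch = best$epoch,
       best_metric = best$metric)
}
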