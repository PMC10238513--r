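#' Site-score matrix for a set of patients
#'
#' Scores every recording of every complete patient (all 8 sites) with the
#' trained model and assembles the canonical length-8 site vectors. Patients
#' missing any site are dropped, mirroring the aggregation selection rule.
#'
#' @param model A trained `segment_model`.
#' @param patients List of [patient_record]s.
#' @param spec_cfg A [spectrogram_config].
#' @return List with `x` (matrix n x 8, rownames = patient ids) and
#'   `diagnosis` (character vector).
#' @export
site_score_matrix <- function(model, patients, spec_cfg = spectrogram_config()) {
  complete <- vapply(patients, function(p)
    all(ausc_sites %in% names(p$clips)), logical(1))
  patients <- patients[complete]
  if (!length(patients)) stop("no complete patients (8 sites required)")
  clips <- list(); owner <- list()
  for (pi in seq_along(patients)) {
    for (site in ausc_sites) {
      clips[[length(clips) + 1L]] <- patients[[pi]]$clips[[site]]
      owner[[length(owner) + 1L]] <- c(pi, match(site, ausc_sites))
    }
  }
  sc <- score_recordings(model, clips, spec_cfg)
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  x <- matrix(NA_real_, length(patients), 8L,
              dimnames = list(ids, ausc_sites))
  for (j in seq_along(sc)) x[owner[[j]][1L], owner[[j]][2L]] <- sc[j]
  list(x = x, diagnosis = vapply(patients, function(p) p$diagnosis,
                                 character(1)))
}

#' Train one full binary patient-level classifier
#'
#' Trains the CNN on the train fold with tune-fold model selection, fits the
#' logistic site aggregator on the pooled train + tune patients, and evaluates
#' on the test fold. The test fold is touched only at evaluation; fold
#' isolation is asserted.
#'
#' @param patients List of [patient_record]s.
#' @param split List with `train`, `tune`, `test` patient-id vectors.
#' @param target_class Positive class, one of [ausc_diagnoses].
#' @param model_cfg,train_cfg,spec_cfg Configurations.
#' @param verbose Print training progress.
#' @return List with `model`, `aggregator`, `cnn_fit` (training history),
#'   `test_scores` (named patient probabilities), `test_labels` and
#'   `test_metrics`.
#' @export
train_patient_classifier <- function(patients, split, target_class,
                                     model_cfg = model_config(),
                                     train_cfg = train_config(),
                                     spec_cfg = spectrogram_config(),
                                     verbose = FALSE) {
  stopifnot(!length(intersect(split$test, c(split$train, split$tune))))
  fit <- train_binary_model(patients, split$train, split$tune, target_class,
                            model_cfg, train_cfg, spec_cfg, verbose = verbose)
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  dev <- site_score_matrix(fit$model,
                           patients[ids %in% c(split$train, split$tune)],
                           spec_cfg)
  agg <- fit_binary_aggregator(dev$x, dev$diagnosis == target_class)
  tst <- site_score_matrix(fit$model, patients[ids %in% split$test], spec_cfg)
  scores <- predict_patient(tst$x, agg)
  labels <- tst$diagnosis == target_class
  list(model = fit$model, aggregator = agg, cnn_fit = fit,
       test_scores = stats::setNames(scores, rownames(tst$x)),
       test_labels = labels,
       test_metrics = evaluate_binary(scores, labels))
}
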