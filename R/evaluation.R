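#' Nested stratified cross-validation plan
#'
#' Patients are dealt into `k` folds preserving class proportions (all of a
#' patient's recordings stay in one fold). Every ordered pair of distinct
#' folds (test, tune) yields one split with the remaining `k - 2` folds as
#' training data: `k * (k - 1)` splits in total (20 for `k = 5`).
#'
#' @param patient_ids Character vector of patient ids.
#' @param diagnoses Stratification labels, same length.
#' @param k Fold count (>= 3).
#' @param seed Seed for the fold assignment.
#' @return An object of class `fold_plan`: list with `k`, `assignment`
#'   (named integer vector patient -> fold) and `splits` (list of lists with
#'   `train`, `tune`, `test` id vectors).
#' @export
make_nested_folds <- function(patient_ids, diagnoses, k = 5L, seed = 1L) {
  if (k < 3L) stop("k must be >= 3")
  if (anyDuplicated(patient_ids)) stop("duplicated patient ids")
  tab <- table(diagnoses)
  if (any(tab < k))
    stop("stratification error: class '", names(tab)[which.min(tab)],
         "' has fewer patients than folds")
  set.seed(seed)
  assignment <- integer(length(patient_ids))
  names(assignment) <- patient_ids
  for (cl in names(tab)) {
    idx <- sample(which(diagnoses == cl))
    assignment[idx] <- rep_len(seq_len(k), length(idx))
  }
  splits <- list()
  for (test in seq_len(k)) {
    for (tune in setdiff(seq_len(k), test)) {
      splits[[length(splits) + 1L]] <- list(
        train = patient_ids[!assignment %in% c(test, tune)],
        tune = patient_ids[assignment == tune],
        test = patient_ids[assignment == test])
    }
  }
  structure(list(k = as.integer(k), assignment = assignment, splits = splits),
            class = "fold_plan")
}

#' Write / read a fold plan as JSON
#' @param plan A `fold_plan`.
#' @param path File path.
#' @return `path` (write) or the `fold_plan` (read).
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(list(k = plan$k, assignment = as.list(plan$assignment)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  assignment <- unlist(x$assignment)
  k <- x$k
  ids <- names(assignment)
  splits <- list()
  for (test in seq_len(k)) {
    for (tune in setdiff(seq_len(k), test)) {
      splits[[length(splits) + 1L]] <- list(
        train = ids[!assignment %in% c(test, tune)],
        tune = ids[assignment == tune],
        test = ids[assignment == test])
    }
  }
  structure(list(k = k, assignment = assignment, splits = splits),
            class = "fold_plan")
}

#' Binary classification metrics
#'
#' Sensitivity and specificity at a decision threshold (default 0.5 on the
#' aggregator's probability) and rank-based AUROC (ties get half credit).
#'
#' @param scores Predicted probabilities.
#' @param labels Binary labels.
#' @param threshold Decision threshold; a score `>= threshold` is positive.
#' @return List with sensitivity, specificity, auroc, n_pos, n_neg, threshold.
#' @export
evaluate_binary <- function(scores, labels, threshold = 0.5) {
  y <- as.logical(labels)
  if (length(unique(y)) < 2L)
    stop("undefined metric: both classes must be present")
  pred <- scores >= threshold
  list(sensitivity = mean(pred[y]), specificity = mean(!pred[!y]),
       auroc = auroc(scores, y), n_pos = sum(y), n_neg = sum(!y),
       threshold = threshold)
}

#' Attach confidence intervals to binary metrics
#'
#' Exact (Clopper-Pearson) binomial intervals for sensitivity and specificity;
#' asymptotic DeLong interval for AUROC, truncated to \[0, 1\]. When the score
#' distributions are perfectly separated the DeLong variance is zero and the
#' degenerate interval is returned with a warning.
#'
#' @param scores,labels,threshold As in [evaluate_binary].
#' @param level Confidence level (default 0.95).
#' @return The [evaluate_binary] list, with `_low` / `_high` bounds added for
#'   each metric.
#' @export
confidence_intervals <- function(scores, labels, threshold = 0.5, level = 0.95) {
  m <- evaluate_binary(scores, labels, threshold)
  if (m$n_pos == 0L || m$n_neg == 0L) stop("need observations in both classes")
  cp <- function(x, n) {
    as.numeric(stats::binom.test(x, n, conf.level = level)$conf.int)
  }
  se_ci <- cp(round(m$sensitivity * m$n_pos), m$n_pos)
  sp_ci <- cp(round(m$specificity * m$n_neg), m$n_neg)
  r <- pROC::roc(response = as.integer(as.logical(labels)), predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  v <- pROC::var(r, method = "delong")
  if (v <= 0) {
    warning("degenerate DeLong interval: zero variance (perfect separation)")
    au_ci <- c(m$auroc, m$auroc)
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    au_ci <- pmin(pmax(m$auroc + c(-1, 1) * z * sqrt(v), 0), 1)
  }
  m$sensitivity_low <- se_ci[1]; m$sensitivity_high <- se_ci[2]
  m$specificity_low <- sp_ci[1]; m$specificity_high <- sp_ci[2]
  m$auroc_low <- au_ci[1]; m$auroc_high <- au_ci[2]
  m$level <- level
  m
}

#' Ensemble prediction by averaging
#'
#' External validation uses the nested-CV models as an ensemble: per-patient
#' probabilities are averaged, unweighted, across members.
#'
#' @param prob_matrix Matrix `n_patients x n_models` of member probabilities
#'   (or a list of equal-length vectors).
#' @return Numeric vector of ensemble probabilities.
#' @export
ensemble_predict <- function(prob_matrix) {
  if (is.list(prob_matrix)) prob_matrix <- do.call(cbind, prob_matrix)
  rowMeans(as.matrix(prob_matrix))
}

#' Row-normalized 4x4 confusion matrix
#'
#' Rows are true diagnoses, columns predicted, in [ausc_diagnoses] order;
#' non-empty rows sum to 1.
#'
#' @param predicted,truth Character vectors of diagnoses.
#' @return `4 x 4` numeric matrix.
#' @export
confusion_matrix4 <- function(predicted, truth) {
  m <- table(factor(truth, levels = ausc_diagnoses),
             factor(predicted, levels = ausc_diagnoses))
  m <- unclass(m)
  rs <- rowSums(m)
  m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  m
}

#' Clinical baseline on age and respiratory rate
#'
#' Logistic regression on the two routinely collected covariates, with the
#' same nested-CV fold plan as the audio pipeline. Hyper-parameters
#' (regularization strength and penalty type) are grid-searched on the
#' train/tune folds by mean tune AUROC; one model per split is then fitted on
#' the pooled train + tune folds. Patients with missing respiratory rate are
#' excluded. Features are standardized inside each fit.
#'
#' @param data Data frame with columns patient_id, age, respiratory_rate, and
#'   a logical/0-1 column `label` (positive class).
#' @param plan A `fold_plan` over (a superset of) these patients.
#' @param reg_grid Regularization strengths to search.
#' @param penalties Penalty types, subset of `c("l1", "l2")`.
#' @return List with `models` (one per split: coefficient list), `best`
#'   (chosen hyper-parameters), and `metrics` (per-split test metrics).
#' @export
fit_baseline <- function(data, plan, reg_grid = c(0.01, 0.1, 1, 10, 100),
                         penalties = c("l1", "l2")) {
  data <- data[!is.na(data$respiratory_rate), , drop = FALSE]
  x_all <- as.matrix(data[, c("age", "respiratory_rate")])
  y_all <- as.integer(as.logical(data$label))
  rownames(x_all) <- data$patient_id
  fit1 <- function(ids, reg, alpha) {
    sel <- data$patient_id %in% ids
    x <- x_all[sel, , drop = FALSE]; y <- y_all[sel]
    if (length(unique(y)) < 2L) stop("single-class fold in baseline fit")
    mu <- colMeans(x); sd <- pmax(apply(x, 2L, stats::sd), 1e-12)
    xs <- sweep(sweep(x, 2L, mu), 2L, sd, "/")
    co <- ridge_logistic_fit(xs, y, reg, alpha = alpha)
    list(intercept = co$intercept, weights = co$weights, mu = mu, sd = sd)
  }
  pred1 <- function(mod, ids) {
    x <- x_all[data$patient_id %in% ids, , drop = FALSE]
    xs <- sweep(sweep(x, 2L, mod$mu), 2L, mod$sd, "/")
    drop(1 / (1 + exp(-(mod$intercept + xs %*% mod$weights))))
  }
  # grid search: mean tune AUROC over splits
  grid <- expand.grid(reg = reg_grid, penalty = penalties,
                      stringsAsFactors = FALSE)
  grid$score <- vapply(seq_len(nrow(grid)), function(i) {
    alpha <- if (grid$penalty[i] == "l1") 1 else 0
    mean(vapply(plan$splits, function(sp) {
      tr <- intersect(sp$train, data$patient_id)
      tu <- intersect(sp$tune, data$patient_id)
      mod <- fit1(tr, grid$reg[i], alpha)
      ysel <- y_all[data$patient_id %in% tu]
      if (length(unique(ysel)) < 2L) return(NA_real_)
      auroc(pred1(mod, tu), ysel)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- grid[which.max(grid$score), ]
  alpha <- if (best$penalty == "l1") 1 else 0
  models <- lapply(plan$splits, function(sp) {
    fit1(intersect(c(sp$train, sp$tune), data$patient_id), best$reg, alpha)
  })
  metrics <- lapply(seq_along(plan$splits), function(i) {
    te <- intersect(plan$splits[[i]]$test, data$patient_id)
    ysel <- y_all[data$patient_id %in% te]
    if (length(unique(ysel)) < 2L) return(NULL)
    evaluate_binary(pred1(models[[i]], te), ysel)
  })
  list(models = models, best = best[, c("reg", "penalty")], metrics = metrics,
       predict = function(i, ids) pred1(models[[i]], ids))
}

#' Position sets for the inference sweep
#'
#' Nested combinations anchored on the anterior superior sites, which carry
#' the least heart/stomach interference: 1 = anterior right superior,
#' 2 = both anterior superior, 4 = anterior + posterior superior, 8 = all.
#'
#' @return Named list of site-name vectors.
#' @export
sweep_position_sets <- function() {
  list(`8` = ausc_sites,
       `4` = ausc_sites[c(1, 2, 5, 6)],
       `2` = ausc_sites[1:2],
       `1` = ausc_sites[1])
}

#' Duration x position inference sweep
#'
#' For eligible patients (all 8 sites present, every recording at least the
#' longest duration), recordings are cropped from the start to each duration,
#' scored by the trained model, and patient-level AUROC is computed for each
#' position set: an aggregator of matching dimensionality is re-fitted on the
#' train patients and evaluated on the test patients. The full-duration,
#' 8-position cell reproduces the standard pipeline exactly.
#'
#' @param model A trained `segment_model`.
#' @param patients List of [patient_record]s.
#' @param target_class Positive class.
#' @param train_ids,test_ids Patient ids used to fit and evaluate the
#'   aggregators (train = pooled train + tune folds).
#' @param durations Crop durations in seconds (default 2.5 to 30 by 2.5).
#' @param position_sets Named list of site subsets (default
#'   [sweep_position_sets]).
#' @param spec_cfg A [spectrogram_config].
#' @param reg Aggregator regularization strength.
#' @return Data frame with columns positions, duration, auroc.
#' @export
sweep_inference <- function(model, patients, target_class, train_ids, test_ids,
                            durations = seq(2.5, 30, by = 2.5),
                            position_sets = sweep_position_sets(),
                            spec_cfg = spectrogram_config(), reg = 1.0) {
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  max_d <- max(durations)
  eligible <- vapply(patients, function(p) {
    length(p$clips) == 8L &&
      all(vapply(p$clips, clip_duration, numeric(1)) >= max_d - 1e-9)
  }, logical(1))
  patients <- patients[eligible]
  ids <- ids[eligible]
  if (!length(patients)) stop("no eligible patients (need 8 sites, full duration)")
  train_ids <- intersect(train_ids, ids)
  test_ids <- intersect(test_ids, ids)
  labels <- vapply(patients, function(p) p$diagnosis == target_class, logical(1))
  names(labels) <- ids

  res <- list()
  for (d in durations) {
    score_mat <- matrix(NA_real_, length(patients), 8L,
                        dimnames = list(ids, ausc_sites))
    cropped <- list(); where <- list()
    for (pi in seq_along(patients)) {
      for (site in ausc_sites) {
        cl <- patients[[pi]]$clips[[site]]
        n <- as.integer(round(d * cl$rate))
        cl$samples <- cl$samples[seq_len(min(n, length(cl$samples)))]
        cropped[[length(cropped) + 1L]] <- cl
        where[[length(where) + 1L]] <- c(pi, match(site, ausc_sites))
      }
    }
    sc <- score_recordings(model, cropped, spec_cfg)
    for (j in seq_along(sc)) score_mat[where[[j]][1L], where[[j]][2L]] <- sc[j]
    for (ps in names(position_sets)) {
      cols <- position_sets[[ps]]
      xtr <- score_mat[train_ids, cols, drop = FALSE]
      xte <- score_mat[test_ids, cols, drop = FALSE]
      co <- ridge_logistic_fit(xtr, labels[train_ids], reg)
      pr <- drop(1 / (1 + exp(-(co$intercept + xte %*% co$weights))))
      res[[length(res) + 1L]] <- data.frame(
        positions = ps, duration = d,
        auroc = auroc(pr, labels[test_ids]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
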