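test_that("nested fold plans enumerate k*(k-1) leakage-free splits", {
  ids <- sprintf("p%03d", 1:60)
  dg <- rep(ausc_diagnoses, c(18, 12, 15, 15))
  plan5 <- make_nested_folds(ids, dg, k = 5, seed = 2)
  expect_length(plan5$splits, 20L)
  plan3 <- make_nested_folds(ids, dg, k = 3, seed = 2)
  expect_length(plan3$splits, 6L)
  for (sp in plan5$splits) {
    expect_length(intersect(c(sp$train, sp$tune), sp$test), 0L)
    expect_length(intersect(sp$train, sp$tune), 0L)
    expect_setequal(c(sp$train, sp$tune, sp$test), ids)
  }
  # stratification: per-fold class counts within +-1 of the ideal share
  for (cl in ausc_diagnoses) {
    per_fold <- table(plan5$assignment[dg == cl])
    expect_lte(diff(range(per_fold)), 1)
  }
  expect_error(make_nested_folds(ids[1:10], rep(ausc_diagnoses, c(4, 2, 2, 2)),
                                 k = 5), "stratification error")
})

test_that("fold plans survive a JSON round trip", {
  ids <- sprintf("p%02d", 1:20)
  dg <- rep(ausc_diagnoses, each = 5)
  plan <- make_nested_folds(ids, dg, k = 4, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_fold_plan(plan, f)
  back <- read_fold_plan(f)
  expect_identical(back$assignment, plan$assignment)
  expect_identical(back$splits, plan$splits)
})

test_that("binary metrics follow their definitions", {
  m <- evaluate_binary(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$auroc, 1.0)
  m2 <- evaluate_binary(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(m2$auroc, 0.75)
  expect_equal(m2$sensitivity, 0.5)
  expect_error(evaluate_binary(c(0.2, 0.4), c(1, 1)), "both classes")
})

test_that("Clopper-Pearson bounds match the closed-form beta quantiles", {
  set.seed(40)
  scores <- c(runif(10, 0.6, 1), runif(12, 0, 0.4))
  labels <- rep(c(1, 0), c(10, 12))
  ci <- confidence_intervals(scores, labels)       # 10/10 sens, 12/12 spec
  expect_equal(ci$sensitivity_low, 0.025^(1 / 10), tolerance = 1e-9)
  expect_equal(ci$sensitivity_high, 1)
  # 0 successes: lower bound exactly 0
  ci0 <- suppressWarnings(
    confidence_intervals(1 - scores, labels))      # all positives below 0.5
  expect_equal(ci0$sensitivity, 0)
  expect_equal(ci0$sensitivity_low, 0)
  # general case agrees with binom.test
  x <- 17; n <- 23
  bt <- stats::binom.test(x, n)$conf.int
  sc <- c(runif(x, 0.6, 1), runif(n - x, 0, 0.4), runif(5, 0.6, 1), runif(9, 0, .4))
  lb <- c(rep(1, n), rep(0, 14))
  ci2 <- suppressWarnings(confidence_intervals(sc, lb))
  expect_equal(c(ci2$sensitivity_low, ci2$sensitivity_high), as.numeric(bt),
               tolerance = 1e-9)
})

test_that("DeLong interval centres on the rank AUROC and degenerates at 1", {
  set.seed(41)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.5)
  ci <- confidence_intervals(scores, labels)
  expect_equal(ci$auroc, auroc(scores, labels), tolerance = 1e-12)
  expect_lte(ci$auroc_low, ci$auroc)
  expect_gte(ci$auroc_high, ci$auroc)
  expect_lte(ci$auroc_high, 1)
  sep <- c(runif(8, 0.7, 1), runif(8, 0, 0.3))
  expect_warning(cs <- confidence_intervals(sep, rep(c(1, 0), each = 8)),
                 "degenerate DeLong")
  expect_equal(c(cs$auroc_low, cs$auroc_high), c(1, 1))
})

test_that("ensembles average member probabilities", {
  expect_equal(ensemble_predict(matrix(c(0.2, 0.4, 0.6), 1)), 0.4)
  m <- matrix(runif(50), 10, 5)
  e <- ensemble_predict(m)
  expect_true(all(e >= apply(m, 1, min) & e <= apply(m, 1, max)))
  expect_equal(ensemble_predict(cbind(m[, 1], m[, 1])), m[, 1])
})

test_that("confusion matrices are row-stochastic and convex under averaging", {
  pred <- c("control", "pneumonia", "pneumonia", "bronchiolitis",
            "wheezing_disorder", "control")
  truth <- c("control", "pneumonia", "control", "bronchiolitis",
             "wheezing_disorder", "pneumonia")
  cm <- confusion_matrix4(pred, truth)
  expect_identical(dim(cm), c(4L, 4L))
  expect_true(all(abs(rowSums(cm)[rowSums(cm) > 0] - 1) < 1e-12))
  ident <- confusion_matrix4(ausc_diagnoses, ausc_diagnoses)
  expect_equal(unname(ident), diag(4))
  # average of row-stochastic matrices is row-stochastic
  cm2 <- confusion_matrix4(truth, truth)
  avg <- (cm + cm2) / 2
  expect_true(all(abs(rowSums(avg)[rowSums(avg) > 0] - 1) < 1e-12))
})

test_that("clinical baseline recovers a planted age effect", {
  set.seed(42)
  n <- 120
  dg <- sample(rep(ausc_diagnoses, n / 4))
  age <- ifelse(dg == "bronchiolitis", runif(n, 0.1, 1.5), runif(n, 2, 14))
  rr <- ifelse(dg == "control", rnorm(n, 25, 4), rnorm(n, 45, 8))
  data <- data.frame(patient_id = sprintf("p%03d", 1:n), age = age,
                     respiratory_rate = rr,
                     label = dg == "bronchiolitis",
                     stringsAsFactors = FALSE)
  plan <- make_nested_folds(data$patient_id, dg, k = 5, seed = 4)
  bl <- fit_baseline(data, plan)
  expect_length(bl$models, 20L)                    # one per CV split
  auc <- vapply(Filter(Negate(is.null), bl$metrics),
                function(m) m$auroc, numeric(1))
  expect_gt(mean(auc), 0.8)
  # standardization: shifting age by a constant leaves predictions unchanged
  data2 <- data; data2$age <- data2$age + 100
  bl2 <- fit_baseline(data2, plan)
  expect_equal(bl2$predict(1, plan$splits[[1]]$test),
               bl$predict(1, plan$splits[[1]]$test), tolerance = 1e-6)
  # missing respiratory rate excludes the patient
  data3 <- data; data3$respiratory_rate[1:5] <- NA
  bl3 <- fit_baseline(data3, plan)
  expect_true(all(!data3$patient_id[1:5] %in%
                    names(bl3$predict(1, plan$splits[[1]]$test))))
})

test_that("the duration sweep grid is complete and consistent at full scale", {
  durations <- seq(2.5, 30, by = 2.5)
  expect_length(durations, 12L)                    # (30 - 2.5)/2.5 + 1

  cohort <- tiny_cohort()
  ids <- cohort$metadata$patient_id
  model <- build_model(model_config(n_blocks = 2L, channels = c(2L, 4L),
                                    n_mels = 32L, dropout = 0,
                                    init_seed = 21L))
  train_ids <- ids[c(1, 2, 3, 5, 6, 9, 10, 13, 14)]
  test_ids <- ids[c(4, 7, 11, 15)]                 # one control, three cases
  grid <- sweep_inference(model, cohort$patients, "control", train_ids,
                          test_ids, durations = c(4, 8),
                          position_sets = sweep_position_sets())
  expect_identical(nrow(grid), 8L)                 # 2 durations x 4 sets
  expect_setequal(unique(grid$positions), c("8", "4", "2", "1"))

  # full duration + 8 positions reproduces the standard pipeline exactly
  std <- site_score_matrix(model, cohort$patients)
  agg <- fit_binary_aggregator(std$x[train_ids, ],
                               std$diagnosis[match(train_ids, rownames(std$x))]
                               == "control")
  pr <- predict_patient(std$x[test_ids, ], agg)
  std_auroc <- auroc(pr, std$diagnosis[match(test_ids, rownames(std$x))]
                     == "control")
  full <- grid$auroc[grid$duration == 8 & grid$positions == "8"]
  expect_identical(full, std_auroc)
  expect_error(sweep_inference(model, cohort$patients, "control", train_ids,
                               test_ids, durations = 100), "no eligible")
})
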