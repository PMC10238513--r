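test_that("balanced sampler hits its target cell frequencies", {
  # 4 classes x 2 centres, equal sizes: multinomial frequency oracle
  meta <- expand.grid(diagnosis = ausc_diagnoses,
                      centre = c("a", "b"), rec = 1:5,
                      stringsAsFactors = FALSE)
  meta$patient_id <- sprintf("p%03d", seq_len(nrow(meta)))
  meta$site <- ausc_sites[1]
  plan <- sampling_plan(meta, "pneumonia")
  set.seed(30)
  n_draws <- 10000L
  idx <- sample_epoch(plan, n_draws)
  cell <- paste(meta$diagnosis[idx], meta$centre[idx], sep = "|")
  target <- c("pneumonia|a" = 0.25, "pneumonia|b" = 0.25)
  others <- setdiff(ausc_diagnoses, "pneumonia")
  for (cl in others) for (ce in c("a", "b"))
    target[paste(cl, ce, sep = "|")] <- 0.5 / 3 / 2
  for (nm in names(target)) {
    p <- target[[nm]]
    se <- sqrt(p * (1 - p) / n_draws)
    expect_lt(abs(mean(cell == nm) - p), 3 * se,
              label = sprintf("draw frequency of cell %s", nm))
  }
})

test_that("sampler marginalizes to pure class balancing with one centre", {
  meta <- expand.grid(diagnosis = ausc_diagnoses, rec = 1:6,
                      stringsAsFactors = FALSE)
  meta$centre <- "only"
  meta$site <- ausc_sites[1]
  plan <- sampling_plan(meta, "control")
  probs <- tapply(plan$probs, sub("\\|.*", "", names(plan$probs)), sum)
  expect_equal(unname(probs["control"]), 0.5)
  expect_true(all(abs(probs[setdiff(names(probs), "control")] - 1 / 6) < 1e-12))
  expect_error(sampling_plan(meta[meta$diagnosis != "control", ], "control"),
               "configuration error")
})

test_that("an epoch draws exactly N recordings in ceil(N/batch) batches", {
  meta <- data.frame(diagnosis = rep(ausc_diagnoses, c(50, 7, 3, 10)),
                     centre = "c", site = ausc_sites[1],
                     stringsAsFactors = FALSE)
  plan <- sampling_plan(meta, "bronchiolitis")
  set.seed(31)
  batches <- balanced_batches(plan, batch_size = 16L)
  expect_identical(sum(lengths(batches)), nrow(meta))
  expect_identical(length(batches), as.integer(ceiling(nrow(meta) / 16)))
})

test_that("1cycle schedule has one peak at max_lr and decays far below start", {
  total <- 501L                      # a step lands exactly on the peak
  lrs <- one_cycle_lr(0:(total - 1L), total, max_lr = 1e-3)
  expect_equal(max(lrs), 1e-3, tolerance = 1e-12)
  expect_lt(lrs[1], 1e-3)
  expect_lt(lrs[total], lrs[1])
  # unimodal: rises to the peak, then falls (exhaustive scan)
  peak <- which.max(lrs)
  expect_true(all(diff(lrs[1:peak]) >= -1e-15))
  expect_true(all(diff(lrs[peak:total]) <= 1e-15))
  expect_error(one_cycle_lr(total, total, 1e-3), "out of range")
})

test_that("binary cross entropy matches its closed forms", {
  expect_equal(bce_loss(rep(0.5, 4), c(1, 0, 1, 0)), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0.9, 1), -log(0.9), tolerance = 1e-12)
  expect_true(is.finite(bce_loss(c(0, 1), c(1, 0))))   # clamped extremes
})

test_that("rank AUROC matches concordant-pair counting and its symmetries", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  set.seed(32)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq_len(n) / n, n, replace = TRUE)   # with ties
    pairs <- outer(s[y == 1], s[y == 0], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(auroc(s, y), mean(pairs), tolerance = 1e-12)
    expect_equal(auroc(s, 1 - y), 1 - auroc(s, y), tolerance = 1e-12)
    expect_equal(auroc(qlogis(pmin(pmax(s, .01), .99)), y), auroc(s, y),
                 tolerance = 1e-12)                  # monotone invariance
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("mean positional AUROC averages per-site AUROCs", {
  sites <- rep(ausc_sites, each = 4)
  labels <- rep(c(1, 1, 0, 0), 8)
  scores <- rep(c(0.8, 0.7, 0.3, 0.2), 8)           # all sites perfect
  expect_equal(mean_positional_auroc(scores, labels, sites), 1.0)

  # site AUROCs (1.0, 0.5) with six at 0.75 -> unweighted mean 0.75
  scores2 <- c(c(0.8, 0.7, 0.3, 0.2),               # 1.0
               c(0.5, 0.3, 0.5, 0.3),               # 0.5
               rep(c(0.8, 0.4, 0.6, 0.2), 6))       # 0.75 each
  expect_equal(mean_positional_auroc(scores2, labels, sites),
               mean(c(1, 0.5, rep(0.75, 6))))

  labels3 <- labels; labels3[1:4] <- 1              # one single-class site
  expect_warning(m <- mean_positional_auroc(scores2, labels3, sites),
                 "single-class")
  expect_equal(m, mean(c(0.5, rep(0.75, 6))))
})

test_that("training is deterministic and respects fold structure", {
  cohort <- tiny_cohort()
  ids <- cohort$metadata$patient_id
  ctr <- ids[cohort$metadata$diagnosis == "control"]
  pat <- ids[cohort$metadata$diagnosis != "control"]
  train <- c(ctr[1:2], pat[1:4]); tune <- c(ctr[3:4], pat[5:8])
  mc <- model_config(n_blocks = 2L, channels = c(2L, 4L), n_mels = 32L)
  tc <- train_config(batch_size = 8L, epochs = 2L, selection_start = 1L,
                     crop_duration = 3, seed = 5L)
  r1 <- train_binary_model(cohort$patients, train, tune, "control", mc, tc)
  r2 <- train_binary_model(cohort$patients, train, tune, "control", mc, tc)
  expect_identical(r1$best_metric, r2$best_metric)
  expect_identical(r1$history$loss, r2$history$loss)
  expect_identical(r1$model$params[["fc.W"]], r2$model$params[["fc.W"]])
  expect_equal(nrow(r1$history), 2L)
  expect_false(any(is.na(r1$history$tune_metric)))

  expect_error(train_binary_model(cohort$patients, train, train, "control",
                                  mc, tc), "overlap")
  expect_error(train_binary_model(cohort$patients, train, pat[9], "control",
                                  mc, tc), "single class")
})
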