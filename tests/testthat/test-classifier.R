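test_that("the default grid enumerates 18 configurations with floor-halving widths", {
  grid <- enumerate_grid()
  expect_length(grid, 18L)
  # depth 3, first width 32 -> (32, 16, 8)
  hiddens <- lapply(grid, `[[`, "hidden")
  expect_true(list(c(32L, 16L, 8L)) %in% hiddens)
  # halving rule everywhere, widths never below 1
  for (h in hiddens) {
    expect_true(all(h >= 1L))
    if (length(h) > 1L)
      expect_identical(h[-1L], pmax(1L, h[-length(h)] %/% 2L))
  }
  expect_length(enumerate_grid(depths = 2L, first_widths = 8L), 1L)
  expect_error(enumerate_grid(depths = integer(0)), "non-empty")
})

test_that("SMOTE balances to the majority count with convex-combination synthetics", {
  set.seed(1)
  X <- matrix(rnorm(17 * 4), 17, 4)
  y <- rep(c(0L, 1L), c(12L, 5L))
  bal <- smote_balance(X, y, seed = 2L)
  expect_identical(as.integer(table(bal$y)), c(12L, 12L))
  expect_identical(bal$X[1:17, ], X)           # originals unchanged
  expect_identical(bal$real, rep(c(TRUE, FALSE), c(17L, 7L)))
  expect_identical(bal$y[!bal$real], rep(1L, 7L))

  # balanced input returned unchanged
  bal2 <- smote_balance(X[1:10, ], rep(c(0L, 1L), each = 5L))
  expect_identical(bal2$X, X[1:10, ])
  expect_true(all(bal2$real))

  # minority of two points: every synthetic sample lies on the segment [a, b]
  a <- c(0, 0); b <- c(1, 2)
  X3 <- rbind(matrix(rnorm(12), 6, 2), a, b)
  y3 <- rep(c(0L, 1L), c(6L, 2L))
  bal3 <- smote_balance(X3, y3, seed = 3L)
  syn <- bal3$X[!bal3$real, , drop = FALSE]
  ts <- syn[, 1] / b[1]
  expect_true(all(ts >= 0 & ts <= 1))
  expect_equal(syn[, 2], ts * b[2], tolerance = 1e-12)

  # single-sample minority duplicates with a warning
  expect_warning(bal4 <- smote_balance(X3[1:7, ], rep(c(0L, 1L), c(6L, 1L))),
                 "single")
  expect_identical(as.integer(table(bal4$y)), c(6L, 6L))
  expect_error(smote_balance(X, rep(0L, 17)), "both classes")
})

test_that("Monte-Carlo cv sizes test sets by round-half-up per class and is deterministic", {
  # 217 patients split 120/97 at 10% -> 12 + 10 = 22 test samples
  splits <- dsafgs:::make_mc_splits(rep(c(0L, 1L), c(120L, 97L)),
                                    iterations = 10L, test_frac = 0.10, seed = 3L)
  expect_length(splits, 10L)
  for (sp in splits) {
    expect_length(sp$test, 22L)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), 1:217)
  }
  splits2 <- dsafgs:::make_mc_splits(rep(c(0L, 1L), c(120L, 97L)),
                                     iterations = 10L, test_frac = 0.10, seed = 3L)
  expect_identical(splits, splits2)

  ds <- make_toy_dataset(n_genes = 8L, n_patients = 40L)
  cfg <- classifier_config(hidden = c(8L, 4L), epochs = 60L)
  cv1 <- monte_carlo_cv(ds, cfg, iterations = 4L, seed = 5L)
  cv2 <- monte_carlo_cv(ds, cfg, iterations = 4L, seed = 5L)
  expect_identical(vapply(cv1$iterations, `[[`, numeric(1), "accuracy"),
                   vapply(cv2$iterations, `[[`, numeric(1), "accuracy"))
  expect_equal(cv1$mean, mean(vapply(cv1$iterations, `[[`, numeric(1), "accuracy")))
  expect_equal(unname(cv1$ci["upper"] - cv1$ci["lower"]), 2 * 1.96 * cv1$sd)
  # test sets contain only real patients (ids drawn from the cohort)
  for (it in cv1$iterations)
    expect_true(all(it$test_ids %in% ds$patient_ids))
})

test_that("separable data reaches near-perfect cv accuracy, like the logistic oracle", {
  ds <- make_toy_dataset(n_genes = 10L, n_patients = 60L, n_signal = 3L,
                         shift = 3, seed = 42L)
  cfg <- classifier_config(hidden = c(16L, 8L), epochs = 150L)
  cv <- monte_carlo_cv(ds, cfg, seed = 7L)
  expect_gte(cv$mean, 0.95)
  # the independent oracle: pooled logistic regression separates the data
  df <- data.frame(t(ds$values), y = ds$labels)
  glm_acc <- mean((stats::predict(suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial)),
    type = "response") > 0.5) == ds$labels)
  expect_equal(glm_acc, 1.0)
})

test_that("grid search picks the argmax-mean config and its best iteration", {
  ds <- make_toy_dataset(n_genes = 6L, n_patients = 50L)
  grid <- enumerate_grid(depths = 2L, first_widths = c(8L, 16L), epochs = 80L)
  gs <- grid_search_select(ds, grid, iterations = 3L, seed = 11L)
  means <- vapply(gs$records, `[[`, numeric(1), "mean")
  expect_identical(gs$chosen_index, order(-means, seq_along(means))[1L])
  rec <- gs$records[[gs$chosen_index]]
  accs <- vapply(rec$iterations, `[[`, numeric(1), "accuracy")
  expect_identical(gs$best_iteration, which.max(accs))
  expect_gte(rec$iterations[[gs$best_iteration]]$accuracy, rec$mean - 1e-12)
  expect_s3_class(gs$model, "TrainedClassifier")
  # single config -> chosen trivially
  gs1 <- grid_search_select(ds, grid[1], iterations = 2L, seed = 1L)
  expect_identical(gs1$chosen_index, 1L)
})

test_that("evaluation metrics satisfy their identities on solved counts", {
  rep <- confusion_report(tp = 17, fn = 3, fp = 3, tn = 21)
  expect_equal(rep$accuracy, 38 / 44)
  expect_equal(round(rep$accuracy, 4), 0.8636)
  expect_equal(rep$sensitivity, 0.85)
  expect_equal(rep$specificity, 0.875)
  solved <- confusion_from_rates(0.85, 0.875, fp = 3, fn = 3)
  expect_identical(solved$counts, c(tp = 17, fn = 3, fp = 3, tn = 21))
  expect_equal(solved$accuracy, rep$accuracy)
  expect_error(confusion_from_rates(0.851, 0.875, fp = 3, fn = 3), "integer")
})

test_that("ROC/AUC behave at the extremes and match the pROC oracle", {
  ds <- make_toy_dataset(n_genes = 5L, n_patients = 40L)
  cfg <- classifier_config(hidden = 8L, epochs = 100L)
  X <- t(ds$values)
  model <- train_classifier(X, ds$labels, cfg, seed = 2L)
  ev <- evaluate_classifier(model, X, ds$labels)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  skip_if_not_installed("pROC")
  scores <- predict(model, X)
  proc_auc <- as.numeric(pROC::auc(pROC::roc(ds$labels, scores, quiet = TRUE)))
  expect_equal(ev$auc, proc_auc, tolerance = 1e-10)
})

test_that("AUC is 0.5 for constant scores, 1 for perfect scores, and monotone-invariant", {
  y <- rep(c(0L, 1L), each = 10L)
  const <- dsafgs:::roc_points(rep(0.4, 20), y)
  expect_equal(dsafgs:::auc_trapezoid(const), 0.5)
  perfect <- dsafgs:::roc_points(y * 0.9 + 0.05, y)
  expect_equal(dsafgs:::auc_trapezoid(perfect), 1.0)
  set.seed(6)
  s <- runif(20)
  a1 <- dsafgs:::auc_trapezoid(dsafgs:::roc_points(s, y))
  a2 <- dsafgs:::auc_trapezoid(dsafgs:::roc_points(plogis(5 * s - 2), y))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("prediction refuses silently reordered gene columns", {
  ds <- make_toy_dataset(n_genes = 4L, n_patients = 30L)
  X <- t(ds$values)
  model <- train_classifier(X, ds$labels,
                            classifier_config(hidden = 4L, epochs = 30L))
  expect_error(predict(model, X[, rev(colnames(X))]), "gene")
  expect_error(predict(model, unname(X)), "gene")
})

test_that("persisted models reload and reproduce scores within 1e-6", {
  ds <- make_toy_dataset(n_genes = 6L, n_patients = 30L)
  X <- t(ds$values)
  model <- train_classifier(X, ds$labels,
                            classifier_config(hidden = c(8L, 4L), epochs = 50L),
                            seed = 9L)
  dir <- withr::local_tempdir()
  save_classifier(model, dir)
  back <- load_classifier(dir)
  expect_identical(back$gene_ids, model$gene_ids)
  expect_lt(max(abs(predict(back, X) - predict(model, X))), 1e-6)
})
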