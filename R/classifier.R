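#' Enumerate the classifier hyperparameter grid
#'
#' The search space is the cartesian product of hidden-layer depths and
#' first-layer widths; every successive hidden layer has half (floor) the
#' neurons of the preceding one, clamped to at least 1, and the output layer
#' is a single sigmoid neuron. The default sets (depths 2/3/4, first widths
#' 8/16/32/64/128/256) give 18 configurations.
#'
#' @param depths Integer vector of hidden-layer counts.
#' @param first_widths Integer vector of first-hidden-layer widths.
#' @param lr Adam learning rate (default 0.001).
#' @param epochs Training epochs per fit (default 200).
#' @param batch_size Mini-batch size (default 32).
#' @return List of `classifier_config` objects.
#' @export
enumerate_grid <- function(depths = c(2L, 3L, 4L),
                           first_widths = c(8L, 16L, 32L, 64L, 128L, 256L),
                           lr = 0.001, epochs = 200L, batch_size = 32L) {
  if (length(depths) == 0L || length(first_widths) == 0L)
    stop("depths and first_widths must be non-empty")
  grid <- list()
  for (d in depths) {
    for (w in first_widths) {
      hidden <- integer(d)
      hidden[1L] <- as.integer(w)
      for (i in seq_len(d - 1L)) hidden[i + 1L] <- max(1L, hidden[i] %/% 2L)
      grid[[length(grid) + 1L]] <- classifier_config(
        hidden = hidden, lr = lr, epochs = epochs, batch_size = batch_size)
    }
  }
  grid
}

#' Classifier configuration
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(hidden, lr = 0.001, epochs = 200L,
                              batch_size = 32L) {
  hidden <- as.integer(hidden)
  stopifnot(length(hidden) >= 1L, all(hidden >= 1L))
  structure(list(hidden = hidden, activation = "relu",
                 output_activation = "sigmoid", loss = "bce",
                 optimizer = "adam", lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size)),
            class = "classifier_config")
}

# number of trainable parameters, used as the grid-search tie-break
n_parameters <- function(cfg, n_inputs) {
  sizes <- c(n_inputs, cfg$hidden, 1L)
  sum(sizes[-length(sizes)] * sizes[-1L] + sizes[-1L])
}

#' SMOTE class balancing
#'
#' Raises the minority class to the majority count by interpolating new
#' samples between each minority point and one of its k nearest minority
#' neighbors: `x_new = x_i + u * (x_nn - x_i)`, `u ~ U(0, 1)`. Original rows
#' are returned unchanged and flagged as real; synthetic rows are flagged
#' so they can be kept out of any test set.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Binary labels (0/1), one per row of `X`.
#' @param k_neighbors Neighborhood size (default 5, clipped to minority
#'   size - 1). A minority class of a single sample falls back to
#'   duplication with a warning.
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @return List with `X`, `y`, and logical `real` flags.
#' @export
smote_balance <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts == 0L)) stop("SMOTE requires both classes present")
  if (counts[["0"]] == counts[["1"]])
    return(list(X = X, y = y, real = rep(TRUE, nrow(X))))
  minority <- if (counts[["0"]] < counts[["1"]]) 0L else 1L
  idx_min <- which(y == minority)
  n_min <- length(idx_min)
  n_syn <- abs(counts[["0"]] - counts[["1"]])
  Xm <- X[idx_min, , drop = FALSE]
  if (n_min < 2L) {
    warning("minority class has a single sample; duplicating instead of interpolating")
    Xs <- Xm[rep(1L, n_syn), , drop = FALSE]
  } else {
    k <- min(as.integer(k_neighbors), n_min - 1L)
    d <- as.matrix(stats::dist(Xm))
    diag(d) <- Inf
    ord <- apply(d, 1L, function(row) order(row)[seq_len(k)])
    # apply() drops to a vector when k = 1
    nn_idx <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)
    Xs <- with_seed(seed, {
      base_i <- rep(seq_len(n_min), length.out = n_syn)
      pick <- nn_idx[cbind(base_i, sample.int(k, n_syn, replace = TRUE))]
      u <- stats::runif(n_syn)
      Xm[base_i, , drop = FALSE] +
        u * (Xm[pick, , drop = FALSE] - Xm[base_i, , drop = FALSE])
    })
  }
  rownames(Xs) <- NULL
  list(X = rbind(X, Xs),
       y = c(y, rep(minority, n_syn)),
       real = c(rep(TRUE, nrow(X)), rep(FALSE, n_syn)))
}

#' Train a feed-forward binary classifier
#'
#' relu hidden layers, single sigmoid output, binary cross-entropy loss,
#' Adam optimizer. Deterministic for a fixed seed.
#'
#' @param X Numeric matrix, samples x genes; column names fix the input
#'   gene order the model expects forever after.
#' @param y Binary labels.
#' @param cfg A `classifier_config`.
#' @param seed Integer seed.
#' @return A `TrainedClassifier`.
#' @export
train_classifier <- function(X, y, cfg, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(inherits(cfg, "classifier_config"), !is.null(colnames(X)))
  sizes <- c(ncol(X), cfg$hidden, 1L)
  net <- nn_train(X, matrix(as.numeric(y), ncol = 1L), sizes,
                  activation = cfg$activation,
                  output_activation = cfg$output_activation,
                  loss = cfg$loss, lr = cfg$lr, epochs = cfg$epochs,
                  batch_size = min(cfg$batch_size, nrow(X)), seed = seed)
  structure(list(net = net, config = cfg, gene_ids = colnames(X),
                 threshold = 0.5, seed = seed),
            class = "TrainedClassifier")
}

#' Predict event scores or classes
#'
#' @param object A `TrainedClassifier`.
#' @param X Samples x genes matrix; column names must match the model's
#'   gene list exactly and in order (a mismatch is an error, never a silent
#'   reorder).
#' @param type `"score"` for the sigmoid output, `"class"` for the 0/1 call
#'   at the model threshold.
#' @param ... Unused.
#' @return Numeric vector of scores or integer vector of classes.
#' @export
predict.TrainedClassifier <- function(object, X, type = c("score", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (is.null(colnames(X)) || !identical(colnames(X), object$gene_ids))
    stop("input gene columns do not match the model's gene list (order matters)")
  s <- as.numeric(nn_predict(object$net, X))
  if (type == "score") s else as.integer(s >= object$threshold)
}

# Stratified Monte-Carlo splits: per class, round-half-up(n_class *
# test_frac) samples go to test. Shared across configs for comparability.
make_mc_splits <- function(labels, iterations = 10L, test_frac = 0.10,
                           seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1)
  n <- length(labels)
  idx0 <- which(labels == 0L); idx1 <- which(labels == 1L)
  t0 <- round_half_up(length(idx0) * test_frac)
  t1 <- round_half_up(length(idx1) * test_frac)
  if (t0 >= length(idx0) || t1 >= length(idx1))
    stop("test fraction leaves no training samples in one class")
  lapply(seq_len(iterations), function(i) {
    with_seed(derive_seed(seed, 7L, i), {
      test <- c(if (t0 > 0) sample(idx0, t0), if (t1 > 0) sample(idx1, t1))
      test <- sort(test)
      list(train = setdiff(seq_len(n), test), test = test)
    })
  })
}

#' Monte-Carlo cross-validation of one configuration
#'
#' Repeated stratified random 90/10 splits; SMOTE is applied to the
#' training portion only, so every test set contains only real samples.
#' Each iteration trains a fresh seeded model and records its test accuracy
#' at threshold 0.5.
#'
#' @param ds A labeled `ExpressionDataset` already restricted to the
#'   selected genes.
#' @param cfg A `classifier_config`.
#' @param iterations Number of Monte-Carlo iterations (default 10).
#' @param test_frac Test fraction (default 0.10); the per-class test count
#'   is `round_half_up(n_class * test_frac)`.
#' @param seed Master seed (drives splits, SMOTE and model init).
#' @param smote_k SMOTE neighborhood size.
#' @param splits Optional precomputed splits from the internal split maker,
#'   so several configurations can share identical partitions.
#' @param keep_models Keep the fitted model of each iteration (needed for
#'   best-iteration selection).
#' @return A `CVRecord`: list with `config`, `iterations` (per-iteration
#'   train/test ids, accuracy, model), `mean`, `sd` and `ci` (mean +/- 1.96
#'   sd).
#' @export
monte_carlo_cv <- function(ds, cfg, iterations = 10L, test_frac = 0.10,
                           seed = 1L, smote_k = 5L, splits = NULL,
                           keep_models = TRUE) {
  stopifnot(inherits(ds, "ExpressionDataset"), !is.null(ds$labels))
  X <- t(ds$values)  # patients x genes
  y <- ds$labels
  if (is.null(splits))
    splits <- make_mc_splits(y, iterations = iterations, test_frac = test_frac,
                             seed = seed)
  iters <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    bal <- smote_balance(X[sp$train, , drop = FALSE], y[sp$train],
                         k_neighbors = smote_k, seed = derive_seed(seed, 11L, i))
    colnames(bal$X) <- colnames(X)
    model <- train_classifier(bal$X, bal$y, cfg, seed = derive_seed(seed, 13L, i))
    pred <- predict(model, X[sp$test, , drop = FALSE], type = "class")
    acc <- mean(pred == y[sp$test])
    iters[[i]] <- list(train_ids = ds$patient_ids[sp$train],
                       test_ids = ds$patient_ids[sp$test],
                       accuracy = acc,
                       model = if (keep_models) model else NULL)
  }
  accs <- vapply(iters, function(it) it$accuracy, numeric(1))
  m <- mean(accs); s <- stats::sd(accs)
  structure(list(config = cfg, iterations = iters, mean = m, sd = s,
                 ci = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
                 seed = seed),
            class = "CVRecord")
}

#' Grid search over classifier configurations
#'
#' Every configuration is cross-validated on identical splits; the chosen
#' configuration maximizes mean test accuracy (ties: fewer parameters, then
#' enumeration order) and the returned model is the iteration of that
#' configuration with the highest test accuracy (ties: lowest iteration
#' index).
#'
#' @param ds A labeled `ExpressionDataset` restricted to the selected genes.
#' @param grid List of `classifier_config`s (default [enumerate_grid()]).
#' @param iterations,test_frac,seed,smote_k As in [monte_carlo_cv()].
#' @param verbose Progress logging.
#' @return List with `config` (chosen), `model` (best `TrainedClassifier`),
#'   `best_iteration` (its index), `records` (all `CVRecord`s).
#' @export
grid_search_select <- function(ds, grid = enumerate_grid(), iterations = 10L,
                               test_frac = 0.10, seed = 1L, smote_k = 5L,
                               verbose = FALSE) {
  if (length(grid) == 0L) stop("empty configuration grid")
  splits <- make_mc_splits(ds$labels, iterations = iterations,
                           test_frac = test_frac, seed = seed)
  records <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    records[[g]] <- monte_carlo_cv(ds, grid[[g]], seed = seed,
                                   smote_k = smote_k, splits = splits)
    if (verbose)
      dsaf_log("grid ", g, "/", length(grid), " hidden=(",
               paste(grid[[g]]$hidden, collapse = ","), ") mean acc = ",
               sprintf("%.3f", records[[g]]$mean))
  }
  means <- vapply(records, function(r) r$mean, numeric(1))
  pars <- vapply(grid, n_parameters, numeric(1), n_inputs = length(ds$gene_ids))
  best_g <- order(-means, pars, seq_along(grid))[1L]
  rec <- records[[best_g]]
  accs <- vapply(rec$iterations, function(it) it$accuracy, numeric(1))
  best_i <- order(-accs, seq_along(accs))[1L]
  list(config = grid[[best_g]], model = rec$iterations[[best_i]]$model,
       best_iteration = best_i, chosen_index = best_g, records = records)
}

#' Evaluate a classifier: confusion matrix, accuracy, ROC, AUC
#'
#' Confusion counts are taken at the model threshold; the ROC curve sweeps
#' the score threshold over all distinct scores and the AUC is the
#' trapezoidal integral of that curve.
#'
#' @param model A `TrainedClassifier`.
#' @param X Samples x genes matrix (columns must match the model's gene
#'   list).
#' @param y True binary labels.
#' @return An `EvaluationReport`: list with `counts` (tp/fn/fp/tn),
#'   `accuracy`, `sensitivity`, `specificity`, `roc` (data.frame fpr/tpr),
#'   `auc`.
#' @export
evaluate_classifier <- function(model, X, y) {
  scores <- predict(model, X, type = "score")
  y <- as.integer(y)
  pred <- as.integer(scores >= model$threshold)
  rep <- confusion_report(tp = sum(pred == 1L & y == 1L),
                          fn = sum(pred == 0L & y == 1L),
                          fp = sum(pred == 1L & y == 0L),
                          tn = sum(pred == 0L & y == 0L))
  roc <- roc_points(scores, y)
  rep$roc <- roc
  rep$auc <- auc_trapezoid(roc)
  rep
}

#' Metrics from confusion counts
#'
#' @param tp,fn,fp,tn Non-negative integer confusion counts.
#' @return An `EvaluationReport` (without ROC/AUC): counts plus accuracy
#'   `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#'   `TN/(TN+FP)`.
#' @export
confusion_report <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(counts = c(tp = tp, fn = fn, fp = fp, tn = tn),
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "EvaluationReport")
}

#' Solve integer confusion counts from printed rates
#'
#' Given a reported sensitivity and specificity together with the numbers
#' of false positives and false negatives, recovers the implied integer TP
#' and TN counts (`TP = sens * FN / (1 - sens)`, `TN = spec * FP /
#' (1 - spec)`) and recomputes all metrics from them — a consistency check
#' for published confusion matrices.
#'
#' @param sensitivity,specificity Reported proportions in (0, 1).
#' @param fp,fn Reported false positive / false negative counts.
#' @return An `EvaluationReport` built from the solved integer counts.
#' @export
confusion_from_rates <- function(sensitivity, specificity, fp, fn) {
  stopifnot(sensitivity > 0, sensitivity < 1, specificity > 0, specificity < 1)
  tp <- sensitivity * fn / (1 - sensitivity)
  tn <- specificity * fp / (1 - specificity)
  if (abs(tp - round(tp)) > 1e-6 || abs(tn - round(tn)) > 1e-6)
    stop("stated rates do not solve to integer counts (TP = ", tp,
         ", TN = ", tn, ")")
  confusion_report(tp = round(tp), fn = fn, fp = fp, tn = round(tn))
}

# ROC by sweeping the decision threshold over all distinct scores.
roc_points <- function(scores, y) {
  y <- as.integer(y)
  np <- sum(y == 1L); nn <- sum(y == 0L)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / max(np, 1L), numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / max(nn, 1L), numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

auc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; yv <- roc$tpr[o]
  sum(diff(x) * (utils::head(yv, -1) + utils::tail(yv, -1)) / 2)
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("EvaluationReport\n")
  cat("  counts: TP =", x$counts[["tp"]], " FN =", x$counts[["fn"]],
      " FP =", x$counts[["fp"]], " TN =", x$counts[["tn"]], "\n")
  cat(sprintf("  accuracy = %.4f  sensitivity = %.4f  specificity = %.4f\n",
              x$accuracy, x$sensitivity, x$specificity))
  if (!is.null(x$auc)) cat(sprintf("  AUC = %.4f\n", x$auc))
  invisible(x)
}

#' Persist a trained classifier to a directory
#'
#' Writes a JSON architecture/config descriptor plus a JSON weight
#' container; [load_classifier()] reproduces scores within 1e-6.
#'
#' @param model A `TrainedClassifier`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_classifier <- function(model, dir) {
  stopifnot(inherits(model, "TrainedClassifier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  desc <- list(gene_ids = model$gene_ids, threshold = model$threshold,
               seed = model$seed,
               config = unclass(model$config),
               layer_sizes = model$net$layer_sizes)
  jsonlite::write_json(desc, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  weights <- list(W = lapply(model$net$W, identity),
                  b = lapply(model$net$b, identity))
  jsonlite::write_json(weights, file.path(dir, "weights.json"), digits = NA)
  invisible(dir)
}

#' Load a classifier saved by [save_classifier()]
#'
#' @param dir Directory written by [save_classifier()].
#' @return A `TrainedClassifier`.
#' @export
load_classifier <- function(dir) {
  desc <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  w <- jsonlite::read_json(file.path(dir, "weights.json"), simplifyVector = TRUE)
  sizes <- as.integer(desc$layer_sizes)
  W <- lapply(w$W, function(m) {
    if (is.matrix(m)) m else matrix(unlist(m), nrow = length(m), byrow = TRUE)
  })
  b <- if (is.matrix(w$b)) {
    lapply(seq_len(nrow(w$b)), function(i) as.numeric(w$b[i, ]))
  } else {
    lapply(w$b, as.numeric)
  }
  cfg <- classifier_config(hidden = as.integer(desc$config$hidden),
                           lr = desc$config$lr,
                           epochs = as.integer(desc$config$epochs),
                           batch_size = as.integer(desc$config$batch_size))
  net <- list(W = W, b = b, layer_sizes = sizes,
              activation = cfg$activation,
              output_activation = cfg$output_activation,
              loss = cfg$loss, seed = desc$seed)
  structure(list(net = net, config = cfg, gene_ids = as.character(desc$gene_ids),
                 threshold = desc$threshold, seed = desc$seed),
            class = "TrainedClassifier")
}
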