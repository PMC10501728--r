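#' Autoencoder architecture for a given patient count
#'
#' The encoder compresses the P patient-features to `floor(P/5)` then
#' `floor(P/10)` units (clamped to at least 1) and the decoder mirrors it,
#' so P = 217 yields the five-layer stack 217-43-21-43-217. Hidden units are
#' relu; the output layer is linear; reconstruction loss is mean absolute
#' error; optimization is Adam at learning rate 0.01 for 1000 epochs.
#'
#' @param p Number of patients (input/output width).
#' @param epochs Training epochs (default 1000).
#' @param lr Adam learning rate (default 0.01).
#' @param batch_size Mini-batch size (default 32; clipped to the cluster
#'   size at training time).
#' @param standardize Standardize each patient-feature to zero mean / unit
#'   variance within the cluster sub-matrix before training (errors are
#'   reported on the original scale either way). Default `FALSE`: because
#'   the cluster's genes are the training samples, per-feature centering
#'   subtracts the cluster's shared expression pattern — the very signal
#'   the autoencoder must reconstruct — and degrades representative
#'   recovery. The toggle remains for data on wildly different scales.
#' @return An `ae_config` list.
#' @export
build_ae_architecture <- function(p, epochs = 1000L, lr = 0.01,
                                  batch_size = 32L, standardize = FALSE) {
  if (p <= 0) stop("patient count must be positive")
  p <- as.integer(p)
  sizes <- c(p, max(1L, p %/% 5L), max(1L, p %/% 10L), max(1L, p %/% 5L), p)
  structure(list(layer_sizes = sizes, activation = "relu",
                 output_activation = "linear", loss = "mae",
                 optimizer = "adam", lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 standardize = isTRUE(standardize)),
            class = "ae_config")
}

#' Select a cluster's representative gene by autoencoder reconstruction
#'
#' The cluster sub-matrix is transposed so that patients are the features
#' and genes are the samples; an autoencoder is trained to reconstruct the
#' gene profiles, and the gene with the lowest mean absolute reconstruction
#' error over its P patient values is kept as the cluster representative
#' (ties broken by lexicographic gene id).
#'
#' @param ds An `ExpressionDataset`.
#' @param cluster Character vector of gene ids forming the cluster.
#' @param cfg An `ae_config` from [build_ae_architecture()]; `NULL` builds
#'   the default for the dataset's patient count.
#' @param seed Integer seed controlling weight initialization and batch
#'   shuffling; the result is deterministic for a fixed seed.
#' @param linear If `TRUE`, the network is trained with linear activations
#'   and squared-error loss — the regime in which a bottleneck-b
#'   autoencoder converges to the rank-b truncated-SVD reconstruction, so
#'   selection can be validated against that closed form. Reported errors
#'   stay mean-absolute for comparability.
#' @return A `ReconstructionReport`: list with `errors` (named non-negative
#'   vector), `representative` (gene id achieving the minimum) and `seed`.
#' @export
select_cluster_representative <- function(ds, cluster, cfg = NULL, seed = 1L,
                                          linear = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  cluster <- as.character(cluster)
  if (length(cluster) == 0L) stop("empty cluster")
  missing_g <- setdiff(cluster, ds$gene_ids)
  if (length(missing_g)) stop("cluster gene(s) not in dataset: ",
                              paste(missing_g, collapse = ", "))
  p <- length(ds$patient_ids)
  if (is.null(cfg)) cfg <- build_ae_architecture(p)
  stopifnot(inherits(cfg, "ae_config"), cfg$layer_sizes[1L] == p)

  X <- ds$values[cluster, , drop = FALSE]  # genes as samples, patients as features
  if (cfg$standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2L, stats::sd)
    sdv[is.na(sdv) | sdv == 0] <- 1
    Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
  } else {
    mu <- rep(0, p); sdv <- rep(1, p)
    Xs <- X
  }
  net <- nn_train(Xs, Xs, cfg$layer_sizes,
                  activation = if (linear) "linear" else cfg$activation,
                  output_activation = cfg$output_activation,
                  loss = if (linear) "mse" else cfg$loss,
                  lr = cfg$lr, epochs = cfg$epochs,
                  batch_size = min(cfg$batch_size, nrow(Xs)), seed = seed)
  recon <- nn_predict(net, Xs)
  recon_orig <- sweep(sweep(recon, 2L, sdv, "*"), 2L, mu, "+")
  errors <- rowMeans(abs(recon_orig - X))
  names(errors) <- cluster
  ord <- order(errors, cluster)
  structure(list(errors = errors, representative = cluster[ord[1L]],
                 seed = seed),
            class = "ReconstructionReport")
}

#' Select one representative per cluster
#'
#' Runs [select_cluster_representative()] on every cluster of a partition.
#' Each cluster gets its own seed derived deterministically from the master
#' seed and the cluster index, so a fixed master seed reproduces the full
#' representative list.
#'
#' @param ds An `ExpressionDataset`.
#' @param part A `ClusterPartition` over the dataset's genes.
#' @param cfg `ae_config` template (`NULL` for the default).
#' @param seed Master seed.
#' @param linear Passed through to the per-cluster call.
#' @param verbose Progress logging.
#' @return List of `ReconstructionReport`s, one per cluster, in cluster
#'   order.
#' @export
select_all_representatives <- function(ds, part, cfg = NULL, seed = 1L,
                                       linear = FALSE, verbose = FALSE) {
  stopifnot(inherits(part, "ClusterPartition"))
  members <- cluster_members(part)
  reports <- vector("list", length(members))
  for (i in seq_along(members)) {
    reports[[i]] <- select_cluster_representative(
      ds, members[[i]], cfg = cfg, seed = derive_seed(seed, 100L, i),
      linear = linear)
    reports[[i]]$cluster <- as.integer(names(members)[i])
    if (verbose && i %% 50L == 0L)
      dsaf_log("AE selection: cluster ", i, "/", length(members))
  }
  reports
}

#' Tabulate reconstruction reports
#'
#' @param reports List of `ReconstructionReport`s from
#'   [select_all_representatives()].
#' @return data.frame with columns `cluster`, `gene_id`,
#'   `reconstruction_error` (one row per cluster, the representative).
#' @export
representatives_table <- function(reports) {
  data.frame(
    cluster = vapply(reports, function(r) r$cluster %||% NA_integer_, integer(1)),
    gene_id = vapply(reports, function(r) r$representative, character(1)),
    reconstruction_error = vapply(
      reports, function(r) unname(r$errors[r$representative]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

# Affine rank-b reconstruction errors: column mean plus rank-b truncated
# SVD of the column-centered sub-matrix. This is the optimum a
# linear-activation autoencoder with biases and bottleneck b converges to
# under squared error, so it is the closed-form oracle for selection in
# the linear limit. Errors are reported as MAE for comparability.
svd_reconstruction_errors <- function(ds, cluster, bottleneck,
                                      standardize = FALSE) {
  X <- ds$values[cluster, , drop = FALSE]
  mu <- colMeans(X)
  if (standardize) {
    sdv <- apply(X, 2L, stats::sd)
    sdv[is.na(sdv) | sdv == 0] <- 1
  } else {
    sdv <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
  sv <- svd(Xs)
  b <- min(bottleneck, length(sv$d))
  recon <- sv$u[, seq_len(b), drop = FALSE] %*%
    (sv$d[seq_len(b)] * t(sv$v[, seq_len(b), drop = FALSE]))
  recon_orig <- sweep(sweep(recon, 2L, sdv, "*"), 2L, mu, "+")
  errors <- rowMeans(abs(recon_orig - X))
  names(errors) <- cluster
  errors
}
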