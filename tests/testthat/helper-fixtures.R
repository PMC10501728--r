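# Shared fixture builders; everything is generated in code, nothing stored.

# tiny labeled dataset with `n_signal` genes separating the classes
make_toy_dataset <- function(n_genes = 10L, n_patients = 40L, n_signal = 3L,
                             shift = 3, seed = 42L) {
  set.seed(seed)
  n0 <- min(n_patients - 1L, max(1L, floor(n_patients * 0.55)))
  y <- rep(c(0L, 1L), c(n0, n_patients - n0))
  X <- matrix(rnorm(n_genes * n_patients), n_genes, n_patients)
  if (n_signal > 0)
    X[seq_len(n_signal), y == 1L] <- X[seq_len(n_signal), y == 1L] + shift
  rownames(X) <- sprintf("G%02d", seq_len(n_genes))
  colnames(X) <- sprintf("P%02d", seq_len(n_patients))
  expression_dataset(X, labels = stats::setNames(y, colnames(X)))
}

# 5-gene cluster: one noiseless copy of a common pattern + 4 noisy copies
make_centroid_cluster <- function(p = 15L, noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  pattern <- rnorm(p)
  X <- rbind(clean = pattern,
             n1 = pattern + rnorm(p, sd = noise_sd),
             n2 = pattern + rnorm(p, sd = noise_sd),
             n3 = pattern + rnorm(p, sd = noise_sd),
             n4 = pattern + rnorm(p, sd = noise_sd))
  colnames(X) <- sprintf("P%02d", seq_len(p))
  expression_dataset(X)
}

# write a small expression TSV + label TSV to a temp dir; returns the paths
write_toy_files <- function(ds, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ep <- file.path(dir, "expr.tsv")
  lp <- file.path(dir, "labels.tsv")
  write_expression_matrix(ds, ep)
  if (!is.null(ds$labels)) write_labels(ds, lp)
  list(expression = ep, labels = lp, dir = dir)
}
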