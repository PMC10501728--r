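#' Shapley kernel weight
#'
#' The coalition weight `(m - 1) / (choose(m, s) * s * (m - s))` under which
#' weighted linear regression on coalition indicators recovers Shapley
#' values. The empty and full coalitions carry infinite weight and are
#' enforced as equality constraints in the solve.
#'
#' @param m Number of features (>= 1).
#' @param s Coalition size, `0 <= s <= m`.
#' @return Positive weight, or `Inf` for `s` in `{0, m}`.
#' @export
shapley_kernel_weight <- function(m, s) {
  if (m < 1) stop("m must be >= 1")
  if (s < 0 || s > m) stop("coalition size s = ", s, " out of range [0, ", m, "]")
  if (s == 0 || s == m) return(Inf)
  (m - 1) / (choose(m, s) * s * (m - s))
}

# Interventional value function: v(S) = mean over background rows of
# f(x with features outside S replaced by the background row). Z is a
# 0/1 coalition matrix (n_coalitions x m); one batched model call.
coalition_values <- function(f, x, background, Z) {
  nb <- nrow(background); m <- ncol(background)
  nc <- nrow(Z)
  big <- background[rep(seq_len(nb), times = nc), , drop = FALSE]
  zrep <- Z[rep(seq_len(nc), each = nb), , drop = FALSE]
  xrep <- matrix(x, nrow = nrow(big), ncol = m, byrow = TRUE)
  big <- zrep * xrep + (1 - zrep) * big
  colnames(big) <- colnames(background)
  vals <- f(big)
  rowMeans(matrix(vals, nrow = nc, byrow = TRUE))
}

# Deterministic coalition design: enumerate complete size pairs (1, m-1),
# (2, m-2), ... while the budget allows, then sample the remaining budget
# from the residual sizes proportionally to the kernel mass.
sample_coalitions <- function(m, budget, seed) {
  total <- 2^m - 2
  if (m <= 15 && (is.null(budget) || budget >= total)) {
    Z <- matrix(0L, total, m)
    for (i in seq_len(total)) Z[i, ] <- as.integer(intToBits(i)[seq_len(m)])
    return(list(Z = Z, w = vapply(rowSums(Z), function(s)
      shapley_kernel_weight(m, s), numeric(1))))
  }
  if (is.null(budget)) budget <- 2L * m + 2048L
  sizes <- seq_len(m - 1L)
  counts <- choose(m, sizes)
  Zrows <- list(); wrows <- numeric(0)
  remaining <- budget
  done <- rep(FALSE, length(sizes))
  # pair sizes from the outside in; each full size costs choose(m, s) rows
  pair_order <- unique(as.vector(rbind(sizes, rev(sizes))))
  for (s in pair_order) {
    if (done[s]) next
    if (counts[s] <= remaining) {
      combs <- utils::combn(m, s)
      Zs <- matrix(0L, ncol(combs), m)
      Zs[cbind(rep(seq_len(ncol(combs)), each = s), as.vector(combs))] <- 1L
      Zrows[[length(Zrows) + 1L]] <- Zs
      wrows <- c(wrows, rep(shapley_kernel_weight(m, s), nrow(Zs)))
      remaining <- remaining - nrow(Zs)
      done[s] <- TRUE
    }
  }
  if (remaining > 0 && !all(done)) {
    open_sizes <- sizes[!done]
    mass <- (m - 1) / (open_sizes * (m - open_sizes))
    with_seed(seed, {
      draw_s <- sample(open_sizes, remaining, replace = TRUE,
                       prob = mass / sum(mass))
      Zs <- matrix(0L, remaining, m)
      for (i in seq_len(remaining)) {
        Zs[i, sample.int(m, draw_s[i])] <- 1L
      }
      # deduplicate, keeping analytic kernel weights
      key <- apply(Zs, 1L, paste, collapse = "")
      keep <- !duplicated(key)
      Zs <- Zs[keep, , drop = FALSE]
      Zrows[[length(Zrows) + 1L]] <- Zs
      wrows <- c(wrows, vapply(rowSums(Zs), function(s)
        shapley_kernel_weight(m, s), numeric(1)))
    })
  }
  list(Z = do.call(rbind, Zrows), w = wrows)
}

#' Kernel SHAP attribution for one instance
#'
#' Estimates Shapley values by weighted least squares over coalition
#' indicators under the Shapley kernel, with masked features replaced by
#' background values (averaged over background rows) and the efficiency
#' constraint `sum(phi) = f(x) - base` eliminated into the solve. All
#' `2^m - 2` coalitions are enumerated when `m <= 15` (then the result is
#' exact); otherwise a deterministic seeded design of `n_coalitions` rows
#' is used.
#'
#' @param f Prediction function: matrix of rows -> numeric scores.
#' @param x Numeric instance vector (length m >= 1).
#' @param background Background matrix (rows are reference samples, m
#'   columns).
#' @param n_coalitions Sampling budget when `m > 15` (default `2m + 2048`).
#' @param seed Seed for the sampled design.
#' @return List with `phi` (length-m attribution vector), `base_value`
#'   (mean model output over the background) and `fx` (= `f(x)`).
#' @export
kernel_shap <- function(f, x, background, n_coalitions = NULL, seed = 1L) {
  x <- as.numeric(x)
  m <- length(x)
  if (m == 0L) stop("instance has no features")
  background <- as.matrix(background)
  if (nrow(background) == 0L) stop("empty background")
  stopifnot(ncol(background) == m)
  base <- mean(f(background))
  fx <- as.numeric(f(matrix(x, nrow = 1L,
                            dimnames = list(NULL, colnames(background)))))
  if (m == 1L) return(list(phi = fx - base, base_value = base, fx = fx))
  des <- sample_coalitions(m, n_coalitions, seed)
  v <- coalition_values(f, x, background, des$Z)
  # eliminate phi_m via the efficiency constraint:
  # y - z_m (fx - base) = (z_i - z_m) phi_{1..m-1}
  y <- v - base
  zm <- des$Z[, m]
  A <- des$Z[, -m, drop = FALSE] - zm
  yy <- y - zm * (fx - base)
  Wd <- des$w
  AtW <- t(A * Wd)
  M <- AtW %*% A
  rhs <- AtW %*% yy
  phi_head <- tryCatch(
    solve(M, rhs),
    error = function(e) {
      warning("singular Kernel SHAP design; ridge fallback applied")
      solve(M + diag(1e-8, nrow(M)), rhs)
    })
  phi <- c(as.numeric(phi_head), (fx - base) - sum(phi_head))
  list(phi = phi, base_value = base, fx = fx)
}

#' Exact Shapley values by coalition enumeration
#'
#' The definitional computation: `phi_i = sum_S |S|! (m - |S| - 1)! / m! *
#' (v(S u {i}) - v(S))` with the same interventional value function as
#' [kernel_shap()]. Cost is `2^m` model-call batches, so `m <= 15` is
#' enforced.
#'
#' @param f Prediction function: matrix of rows -> numeric scores.
#' @param x Numeric instance vector (length m, `m <= 15`).
#' @param background Background matrix.
#' @return List with `phi`, `base_value`, `fx`.
#' @export
exact_shapley <- function(f, x, background) {
  x <- as.numeric(x)
  m <- length(x)
  if (m == 0L) stop("instance has no features")
  if (m > 15L) stop("m = ", m, " too large for enumeration; use kernel_shap()")
  background <- as.matrix(background)
  stopifnot(ncol(background) == m)
  n_sets <- 2^m
  Z <- matrix(0L, n_sets, m)
  for (i in seq_len(n_sets)) Z[i, ] <- as.integer(intToBits(i - 1L)[seq_len(m)])
  v <- coalition_values(f, x, background, Z)
  sizes <- rowSums(Z)
  # weight of S (the coalition excluding i); the full set never occurs as S
  wt <- numeric(n_sets)
  proper <- sizes < m
  wt[proper] <- factorial(sizes[proper]) * factorial(m - sizes[proper] - 1) /
    factorial(m)
  phi <- numeric(m)
  for (i in seq_len(m)) {
    without <- which(Z[, i] == 0L)
    with_i <- without + 2^(i - 1L)
    phi[i] <- sum(wt[without] * (v[with_i] - v[without]))
  }
  list(phi = phi, base_value = v[1L], fx = v[n_sets])
}

#' Explain a trained classifier over a patient set
#'
#' Draws a seeded background subsample of patients (default 100, without
#' replacement, clipped to the cohort size), computes per-patient Kernel
#' SHAP attributions of the model's sigmoid score, and summarizes each
#' gene by its mean absolute attribution.
#'
#' @param model A `TrainedClassifier`.
#' @param ds A (labeled or unlabeled) `ExpressionDataset` containing the
#'   model's genes.
#' @param background_size Background subsample size B (default 100).
#' @param patients Patient ids to explain; the default explains the
#'   background subsample itself.
#' @param n_coalitions Coalition budget passed to [kernel_shap()].
#' @param seed Seed for the background draw and coalition sampling.
#' @param verbose Progress logging.
#' @return A `ShapExplanation`: list with `gene_ids`, `background_ids`,
#'   `base_value`, `phi` (patients x genes matrix), `X` (explained
#'   expression values), `mean_abs` (named vector).
#' @export
explain_classifier <- function(model, ds, background_size = 100L,
                               patients = NULL, n_coalitions = NULL,
                               seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "TrainedClassifier"), inherits(ds, "ExpressionDataset"))
  X <- t(ds$values[model$gene_ids, , drop = FALSE])  # patients x genes
  n <- nrow(X)
  b <- min(as.integer(background_size), n)
  bg_ids <- with_seed(derive_seed(seed, 31L),
                      sort(sample(ds$patient_ids, b)))
  background <- X[bg_ids, , drop = FALSE]
  if (is.null(patients)) patients <- bg_ids
  stopifnot(all(patients %in% ds$patient_ids))
  f <- function(M) predict(model, M, type = "score")
  m <- length(model$gene_ids)
  phi <- matrix(NA_real_, length(patients), m,
                dimnames = list(patients, model$gene_ids))
  base <- NA_real_
  for (i in seq_along(patients)) {
    ks <- kernel_shap(f, X[patients[i], ], background,
                      n_coalitions = n_coalitions,
                      seed = derive_seed(seed, 37L, i))
    phi[i, ] <- ks$phi
    base <- ks$base_value
    if (verbose && i %% 20L == 0L)
      dsaf_log("SHAP: explained ", i, "/", length(patients), " patients")
  }
  mean_abs <- colMeans(abs(phi))
  structure(list(gene_ids = model$gene_ids, background_ids = bg_ids,
                 base_value = base, phi = phi,
                 X = X[patients, , drop = FALSE], mean_abs = mean_abs,
                 seed = seed),
            class = "ShapExplanation")
}

#' Gene importance ranking from a SHAP explanation
#'
#' @param expl A `ShapExplanation`.
#' @return data.frame with `rank`, `gene_id`, `mean_abs_shap`, ordered by
#'   descending mean absolute attribution (ties by ascending gene id).
#' @export
importance_ranking <- function(expl) {
  stopifnot(inherits(expl, "ShapExplanation"))
  ord <- order(-expl$mean_abs, expl$gene_ids)
  data.frame(rank = seq_along(ord), gene_id = expl$gene_ids[ord],
             mean_abs_shap = unname(expl$mean_abs[ord]),
             stringsAsFactors = FALSE)
}

#' Long-form per-patient SHAP table (beeswarm-style export)
#'
#' @param expl A `ShapExplanation`.
#' @return data.frame with `patient_id`, `gene_id`, `phi`, `expression`.
#' @export
shap_long_table <- function(expl) {
  stopifnot(inherits(expl, "ShapExplanation"))
  data.frame(
    patient_id = rep(rownames(expl$phi), times = ncol(expl$phi)),
    gene_id = rep(colnames(expl$phi), each = nrow(expl$phi)),
    phi = as.vector(expl$phi),
    expression = as.vector(expl$X),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ShapExplanation <- function(x, ...) {
  cat("ShapExplanation:", nrow(x$phi), "patients x", ncol(x$phi), "genes;",
      "base value", sprintf("%.4f", x$base_value), "\n")
  top <- utils::head(importance_ranking(x), 5L)
  cat("  top genes:", paste(sprintf("%s (%.3f)", top$gene_id,
                                    top$mean_abs_shap), collapse = ", "), "\n")
  invisible(x)
}
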