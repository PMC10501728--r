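# small helpers for constructed models
linmod <- function(w, b = 0) function(M) as.numeric(M %*% w + b)

test_that("Shapley kernel weights match the closed form and pin the boundaries", {
  expect_equal(shapley_kernel_weight(4, 1), 3 / (4 * 1 * 3))
  expect_equal(shapley_kernel_weight(4, 1), 0.25)
  expect_equal(shapley_kernel_weight(2, 1), 0.5)
  expect_equal(shapley_kernel_weight(6, 3), 5 / (choose(6, 3) * 9))
  expect_identical(shapley_kernel_weight(5, 0), Inf)
  expect_identical(shapley_kernel_weight(5, 5), Inf)
  expect_error(shapley_kernel_weight(3, 4), "out of range")
  expect_error(shapley_kernel_weight(3, -1), "out of range")
})

test_that("linear models have the closed-form attribution w_i * (x_i - mean(bg_i))", {
  f <- linmod(c(2, 0), b = 1)
  bg <- matrix(0, 2, 2)
  ks <- kernel_shap(f, c(3, 5), bg)
  expect_equal(ks$phi, c(6, 0), tolerance = 1e-10)
  expect_equal(ks$base_value, 1)
  ex <- exact_shapley(f, c(3, 5), bg)
  expect_equal(ex$phi, c(6, 0), tolerance = 1e-10)

  # non-trivial background mean
  set.seed(2)
  w <- c(1.5, -2, 0.7)
  bg2 <- matrix(rnorm(15), 5, 3)
  x <- c(1, 2, 3)
  ks2 <- kernel_shap(linmod(w), x, bg2)
  expect_equal(ks2$phi, w * (x - colMeans(bg2)), tolerance = 1e-8)
})

test_that("dummy features get zero attribution; the AND game splits evenly", {
  f <- function(M) 3 * M[, 1] - M[, 3]
  set.seed(4)
  bg <- matrix(rnorm(12), 4, 3)
  ks <- kernel_shap(f, c(1, 9, 2), bg)
  expect_lt(abs(ks$phi[2]), 1e-6)

  fa <- function(M) as.numeric(M[, 1] > 0.5 & M[, 2] > 0.5)
  ks2 <- kernel_shap(fa, c(1, 1), matrix(0, 1, 2))
  expect_equal(ks2$phi, c(0.5, 0.5), tolerance = 1e-10)
  ex2 <- exact_shapley(fa, c(1, 1), matrix(0, 1, 2))
  expect_equal(ex2$phi, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("kernel regression and exact enumeration agree on 50 random models", {
  set.seed(77)
  worst <- 0
  for (i in 1:50) {
    m <- sample(2:8, 1)
    # random two-layer tanh network: nonlinear, smooth, bounded
    W1 <- matrix(rnorm(m * 4), m, 4); b1 <- rnorm(4)
    w2 <- rnorm(4)
    f <- function(M) as.numeric(tanh(sweep(M %*% W1, 2, b1, "+")) %*% w2)
    bg <- matrix(rnorm(3 * m), 3, m)
    x <- rnorm(m)
    ks <- kernel_shap(f, x, bg)
    ex <- exact_shapley(f, x, bg)
    worst <- max(worst, max(abs(ks$phi - ex$phi)))
    # efficiency for both solvers
    expect_lt(abs(sum(ks$phi) + ks$base_value - ks$fx), 1e-6)
    expect_lt(abs(sum(ex$phi) + ex$base_value - ex$fx), 1e-6)
  }
  expect_lt(worst, 1e-6)
})

test_that("symmetric models on symmetric inputs get equal attributions", {
  f <- function(M) M[, 1] + M[, 2] + 0.5 * M[, 1] * M[, 2]
  bg <- matrix(c(0, 0), 1, 2)
  ex <- exact_shapley(f, c(2, 2), bg)
  expect_equal(ex$phi[1], ex$phi[2], tolerance = 1e-10)
})

test_that("the sampled-design path stays deterministic and near the enumerated result", {
  set.seed(8)
  m <- 12L
  w <- rnorm(m)
  f <- linmod(w)
  bg <- matrix(rnorm(5 * m), 5, m)
  x <- rnorm(m)
  s1 <- kernel_shap(f, x, bg, n_coalitions = 600L, seed = 4L)
  s2 <- kernel_shap(f, x, bg, n_coalitions = 600L, seed = 4L)
  expect_identical(s1$phi, s2$phi)
  full <- kernel_shap(f, x, bg)
  expect_equal(s1$phi, full$phi, tolerance = 1e-6)
  expect_lt(abs(sum(s1$phi) + s1$base_value - s1$fx), 1e-6)
})

test_that("exact enumeration refuses large feature sets; kernel path handles them", {
  expect_error(exact_shapley(function(M) rowSums(M), rnorm(16),
                             matrix(0, 1, 16)), "kernel_shap")
  expect_error(kernel_shap(function(M) rowSums(M), numeric(0),
                           matrix(0, 1, 0)), "no features")
})

test_that("classifier explanations satisfy efficiency and rank planted signal first", {
  ds <- make_toy_dataset(n_genes = 8L, n_patients = 50L, n_signal = 2L,
                         shift = 4, seed = 10L)
  X <- t(ds$values)
  model <- train_classifier(X, ds$labels,
                            classifier_config(hidden = c(8L, 4L), epochs = 150L),
                            seed = 3L)
  expl <- explain_classifier(model, ds, background_size = 25L, seed = 5L)
  expect_identical(dim(expl$phi), c(25L, 8L))
  # efficiency per explained patient
  f <- function(M) predict(model, M, type = "score")
  fx <- f(expl$X)
  expect_lt(max(abs(rowSums(expl$phi) + expl$base_value - fx)), 1e-6)
  # the two planted genes dominate the importance ranking
  rk <- importance_ranking(expl)
  expect_setequal(rk$gene_id[1:2], c("G01", "G02"))
  # determinism
  expl2 <- explain_classifier(model, ds, background_size = 25L, seed = 5L)
  expect_identical(expl2$phi, expl$phi)
})

test_that("importance ranking orders by mean |phi| with lexicographic ties", {
  expl <- structure(list(
    gene_ids = c("g2", "g1", "g3"),
    phi = matrix(c(1, -1, 0.08, 0.08, 0.09, 0.09), nrow = 2,
                 dimnames = list(c("p1", "p2"), c("g2", "g1", "g3"))),
    X = matrix(0, 2, 3, dimnames = list(c("p1", "p2"), c("g2", "g1", "g3"))),
    mean_abs = c(g2 = 1, g1 = 0.08, g3 = 0.09),
    base_value = 0.5, background_ids = c("p1", "p2")),
    class = "ShapExplanation")
  rk <- importance_ranking(expl)
  expect_identical(rk$gene_id, c("g2", "g3", "g1"))
  # all-zero phi -> pure lexicographic order
  expl$mean_abs <- c(g2 = 0, g1 = 0, g3 = 0)
  expect_identical(importance_ranking(expl)$gene_id, c("g1", "g2", "g3"))
  # long-form export carries one row per patient x gene
  lt <- shap_long_table(expl)
  expect_identical(nrow(lt), 6L)
  expect_identical(unique(lt$gene_id), c("g2", "g1", "g3"))
})
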