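test_that("generation is deterministic and matches the requested shape", {
  spec <- synthetic_spec(n_patients = 60L, n_genes = 200L, n_clusters = 10L,
                         n_informative = 5L, effect_size = 1.2,
                         class_balance = c(33L, 27L), seed = 21L)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$dataset$values, c2$dataset$values)
  expect_identical(c1$dataset$labels, c2$dataset$labels)
  expect_identical(c1$informative_genes, c2$informative_genes)
  expect_identical(dim(c1$dataset$values), c(200L, 60L))
  expect_identical(as.integer(table(c1$dataset$labels)), c(33L, 27L))
  expect_length(c1$informative_genes, 5L)
  expect_length(unique(c1$cluster_map[c1$informative_genes]), 5L)  # spread
  # the default spec mirrors the reference cohort shape
  def <- synthetic_spec()
  expect_identical(def$n_genes, 19367L)
  expect_identical(def$n_patients, 217L)
  expect_identical(def$class_balance, c(120L, 97L))
  expect_identical(def$n_clusters, 500L)
})

test_that("infeasible specifications are rejected", {
  expect_error(synthetic_spec(n_genes = 5L, n_informative = 6L), "n_informative")
  expect_error(synthetic_spec(n_patients = 10L, class_balance = c(5L, 6L)), "sum")
  expect_error(synthetic_spec(within_cluster_r = 1), "within_cluster_r")
  expect_error(synthetic_spec(n_genes = 10L, n_clusters = 11L), "clusters")
})

test_that("within-block correlation approaches the target and between-block is near zero", {
  spec <- synthetic_spec(n_patients = 120L, n_genes = 120L, n_clusters = 4L,
                         n_informative = 0L, effect_size = 0,
                         within_cluster_r = 0.9, class_balance = c(60L, 60L),
                         seed = 8L)
  coh <- generate_cohort(spec)
  cm <- pearson_correlation(coh$dataset)$r
  blocks <- split(names(coh$cluster_map), coh$cluster_map)
  within <- unlist(lapply(blocks, function(g) {
    sub <- cm[g, g]
    sub[upper.tri(sub)]
  }))
  expect_lt(abs(mean(within) - 0.9), 0.1)
  # average over all block pairs: single pairs inherit the sampling noise of
  # one factor-factor correlation
  pairs <- utils::combn(length(blocks), 2)
  between <- unlist(lapply(seq_len(ncol(pairs)), function(j)
    cm[blocks[[pairs[1, j]]], blocks[[pairs[2, j]]]]))
  expect_lt(abs(mean(between)), 0.1)
})

test_that("null effect gives F statistics with the F(1, n-2) null distribution", {
  spec <- synthetic_spec(n_patients = 100L, n_genes = 2000L, n_clusters = 100L,
                         n_informative = 0L, effect_size = 0,
                         class_balance = c(55L, 45L), seed = 13L)
  coh <- generate_cohort(spec)
  f <- dsafgs:::f_statistic_matrix(coh$dataset$values, coh$dataset$labels)
  ks <- suppressWarnings(stats::ks.test(f, stats::pf, 1, 98))
  expect_gt(ks$p.value, 0.01)
})

test_that("informative genes carry systematically larger F than background genes", {
  spec <- synthetic_spec(n_patients = 100L, n_genes = 300L, n_clusters = 20L,
                         n_informative = 10L, effect_size = 1.0,
                         class_balance = c(55L, 45L), seed = 5L)
  coh <- generate_cohort(spec)
  f <- dsafgs:::f_statistic_matrix(coh$dataset$values, coh$dataset$labels)
  inf <- f[coh$informative_genes]
  rest <- f[setdiff(names(f), coh$informative_genes)]
  wt <- stats::wilcox.test(inf, rest, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("the confound flag co-locates all informative genes in one block", {
  spec <- synthetic_spec(n_patients = 50L, n_genes = 100L, n_clusters = 5L,
                         n_informative = 5L, effect_size = 1.5,
                         class_balance = c(25L, 25L), confound = TRUE, seed = 2L)
  coh <- generate_cohort(spec)
  expect_length(unique(coh$cluster_map[coh$informative_genes]), 1L)
})

test_that("written cohorts round-trip through the expression readers", {
  spec <- synthetic_spec(n_patients = 20L, n_genes = 30L, n_clusters = 3L,
                         n_informative = 2L, class_balance = c(11L, 9L),
                         seed = 3L)
  coh <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  ds <- read_expression_matrix(paths$expression)
  ds <- suppressMessages(attach_labels(ds, paths$labels))
  expect_equal(ds$values, coh$dataset$values)
  expect_identical(ds$labels, coh$dataset$labels)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_identical(truth$informative_genes, coh$informative_genes)
})
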