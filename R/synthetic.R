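#' Specification of a synthetic expression cohort
#'
#' Describes a seeded cohort with block-correlated genes and a small set of
#' label-informative genes. The defaults emulate the reference study shape:
#' 19,367 genes x 217 patients with a 120 / 97 class split and 500
#' correlation blocks.
#'
#' Genes are drawn from a latent-factor block model: gene g in block b is
#' `sqrt(r) * factor_b + sqrt(1 - r) * noise_g`, scaled by `noise_sd`, so
#' the within-block correlation is approximately `within_cluster_r` and the
#' between-block correlation is ~0. Label-informative structure is planted
#' as outcome-associated modules with a hub gene: in each informative
#' block the latent factor receives a class shift, and the planted gene is
#' the block's hub — loading 1 on the (shifted) factor with no
#' idiosyncratic noise — so its class-mean separation is exactly
#' `effect_size` within-class standard deviations while the remaining
#' block members carry the attenuated shift `sqrt(r) * effect_size`. The
#' hub is also the block member an autoencoder reconstructs best, which is
#' what makes planted genes recoverable by reconstruction-based
#' representative selection.
#'
#' @param n_patients,n_genes,n_clusters Cohort dimensions.
#' @param n_informative Number of label-associated genes.
#' @param effect_size Class-mean shift in within-class sd units.
#' @param within_cluster_r Target within-block correlation in `[0, 1)`.
#'   The default 0.9 models blocks of *redundant* genes (near-duplicate
#'   probes / tightly co-regulated transcripts) — the regime the
#'   redundancy-removal stage is designed to collapse; at substantially
#'   lower correlation the members of a block are not interchangeable and
#'   no single representative can stand in for the block.
#' @param class_balance Length-2 integer vector `(n0, n1)` summing to
#'   `n_patients`.
#' @param noise_sd Marginal sd of every gene.
#' @param confound If `TRUE`, all informative genes are co-located in the
#'   first block (stress test); by default they are spread across distinct
#'   blocks.
#' @param seed Integer seed; generation is fully deterministic.
#' @return A `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_patients = 217L, n_genes = 19367L,
                           n_clusters = 500L, n_informative = 10L,
                           effect_size = 1.0, within_cluster_r = 0.9,
                           class_balance = c(120L, 97L), noise_sd = 1.0,
                           confound = FALSE, seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               n_genes = as.integer(n_genes),
               n_clusters = as.integer(n_clusters),
               n_informative = as.integer(n_informative),
               effect_size = effect_size,
               within_cluster_r = within_cluster_r,
               class_balance = as.integer(class_balance),
               noise_sd = noise_sd, confound = isTRUE(confound),
               seed = as.integer(seed))
  if (spec$n_informative > spec$n_genes)
    stop("n_informative exceeds n_genes")
  if (sum(spec$class_balance) != spec$n_patients)
    stop("class_balance must sum to n_patients")
  if (spec$within_cluster_r < 0 || spec$within_cluster_r >= 1)
    stop("within_cluster_r must lie in [0, 1)")
  if (spec$n_clusters > spec$n_genes) stop("more clusters than genes")
  if (spec$noise_sd <= 0) stop("noise_sd must be positive")
  structure(spec, class = "SyntheticSpec")
}

#' Generate a synthetic cohort
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (labeled `ExpressionDataset`),
#'   `informative_genes` (planted gene ids) and `cluster_map` (named
#'   integer vector, gene id -> true block).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  n <- spec$n_patients; g <- spec$n_genes; k <- spec$n_clusters
  gene_ids <- sprintf("G%0*d", nchar(g), seq_len(g))
  patient_ids <- sprintf("P%0*d", nchar(n), seq_len(n))
  block <- rep(seq_len(k), length.out = g)
  block <- sort(block)  # contiguous near-equal blocks
  names(block) <- gene_ids
  r <- spec$within_cluster_r
  with_seed(spec$seed, {
    labels <- sample(rep(c(0L, 1L), times = spec$class_balance))
    names(labels) <- patient_ids
    factors <- matrix(stats::rnorm(k * n), nrow = k)  # block x patient
    noise <- matrix(stats::rnorm(g * n), nrow = g)
    informative <- character(0)
    inf_blocks <- integer(0)
    if (spec$n_informative > 0L) {
      if (spec$confound) {
        inf_blocks <- rep(1L, spec$n_informative)
        informative <- gene_ids[block == 1L][seq_len(spec$n_informative)]
        if (anyNA(informative))
          stop("first block too small to confound all informative genes")
      } else {
        if (spec$n_informative > k)
          stop("cannot spread ", spec$n_informative,
               " informative genes over ", k, " blocks")
        inf_blocks <- seq_len(spec$n_informative)
        informative <- vapply(inf_blocks, function(b)
          gene_ids[block == b][1L], character(1))
      }
      # class shift enters the shared factor of each informative block
      for (b in unique(inf_blocks))
        factors[b, ] <- factors[b, ] + spec$effect_size * (labels == 1L)
    }
    values <- (sqrt(r) * factors[block, , drop = FALSE] +
                 sqrt(1 - r) * noise) * spec$noise_sd
    dimnames(values) <- list(gene_ids, patient_ids)
    # hub genes: loading 1 on the shifted factor, no idiosyncratic noise.
    # Under `confound` the planted genes stay ordinary members of one
    # shared block (the stress case: redundancy removal keeps at most one).
    if (length(informative) && !spec$confound)
      values[informative, ] <- factors[block[informative], , drop = FALSE] *
        spec$noise_sd
  })
  ds <- expression_dataset(values, gene_ids, patient_ids, labels = labels)
  list(dataset = ds, informative_genes = informative, cluster_map = block,
       spec = spec)
}

#' Write a synthetic cohort to disk
#'
#' Emits the exact formats the readers consume — the expression TSV, the
#' two-column label TSV — plus a ground-truth JSON (informative genes,
#' block map, spec echo).
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                labels = file.path(dir, "labels.tsv"),
                truth = file.path(dir, "ground_truth.json"))
  write_expression_matrix(cohort$dataset, paths$expression)
  write_labels(cohort$dataset, paths$labels)
  jsonlite::write_json(
    list(informative_genes = cohort$informative_genes,
         cluster_map = as.list(cohort$cluster_map),
         spec = unclass(cohort$spec)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
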