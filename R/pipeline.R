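#' Pipeline run configuration
#'
#' All defaults reproduce the reference protocol: 500 correlation clusters,
#' candidate subset sizes 5/10/50/100/300, autoencoders 1000 epochs at
#' learning rate 0.01, the 18-configuration classifier grid at learning
#' rate 0.001, 10 Monte-Carlo cross-validation iterations at a 90/10
#' split, SMOTE on training folds only, and a 100-patient SHAP background.
#'
#' @param k_clusters Number of gene clusters.
#' @param subset_sizes Candidate top-k subset sizes for the F ranking.
#' @param linkage Hierarchical clustering linkage method.
#' @param dissimilarity `"signed"` (`1 - r`) or `"abs"` (`1 - |r|`).
#' @param ae List of autoencoder overrides: `epochs`, `lr`, `batch_size`,
#'   `standardize`.
#' @param grid List of classifier-grid overrides: `depths`, `first_widths`,
#'   `epochs`, `lr`, `batch_size`.
#' @param cv List: `iterations`, `test_frac`, `smote_k`.
#' @param shap List: `background`, `budget` (`NULL` = enumerate when
#'   feasible, else `2m + 2048`).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param verbose Progress logging.
#' @return A `RunConfig` list.
#' @export
run_config <- function(k_clusters = 500L,
                       subset_sizes = c(5L, 10L, 50L, 100L, 300L),
                       linkage = "average",
                       dissimilarity = "signed",
                       ae = list(), grid = list(), cv = list(), shap = list(),
                       seed = 1L, verbose = TRUE) {
  ae_def <- list(epochs = 1000L, lr = 0.01, batch_size = 32L, standardize = FALSE)
  grid_def <- list(depths = c(2L, 3L, 4L),
                   first_widths = c(8L, 16L, 32L, 64L, 128L, 256L),
                   epochs = 200L, lr = 0.001, batch_size = 32L)
  cv_def <- list(iterations = 10L, test_frac = 0.10, smote_k = 5L)
  shap_def <- list(background = 100L, budget = NULL)
  structure(list(k_clusters = as.integer(k_clusters),
                 subset_sizes = sort(as.integer(subset_sizes)),
                 linkage = linkage, dissimilarity = dissimilarity,
                 ae = utils::modifyList(ae_def, ae),
                 grid = utils::modifyList(grid_def, grid),
                 cv = utils::modifyList(cv_def, cv),
                 shap = utils::modifyList(shap_def, shap, keep.null = TRUE),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "RunConfig")
}

#' Run the full gene-selection pipeline
#'
#' Executes the six stages end to end on a labeled dataset: (1) gene-gene
#' Pearson correlation, (2) hierarchical partition into `k_clusters`
#' clusters, (3) autoencoder representative per cluster, (4) F-statistic
#' ranking of the representatives and truncation to each candidate subset
#' size, (5) grid-searched Monte-Carlo cross-validated classifier per
#' subset size — the best subset size is the one whose chosen
#' configuration attains the highest mean cv accuracy (ties: smaller
#' size) — and (6) Kernel SHAP attribution of the best model.
#'
#' When `out_dir` is given every stage is checkpointed as TSV/JSON; with
#' `resume = TRUE` the expensive stages (partition, representatives) are
#' reloaded from their checkpoints when present.
#'
#' @param ds A labeled `ExpressionDataset`.
#' @param config A [run_config()].
#' @param out_dir Optional output/checkpoint directory.
#' @param resume Reuse existing stage checkpoints in `out_dir`.
#' @return A `RunReport`: list with `representatives`, `rankings` (one
#'   `GeneRanking` per subset size), `accuracy_table` (per-size mean/sd/95%
#'   interval and the best iteration accuracy), `best_size`,
#'   `best_config`, `model`, `evaluation` (confusion/ROC/AUC of the best
#'   model on its held-out test split), `shap` (`ShapExplanation`),
#'   `shap_ranking`, `seeds` used per stage, and `timestamp`.
#' @export
run_pipeline <- function(ds, config = run_config(), out_dir = NULL,
                         resume = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(config, "RunConfig"))
  if (is.null(ds$labels)) stop("stage input: dataset has no labels")
  verbose <- config$verbose
  ckpt <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir, name)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(master = config$seed,
                ae = derive_seed(config$seed, 3L),
                cv = derive_seed(config$seed, 5L),
                shap = derive_seed(config$seed, 9L))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # stages 1-2: correlation + partition
  part_file <- ckpt("partition.tsv")
  if (resume && !is.null(part_file) && file.exists(part_file)) {
    dsaf_log("resuming partition from checkpoint", verbose = verbose)
    part <- read_partition(part_file)
  } else {
    dsaf_log("stage 1: gene-gene Pearson correlation", verbose = verbose)
    cm <- run_stage("correlation", pearson_correlation(ds))
    dsaf_log("stage 2: hierarchical partition into k = ", config$k_clusters,
             verbose = verbose)
    part <- run_stage("clustering",
                      hierarchical_partition(cm, config$k_clusters,
                                             linkage = config$linkage,
                                             dissimilarity = config$dissimilarity))
    rm(cm)
    if (!is.null(part_file)) write_partition(part, part_file)
  }

  # stage 3: AE representative per cluster
  rep_file <- ckpt("representatives.tsv")
  if (resume && !is.null(rep_file) && file.exists(rep_file)) {
    dsaf_log("resuming representatives from checkpoint", verbose = verbose)
    rep_tab <- as.data.frame(data.table::fread(rep_file))
  } else {
    dsaf_log("stage 3: autoencoder representatives (", config$k_clusters,
             " clusters)", verbose = verbose)
    ae_cfg <- build_ae_architecture(length(ds$patient_ids),
                                    epochs = config$ae$epochs,
                                    lr = config$ae$lr,
                                    batch_size = config$ae$batch_size,
                                    standardize = config$ae$standardize)
    reports <- run_stage("ae_selection",
                         select_all_representatives(ds, part, cfg = ae_cfg,
                                                    seed = seeds$ae,
                                                    verbose = verbose))
    rep_tab <- representatives_table(reports)
    if (!is.null(rep_file))
      data.table::fwrite(rep_tab, rep_file, sep = "\t")
  }
  representatives <- rep_tab$gene_id

  # stage 4: F ranking of representatives, per candidate size
  dsaf_log("stage 4: F-statistic ranking of ", length(representatives),
           " representatives", verbose = verbose)
  sizes <- config$subset_sizes[config$subset_sizes <= length(representatives)]
  if (length(sizes) == 0L)
    stop("no candidate subset size fits the number of representatives")
  full_ranking <- run_stage("ranking",
                            rank_and_select(ds, representatives,
                                            k = length(representatives)))
  rankings <- lapply(sizes, function(k) full_ranking[seq_len(k), ])
  names(rankings) <- as.character(sizes)
  if (!is.null(out_dir))
    for (k in sizes)
      write_ranking(rankings[[as.character(k)]],
                    file.path(out_dir, sprintf("ranking_top%d.tsv", k)))

  # stage 5: grid search per subset size
  grid <- enumerate_grid(depths = config$grid$depths,
                         first_widths = config$grid$first_widths,
                         lr = config$grid$lr, epochs = config$grid$epochs,
                         batch_size = config$grid$batch_size)
  per_size <- vector("list", length(sizes))
  names(per_size) <- as.character(sizes)
  for (k in sizes) {
    dsaf_log("stage 5: grid search, subset size ", k, " (",
             length(grid), " configs x ", config$cv$iterations, " cv)",
             verbose = verbose)
    ds_k <- subset_genes(ds, rankings[[as.character(k)]]$gene_id)
    per_size[[as.character(k)]] <- run_stage(
      paste0("grid_search_k", k),
      grid_search_select(ds_k, grid = grid,
                         iterations = config$cv$iterations,
                         test_frac = config$cv$test_frac,
                         seed = seeds$cv, smote_k = config$cv$smote_k,
                         verbose = FALSE))
  }
  acc_rows <- lapply(as.character(sizes), function(kk) {
    gs <- per_size[[kk]]
    rec <- gs$records[[gs$chosen_index]]
    best_acc <- rec$iterations[[gs$best_iteration]]$accuracy
    data.frame(n_genes = as.integer(kk), mean_accuracy = rec$mean,
               sd_accuracy = rec$sd, ci_lower = rec$ci[["lower"]],
               ci_upper = rec$ci[["upper"]], best_accuracy = best_acc,
               hidden = paste(gs$config$hidden, collapse = "-"))
  })
  accuracy_table <- do.call(rbind, acc_rows)
  best_row <- order(-accuracy_table$mean_accuracy, accuracy_table$n_genes)[1L]
  best_size <- accuracy_table$n_genes[best_row]
  best <- per_size[[as.character(best_size)]]
  dsaf_log("best subset size: ", best_size, " genes (mean cv accuracy ",
           sprintf("%.3f", accuracy_table$mean_accuracy[best_row]), ")",
           verbose = verbose)
  if (!is.null(out_dir))
    data.table::fwrite(accuracy_table, file.path(out_dir, "accuracy_table.tsv"),
                       sep = "\t")

  # evaluate the best model on its held-out test split
  ds_best <- subset_genes(ds, best$model$gene_ids)
  rec <- best$records[[best$chosen_index]]
  test_ids <- rec$iterations[[best$best_iteration]]$test_ids
  Xt <- t(ds_best$values[, test_ids, drop = FALSE])
  evaluation <- run_stage("evaluation",
                          evaluate_classifier(best$model, Xt,
                                              ds$labels[test_ids]))

  # stage 6: SHAP attribution of the best model
  dsaf_log("stage 6: Kernel SHAP attribution (", length(best$model$gene_ids),
           " genes, background ", config$shap$background, ")", verbose = verbose)
  expl <- run_stage("shap",
                    explain_classifier(best$model, ds,
                                       background_size = config$shap$background,
                                       n_coalitions = config$shap$budget,
                                       seed = seeds$shap, verbose = verbose))
  shap_ranking <- importance_ranking(expl)

  report <- structure(
    list(config = config, seeds = seeds,
         representatives = rep_tab, rankings = rankings,
         accuracy_table = accuracy_table,
         best_size = best_size, best_config = best$config,
         model = best$model, test_ids = test_ids,
         evaluation = evaluation, shap = expl, shap_ranking = shap_ranking,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "RunReport")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a run report to a directory
#'
#' Emits `report.json` plus TSV duplicates of every table (accuracy table,
#' representatives, SHAP ranking, per-patient SHAP values, ROC points) and
#' the persisted best model.
#'
#' @param report A `RunReport`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "RunReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(report$accuracy_table,
                     file.path(dir, "accuracy_table.tsv"), sep = "\t")
  data.table::fwrite(report$representatives,
                     file.path(dir, "representatives.tsv"), sep = "\t")
  data.table::fwrite(report$shap_ranking,
                     file.path(dir, "shap_mean_abs.tsv"), sep = "\t")
  data.table::fwrite(shap_long_table(report$shap),
                     file.path(dir, "shap_values_long.tsv"), sep = "\t")
  data.table::fwrite(report$evaluation$roc, file.path(dir, "roc_points.tsv"),
                     sep = "\t")
  save_classifier(report$model, file.path(dir, "best_model"))
  json <- list(
    best_size = report$best_size,
    best_hidden = report$best_config$hidden,
    accuracy_table = report$accuracy_table,
    confusion = as.list(report$evaluation$counts),
    accuracy = report$evaluation$accuracy,
    sensitivity = report$evaluation$sensitivity,
    specificity = report$evaluation$specificity,
    auc = report$evaluation$auc,
    shap_base_value = report$shap$base_value,
    shap_top = utils::head(report$shap_ranking, 20L),
    seeds = report$seeds,
    timestamp = report$timestamp
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (seed ", x$seeds$master, ")\n", sep = "")
  cat("  best subset size:", x$best_size, "genes; hidden layers (",
      paste(x$best_config$hidden, collapse = ", "), ")\n")
  print(x$accuracy_table, row.names = FALSE)
  cat(sprintf("  held-out: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
              x$evaluation$accuracy, x$evaluation$sensitivity,
              x$evaluation$specificity, x$evaluation$auc))
  cat("  top SHAP genes:",
      paste(utils::head(x$shap_ranking$gene_id, 5L), collapse = ", "), "\n")
  invisible(x)
}
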