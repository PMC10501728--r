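#' One-way F statistic for two groups
#'
#' The classical one-way ANOVA ratio of between-group to within-group mean
#' squares, here with g = 2 groups: `F = (SSB / 1) / (SSW / (n - 2))`. For
#' two groups it equals the square of the pooled-variance two-sample t
#' statistic. A zero within-group sum of squares with unequal means yields
#' `Inf` (such genes sort above every finite value); zero between- and
#' within-group sums of squares yield 0 with a warning.
#'
#' @param values0 Numeric vector, observations in group 0 (>= 1 value).
#' @param values1 Numeric vector, observations in group 1 (>= 1 value).
#' @return Non-negative scalar (possibly `Inf`).
#' @export
f_statistic <- function(values0, values1) {
  n0 <- length(values0); n1 <- length(values1)
  if (n0 < 1L || n1 < 1L) stop("each group needs at least one observation")
  if (n0 + n1 < 3L) stop("need at least 3 observations in total")
  m0 <- mean(values0); m1 <- mean(values1)
  gm <- (n0 * m0 + n1 * m1) / (n0 + n1)
  ssb <- n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2
  ssw <- sum((values0 - m0)^2) + sum((values1 - m1)^2)
  if (ssw == 0) {
    if (ssb == 0) {
      warning("all observations identical; F defined as 0")
      return(0)
    }
    return(Inf)
  }
  (ssb / 1) / (ssw / (n0 + n1 - 2))
}

# Vectorized per-gene F over a genes x patients matrix and a 0/1 label
# vector; same conventions as f_statistic().
f_statistic_matrix <- function(values, labels) {
  i0 <- labels == 0L; i1 <- labels == 1L
  n0 <- sum(i0); n1 <- sum(i1)
  n <- n0 + n1
  m0 <- rowMeans(values[, i0, drop = FALSE])
  m1 <- rowMeans(values[, i1, drop = FALSE])
  gm <- (n0 * m0 + n1 * m1) / n
  ssb <- n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2
  ssw <- rowSums((values[, i0, drop = FALSE] - m0)^2) +
    rowSums((values[, i1, drop = FALSE] - m1)^2)
  f <- ifelse(ssw == 0, ifelse(ssb == 0, 0, Inf), ssb / (ssw / (n - 2)))
  if (any(ssw == 0 & ssb == 0))
    warning(sum(ssw == 0 & ssb == 0), " gene(s) with all-identical values; F = 0")
  names(f) <- rownames(values)
  f
}

#' Rank genes by F statistic and keep the top k
#'
#' Computes the per-gene two-group F statistic over the event label, orders
#' genes by descending F (Inf first; ties broken by ascending gene id) and
#' returns the first `k`.
#'
#' @param ds A labeled `ExpressionDataset`.
#' @param genes Gene ids to rank (default: all genes in `ds`).
#' @param k Number of genes to keep, `1 <= k <= length(genes)`.
#' @return A `GeneRanking`: data.frame with columns `rank`, `gene_id`, `F`,
#'   ordered by rank.
#' @export
rank_and_select <- function(ds, genes = ds$gene_ids, k = length(genes)) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.null(ds$labels)) stop("dataset has no labels; attach_labels() first")
  genes <- as.character(genes)
  missing_g <- setdiff(genes, ds$gene_ids)
  if (length(missing_g)) stop("unknown gene id(s): ", paste(missing_g, collapse = ", "))
  if (k <= 0) stop("k must be positive")
  if (k > length(genes)) stop("k (", k, ") exceeds the number of genes (", length(genes), ")")
  f <- f_statistic_matrix(ds$values[genes, , drop = FALSE], ds$labels)
  ord <- order(-f, genes)
  out <- data.frame(rank = seq_len(k), gene_id = genes[ord][seq_len(k)],
                    F = unname(f[ord])[seq_len(k)], stringsAsFactors = FALSE)
  class(out) <- c("GeneRanking", "data.frame")
  out
}

#' Export a gene ranking as TSV (`rank<TAB>gene_id<TAB>F`)
#'
#' @param ranking A `GeneRanking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  data.table::fwrite(as.data.frame(ranking), path, sep = "\t")
  invisible(path)
}
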