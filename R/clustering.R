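#' Gene-gene Pearson correlation matrix
#'
#' Computes the pairwise Pearson correlation of every gene pair across
#' patients. At genome scale the computation runs in row blocks over
#' standardized rows (`crossprod` of block pairs), which bounds peak working
#' memory while producing results identical to the dense computation.
#'
#' Zero-variance genes have no defined correlation; by default their
#' off-diagonal entries are set to 0 with a warning (`on_zero_variance =
#' "error"` turns this into a hard error).
#'
#' @param ds An `ExpressionDataset` with at least two patients.
#' @param block_size Number of genes per block.
#' @param on_zero_variance `"zero"` (default) or `"error"`.
#' @return An object of class `CorrelationMatrix`: list with `gene_ids` and
#'   `r`, a symmetric matrix with unit diagonal, entries in `[-1, 1]`.
#' @export
pearson_correlation <- function(ds, block_size = 2000L,
                                on_zero_variance = c("zero", "error")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  on_zero_variance <- match.arg(on_zero_variance)
  X <- ds$values
  n <- ncol(X)
  if (n < 2L) stop("need at least 2 patients to correlate genes")
  mu <- rowMeans(X)
  Xc <- X - mu
  ss <- sqrt(rowSums(Xc^2))
  zero_var <- ss == 0
  if (any(zero_var)) {
    if (on_zero_variance == "error")
      stop("zero-variance gene(s): ",
           paste(utils::head(ds$gene_ids[zero_var], 5L), collapse = ", "))
    warning(sum(zero_var), " zero-variance gene(s); their correlations set to 0")
    ss[zero_var] <- 1  # rows are all-zero after centering, so r comes out 0
  }
  Z <- Xc / ss
  g <- nrow(Z)
  r <- matrix(0, g, g, dimnames = list(ds$gene_ids, ds$gene_ids))
  starts <- seq(1L, g, by = block_size)
  for (i in starts) {
    ri <- i:min(i + block_size - 1L, g)
    for (j in starts[starts >= i]) {
      rj <- j:min(j + block_size - 1L, g)
      blk <- tcrossprod(Z[ri, , drop = FALSE], Z[rj, , drop = FALSE])
      r[ri, rj] <- blk
      if (j > i) r[rj, ri] <- t(blk)
    }
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  structure(list(gene_ids = ds$gene_ids, r = r), class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat("CorrelationMatrix:", length(x$gene_ids), "genes\n")
  invisible(x)
}

#' Partition genes by hierarchical clustering of correlation dissimilarity
#'
#' Builds an agglomerative tree on the dissimilarity `1 - r` (signed, so
#' anticorrelated genes are far apart; `1 - |r|` available via
#' `dissimilarity = "abs"`) and cuts it into exactly `k` clusters.
#'
#' @param cm A `CorrelationMatrix`.
#' @param k Number of clusters, `1 <= k <=` number of genes.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (`"average"` default; `"complete"`, `"ward.D2"`, ... accepted).
#' @param dissimilarity `"signed"` for `1 - r` (default) or `"abs"` for
#'   `1 - |r|`.
#' @return An object of class `ClusterPartition`: list with `k`,
#'   `assignment` (named integer vector, gene id -> cluster in `1..k`) and
#'   `merge_heights` (the linkage heights, non-decreasing for average
#'   linkage).
#' @export
hierarchical_partition <- function(cm, k, linkage = "average",
                                   dissimilarity = c("signed", "abs")) {
  stopifnot(inherits(cm, "CorrelationMatrix"))
  dissimilarity <- match.arg(dissimilarity)
  g <- length(cm$gene_ids)
  if (k <= 0) stop("k must be positive")
  if (k > g) stop("k (", k, ") exceeds the number of genes (", g, ")")
  d <- if (dissimilarity == "signed") 1 - cm$r else 1 - abs(cm$r)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  assignment <- stats::cutree(hc, k = k)
  names(assignment) <- cm$gene_ids
  stopifnot(length(unique(assignment)) == k)
  structure(list(k = as.integer(k), assignment = assignment,
                 merge_heights = hc$height, linkage = linkage,
                 dissimilarity = dissimilarity),
            class = "ClusterPartition")
}

#' @export
print.ClusterPartition <- function(x, ...) {
  cat("ClusterPartition: k =", x$k, "over", length(x$assignment), "genes\n")
  invisible(x)
}

#' Cluster members as a list
#'
#' @param part A `ClusterPartition`.
#' @return List of length `k`; element `i` holds the gene ids of cluster `i`.
#' @export
cluster_members <- function(part) {
  stopifnot(inherits(part, "ClusterPartition"))
  split(names(part$assignment), part$assignment)
}

#' Export a partition as TSV (`gene_id<TAB>cluster`)
#'
#' @param part A `ClusterPartition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  stopifnot(inherits(part, "ClusterPartition"))
  data.table::fwrite(data.table::data.table(gene_id = names(part$assignment),
                                            cluster = unname(part$assignment)),
                     path, sep = "\t")
  invisible(path)
}

read_partition <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  assignment <- as.integer(dt$cluster)
  names(assignment) <- dt$gene_id
  structure(list(k = length(unique(assignment)), assignment = assignment,
                 merge_heights = NULL, linkage = NA_character_,
                 dissimilarity = NA_character_),
            class = "ClusterPartition")
}
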