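#' Construct and validate an expression dataset
#'
#' The canonical in-memory container: a genes x patients matrix of log-scale
#' expression values with unique gene and patient identifiers and, once
#' attached, a binary event label per patient.
#'
#' @param values Numeric matrix, genes as rows and patients as columns.
#' @param gene_ids Character vector of unique gene identifiers (row names).
#' @param patient_ids Character vector of unique patient identifiers
#'   (column names).
#' @param labels Optional named integer vector in \{0, 1\}, one entry per
#'   patient (names must match `patient_ids`). `NULL` for an unlabeled
#'   dataset.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `gene_ids`, `patient_ids`, `labels`.
#' @export
expression_dataset <- function(values, gene_ids = rownames(values),
                               patient_ids = colnames(values), labels = NULL) {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("empty expression matrix")
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(nrow(values)))
  if (is.null(patient_ids)) patient_ids <- paste0("P", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  patient_ids <- as.character(patient_ids)
  if (nrow(values) != length(gene_ids))
    stop("row count (", nrow(values), ") != number of gene ids (", length(gene_ids), ")")
  if (ncol(values) != length(patient_ids))
    stop("column count (", ncol(values), ") != number of patient ids (", length(patient_ids), ")")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- patient_ids[duplicated(patient_ids)]
  if (length(dup)) stop("duplicate patient id(s): ", paste(unique(dup), collapse = ", "))
  if (!is.numeric(values)) stop("expression values must be numeric")
  dimnames(values) <- list(gene_ids, patient_ids)
  if (!is.null(labels)) {
    labels <- .validate_labels(labels, patient_ids)
  }
  structure(list(values = values, gene_ids = gene_ids,
                 patient_ids = patient_ids, labels = labels),
            class = "ExpressionDataset")
}

.validate_labels <- function(labels, patient_ids) {
  if (is.null(names(labels))) {
    if (length(labels) != length(patient_ids))
      stop("unnamed labels must have one entry per patient")
    names(labels) <- patient_ids
  }
  missing_pt <- setdiff(patient_ids, names(labels))
  if (length(missing_pt))
    stop("no label for patient(s): ", paste(missing_pt, collapse = ", "))
  labels <- labels[patient_ids]
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be 0 or 1 with no missing values")
  labels <- as.integer(labels)
  names(labels) <- patient_ids
  if (length(unique(labels)) < 2L)
    stop("both label classes must be represented (at least one 0 and one 1)")
  labels
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", length(x$gene_ids), "genes x",
      length(x$patient_ids), "patients\n")
  if (!is.null(x$labels)) {
    tb <- table(factor(x$labels, levels = c(0, 1)))
    cat("  labels: event=0 n =", tb[["0"]], "; event=1 n =", tb[["1"]], "\n")
  } else {
    cat("  labels: none attached\n")
  }
  invisible(x)
}

#' Read a delimited expression matrix
#'
#' Expects genes in rows: the first column holds gene identifiers and the
#' header row holds patient identifiers. TSV and CSV (optionally
#' gzip-compressed) are auto-detected from the content.
#'
#' @param path Path to a TSV/CSV file (`.gz` accepted).
#' @param transpose If `TRUE`, the file holds patients in rows and is
#'   transposed on read so the returned dataset is genes x patients.
#' @param sep Field separator; `"auto"` lets the reader detect it.
#' @return An unlabeled [expression_dataset()].
#' @export
read_expression_matrix <- function(path, transpose = FALSE, sep = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  if (nrow(dt) == 0L || ncol(dt) < 2L) stop("empty expression matrix: ", path)
  ids <- dt[[1L]]
  body <- dt[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "NA")
      if (length(bad))
        stop("non-numeric value ", dQuote(col[bad[1L]]), " at row ", bad[1L],
             " (id ", ids[bad[1L]], "), column ", dQuote(colnames(body)[j]))
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  expression_dataset(m)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: first column `gene_id`, header row
#' of patient identifiers.
#'
#' @param ds An `ExpressionDataset`.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(ds, path) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  dt <- data.table::data.table(gene_id = ds$gene_ids)
  dt <- cbind(dt, data.table::as.data.table(ds$values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Attach event labels from a two-column file
#'
#' The label file is a headered TSV/CSV mapping `patient_id` to `event`
#' (0 = no event, 1 = event). Every patient in the dataset must be labeled;
#' labels for unknown patients are ignored with a warning.
#'
#' @param ds An `ExpressionDataset`.
#' @param labels_path Path to the label file, or a named vector of labels.
#' @param verbose Log the class counts.
#' @return The labeled dataset.
#' @export
attach_labels <- function(ds, labels_path, verbose = TRUE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.character(labels_path) && length(labels_path) == 1L && file.exists(labels_path)) {
    lab <- data.table::fread(labels_path, header = TRUE, data.table = FALSE,
                             colClasses = list(character = 1L))
    if (ncol(lab) < 2L) stop("label file must have two columns: patient_id, event")
    labels <- lab[[2L]]
    names(labels) <- lab[[1L]]
  } else {
    labels <- labels_path
    if (is.null(names(labels))) stop("labels must be named by patient id or read from file")
  }
  extra <- setdiff(names(labels), ds$patient_ids)
  if (length(extra)) {
    warning("ignoring ", length(extra), " label(s) for unknown patient(s): ",
            paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ..." else "")
    labels <- labels[setdiff(names(labels), extra)]
  }
  out <- expression_dataset(ds$values, ds$gene_ids, ds$patient_ids, labels = labels)
  tb <- table(factor(out$labels, levels = c(0, 1)))
  dsaf_log("labels attached: event=0 n=", tb[["0"]], ", event=1 n=", tb[["1"]],
           verbose = verbose)
  out
}

#' Quality-filter patient profiles
#'
#' Removes patients whose fraction of missing values exceeds
#' `max_missing_frac`, and (optionally) patients whose whole profile is
#' constant (zero variance). Missing values are never imputed.
#'
#' @param ds An `ExpressionDataset`.
#' @param max_missing_frac Maximum tolerated fraction of missing values per
#'   patient, in `[0, 1]`. The default `0` removes any patient with a missing
#'   value.
#' @param drop_zero_variance Remove patients with a constant profile.
#' @param verbose Log removals.
#' @return A list with `dataset` (the filtered `ExpressionDataset`) and
#'   `removed` (character vector of removed patient ids).
#' @export
qc_filter_samples <- function(ds, max_missing_frac = 0, drop_zero_variance = TRUE,
                              verbose = TRUE) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            max_missing_frac >= 0, max_missing_frac <= 1)
  miss_frac <- colMeans(is.na(ds$values))
  bad_miss <- miss_frac > max_missing_frac
  bad_var <- rep(FALSE, ncol(ds$values))
  if (drop_zero_variance) {
    v <- apply(ds$values, 2L, function(col) stats::var(col[!is.na(col)]))
    bad_var <- !is.na(v) & v == 0
  }
  drop <- bad_miss | bad_var
  removed <- ds$patient_ids[drop]
  if (all(drop)) stop("QC removed every patient")
  if (length(removed))
    dsaf_log("QC removed ", length(removed), " patient(s): ",
             paste(utils::head(removed, 10L), collapse = ", "), verbose = verbose)
  keep <- !drop
  labels <- if (!is.null(ds$labels)) ds$labels[keep] else NULL
  out <- expression_dataset(ds$values[, keep, drop = FALSE],
                            ds$gene_ids, ds$patient_ids[keep], labels = labels)
  list(dataset = out, removed = removed)
}

#' Restrict a dataset to a subset of genes
#'
#' @param ds An `ExpressionDataset`.
#' @param genes Character vector of gene ids to keep (order preserved).
#' @return The restricted `ExpressionDataset`.
#' @export
subset_genes <- function(ds, genes) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  missing_g <- setdiff(genes, ds$gene_ids)
  if (length(missing_g)) stop("unknown gene id(s): ", paste(missing_g, collapse = ", "))
  expression_dataset(ds$values[genes, , drop = FALSE], genes, ds$patient_ids,
                     labels = ds$labels)
}

#' Write a label file
#'
#' @param ds A labeled `ExpressionDataset`.
#' @param path Output path for the two-column TSV (`patient_id`, `event`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(ds, path) {
  stopifnot(inherits(ds, "ExpressionDataset"), !is.null(ds$labels))
  data.table::fwrite(data.table::data.table(patient_id = ds$patient_ids,
                                            event = ds$labels),
                     path, sep = "\t")
  invisible(path)
}
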