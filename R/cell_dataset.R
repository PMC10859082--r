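#' Assemble a single-cell expression dataset with donor-age metadata
#'
#' Bundles a cells x genes expression matrix with per-cell sample labels and
#' per-sample donor metadata into the container used by the whole workflow.
#' Expression values are taken as given (typically the processed/normalised
#' values of an upstream pipeline); no transformation is applied here.
#'
#' @param expression Numeric matrix, cells in rows and genes in columns.
#'   Sparse [Matrix::Matrix] input is densified.
#' @param sample_ids Character vector, one sample label per cell (row).
#' @param sample_metadata Data frame with one row per sample. Must contain a
#'   `sample_id` column and an `age` column (finite numeric donor age; months
#'   for real data, ordinal category for simulations). Additional columns
#'   (e.g. `sex`, `tissue`) are kept and visible to [subset_dataset()].
#' @param gene_ids Character vector of unique gene identifiers; defaults to
#'   `colnames(expression)`.
#' @param cell_ids Character vector of cell identifiers; defaults to
#'   `rownames(expression)` or generated labels.
#' @param cell_metadata Optional data frame of per-cell annotations (e.g.
#'   `cell_type`), one row per cell.
#'
#' @return An object of class `cell_dataset`: a list with elements
#'   `expression`, `gene_ids`, `cell_ids`, `cell_sample_ids`,
#'   `sample_metadata` and `cell_metadata`.
#'
#' @details Validation enforces that every cell's sample label appears in
#'   `sample_metadata`, that gene identifiers are unique, and that every
#'   sample has a finite numeric age. Cells with missing sample labels are
#'   rejected rather than dropped.
#'
#' @seealso [read_dataset()], [subset_dataset()], [filter_top_genes()],
#'   [run_workflow()]
#' @examples
#' expr <- matrix(rnorm(12), nrow = 4,
#'                dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
#' meta <- data.frame(sample_id = c("s1", "s2"), age = c(3, 24))
#' ds <- cell_dataset(expr, c("s1", "s1", "s2", "s2"), meta)
#' ds
#' @export
cell_dataset <- function(expression, sample_ids, sample_metadata,
                         gene_ids = colnames(expression),
                         cell_ids = rownames(expression),
                         cell_metadata = NULL) {
  if (inherits(expression, "Matrix")) expression <- as.matrix(expression)
  if (!is.matrix(expression) || !is.numeric(expression)) {
    stop("`expression` must be a numeric matrix (cells x genes)", call. = FALSE)
  }
  n_cells <- nrow(expression)
  n_genes <- ncol(expression)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(n_genes))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n_cells))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  sample_ids <- as.character(sample_ids)

  if (length(gene_ids) != n_genes) {
    stop("length(gene_ids) must equal ncol(expression)", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("gene_ids must be unique", call. = FALSE)
  }
  if (length(sample_ids) != n_cells) {
    stop("`sample_ids` must have one entry per cell (row of `expression`)",
         call. = FALSE)
  }
  if (anyNA(sample_ids) || any(!nzchar(sample_ids))) {
    stop("cells with missing sample labels are not allowed", call. = FALSE)
  }

  sample_metadata <- as.data.frame(sample_metadata)
  if (!all(c("sample_id", "age") %in% names(sample_metadata))) {
    stop("`sample_metadata` must have columns `sample_id` and `age`",
         call. = FALSE)
  }
  sample_metadata$sample_id <- as.character(sample_metadata$sample_id)
  if (anyDuplicated(sample_metadata$sample_id)) {
    stop("duplicated sample_id in sample_metadata", call. = FALSE)
  }
  missing_samples <- setdiff(unique(sample_ids), sample_metadata$sample_id)
  if (length(missing_samples)) {
    stop("cell sample label(s) absent from sample_metadata: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  age <- suppressWarnings(as.numeric(sample_metadata$age))
  if (anyNA(age) || any(!is.finite(age))) {
    bad <- sample_metadata$sample_id[!is.finite(age) | is.na(age)]
    stop("non-finite or non-numeric age for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sample_metadata$age <- age
  # keep only samples that actually have cells, in first-appearance order
  used <- unique(sample_ids)
  sample_metadata <-
    sample_metadata[match(used, sample_metadata$sample_id), , drop = FALSE]
  rownames(sample_metadata) <- NULL

  if (!is.null(cell_metadata)) {
    cell_metadata <- as.data.frame(cell_metadata)
    if (nrow(cell_metadata) != n_cells) {
      stop("`cell_metadata` must have one row per cell", call. = FALSE)
    }
    rownames(cell_metadata) <- NULL
  }

  dimnames(expression) <- list(cell_ids, gene_ids)
  structure(
    list(expression = expression,
         gene_ids = gene_ids,
         cell_ids = cell_ids,
         cell_sample_ids = sample_ids,
         sample_metadata = sample_metadata,
         cell_metadata = cell_metadata),
    class = "cell_dataset"
  )
}

#' Validate a cell_dataset
#'
#' Re-checks the container invariants (label coverage, unique genes, finite
#' ages, at least one cell per listed sample). Called by the workflow entry
#' points; exported for use after manual surgery on a dataset.
#'
#' @param ds A [cell_dataset()].
#' @return `ds`, invisibly, if valid; otherwise an error.
#' @export
validate_dataset <- function(ds) {
  if (!inherits(ds, "cell_dataset")) {
    stop("`ds` must be a cell_dataset", call. = FALSE)
  }
  if (anyDuplicated(ds$gene_ids)) stop("gene_ids must be unique", call. = FALSE)
  if (ncol(ds$expression) != length(ds$gene_ids)) {
    stop("expression columns do not match gene_ids", call. = FALSE)
  }
  if (nrow(ds$expression) != length(ds$cell_sample_ids)) {
    stop("expression rows do not match cell_sample_ids", call. = FALSE)
  }
  missing <- setdiff(unique(ds$cell_sample_ids), ds$sample_metadata$sample_id)
  if (length(missing)) {
    stop("sample(s) missing from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  empty <- setdiff(ds$sample_metadata$sample_id, unique(ds$cell_sample_ids))
  if (length(empty)) {
    stop("sample(s) listed in metadata have zero cells: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(ds$sample_metadata$age) ||
      any(!is.finite(ds$sample_metadata$age))) {
    stop("every sample needs a finite numeric age", call. = FALSE)
  }
  invisible(ds)
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat("cell_dataset:", nrow(x$expression), "cells x",
      ncol(x$expression), "genes;",
      nrow(x$sample_metadata), "samples\n")
  ages <- x$sample_metadata$age
  cat("  donor ages:", paste(sort(unique(ages)), collapse = ", "), "\n")
  if (!is.null(x$cell_metadata)) {
    cat("  cell annotations:", paste(names(x$cell_metadata), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Number of samples / cells / genes in a dataset
#' @param ds A [cell_dataset()].
#' @return Integer count.
#' @export
n_samples <- function(ds) nrow(ds$sample_metadata)

# per-cell annotation frame used by subset predicates: cell metadata plus
# sample-level columns broadcast to cells
.cell_annotation_frame <- function(ds) {
  frame <- data.frame(cell_id = ds$cell_ids,
                      sample_id = ds$cell_sample_ids,
                      stringsAsFactors = FALSE)
  if (!is.null(ds$cell_metadata)) {
    for (nm in setdiff(names(ds$cell_metadata), names(frame))) {
      frame[[nm]] <- ds$cell_metadata[[nm]]
    }
  }
  idx <- match(ds$cell_sample_ids, ds$sample_metadata$sample_id)
  for (nm in setdiff(names(ds$sample_metadata), names(frame))) {
    frame[[nm]] <- ds$sample_metadata[[nm]][idx]
  }
  frame
}

#' Subset a dataset by a predicate over cell annotations
#'
#' Restricts the dataset to cells matching a predicate evaluated over the
#' per-cell annotation frame (cell-level columns such as `cell_type`, plus
#' sample-level columns such as `sex` or `tissue` broadcast to cells).
#' Samples left with zero cells are dropped from the metadata. Typical uses
#' are restricting to one sex before an aging scan, or to a single annotated
#' cell type so that distribution changes reflect expression shifts rather
#' than cell-composition changes.
#'
#' @param ds A [cell_dataset()].
#' @param predicate An unquoted logical expression over annotation columns
#'   (e.g. `sex == "male"`), or a string such as `'cell_type == "granulocyte"'`
#'   (the form the command-line interface passes through).
#' @return The restricted `cell_dataset`.
#' @examples
#' expr <- matrix(rnorm(10), nrow = 5,
#'                dimnames = list(paste0("c", 1:5), c("g1", "g2")))
#' meta <- data.frame(sample_id = c("a", "b"), age = c(3, 18),
#'                    sex = c("male", "female"))
#' ds <- cell_dataset(expr, c("a", "a", "a", "b", "b"), meta)
#' subset_dataset(ds, sex == "male")
#' @export
subset_dataset <- function(ds, predicate) {
  validate_dataset(ds)
  expr <- substitute(predicate)
  if (is.character(expr)) expr <- str2lang(expr)
  frame <- .cell_annotation_frame(ds)
  keep <- tryCatch(
    eval(expr, frame, parent.frame()),
    error = function(e) {
      stop("predicate could not be evaluated over cell annotations (",
           conditionMessage(e), ")", call. = FALSE)
    }
  )
  if (!is.logical(keep) || length(keep) != nrow(frame)) {
    stop("predicate must yield one logical per cell", call. = FALSE)
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("predicate removes every cell", call. = FALSE)

  cell_dataset(
    expression = ds$expression[keep, , drop = FALSE],
    sample_ids = ds$cell_sample_ids[keep],
    sample_metadata = ds$sample_metadata,
    gene_ids = ds$gene_ids,
    cell_ids = ds$cell_ids[keep],
    cell_metadata = if (is.null(ds$cell_metadata)) NULL else
      ds$cell_metadata[keep, , drop = FALSE]
  )
}

#' Keep the most highly expressed genes
#'
#' Restricts the dataset to the `k` genes with the highest mean expression.
#' With `per_age = TRUE` (the default) the mean is computed within each age
#' category and the union of the per-age top-`k` sets is kept, so a gene
#' highly expressed at any age survives the filter; with `per_age = FALSE` a
#' single overall mean is used. Gene order is preserved. Distribution
#' distances are only informative for genes expressed well enough to estimate
#' a density, which is why aging scans are typically restricted this way.
#'
#' @param ds A [cell_dataset()].
#' @param k Number of genes to keep per ranking (default 3000).
#' @param per_age Rank within each age category and take the union
#'   (default `TRUE`), or rank once on the overall mean.
#' @return The filtered `cell_dataset`; unchanged if `k >=` the number of
#'   genes.
#' @export
filter_top_genes <- function(ds, k = 3000, per_age = TRUE) {
  validate_dataset(ds)
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  n_genes <- length(ds$gene_ids)
  if (k >= n_genes) return(ds)

  cell_age <- ds$sample_metadata$age[
    match(ds$cell_sample_ids, ds$sample_metadata$sample_id)]
  if (per_age) {
    keep_idx <- integer(0)
    for (a in unique(cell_age)) {
      m <- colMeans(ds$expression[cell_age == a, , drop = FALSE])
      keep_idx <- c(keep_idx, order(m, decreasing = TRUE)[seq_len(k)])
    }
    keep_idx <- sort(unique(keep_idx))
  } else {
    m <- colMeans(ds$expression)
    keep_idx <- sort(order(m, decreasing = TRUE)[seq_len(k)])
  }

  cell_dataset(
    expression = ds$expression[, keep_idx, drop = FALSE],
    sample_ids = ds$cell_sample_ids,
    sample_metadata = ds$sample_metadata,
    gene_ids = ds$gene_ids[keep_idx],
    cell_ids = ds$cell_ids,
    cell_metadata = ds$cell_metadata
  )
}

#' Extract one gene's expression values for one sample
#'
#' @param ds A [cell_dataset()].
#' @param gene_id Gene identifier.
#' @param sample_id Sample identifier.
#' @return Numeric vector of expression values over the sample's cells.
#' @export
gene_sample_values <- function(ds, gene_id, sample_id) {
  j <- match(gene_id, ds$gene_ids)
  if (is.na(j)) stop("unknown gene: ", gene_id, call. = FALSE)
  sel <- ds$cell_sample_ids == sample_id
  if (!any(sel)) stop("unknown sample: ", sample_id, call. = FALSE)
  ds$expression[sel, j]
}

#' Coerce other single-cell containers to cell_dataset
#'
#' @param x Object to coerce. A method is provided for
#'   `SingleCellExperiment` / `SummarizedExperiment` objects: the named assay
#'   is transposed to cells x genes, `colData` becomes the cell annotation
#'   frame, and the sample metadata table is derived from the `sample_key`
#'   and `age_key` columns.
#' @param ... Passed to methods.
#' @return A [cell_dataset()].
#' @export
as_cell_dataset <- function(x, ...) UseMethod("as_cell_dataset")

#' @rdname as_cell_dataset
#' @param sample_key Name of the per-cell column holding the sample label.
#' @param age_key Name of the per-cell column holding donor age.
#' @param assay Assay name or index to use (default first assay).
#' @export
as_cell_dataset.SummarizedExperiment <- function(x, sample_key = "sample_id",
                                                 age_key = "age",
                                                 assay = 1L, ...) {
  if (!requireNamespace("SummarizedExperiment", quietly = TRUE)) {
    stop("the SummarizedExperiment package is required for this coercion",
         call. = FALSE)
  }
  mat <- t(as.matrix(SummarizedExperiment::assay(x, assay)))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  for (key in c(sample_key, age_key)) {
    if (!key %in% names(cd)) {
      stop("colData lacks required column `", key, "`", call. = FALSE)
    }
  }
  .dataset_from_cell_table(mat, cd, sample_key, age_key)
}

#' @export
as_cell_dataset.default <- function(x, ...) {
  # S4 single-cell containers reach the default method under S3 dispatch
  if (requireNamespace("methods", quietly = TRUE) &&
      methods::is(x, "SummarizedExperiment")) {
    return(as_cell_dataset.SummarizedExperiment(x, ...))
  }
  stop("cannot coerce objects of class ", paste(class(x), collapse = "/"),
       " to cell_dataset", call. = FALSE)
}

# shared assembly path: dense cells x genes matrix + per-cell annotation
# table containing sample and age columns
.dataset_from_cell_table <- function(mat, cells, sample_key, age_key) {
  sample_ids <- as.character(cells[[sample_key]])
  ages <- .parse_ages(cells[[age_key]], sample_ids)
  first <- !duplicated(sample_ids)
  sm <- data.frame(sample_id = sample_ids[first], age = ages[first],
                   stringsAsFactors = FALSE)
  extra <- setdiff(names(cells), c(sample_key, age_key))
  cell_md <- if (length(extra)) cells[, extra, drop = FALSE] else NULL
  cell_dataset(mat, sample_ids, sm,
               gene_ids = colnames(mat), cell_ids = rownames(mat),
               cell_metadata = cell_md)
}

# coerce ages like 18, "18", "18m", "30 months" to numeric; error naming the
# samples whose age cannot be parsed
.parse_ages <- function(age, sample_ids) {
  age_chr <- trimws(as.character(age))
  num <- suppressWarnings(as.numeric(age_chr))
  bad <- is.na(num)
  if (any(bad)) {
    stripped <- sub("^([0-9]+\\.?[0-9]*).*$", "\\1", age_chr[bad])
    num[bad] <- suppressWarnings(as.numeric(stripped))
  }
  if (anyNA(num)) {
    offenders <- unique(sample_ids[is.na(num)])
    stop("non-numeric age for sample(s): ", paste(offenders, collapse = ", "),
         call. = FALSE)
  }
  num
}
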