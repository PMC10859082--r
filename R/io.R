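#' Read a single-cell expression dataset from disk
#'
#' Reads the three on-disk layouts the workflow accepts and returns a
#' validated [cell_dataset()].
#'
#' @section Formats:
#' \describe{
#'   \item{`dense_tsv`}{`path` is a tab-delimited matrix with a `cell_id`
#'     first column and one column per gene. Cell annotations (sample label,
#'     optional `cell_type`, ...) come from `cells_file`, sample metadata
#'     (age, optional `sex`/`tissue`, ...) from `samples_file`; both are
#'     tab-delimited with headers and default to `<stem>_cells.tsv` /
#'     `<stem>_samples.tsv` next to `path`.}
#'   \item{`mtx`}{`path` is a MatrixMarket sparse matrix, genes in rows and
#'     cells in columns (the usual export convention). Gene identifiers come
#'     from `genes_file` (one per line, default `<stem>_genes.tsv`);
#'     `cells_file` / `samples_file` as for `dense_tsv`.}
#'   \item{`h5ad`}{`path` is an annotated-HDF5 single-cell file (h5ad
#'     dialect): `X` holds cells x genes values (dense, CSR or CSC), `obs`
#'     the per-cell annotation columns and `var` the gene index. The sample
#'     label and donor age are taken from the `obs` columns named by
#'     `sample_key` and `age_key`; ages given as strings such as `"18m"` or
#'     `"30 months"` are coerced to their numeric part. Requires the
#'     \pkg{rhdf5} package.}
#' }
#'
#' @param path Path to the expression file (see Formats).
#' @param format One of `"dense_tsv"`, `"mtx"`, `"h5ad"`.
#' @param sample_key Column (in `cells_file` or `obs`) holding the per-cell
#'   sample label. Default `"sample_id"`.
#' @param age_key Column (in `samples_file` or `obs`) holding donor age.
#'   Default `"age"`.
#' @param cells_file,samples_file,genes_file Optional explicit sidecar paths
#'   for the text formats.
#' @return A validated [cell_dataset()], cell order preserved.
#' @seealso [write_dataset()] writes the same layouts.
#' @export
read_dataset <- function(path, format = c("dense_tsv", "mtx", "h5ad"),
                         sample_key = "sample_id", age_key = "age",
                         cells_file = NULL, samples_file = NULL,
                         genes_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ds <- switch(format,
    dense_tsv = .read_dense_tsv(path, sample_key, age_key,
                                cells_file, samples_file),
    mtx = .read_mtx(path, sample_key, age_key,
                    cells_file, samples_file, genes_file),
    h5ad = .read_h5ad(path, sample_key, age_key)
  )
  validate_dataset(ds)
  ds
}

#' Write a dataset to disk
#'
#' Inverse of [read_dataset()]: writes the expression matrix plus annotation
#' sidecars (`dense_tsv`, `mtx`) or a self-contained annotated-HDF5 file
#' (`h5ad`). A round-trip through any format reproduces the expression
#' values exactly and the metadata field-for-field.
#'
#' @param ds A [cell_dataset()].
#' @param path Output path for the expression file (sidecar names are
#'   derived from it as in [read_dataset()]).
#' @param format One of `"dense_tsv"`, `"mtx"`, `"h5ad"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("dense_tsv", "mtx", "h5ad")) {
  format <- match.arg(format)
  validate_dataset(ds)
  switch(format,
    dense_tsv = .write_dense_tsv(ds, path),
    mtx = .write_mtx(ds, path),
    h5ad = .write_h5ad(ds, path)
  )
  invisible(path)
}

.sidecar <- function(path, suffix) {
  stem <- sub("\\.(tsv|txt|mtx)$", "", path)
  paste0(stem, suffix)
}

.read_annotation_sidecars <- function(path, sample_key, age_key,
                                      cells_file, samples_file) {
  if (is.null(cells_file)) cells_file <- .sidecar(path, "_cells.tsv")
  if (is.null(samples_file)) samples_file <- .sidecar(path, "_samples.tsv")
  for (f in c(cells_file, samples_file)) {
    if (!file.exists(f)) stop("missing annotation file: ", f, call. = FALSE)
  }
  cells <- read.delim(cells_file, stringsAsFactors = FALSE,
                      check.names = FALSE)
  samples <- read.delim(samples_file, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!sample_key %in% names(cells)) {
    stop("cell annotation file lacks column `", sample_key, "`",
         call. = FALSE)
  }
  if (!"sample_id" %in% names(samples)) {
    stop("sample metadata file lacks column `sample_id`", call. = FALSE)
  }
  if (!age_key %in% names(samples)) {
    stop("sample metadata file lacks column `", age_key, "`", call. = FALSE)
  }
  samples$age <- .parse_ages(samples[[age_key]], samples$sample_id)
  if (age_key != "age") samples[[age_key]] <- NULL
  list(cells = cells, samples = samples)
}

.assemble_from_sidecars <- function(mat, ann, sample_key) {
  cells <- ann$cells
  sample_ids <- as.character(cells[[sample_key]])
  extra <- setdiff(names(cells), c("cell_id", sample_key))
  cell_md <- if (length(extra)) cells[, extra, drop = FALSE] else NULL
  cell_dataset(mat, sample_ids, ann$samples,
               gene_ids = colnames(mat), cell_ids = rownames(mat),
               cell_metadata = cell_md)
}

.read_dense_tsv <- function(path, sample_key, age_key,
                            cells_file, samples_file) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "cell_id") {
    stop("dense TSV must have `cell_id` as its first column", call. = FALSE)
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(tab$cell_id)
  ann <- .read_annotation_sidecars(path, sample_key, age_key,
                                   cells_file, samples_file)
  .assemble_from_sidecars(mat, ann, sample_key)
}

.write_dense_tsv <- function(ds, path) {
  tab <- data.frame(cell_id = ds$cell_ids, ds$expression,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  .write_annotation_sidecars(ds, path)
}

.write_annotation_sidecars <- function(ds, path) {
  cells <- data.frame(cell_id = ds$cell_ids,
                      sample_id = ds$cell_sample_ids,
                      stringsAsFactors = FALSE)
  if (!is.null(ds$cell_metadata)) cells <- cbind(cells, ds$cell_metadata)
  write.table(cells, .sidecar(path, "_cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ds$sample_metadata, .sidecar(path, "_samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

.read_mtx <- function(path, sample_key, age_key,
                      cells_file, samples_file, genes_file) {
  if (is.null(genes_file)) genes_file <- .sidecar(path, "_genes.tsv")
  if (!file.exists(genes_file)) {
    stop("missing gene identifier file: ", genes_file, call. = FALSE)
  }
  m <- Matrix::readMM(path)           # genes x cells
  genes <- readLines(genes_file)
  if (length(genes) != nrow(m)) {
    stop("gene file has ", length(genes), " entries but matrix has ",
         nrow(m), " rows", call. = FALSE)
  }
  ann <- .read_annotation_sidecars(path, sample_key, age_key,
                                   cells_file, samples_file)
  if (nrow(ann$cells) != ncol(m)) {
    stop("cell file has ", nrow(ann$cells), " entries but matrix has ",
         ncol(m), " columns", call. = FALSE)
  }
  mat <- t(as.matrix(m))
  dimnames(mat) <- list(as.character(ann$cells$cell_id), genes)
  .assemble_from_sidecars(mat, ann, sample_key)
}

.write_mtx <- function(ds, path) {
  Matrix::writeMM(Matrix::Matrix(t(ds$expression), sparse = TRUE), path)
  writeLines(ds$gene_ids, .sidecar(path, "_genes.tsv"))
  .write_annotation_sidecars(ds, path)
}

.need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("reading/writing h5ad files requires the rhdf5 package",
         call. = FALSE)
  }
}

# Read an obs/var annotation group: plain array columns plus the
# categorical encoding (group with `categories` and 0-based `codes`).
.read_h5ad_frame <- function(path, group) {
  index_name <- tryCatch(rhdf5::h5readAttributes(path, group)[["_index"]],
                         error = function(e) NULL)
  if (is.null(index_name)) index_name <- "_index"
  contents <- rhdf5::h5ls(path)
  here <- contents[contents$group == paste0("/", group), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(here))) {
    nm <- here$name[i]
    obj <- paste0(group, "/", nm)
    if (here$otype[i] == "H5I_GROUP") {
      codes <- as.integer(rhdf5::h5read(path, paste0(obj, "/codes")))
      cats <- as.character(rhdf5::h5read(path, paste0(obj, "/categories")))
      vals <- ifelse(codes < 0, NA_character_, cats[codes + 1L])
      out[[nm]] <- vals
    } else {
      out[[nm]] <- as.vector(rhdf5::h5read(path, obj))
    }
  }
  idx <- as.character(out[[index_name]])
  out[[index_name]] <- NULL
  df <- if (length(out)) as.data.frame(out, stringsAsFactors = FALSE,
                                       check.names = FALSE)
        else data.frame(row.names = seq_along(idx))
  list(index = idx, table = df)
}

.read_h5ad_X <- function(path, n_obs, n_var) {
  info <- rhdf5::h5ls(path)
  x_is_group <- any(info$group == "/X")
  if (!x_is_group) {
    mat <- rhdf5::h5read(path, "X")
    # HDF5 stores (n_obs, n_var) row-major; rhdf5 returns dims reversed
    if (nrow(mat) == n_var && ncol(mat) == n_obs) mat <- t(mat)
    return(mat)
  }
  attrs <- rhdf5::h5readAttributes(path, "X")
  enc <- attrs[["encoding-type"]]
  data <- as.numeric(rhdf5::h5read(path, "X/data"))
  indices <- as.integer(rhdf5::h5read(path, "X/indices"))
  indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
  if (identical(enc, "csc_matrix")) {
    sp <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                               dims = c(n_obs, n_var))
  } else {                              # csr over obs: column-compressed in
    sp <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                               dims = c(n_var, n_obs))
    sp <- Matrix::t(sp)                 # the var dimension -> transpose
  }
  as.matrix(sp)
}

.read_h5ad <- function(path, sample_key, age_key) {
  .need_rhdf5()
  obs <- .read_h5ad_frame(path, "obs")
  var <- .read_h5ad_frame(path, "var")
  n_obs <- length(obs$index)
  n_var <- length(var$index)
  mat <- .read_h5ad_X(path, n_obs, n_var)
  storage.mode(mat) <- "double"
  dimnames(mat) <- list(obs$index, var$index)
  cells <- obs$table
  for (key in c(sample_key, age_key)) {
    if (!key %in% names(cells)) {
      stop("h5ad obs lacks required column `", key, "`", call. = FALSE)
    }
  }
  cells <- cbind(data.frame(cell_id = obs$index, stringsAsFactors = FALSE),
                 cells)
  sample_ids <- as.character(cells[[sample_key]])
  ages <- .parse_ages(cells[[age_key]], sample_ids)
  first <- !duplicated(sample_ids)
  samples <- data.frame(sample_id = sample_ids[first], age = ages[first],
                        stringsAsFactors = FALSE)
  # obs stores everything per cell; columns constant within every sample
  # (e.g. sex, tissue) are sample-level metadata, the rest stay cell-level
  extra <- setdiff(names(cells), c("cell_id", sample_key, age_key))
  sample_level <- vapply(extra, function(nm) {
    all(tapply(cells[[nm]], sample_ids,
               function(v) length(unique(v)) == 1L))
  }, logical(1))
  for (nm in extra[sample_level]) samples[[nm]] <- cells[[nm]][first]
  extra <- extra[!sample_level]
  cell_md <- if (length(extra)) cells[, extra, drop = FALSE] else NULL
  cell_dataset(mat, sample_ids, samples,
               gene_ids = var$index, cell_ids = obs$index,
               cell_metadata = cell_md)
}

.h5_write_frame <- function(h5, group, index, table, index_name = "_index") {
  rhdf5::h5createGroup(h5, group)
  rhdf5::h5write(index, h5, paste0(group, "/", index_name))
  for (nm in names(table)) {
    v <- table[[nm]]
    if (is.factor(v)) v <- as.character(v)
    rhdf5::h5write(v, h5, paste0(group, "/", nm))
  }
  fid <- rhdf5::H5Fopen(h5)
  gid <- rhdf5::H5Gopen(fid, group)
  rhdf5::h5writeAttribute(index_name, gid, "_index")
  col_order <- names(table)
  if (length(col_order)) {
    rhdf5::h5writeAttribute(col_order, gid, "column-order")
  }
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
}

.write_h5ad <- function(ds, path) {
  .need_rhdf5()
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  # transpose so HDF5 shape reads as (n_obs, n_var) from row-major tools
  rhdf5::h5write(t(ds$expression), path, "X")
  obs_tab <- data.frame(sample_id = ds$cell_sample_ids,
                        stringsAsFactors = FALSE)
  idx <- match(ds$cell_sample_ids, ds$sample_metadata$sample_id)
  obs_tab$age <- ds$sample_metadata$age[idx]
  for (nm in setdiff(names(ds$sample_metadata), c("sample_id", "age"))) {
    obs_tab[[nm]] <- ds$sample_metadata[[nm]][idx]
  }
  if (!is.null(ds$cell_metadata)) {
    for (nm in setdiff(names(ds$cell_metadata), names(obs_tab))) {
      obs_tab[[nm]] <- ds$cell_metadata[[nm]]
    }
  }
  .h5_write_frame(path, "obs", ds$cell_ids, obs_tab)
  .h5_write_frame(path, "var", ds$gene_ids,
                  data.frame(row.names = seq_along(ds$gene_ids)))
  if (exists("h5closeAll", where = asNamespace("rhdf5"))) rhdf5::h5closeAll()
  invisible(path)
}

#' Write an association result table
#'
#' Tab-delimited with a header; rows ordered by descending correlation
#' (undefined correlations last), ties broken lexicographically by gene.
#'
#' @param tbl An association table as returned by [run_workflow()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(tbl, path) {
  tbl <- as.data.frame(tbl)
  required <- c("gene_id", "rho", "mantel_p", "adjusted_p", "n_samples",
                "metric", "passed_cutoff")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop("result table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rho_key <- ifelse(is.na(tbl$rho), -Inf, tbl$rho)   # undefined rho sinks
  ord <- order(-rho_key, tbl$gene_id)
  tbl <- tbl[ord, , drop = FALSE]
  write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an association result table written by [write_results()]
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_results <- function(path) {
  tbl <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("passed_cutoff" %in% names(tbl)) {
    tbl$passed_cutoff <- as.logical(tbl$passed_cutoff)
  }
  tbl
}
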