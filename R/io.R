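#' Read an expression matrix
#'
#' Reads a cells x genes expression matrix from a dense TSV/CSV file (with
#' row and column identifiers) or from a MatrixMarket `.mtx` file with
#' sidecar identifier files (one id per line). On-disk orientation defaults
#' to the common genes-in-rows convention; the returned matrix is always
#' cells x genes.
#'
#' @param path Path to the matrix file.
#' @param format `"auto"` (from the file extension), `"tsv"`, `"csv"` or
#'   `"mtx"`.
#' @param orientation Layout of the file on disk: `"genes_by_cells"`
#'   (default) or `"cells_by_genes"`.
#' @param genes_file,cells_file Sidecar identifier files, required for
#'   `"mtx"` input.
#' @return A numeric cells x genes matrix with cell ids as rownames and
#'   gene ids as colnames.
#' @export
read_expression <- function(path,
                            format = c("auto", "tsv", "csv", "mtx"),
                            orientation = c("genes_by_cells",
                                            "cells_by_genes"),
                            genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mtx") "mtx" else if (ext == "csv") "csv" else "tsv"
  }
  if (format == "mtx") {
    if (is.null(genes_file) || is.null(cells_file))
      stop("mtx input requires genes_file and cells_file")
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_file)
    cells <- readLines(cells_file)
    if (orientation == "genes_by_cells") {
      dimnames(m) <- list(genes, cells)
      m <- t(m)
    } else {
      dimnames(m) <- list(cells, genes)
    }
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    m <- as.matrix(df)
    if (orientation == "genes_by_cells") m <- t(m)
  }
  storage.mode(m) <- "double"
  validate_expression(m)
  m
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; the same `format` and `orientation`
#' arguments control the on-disk layout.
#'
#' @inheritParams read_expression
#' @param x Cells x genes numeric matrix with dimnames.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path,
                             format = c("auto", "tsv", "csv", "mtx"),
                             orientation = c("genes_by_cells",
                                             "cells_by_genes"),
                             genes_file = NULL, cells_file = NULL) {
  validate_expression(x)
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mtx") "mtx" else if (ext == "csv") "csv" else "tsv"
  }
  out <- if (orientation == "genes_by_cells") t(x) else x
  if (format == "mtx") {
    if (is.null(genes_file) || is.null(cells_file))
      stop("mtx output requires genes_file and cells_file")
    Matrix::writeMM(Matrix::Matrix(out, sparse = TRUE), path)
    writeLines(colnames(x), genes_file)
    writeLines(rownames(x), cells_file)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(id = rownames(out), out, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a cell metadata table
#'
#' Tab-separated file with a header; must contain a `cell_id` column and may
#' contain `cluster_label` (categorical) and `external_label` (integer rank
#' encoding stage or type order, >= 0).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with at least a `cell_id` column.
#' @export
read_cell_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(md))
    stop("metadata needs a cell_id column")
  if (anyDuplicated(md$cell_id))
    stop("duplicate cell_id in metadata")
  if ("external_label" %in% names(md)) {
    el <- md$external_label
    if (any(el != as.integer(el)) || any(el < 0))
      stop("external_label must be integer ranks >= 0")
    md$external_label <- as.integer(el)
  }
  md
}

#' Read a ligand-receptor pair table
#'
#' Comma-separated file with header `ligand,receptor` and an optional
#' `pair_id` column (generated as `ligand_receptor` when absent). Genes that
#' do not occur in the expression matrix are allowed and simply score zero.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with columns `ligand`, `receptor`, `pair_id`.
#' @export
read_lr_table <- function(path) {
  lr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(lr)))
    stop("ligand-receptor table needs ligand and receptor columns")
  if (!"pair_id" %in% names(lr))
    lr$pair_id <- paste(lr$ligand, lr$receptor, sep = "_")
  if (anyDuplicated(lr$pair_id))
    stop("duplicate pair_id in ligand-receptor table")
  lr[, c("ligand", "receptor", "pair_id")]
}
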