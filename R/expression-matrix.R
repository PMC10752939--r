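#' Expression matrix container
#'
#' A light container for a genes x cells expression matrix together with the
#' gene/cell identifiers and a layer tag recording what the values are
#' (raw counts, median-normalized counts, or natural-log-transformed values).
#'
#' @param values Numeric matrix, genes in rows and cells in columns.
#' @param gene_ids Character vector of unique gene identifiers (one per row).
#' @param cell_ids Character vector of unique cell identifiers (one per
#'   column).
#' @param layer One of `"counts"`, `"tpm"`, `"log"`. A `"counts"` layer must
#'   be non-negative; a `"log"` layer must be finite.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (with dimnames set), `gene_ids`, `cell_ids` and `layer`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              layer = c("counts", "tpm", "log")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") does not match row count (",
         nrow(values), ")")
  if (length(cell_ids) != ncol(values))
    stop("cell_ids length (", length(cell_ids),
         ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell_ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  storage.mode(values) <- "double"
  if (layer == "counts" && any(values < 0))
    stop("counts layer contains negative values")
  if (layer == "log" && !all(is.finite(values)))
    stop("log layer contains non-finite values")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 layer = layer),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " cells, layer = ", x$layer, "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Dense CSV/TSV files carry cell ids in the header row and gene ids in the
#' first column.  Matrix Market (`.mtx`) files are read with
#' [Matrix::readMM()] and expect two sidecar files next to the matrix,
#' `genes.tsv` and `barcodes.tsv`, one identifier per line.
#'
#' @param path Path to the matrix file.
#' @param format `"auto"` (from the file extension), `"csv"`, `"tsv"` or
#'   `"mtx"`.
#' @param layer Layer tag to attach to the values (see
#'   [expression_matrix()]).
#' @param orientation `"genes_by_cells"` (the on-disk convention) or
#'   `"cells_by_genes"`, in which case the matrix is transposed after
#'   reading.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                            layer = "counts",
                            orientation = c("genes_by_cells",
                                            "cells_by_genes")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format= explicitly"))
  }
  if (format == "mtx") {
    gene_file <- file.path(dirname(path), "genes.tsv")
    cell_file <- file.path(dirname(path), "barcodes.tsv")
    if (!file.exists(gene_file) || !file.exists(cell_file))
      stop("mtx sidecar files genes.tsv and barcodes.tsv must exist next to ",
           path)
    m <- tryCatch(as.matrix(Matrix::readMM(path)),
                  error = function(e) stop("malformed mtx file ", path, ": ",
                                           conditionMessage(e)))
    gene_ids <- readLines(gene_file)
    cell_ids <- readLines(cell_file)
    if (orientation == "cells_by_genes") {
      m <- t(m)
      tmp <- gene_ids; gene_ids <- cell_ids; cell_ids <- tmp
    }
    if (length(gene_ids) != nrow(m))
      stop("genes.tsv has ", length(gene_ids), " ids but matrix has ",
           nrow(m), " rows")
    if (length(cell_ids) != ncol(m))
      stop("barcodes.tsv has ", length(cell_ids), " ids but matrix has ",
           ncol(m), " columns")
    return(expression_matrix(m, gene_ids, cell_ids, layer = layer))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      row.names = 1, comment.char = ""),
    error = function(e) stop("malformed ", format, " file ", path, ": ",
                             conditionMessage(e)))
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  if (orientation == "cells_by_genes") m <- t(m)
  expression_matrix(m, rownames(m), colnames(m), layer = layer)
}

#' Write an expression matrix to disk
#'
#' The inverse of [read_expression()]; round-trips ids and values.
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @param format `"auto"`, `"csv"`, `"tsv"` or `"mtx"` (writes `genes.tsv`
#'   and `barcodes.tsv` sidecars).
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, format = c("auto", "csv", "tsv",
                                                  "mtx")) {
  stopifnot(inherits(em, "expression_matrix"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension '.", ext, "'"))
  }
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(em$values, sparse = TRUE), path)
    writeLines(em$gene_ids, file.path(dirname(path), "genes.tsv"))
    writeLines(em$cell_ids, file.path(dirname(path), "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene_id = em$gene_ids, em$values, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Median normalization of per-cell transcript totals
#'
#' Scales every cell (column) so that its total equals the median of the
#' original per-cell totals, the usual "TPM-like" normalization for UMI
#' count matrices.
#'
#' @param em An [expression_matrix()] with `layer == "counts"`.
#' @return An [expression_matrix()] with `layer == "tpm"`.
#' @export
tpm_normalize <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$layer != "counts")
    stop("tpm_normalize expects a counts layer, got '", em$layer, "'")
  totals <- colSums(em$values)
  if (any(totals <= 0))
    stop("cells with zero total count: ",
         paste(em$cell_ids[totals <= 0], collapse = ", "))
  target <- stats::median(totals)
  values <- sweep(em$values, 2, target / totals, `*`)
  expression_matrix(values, em$gene_ids, em$cell_ids, layer = "tpm")
}

#' Natural-log transform
#'
#' Elementwise `ln(x + 1)` of normalized values; maps 0 to 0 exactly.
#'
#' @param em An [expression_matrix()] with `layer == "tpm"`.
#' @return An [expression_matrix()] with `layer == "log"`.
#' @export
log_transform <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$layer != "tpm")
    stop("log_transform expects a tpm layer, got '", em$layer, "'")
  if (any(em$values < 0)) stop("negative values cannot be log-transformed")
  expression_matrix(log1p(em$values), em$gene_ids, em$cell_ids, layer = "log")
}

#' Highly variable gene selection
#'
#' Fits the log(CV) versus log(mean) trend across genes by ordinary least
#' squares and ranks genes by their positive residual dispersion above the
#' trend.  Genes with zero mean are excluded before fitting.  The OLS log-log
#' fit is one simple member of the family of mean-CV trend methods common in
#' single-cell studies; the exact procedure is a documented package choice.
#'
#' @param em An [expression_matrix()] (`tpm` or `log` layer).
#' @param n_genes Number of genes to keep.
#' @return An [expression_matrix()] restricted to the selected genes, ordered
#'   by decreasing residual.
#' @export
select_hvg <- function(em, n_genes) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!em$layer %in% c("tpm", "log"))
    stop("select_hvg expects a tpm or log layer, got '", em$layer, "'")
  mu <- rowMeans(em$values)
  keep <- mu > 0
  if (sum(keep) < n_genes)
    stop("only ", sum(keep), " genes with positive mean, cannot select ",
         n_genes)
  sdv <- apply(em$values[keep, , drop = FALSE], 1, stats::sd)
  cv <- sdv / mu[keep]
  lcv <- log(pmax(cv, .Machine$double.xmin))
  lmu <- log(mu[keep])
  fit <- stats::lm.fit(cbind(1, lmu), lcv)
  resid <- fit$residuals
  ord <- order(resid, decreasing = TRUE)[seq_len(n_genes)]
  ids <- em$gene_ids[keep][ord]
  expression_matrix(em$values[ids, , drop = FALSE], ids, em$cell_ids,
                    layer = em$layer)
}
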