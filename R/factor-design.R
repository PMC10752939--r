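#' Factorial cell-label design
#'
#' Records, for every cell, the level it takes on each categorical
#' phenotypic feature, together with the resulting contingency table over
#' level combinations.  The design is *complete* when every combination in
#' the Cartesian product of the feature level sets is observed in at least
#' one cell, and *partial* otherwise.
#'
#' @param labels A data.frame with one row per cell and one column per
#'   feature (characters or factors).
#' @param cell_ids Character vector of unique cell identifiers, one per row
#'   of `labels`.
#' @param features Optional feature names; defaults to `names(labels)`.
#' @return An object of class `factor_design`: a list with `cell_ids`,
#'   `features`, `labels` (data.frame of factors with levels in
#'   first-appearance order), `level_sets`, `counts` (contingency table over
#'   the full Cartesian product) and `complete`.
#' @export
factor_design <- function(labels, cell_ids = rownames(labels),
                          features = names(labels)) {
  labels <- as.data.frame(labels)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(labels)))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(labels))
    stop("cell_ids length does not match number of label rows")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (length(features) < 1) stop("at least one feature is required")
  names(labels) <- features
  missing <- !stats::complete.cases(labels) |
    Reduce(`|`, lapply(labels, function(x) as.character(x) == ""))
  if (any(missing))
    stop("cells with missing feature levels: ",
         paste(cell_ids[missing], collapse = ", "))
  # levels in first-appearance order
  labels[] <- lapply(labels, function(x) {
    x <- as.character(x)
    factor(x, levels = unique(x))
  })
  counts <- table(labels)
  structure(list(cell_ids = cell_ids,
                 features = features,
                 labels = labels,
                 level_sets = lapply(labels, levels),
                 counts = counts,
                 complete = all(counts >= 1L)),
            class = "factor_design")
}

#' @export
print.factor_design <- function(x, ...) {
  cat("<factor_design> ", length(x$cell_ids), " cells, features: ",
      paste(sprintf("%s (%d levels)", x$features,
                    lengths(x$level_sets)), collapse = ", "),
      if (x$complete) " [complete]" else " [partial]", "\n", sep = "")
  invisible(x)
}

#' Read a cell-label table
#'
#' @param path CSV file with a cell-id column plus one column per feature.
#' @param feature_columns Names of the feature columns to use, in order.
#' @param cell_id_column Name of the cell-id column (default `"cell_id"`).
#' @return A [factor_design()].
#' @export
read_labels <- function(path, feature_columns, cell_id_column = "cell_id") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  need <- c(cell_id_column, feature_columns)
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop("missing columns in ", path, ": ", paste(absent, collapse = ", "))
  factor_design(df[feature_columns], cell_ids = df[[cell_id_column]],
                features = feature_columns)
}

#' Cell-type keys for a design
#'
#' Concatenates each cell's feature levels into a single type label
#' (levels joined with `"_"`).
#'
#' @param fd A [factor_design()].
#' @return Character vector, one type key per cell.
#' @export
design_types <- function(fd) {
  stopifnot(inherits(fd, "factor_design"))
  do.call(paste, c(lapply(fd$labels, as.character), sep = "_"))
}
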