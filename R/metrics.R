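#' Per-axis signal-to-noise ratio
#'
#' Between-cell-type variance of the axis coordinates (unweighted over the
#' type means, divisor `T - 1`) divided by the pooled within-type variance
#' (divisor `n - T`).  This is the one-dimensional Rayleigh quotient the
#' factorized solver maximizes, so "SNR of an axis" is self-consistent with
#' the fitting objective.
#'
#' @param coords Numeric vector of per-cell coordinates on one axis.
#' @param type_labels Per-cell cell-type label.
#' @return A single number; `+Inf` with a warning when the within-type
#'   variance is zero.
#' @export
snr_axis <- function(coords, type_labels) {
  type_labels <- as.character(type_labels)
  sp <- split(coords, type_labels)
  if (length(sp) < 2) stop("at least two cell types are required")
  if (any(lengths(sp) < 2)) stop("every type needs at least two cells")
  means <- vapply(sp, mean, numeric(1))
  between <- stats::var(means)
  within <- sum(vapply(sp, function(z) sum((z - mean(z))^2), numeric(1))) /
    (length(coords) - length(sp))
  if (within == 0) {
    warning("zero within-type variance; SNR is infinite")
    return(Inf)
  }
  between / within
}

#' Explained variance of a feature along an axis
#'
#' One-way ANOVA R-squared: between-level sum of squares over the total sum
#' of squares of the axis coordinates.
#'
#' @param coords Per-cell axis coordinates.
#' @param feature_labels Per-cell levels of one feature.
#' @return A value in `[0, 1]`; 0 by convention for a constant axis.
#' @export
explained_variance <- function(coords, feature_labels) {
  feature_labels <- as.character(feature_labels)
  if (length(unique(feature_labels)) < 2)
    stop("at least two levels are required")
  tot <- sum((coords - mean(coords))^2)
  if (tot == 0) return(0)
  sp <- split(coords, feature_labels)
  between <- sum(vapply(sp, function(z) length(z) * (mean(z) -
                                                       mean(coords))^2,
                        numeric(1)))
  between / tot
}

#' Mutual information between an axis and a feature
#'
#' Plug-in mutual information in bits between the axis discretized into
#' equal-frequency bins and the categorical feature.  Bins collapsed by
#' ties are merged.
#'
#' @param coords Per-cell axis coordinates.
#' @param feature_labels Per-cell feature levels.
#' @param n_bins Number of quantile bins (default 20).
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(coords, feature_labels, n_bins = 20) {
  n <- length(coords)
  if (n < n_bins) stop("need at least n_bins observations")
  br <- unique(stats::quantile(coords, probs = seq(0, 1, length.out =
                                                     n_bins + 1)))
  if (length(br) < 2) return(0)  # constant axis
  bins <- cut(coords, breaks = br, include.lowest = TRUE)
  joint <- table(bins, as.character(feature_labels)) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  pij <- as.numeric(joint)
  eij <- as.numeric(outer(px, py))
  pos <- pij > 0
  sum(pij[pos] * log2(pij[pos] / eij[pos]))
}

#' Modularity of an axis over features
#'
#' Measures whether an axis is informative about a single feature only.
#' With `theta` the largest mutual information over features and `F`
#' features, the deviation is the mean of `(mi_f / theta)^2` over the
#' non-maximal features and the modularity is one minus that deviation.
#'
#' @param mi_values Named numeric vector of per-feature mutual information.
#' @return A value in `[0, 1]`; 0 when all mutual information is zero.
#' @export
modularity_axis <- function(mi_values) {
  mi_values <- unlist(mi_values)
  if (length(mi_values) < 2) stop("at least two features are required")
  theta <- max(mi_values)
  if (theta == 0) return(0)
  k <- which.max(mi_values)
  delta <- sum((mi_values[-k] / theta)^2) / (length(mi_values) - 1)
  1 - delta
}

#' Mean silhouette of an embedding
#'
#' Average silhouette width over all cells in the Euclidean embedding
#' space; cells in singleton types score 0 by convention.
#'
#' @param coords `r x n` matrix of embedding coordinates (axes in rows).
#' @param type_labels Per-cell cell-type label.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_embedding <- function(coords, type_labels) {
  coords <- if (is.null(dim(coords))) matrix(coords, nrow = 1) else coords
  cl <- as.integer(factor(as.character(type_labels)))
  if (length(unique(cl)) < 2) stop("at least two cell types are required")
  sil <- cluster::silhouette(cl, stats::dist(t(coords)))
  mean(sil[, "sil_width"])
}

#' Per-axis metric report for one embedding
#'
#' @param coords `r x n` coordinates with axis tags in `rownames`.
#' @param fd The [factor_design()] of the cells.
#' @param n_bins Bins for [mutual_information()].
#' @return A data.frame with one row per axis: `tag`, `snr`, one `ev_*` and
#'   `mi_*` column per feature, and `modularity`.
#' @export
axis_metrics <- function(coords, fd, n_bins = 20) {
  coords <- if (is.null(dim(coords))) matrix(coords, nrow = 1) else coords
  types <- design_types(fd)
  tags <- rownames(coords)
  if (is.null(tags)) tags <- paste0("axis", seq_len(nrow(coords)))
  rows <- lapply(seq_len(nrow(coords)), function(k) {
    co <- coords[k, ]
    mi <- vapply(fd$labels, function(lab) mutual_information(co, lab,
                                                             n_bins),
                 numeric(1))
    ev <- vapply(fd$labels, function(lab) explained_variance(co, lab),
                 numeric(1))
    out <- data.frame(tag = tags[k], snr = snr_axis(co, types))
    for (f in fd$features) {
      out[[paste0("ev_", f)]] <- ev[[f]]
      out[[paste0("mi_", f)]] <- mi[[f]]
    }
    out$modularity <- modularity_axis(mi)
    out
  })
  do.call(rbind, rows)
}

#' Overall metric report across methods
#'
#' Computes per-axis metrics for each embedding, aggregates them into an
#' overall SNR (mean over axes), an overall SNR normalized by a reference
#' method, an overall modularity (mean over axes) and the embedding
#' silhouette.
#'
#' @param embeddings Named list; each element either a `projected_data`, a
#'   `baseline_embedding`, or a bare `r x n` coordinate matrix.
#' @param fd The shared [factor_design()].
#' @param reference Name of the embedding used to normalize overall SNR.
#' @param n_bins Bins for [mutual_information()].
#' @return A list with `summary` (data.frame: method, overall_snr,
#'   overall_snr_normalized, overall_modularity, silhouette) and `per_axis`
#'   (named list of per-axis data.frames).
#' @export
overall_report <- function(embeddings, fd, reference = "lda", n_bins = 20) {
  if (!reference %in% names(embeddings))
    stop("reference method '", reference, "' is not among the embeddings")
  types <- design_types(fd)
  coords_of <- function(e) {
    if (inherits(e, "projected_data")) e$coordinates
    else if (inherits(e, "baseline_embedding")) e$coordinates
    else as.matrix(e)
  }
  per_axis <- lapply(embeddings, function(e)
    axis_metrics(coords_of(e), fd, n_bins))
  overall_snr <- vapply(per_axis, function(t) mean(t$snr), numeric(1))
  summary <- data.frame(
    method = names(embeddings),
    overall_snr = overall_snr,
    overall_snr_normalized = overall_snr / overall_snr[[reference]],
    overall_modularity = vapply(per_axis, function(t) mean(t$modularity),
                                numeric(1)),
    silhouette = vapply(embeddings, function(e)
      silhouette_embedding(coords_of(e), types), numeric(1)),
    row.names = NULL)
  list(summary = summary, per_axis = per_axis)
}
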