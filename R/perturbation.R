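#' Perturb a factorial annotation
#'
#' Produces deliberately corrupted versions of a cell-label design,
#' emulating common annotation errors: swapping the label tuples of two
#' cell types, merging two levels of a feature, or randomly splitting one
#' level in two.  Expression data are never touched, only labels.
#'
#' @param fd A [factor_design()].
#' @param kind `"swap_types"`, `"merge_levels"` or `"split_level"`.
#' @param type_a,type_b For `swap_types`: the two type label tuples to
#'   exchange, each a character vector with one level per feature.
#' @param feature For `merge_levels` / `split_level`: the feature name.
#' @param from,into For `merge_levels`: the level relabeled (`from`) and
#'   its destination (`into`).
#' @param level For `split_level`: the level split into two.
#' @param seed Seed for the random halves of `split_level`.
#' @return A new [factor_design()] over the same cells.
#' @export
perturb_design <- function(fd, kind = c("swap_types", "merge_levels",
                                        "split_level"),
                           type_a = NULL, type_b = NULL, feature = NULL,
                           from = NULL, into = NULL, level = NULL,
                           seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(fd, "factor_design"))
  labels <- as.data.frame(lapply(fd$labels, as.character),
                          stringsAsFactors = FALSE)
  names(labels) <- fd$features
  switch(kind,
    swap_types = {
      stopifnot(length(type_a) == length(fd$features),
                length(type_b) == length(fd$features))
      key <- do.call(paste, c(labels, sep = "_"))
      ka <- paste(type_a, collapse = "_")
      kb <- paste(type_b, collapse = "_")
      if (!ka %in% key) stop("no cells of type ", ka)
      if (!kb %in% key) stop("no cells of type ", kb)
      if (ka == kb) {
        warning("swap of identical types is a no-op")
        return(fd)
      }
      ia <- key == ka; ib <- key == kb
      for (f in seq_along(fd$features)) {
        labels[ia, f] <- type_b[f]
        labels[ib, f] <- type_a[f]
      }
    },
    merge_levels = {
      stopifnot(!is.null(feature), !is.null(from), !is.null(into))
      if (!feature %in% fd$features) stop("unknown feature: ", feature)
      lv <- fd$level_sets[[feature]]
      if (!all(c(from, into) %in% lv))
        stop("levels not present in feature ", feature)
      labels[labels[[feature]] == from, feature] <- into
      if (length(lv) == 2)
        warning("feature '", feature,
                "' now has a single level (constant feature)")
    },
    split_level = {
      stopifnot(!is.null(feature), !is.null(level))
      if (!feature %in% fd$features) stop("unknown feature: ", feature)
      sel <- which(labels[[feature]] == level)
      if (length(sel) < 2)
        stop("level '", level, "' has fewer than 2 cells, cannot split")
      set.seed(seed)
      half <- sample(sel, floor(length(sel) / 2))
      labels[sel, feature] <- paste0(level, ".2")
      labels[half, feature] <- paste0(level, ".1")
    })
  factor_design(labels, cell_ids = fd$cell_ids, features = fd$features)
}

#' Annotation-quality scan via label perturbations
#'
#' Fits the factorized embedding under the reference annotation and under
#' each perturbed annotation, then evaluates every fit against the
#' *reference* annotation (its cell types and features), the annotation
#' under scrutiny.  The overall SNR of an annotation is the total (summed)
#' per-axis SNR of its fitted axes, so an annotation is credited for all
#' the discriminative structure its axes resolve: axes that separate
#' nothing real add nothing, and an annotation that drops real axes loses
#' their contribution.  The overall modularity is the SNR-weighted mean of
#' per-axis modularity, crediting factor alignment in proportion to the
#' structure an axis resolves.  With a correct reference annotation the
#' reference is expected to score best on both, so a perturbation scoring
#' higher flags a suspect annotation.
#'
#' @param em The [expression_matrix()].
#' @param fd The reference [factor_design()].
#' @param config An [flda_config()]; leave `dims` unset so each perturbed
#'   design gets its own full dimensionality.
#' @param specs Named list of perturbation argument lists, each containing
#'   `kind` plus the arguments of [perturb_design()].
#' @return A data.frame with one row per annotation (original first):
#'   `label`, `kind`, `complete`, `overall_snr`, `snr_normalized`,
#'   `overall_modularity`, and logical `best_snr` / `best_modularity`.
#' @export
perturbation_scan <- function(em, fd, config = flda_config(),
                              specs = list()) {
  designs <- c(list(original = fd),
               stats::setNames(lapply(specs, function(s)
                 do.call(perturb_design,
                         c(list(fd = fd), s))),
                 names(specs)))
  kinds <- c("original", vapply(specs, function(s) s$kind, character(1)))
  rows <- Map(function(label, d, kind) {
    tryCatch({
      fit <- if (d$complete) fit_flda(em, d, config) else
        suppressWarnings(fit_flda_partial(em, d, config))
      co <- flda_project(em, fit)$coordinates
      pm <- axis_metrics(co, fd)   # evaluated against the reference labels
      w <- pm$snr / sum(pm$snr)
      data.frame(label = label, kind = kind, complete = d$complete,
                 overall_snr = sum(pm$snr),
                 overall_modularity = sum(w * pm$modularity))
    }, error = function(e)
      data.frame(label = label, kind = kind, complete = d$complete,
                 overall_snr = NA_real_, overall_modularity = NA_real_))
  }, names(designs), designs, kinds)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$snr_normalized <- out$overall_snr / out$overall_snr[1]
  out$best_snr <- !is.na(out$overall_snr) &
    out$overall_snr == max(out$overall_snr, na.rm = TRUE)
  out$best_modularity <- !is.na(out$overall_modularity) &
    out$overall_modularity == max(out$overall_modularity, na.rm = TRUE)
  out[, c("label", "kind", "complete", "overall_snr", "snr_normalized",
          "overall_modularity", "best_snr", "best_modularity")]
}
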