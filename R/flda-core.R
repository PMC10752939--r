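#' FLDA configuration
#'
#' @param lambda1,lambda2 Non-negative weights of the two penalty covariance
#'   terms in the contrast (the off-target main effect and the interaction,
#'   respectively, when targeting a main effect).  Both default to 1.
#' @param dims Optional named integer vector giving the number of
#'   discriminant axes per component, with names among `"feature_i"`,
#'   `"feature_j"`, `"interaction"`.  Defaults to the full degrees of
#'   freedom: `a - 1`, `b - 1` and `(a - 1)(b - 1)` for an `a x b` design.
#' @param residual `"auto"` (use the full residual covariance when it is
#'   well-conditioned and estimable, otherwise its diagonal), `"full"`, or
#'   `"diagonal"`.
#' @param eig_tol Relative tolerance used both for the auto rule (smallest
#'   over largest residual eigenvalue) and as the floor applied to
#'   zero-variance genes in the diagonal residual.
#' @return An object of class `flda_config`.
#' @export
flda_config <- function(lambda1 = 1, lambda2 = 1, dims = NULL,
                        residual = c("auto", "full", "diagonal"),
                        eig_tol = 1e-8) {
  residual <- match.arg(residual)
  stopifnot(is.finite(lambda1), lambda1 >= 0,
            is.finite(lambda2), lambda2 >= 0,
            is.finite(eig_tol), eig_tol > 0)
  if (!is.null(dims)) {
    if (is.null(names(dims)) ||
        !all(names(dims) %in% c("feature_i", "feature_j", "interaction")))
      stop("dims must be named with feature_i / feature_j / interaction")
    if (any(dims < 1)) stop("dims must be >= 1")
    dims <- vapply(dims, as.integer, integer(1))
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2, dims = dims,
                 residual = residual, eig_tol = eig_tol),
            class = "flda_config")
}

# ---- covariance decomposition -----------------------------------------------

#' Feature-wise covariance decomposition (two-way ANOVA partition)
#'
#' Partitions the gene-gene covariance of a factorially labeled expression
#' matrix into the parts explained by the first feature (`M_A`), the second
#' feature (`M_B`), their interaction (`M_AB`) and the within-type residual
#' (`M_e`).  Type means are averaged unweighted over the contingency table
#' (also when cell counts per type differ), and the residual pools the
#' within-type scatter with an inner `1/n_ij` weighting and divisor
#' `N - a*b`.
#'
#' @param em An [expression_matrix()].
#' @param fd A complete [factor_design()] with exactly two features.
#' @param residual `"auto"`, `"full"` or `"diagonal"`; with `"diagonal"` the
#'   full `M_e` matrix is never formed, only its diagonal.
#' @param eig_tol Tolerance forwarded to the auto residual rule.
#' @return An object of class `flda_decomposition` with the grand/row/
#'   column/cell means, the factor matrices of the three effect covariances
#'   (`C_A`, `C_B`, `C_AB`, such that e.g. `M_A = C_A %*% t(C_A)`), `M_e`
#'   (or `NULL` in diagonal mode), `me_diag`, and the design constants.
#' @export
compute_decomposition <- function(em, fd,
                                  residual = c("auto", "full", "diagonal"),
                                  eig_tol = 1e-8) {
  residual <- match.arg(residual)
  if (!fd$complete)
    stop("design is a partial contingency table; use fit_flda_partial()")
  .decompose(em, fd, residual = residual, eig_tol = eig_tol,
             partial = FALSE)
}

.decompose <- function(em, fd, residual, eig_tol, partial) {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(fd, "factor_design"))
  if (length(fd$features) != 2)
    stop("exactly two phenotypic features are required, got ",
         length(fd$features))
  if (!identical(em$cell_ids, fd$cell_ids))
    stop("expression matrix and design refer to different cells")
  x <- em$values
  g <- nrow(x)
  n <- ncol(x)
  fi <- fd$labels[[1]]
  fj <- fd$labels[[2]]
  a <- nlevels(fi)
  b <- nlevels(fj)
  if (a < 2 || b < 2) stop("each feature needs at least two levels")

  type <- interaction(fi, fj, sep = "\r", drop = TRUE)
  types <- levels(type)
  n_t <- as.integer(table(type))
  names(n_t) <- types
  n_types <- length(types)
  dof_e <- n - (if (partial) n_types else a * b)
  if (dof_e <= 0) stop("residual dof <= 0: need more cells than cell types")

  # type means, g x T
  idx <- split(seq_len(n), type)
  cell_means <- vapply(idx, function(k) rowMeans(x[, k, drop = FALSE]),
                       numeric(g))
  type_i <- vapply(idx, function(k) as.character(fi[k[1]]), character(1))
  type_j <- vapply(idx, function(k) as.character(fj[k[1]]), character(1))

  # unweighted marginal means over (observed) type means
  row_means <- vapply(levels(fi), function(l)
    rowMeans(cell_means[, type_i == l, drop = FALSE]), numeric(g))
  col_means <- vapply(levels(fj), function(l)
    rowMeans(cell_means[, type_j == l, drop = FALSE]), numeric(g))
  grand_mean <- rowMeans(cell_means)

  C_A <- (row_means - grand_mean) / sqrt(a - 1)
  C_B <- (col_means - grand_mean) / sqrt(b - 1)
  C_AB <- NULL
  if (!partial) {
    C_AB <- cell_means -
      row_means[, match(type_i, levels(fi)), drop = FALSE] -
      col_means[, match(type_j, levels(fj)), drop = FALSE] + grand_mean
    C_AB <- C_AB / sqrt((a - 1) * (b - 1))
  }

  # residual: scale each cell's deviation by 1 / sqrt(n_ij * dof_e)
  resid <- x - cell_means[, as.integer(type), drop = FALSE]
  resid <- sweep(resid, 2, sqrt(n_t[as.integer(type)] * dof_e), `/`)
  me_diag <- rowSums(resid^2)
  M_e <- NULL
  if (residual != "diagonal" && g <= dof_e)
    M_e <- tcrossprod(resid)

  structure(list(grand_mean = grand_mean, row_means = row_means,
                 col_means = col_means, cell_means = cell_means,
                 type_i = type_i, type_j = type_j,
                 C_A = C_A, C_B = C_B, C_AB = C_AB,
                 M_e = M_e, me_diag = me_diag,
                 a = a, b = b, N = n, n_types = n_types, n_ij = n_t,
                 dof_e = dof_e, partial = partial, residual = residual,
                 eig_tol = eig_tol, gene_ids = em$gene_ids),
            class = "flda_decomposition")
}

#' Effect covariance matrices of a decomposition
#'
#' @param cd An `flda_decomposition`.
#' @param which One of `"M_A"`, `"M_B"`, `"M_AB"`, `"M_e"`.
#' @return The dense symmetric `g x g` matrix.
#' @export
effect_covariance <- function(cd, which = c("M_A", "M_B", "M_AB", "M_e")) {
  which <- match.arg(which)
  switch(which,
         M_A = tcrossprod(cd$C_A),
         M_B = tcrossprod(cd$C_B),
         M_AB = {
           if (is.null(cd$C_AB))
             stop("interaction covariance is not estimable on a partial table")
           tcrossprod(cd$C_AB)
         },
         M_e = if (!is.null(cd$M_e)) cd$M_e else diag(cd$me_diag,
                                                      length(cd$me_diag)))
}

#' Signed covariance contrast for one component
#'
#' For the first feature the contrast is `M_A - lambda1 M_B - lambda2 M_AB`;
#' for the second feature the roles of `M_A` and `M_B` swap; for the
#' interaction it is `M_AB - lambda1 M_A - lambda2 M_B`, penalizing both
#' main effects symmetrically.
#'
#' @param cd An `flda_decomposition`.
#' @param target `"feature_i"`, `"feature_j"` or `"interaction"`.
#' @param lambda1,lambda2 Penalty weights.
#' @return A dense symmetric `g x g` matrix.
#' @export
build_contrast <- function(cd, target = c("feature_i", "feature_j",
                                          "interaction"),
                           lambda1 = 1, lambda2 = 1) {
  target <- match.arg(target)
  f <- .contrast_factors(cd, target, lambda1, lambda2)
  out <- tcrossprod(f$W %*% diag(f$signs, length(f$signs)), f$W)
  (out + t(out)) / 2
}

# factor form of a contrast: W and a sign/weight per column such that the
# contrast equals W diag(signs) W^T
.contrast_factors <- function(cd, target, lambda1, lambda2) {
  if (cd$partial) {
    if (target == "interaction")
      stop("interaction component is not estimable on a partial table")
    pos <- if (target == "feature_i") cd$C_A else cd$C_B
    neg <- if (target == "feature_i") cd$C_B else cd$C_A
    W <- cbind(pos, neg)
    signs <- c(rep(1, ncol(pos)), rep(-lambda1, ncol(neg)))
  } else {
    parts <- switch(target,
                    feature_i = list(cd$C_A, cd$C_B, cd$C_AB),
                    feature_j = list(cd$C_B, cd$C_A, cd$C_AB),
                    interaction = list(cd$C_AB, cd$C_A, cd$C_B))
    W <- do.call(cbind, parts)
    signs <- c(rep(1, ncol(parts[[1]])), rep(-lambda1, ncol(parts[[2]])),
               rep(-lambda2, ncol(parts[[3]])))
  }
  list(W = W, signs = signs)
}

# ---- generalized eigen machinery --------------------------------------------

# Resolve the effective residual metric.  Returns either
# list(kind="diag", d=<floored diagonal>) or list(kind="chol", R=<chol(M_e)>).
.resolve_me <- function(cd, residual, eig_tol) {
  g <- length(cd$me_diag)
  use_full <- FALSE
  if (residual == "full") {
    if (is.null(cd$M_e))
      stop("full residual covariance requested but not estimable ",
           "(genes >= residual dof); use residual = 'diagonal'")
    use_full <- TRUE
  } else if (residual == "auto" && !is.null(cd$M_e) && g < cd$dof_e) {
    ev <- eigen(cd$M_e, symmetric = TRUE, only.values = TRUE)$values
    use_full <- ev[g] > eig_tol * ev[1]
  }
  if (use_full) {
    R <- tryCatch(chol(cd$M_e), error = function(e) NULL)
    if (is.null(R)) {
      if (residual == "full")
        stop("full residual covariance is not positive definite")
      use_full <- FALSE
    } else {
      return(list(kind = "chol", R = R, matrix = cd$M_e))
    }
  }
  d <- cd$me_diag
  floor_val <- eig_tol * max(d)
  if (max(d) == 0) stop("residual covariance is identically zero")
  list(kind = "diag", d = pmax(d, floor_val))
}

.whiten_cols <- function(me, W) {
  if (me$kind == "diag") W / sqrt(me$d)
  else backsolve(me$R, W, transpose = TRUE)
}

.unwhiten_vec <- function(me, z) {
  if (me$kind == "diag") z / sqrt(me$d)
  else backsolve(me$R, z)
}

# fix sign so the largest-|weight| entry is positive (ties: lowest index)
.fix_sign <- function(u) {
  k <- which.max(abs(u))
  if (u[k] < 0) -u else u
}

# Solve the symmetric pencil (W diag(signs) W^T, M_e_eff) for the top d
# eigenpairs, exactly, in the span of the whitened factor columns.
.solve_pencil_factors <- function(W, signs, me, d) {
  Ww <- .whiten_cols(me, W)
  sv <- svd(Ww)
  keep <- sv$d > 1e-12 * max(sv$d, .Machine$double.eps)
  if (!any(keep)) stop("no signal for component: contrast is zero")
  Q <- sv$u[, keep, drop = FALSE]
  C <- crossprod(Q, Ww)
  M <- C %*% (t(C) * signs)
  ee <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (ncol(Q) < d)
    stop("contrast rank (", ncol(Q), ") is below the requested dimension ",
         d)
  axes <- matrix(0, nrow(W), d)
  for (k in seq_len(d))
    axes[, k] <- .fix_sign(.unwhiten_vec(me, Q %*% ee$vectors[, k]))
  list(axes = axes, eigenvalues = ee$values[seq_len(d)])
}

#' Solve one FLDA component from a dense contrast
#'
#' Solves the symmetric-definite generalized eigenproblem
#' `contrast u = lambda M_e_eff u` for the `d` largest eigenvalues, where
#' the effective residual metric is the full `M_e` when available and
#' numerically positive definite, and otherwise its diagonal with
#' zero-variance entries floored.  Axes are normalized to
#' `u' M_e_eff u = 1` with the largest-magnitude weight positive, and the
#' reported eigenvalues are the generalized Rayleigh quotients.
#'
#' @param contrast Dense symmetric `g x g` contrast matrix (see
#'   [build_contrast()]).
#' @param cd The `flda_decomposition` the contrast came from.
#' @param d Number of axes.
#' @param config An [flda_config()] (residual mode and tolerance).
#' @return A list with `axes` (`g x d`), `eigenvalues`, and `residual_mode`.
#' @export
solve_component <- function(contrast, cd, d, config = flda_config()) {
  stopifnot(d >= 1)
  if (max(abs(contrast)) == 0) stop("no signal for component: contrast is zero")
  if (max(abs(contrast - t(contrast))) > 1e-8 * max(abs(contrast)))
    stop("contrast must be symmetric")
  me <- .resolve_me(cd, config$residual, config$eig_tol)
  g <- nrow(contrast)
  if (d > g) stop("d exceeds available dof")
  Aw <- .whiten_cols(me, t(.whiten_cols(me, contrast)))
  ee <- eigen((Aw + t(Aw)) / 2, symmetric = TRUE)
  axes <- matrix(0, g, d)
  for (k in seq_len(d))
    axes[, k] <- .fix_sign(.unwhiten_vec(me, ee$vectors[, k]))
  list(axes = axes, eigenvalues = ee$values[seq_len(d)],
       residual_mode = me$kind)
}

# ---- fitting ----------------------------------------------------------------

.component_dof <- function(a, b) {
  c(feature_i = a - 1L, feature_j = b - 1L,
    interaction = (a - 1L) * (b - 1L))
}

.axis_tags <- function(tag, d) {
  stem <- switch(tag, feature_i = "FLD_i", feature_j = "FLD_j",
                 interaction = "FLD_ij")
  if (d == 1) stem else paste0(stem, seq_len(d))
}

.fit_flda_impl <- function(em, fd, config, partial) {
  cd <- .decompose(em, fd, residual = config$residual,
                   eig_tol = config$eig_tol, partial = partial)
  dof <- .component_dof(cd$a, cd$b)
  if (partial) dof <- dof[c("feature_i", "feature_j")]
  dims <- config$dims
  if (is.null(dims)) dims <- dof
  if (partial && "interaction" %in% names(dims))
    stop("interaction component is not estimable on a partial table")
  bad <- names(dims)[dims > dof[names(dims)]]
  if (length(bad))
    stop("d exceeds available dof for component ",
         paste(bad, collapse = ", "))
  me <- .resolve_me(cd, config$residual, config$eig_tol)

  components <- list()
  axes <- NULL
  tags <- character(0)
  for (tag in names(dims)) {
    f <- .contrast_factors(cd, tag, config$lambda1, config$lambda2)
    sol <- .solve_pencil_factors(f$W, f$signs, me, dims[[tag]])
    comp_tags <- .axis_tags(tag, dims[[tag]])
    components[[tag]] <- list(tag = tag, axis_tags = comp_tags,
                              eigenvalues = sol$eigenvalues)
    axes <- cbind(axes, sol$axes)
    tags <- c(tags, comp_tags)
  }
  colnames(axes) <- tags
  rownames(axes) <- em$gene_ids
  structure(list(axes = axes, axis_tags = tags, components = components,
                 config = config, gene_ids = em$gene_ids,
                 features = fd$features, partial = partial,
                 residual_mode = me$kind, a = cd$a, b = cd$b),
            class = "flda_fit")
}

#' Fit factorized linear discriminant axes
#'
#' Computes the feature-wise covariance decomposition of the labeled
#' expression matrix, builds the signed contrast for each requested
#' component (first feature, second feature, their interaction) and solves
#' each generalized eigenproblem against the residual covariance.  The
#' result is a set of discriminant axes grouped by the phenotypic factor
#' they align with.
#'
#' @param em An [expression_matrix()].
#' @param fd A complete two-feature [factor_design()] over the same cells.
#' @param config An [flda_config()].
#' @return An object of class `flda_fit` with `axes` (genes x axes, tagged
#'   columns), per-component eigenvalues, and the configuration used.
#' @export
fit_flda <- function(em, fd, config = flda_config()) {
  if (!fd$complete)
    stop("design is a partial contingency table; use fit_flda_partial()")
  .fit_flda_impl(em, fd, config, partial = FALSE)
}

#' Fit FLDA on a partial contingency table
#'
#' When some feature combinations are unobserved the interaction covariance
#' is not estimable; marginal means are taken over the observed type means
#' only, the contrast reduces to `M_A - lambda1 M_B` (and its analogue for
#' the second feature), and the residual pools within-type covariance over
#' the observed types with divisor `N - T`.
#'
#' @inheritParams fit_flda
#' @return An `flda_fit` with only the two main-effect components.
#' @export
fit_flda_partial <- function(em, fd, config = flda_config()) {
  if (fd$complete)
    warning("design is complete; fitting through the partial-table path ",
            "drops the interaction component")
  observed <- lapply(fd$labels, function(x) length(unique(x)) == nlevels(x))
  if (!all(unlist(observed)))
    stop("every level of each feature must be observed in at least one cell")
  if (is.null(config$dims))
    config$dims <- .component_dof(nlevels(fd$labels[[1]]),
                                  nlevels(fd$labels[[2]]))[
                                    c("feature_i", "feature_j")]
  .fit_flda_impl(em, fd, config, partial = TRUE)
}

#' @export
print.flda_fit <- function(x, ...) {
  cat("<flda_fit> ", length(x$gene_ids), " genes, axes: ",
      paste(x$axis_tags, collapse = ", "),
      " (residual: ", x$residual_mode, ")\n", sep = "")
  invisible(x)
}

#' Project cells onto fitted discriminant axes
#'
#' @param em An [expression_matrix()] over the same genes the fit was made
#'   on (aligned by gene id).
#' @param fit An `flda_fit` (or any object with `axes` and `gene_ids`).
#' @return An object of class `projected_data`: `coordinates` (axes x
#'   cells), `axis_tags`, `cell_ids`.
#' @export
flda_project <- function(em, fit) {
  stopifnot(inherits(em, "expression_matrix"))
  missing <- setdiff(fit$gene_ids, em$gene_ids)
  if (length(missing))
    stop("expression matrix lacks fitted genes: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ...")
  x <- em$values[fit$gene_ids, , drop = FALSE]
  co <- crossprod(fit$axes, x)
  rownames(co) <- colnames(fit$axes)
  structure(list(coordinates = co, axis_tags = colnames(fit$axes),
                 cell_ids = em$cell_ids),
            class = "projected_data")
}
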