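#' Principal component embedding
#'
#' Top-`r` principal axes of the gene-centered expression matrix, with the
#' same deterministic sign convention as the discriminant axes.
#'
#' @param em An [expression_matrix()].
#' @param r Number of components, at most `min(genes, cells)`.
#' @return An object of class `baseline_embedding` with `method`, `axes`
#'   (genes x r), `coordinates` (r x cells) and `axis_tags`.
#' @export
pca_embed <- function(em, r) {
  stopifnot(inherits(em, "expression_matrix"))
  g <- nrow(em$values); n <- ncol(em$values)
  if (r > min(g, n)) stop("r exceeds min(genes, cells)")
  xc <- em$values - rowMeans(em$values)
  sv <- svd(xc, nu = r, nv = 0)
  axes <- apply(sv$u[, seq_len(r), drop = FALSE], 2, .fix_sign)
  .baseline("pca", axes, xc, paste0("PC", seq_len(r)), em)
}

.baseline <- function(method, axes, x, tags, em) {
  axes <- as.matrix(axes)
  colnames(axes) <- tags
  rownames(axes) <- em$gene_ids
  co <- crossprod(axes, x)
  rownames(co) <- tags
  colnames(co) <- em$cell_ids
  structure(list(method = method, axes = axes, coordinates = co,
                 axis_tags = tags, gene_ids = em$gene_ids,
                 cell_ids = em$cell_ids),
            class = "baseline_embedding")
}

#' @export
print.baseline_embedding <- function(x, ...) {
  cat("<baseline_embedding> ", x$method, ": ",
      paste(x$axis_tags, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Linear discriminant embedding
#'
#' Top-`r` generalized eigenvectors of the between-class versus
#' within-class covariance pencil.  The scatter estimators use the same
#' conventions as the factorized solver: the between-class covariance
#' averages class means unweighted with divisor `K - 1`, the within-class
#' covariance pools residuals with an inner `1/n_k` weighting and divisor
#' `N - K`, and the same diagonal fallback applies when the within matrix
#' is not estimable or ill-conditioned.
#'
#' @param em An [expression_matrix()].
#' @param class_labels Per-cell class (factor or character).
#' @param r Number of axes, at most `K - 1`.
#' @param residual,eig_tol Residual policy as in [flda_config()].
#' @return A `baseline_embedding` with method `"lda"`.
#' @export
lda_embed <- function(em, class_labels, r,
                      residual = c("auto", "full", "diagonal"),
                      eig_tol = 1e-8) {
  residual <- match.arg(residual)
  stopifnot(inherits(em, "expression_matrix"))
  cls <- factor(class_labels, levels = unique(as.character(class_labels)))
  K <- nlevels(cls)
  if (K < 2) stop("at least two classes are required")
  if (r > K - 1) stop("r exceeds classes - 1")
  x <- em$values
  g <- nrow(x); n <- ncol(x)
  dof_e <- n - K
  if (dof_e <= 0) stop("residual dof <= 0")
  idx <- split(seq_len(n), cls)
  n_k <- lengths(idx)
  means <- vapply(idx, function(k) rowMeans(x[, k, drop = FALSE]),
                  numeric(g))
  C_b <- (means - rowMeans(means)) / sqrt(K - 1)
  resid <- x - means[, as.integer(cls), drop = FALSE]
  resid <- sweep(resid, 2, sqrt(n_k[as.integer(cls)] * dof_e), `/`)
  cd <- list(me_diag = rowSums(resid^2),
             M_e = if (residual != "diagonal" && g <= dof_e)
               tcrossprod(resid) else NULL,
             dof_e = dof_e)
  me <- .resolve_me(cd, residual, eig_tol)
  sol <- .solve_pencil_factors(C_b, rep(1, ncol(C_b)), me, r)
  .baseline("lda", sol$axes, x, paste0("LD", seq_len(r)), em)
}

#' Two per-feature LDA embeddings
#'
#' Runs one LDA per phenotypic feature (levels of that feature as classes)
#' and stacks the resulting axes, the common workaround when a factorized
#' embedding is wanted but only a single-factor discriminant tool is
#' available.  It cannot represent the feature interaction.
#'
#' @param em An [expression_matrix()].
#' @param fd A two-feature [factor_design()].
#' @param residual,eig_tol Residual policy.
#' @return A `baseline_embedding` with method `"two_ldas"` and axis tags
#'   `LD_i*`, `LD_j*`.
#' @export
two_ldas_embed <- function(em, fd, residual = "auto", eig_tol = 1e-8) {
  stopifnot(inherits(fd, "factor_design"))
  if (length(fd$features) != 2) stop("two features are required")
  fits <- lapply(1:2, function(f) {
    lab <- fd$labels[[f]]
    lda_embed(em, lab, nlevels(lab) - 1, residual = residual,
              eig_tol = eig_tol)
  })
  tag_stem <- c("LD_i", "LD_j")
  axes <- NULL; tags <- character(0)
  for (f in 1:2) {
    d <- ncol(fits[[f]]$axes)
    tg <- if (d == 1) tag_stem[f] else paste0(tag_stem[f], seq_len(d))
    axes <- cbind(axes, fits[[f]]$axes)
    tags <- c(tags, tg)
  }
  .baseline("two_ldas", axes, em$values, tags, em)
}

#' Canonical correlation embedding against the phenotype design
#'
#' Builds a numeric phenotype matrix (one row per feature: centered numeric
#' codes for 2-level features, centered drop-one indicator blocks for more
#' levels), then extracts the top-`r` expression-side canonical directions.
#' Both autocovariances receive a small ridge for invertibility.
#'
#' @param em An [expression_matrix()].
#' @param fd A [factor_design()].
#' @param r Number of canonical directions, at most the phenotype rank.
#' @param ridge Relative ridge, scaled by `trace/g` of each autocovariance.
#' @param residual `"auto"`, `"full"` or `"diagonal"`: whether the
#'   expression autocovariance enters in full or only through its diagonal.
#'   As for the discriminant solvers, `"auto"` falls back to the diagonal
#'   when there are at least as many genes as cells, where the full
#'   autocovariance is singular and inverting it overfits the phenotype.
#' @return A `baseline_embedding` with method `"cca"` and attribute
#'   `correlations` (the canonical correlations, in `[0, 1]`).
#' @export
cca_embed <- function(em, fd, r, ridge = 1e-6,
                      residual = c("auto", "full", "diagonal")) {
  residual <- match.arg(residual)
  stopifnot(inherits(em, "expression_matrix"), inherits(fd, "factor_design"))
  x <- em$values
  g <- nrow(x)
  n <- ncol(x)
  xb <- .phenotype_matrix(fd)          # d x n, centered
  if (r > nrow(xb)) stop("r exceeds the phenotype matrix rank")
  xa <- x - rowMeans(x)
  use_full <- switch(residual, full = TRUE, diagonal = FALSE,
                     auto = g < n - 1)
  Sbb <- tcrossprod(xb) / (n - 1)
  Sab <- tcrossprod(xa, xb) / (n - 1)
  if (use_full) {
    Saa <- tcrossprod(xa) / (n - 1)
    Saa <- Saa + diag(ridge * sum(diag(Saa)) / g, g)
    M <- solve(Saa, Sab)                # g x d
    quad <- function(u) sum(u * (Saa %*% u))
  } else {
    daa <- rowSums(xa^2) / (n - 1)
    daa <- pmax(daa, ridge * mean(daa))
    M <- Sab / daa
    quad <- function(u) sum(u^2 * daa)
  }
  Sbb <- Sbb + diag(ridge * sum(diag(Sbb)) / nrow(Sbb), nrow(Sbb))
  small <- solve(Sbb, crossprod(Sab, M))  # d x d, eigvals = rho^2
  ee <- eigen(small)
  if (any(Mod(ee$values) - Re(ee$values) > 1e-8))
    stop("rank deficiency beyond ridge repair")
  ord <- order(Re(ee$values), decreasing = TRUE)[seq_len(r)]
  axes <- matrix(0, nrow(x), r)
  rho <- numeric(r)
  for (k in seq_len(r)) {
    v <- Re(ee$vectors[, ord[k]])
    u <- as.numeric(M %*% v)
    u <- u / sqrt(quad(u))
    axes[, k] <- .fix_sign(u)
    rho[k] <- abs(stats::cor(as.numeric(crossprod(u, xa)),
                             as.numeric(crossprod(v, xb))))
  }
  out <- .baseline("cca", axes, xa, paste0("CCA", seq_len(r)), em)
  attr(out, "correlations") <- rho
  out
}

# centered numeric phenotype design, one row per feature
.phenotype_matrix <- function(fd) {
  rows <- lapply(fd$labels, function(lab) {
    if (nlevels(lab) == 2) {
      v <- as.numeric(lab == levels(lab)[2])
      matrix(v - mean(v), 1)
    } else {
      m <- t(vapply(levels(lab)[-1], function(l) as.numeric(lab == l),
                    numeric(length(lab))))
      m - rowMeans(m)
    }
  })
  do.call(rbind, rows)
}
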