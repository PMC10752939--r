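#' Truncated Rayleigh flow for sparse generalized eigenvectors
#'
#' Maximizes the generalized Rayleigh quotient `u'Au / u'Bu` subject to an
#' l0 constraint `||u||_0 <= l` by iterating a gradient ascent step on the
#' quotient followed by hard truncation to the `l` largest-magnitude
#' coordinates and renormalization.  Convergence requires the step size
#' `eta` to satisfy `eta * lambda_max(B) < 1`; the default uses
#' `0.9 / lambda_max(B)` with `lambda_max` estimated by power iteration.
#'
#' @param contrast Numerator `A`: either a symmetric `g x g` matrix (may be
#'   indefinite) or its factored form, a list with elements `W` (`g x r`)
#'   and `signs` (length `r`) representing `A = W diag(signs) W'`.  The
#'   factored form keeps the per-iteration cost linear in `g`.
#' @param M_e_eff Denominator metric `B`: a symmetric positive definite
#'   matrix or a positive vector interpreted as a diagonal.
#' @param init Nonzero starting vector, typically the dense FLDA axis.
#' @param l Support size (number of nonzero weights retained).
#' @param eta Step size; `NULL` for the default.
#' @param max_iter,tol Iteration cap and stop threshold on the change of the
#'   Rayleigh quotient.
#' @return An object of class `rifle_solution`: `weights` (g-vector with at
#'   most `l` nonzeros, unit Euclidean norm, sign fixed as for dense axes),
#'   `support` (sorted indices), `quotient_trace`, `iterations`,
#'   `converged`.
#' @export
rifle <- function(contrast, M_e_eff, init, l, eta = NULL, max_iter = 1000,
                  tol = 1e-8) {
  factored <- is.list(contrast) && !is.null(contrast$W)
  g <- if (factored) nrow(contrast$W) else nrow(contrast)
  diagonal_b <- is.null(dim(M_e_eff))
  stopifnot(l >= 1, l <= g, max_iter >= 1, tol > 0)
  if (all(init == 0)) stop("init must be nonzero")
  if (diagonal_b && any(M_e_eff <= 0))
    stop("diagonal M_e_eff must be positive")

  amul <- if (factored) {
    W <- contrast$W; signs <- contrast$signs
    function(u) as.numeric(W %*% (signs * crossprod(W, u)))
  } else function(u) as.numeric(contrast %*% u)
  bmul <- if (diagonal_b) function(u) M_e_eff * u else
    function(u) as.numeric(M_e_eff %*% u)
  lam_max <- .power_lambda_max(bmul, g)
  if (is.null(eta)) eta <- 0.9 / lam_max
  if (eta * lam_max >= 1)
    stop("step size eta violates eta * lambda_max(M_e_eff) < 1")

  truncate_l <- function(u) {
    if (l < g) {
      # ties at the l-th magnitude: keep the lower index
      keep <- order(-abs(u), seq_along(u))[seq_len(l)]
      out <- numeric(g)
      out[keep] <- u[keep]
      out
    } else u
  }

  u <- truncate_l(init)
  if (all(u == 0)) u <- truncate_l(init + .Machine$double.eps)
  u <- u / sqrt(sum(u^2))
  quotient <- function(u) {
    den <- sum(u * bmul(u))
    if (den <= 0) stop("u'Bu <= 0: M_e_eff is not positive definite")
    sum(u * amul(u)) / den
  }
  rho <- quotient(u)
  trace <- rho
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    grad <- amul(u) - rho * bmul(u)
    # backtracking safeguard: a near-bound step can cycle between supports,
    # so halve the step within the iteration until the quotient does not
    # decrease; this keeps the flow monotone (and convergent) while leaving
    # already-monotone trajectories untouched
    eta_eff <- eta
    for (bt in 1:30) {
      u_new <- u + (eta_eff / abs(rho)) * grad
      nrm <- sqrt(sum(u_new^2))
      if (nrm == 0) break
      u_new <- truncate_l(u_new / nrm)
      u_new <- u_new / sqrt(sum(u_new^2))
      rho_new <- quotient(u_new)
      if (rho_new >= rho - 1e-12) break
      eta_eff <- eta_eff / 2
    }
    if (nrm == 0) break
    trace <- c(trace, rho_new)
    u <- u_new
    if (abs(rho_new - rho) < tol) {
      rho <- rho_new
      converged <- TRUE
      break
    }
    rho <- rho_new
  }
  u <- .fix_sign(u)
  structure(list(weights = u, support = sort(which(u != 0)),
                 quotient_trace = trace, iterations = it,
                 converged = converged),
            class = "rifle_solution")
}

.power_lambda_max <- function(bmul, g, iter = 50) {
  v <- rep(1 / sqrt(g), g)
  lam <- 1
  for (k in seq_len(iter)) {
    w <- bmul(v)
    lam <- sqrt(sum(w^2))
    if (lam == 0) stop("M_e_eff is zero")
    v <- w / lam
  }
  lam
}

#' @export
print.rifle_solution <- function(x, ...) {
  cat("<rifle_solution> ", length(x$support), " nonzero weights, ",
      x$iterations, " iterations, quotient = ",
      signif(utils::tail(x$quotient_trace, 1), 6),
      if (x$converged) " (converged)" else " (max_iter)", "\n", sep = "")
  invisible(x)
}

#' Sparse gene signatures for fitted discriminant axes
#'
#' For each requested axis, rebuilds the matching covariance contrast and
#' runs [rifle()] initialized at the dense axis, yielding a gene signature
#' of at most `l` genes whose weights approximate the axis under the
#' sparsity constraint.
#'
#' @param em,fd The expression matrix and design the fit was made on.
#' @param fit An `flda_fit` from [fit_flda()].
#' @param l Support size (e.g. 20 for a follow-up candidate gene list).
#' @param targets Axis tags to sparsify (default: the leading axis of every
#'   fitted component).
#' @param eta,max_iter,tol Forwarded to [rifle()].
#' @return A named list of `rifle_solution` objects, one per target tag.
#' @export
sparse_signatures <- function(em, fd, fit, l, targets = NULL, eta = NULL,
                              max_iter = 1000, tol = 1e-8) {
  stopifnot(inherits(fit, "flda_fit"))
  if (is.null(targets))
    targets <- vapply(fit$components, function(co) co$axis_tags[1],
                      character(1))
  unknown <- setdiff(targets, fit$axis_tags)
  if (length(unknown))
    stop("unknown axis tags: ", paste(unknown, collapse = ", "))
  cfg <- fit$config
  cd <- .decompose(em, fd, residual = cfg$residual, eig_tol = cfg$eig_tol,
                   partial = fit$partial)
  me <- .resolve_me(cd, cfg$residual, cfg$eig_tol)
  B <- if (me$kind == "diag") me$d else me$matrix
  out <- list()
  for (tag in targets) {
    comp <- Filter(function(co) tag %in% co$axis_tags, fit$components)[[1]]
    f <- .contrast_factors(cd, comp$tag, cfg$lambda1, cfg$lambda2)
    init <- fit$axes[, tag]
    out[[tag]] <- rifle(list(W = f$W, signs = f$signs), B, init, l,
                        eta = eta, max_iter = max_iter, tol = tol)
  }
  out
}
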