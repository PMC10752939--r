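test_that("covariance decomposition matches a literal loop transcription", {
  d <- tiny_dataset()
  cd <- compute_decomposition(d$em, d$fd, residual = "full")
  nv <- naive_decomposition(d$em$values,
                            as.character(d$fd$labels$f1),
                            as.character(d$fd$labels$f2))
  expect_equal(unname(effect_covariance(cd, "M_A")), nv$MA,
               tolerance = 1e-12)
  expect_equal(unname(effect_covariance(cd, "M_B")), nv$MB,
               tolerance = 1e-12)
  expect_equal(unname(effect_covariance(cd, "M_AB")), nv$MAB,
               tolerance = 1e-12)
  expect_equal(unname(cd$M_e), nv$Me, tolerance = 1e-12)
  expect_equal(unname(cd$grand_mean), unname(nv$m), tolerance = 1e-12)
  # symmetry and residual PSD
  expect_lt(max(abs(cd$M_e - t(cd$M_e))), 1e-10)
  expect_gt(min(eigen(cd$M_e, symmetric = TRUE)$values), -1e-10)
})

test_that("decomposition matches the loop oracle on an unbalanced design", {
  set.seed(11)
  li <- c(rep("i1", 5), rep("i1", 3), rep("i2", 4), rep("i2", 6))
  lj <- c(rep("j1", 5), rep("j2", 3), rep("j1", 4), rep("j2", 6))
  x <- matrix(rnorm(3 * 18), 3, 18)
  em <- em_of(x)
  fd <- factor_design(data.frame(f1 = li, f2 = lj),
                      cell_ids = em$cell_ids)
  cd <- compute_decomposition(em, fd, residual = "full")
  nv <- naive_decomposition(x, li, lj)
  expect_equal(unname(effect_covariance(cd, "M_A")), nv$MA,
               tolerance = 1e-12)
  expect_equal(unname(effect_covariance(cd, "M_B")), nv$MB,
               tolerance = 1e-12)
  expect_equal(unname(effect_covariance(cd, "M_AB")), nv$MAB,
               tolerance = 1e-12)
  expect_equal(unname(cd$M_e), nv$Me, tolerance = 1e-12)
})

test_that("degenerate inputs give zero effect matrices", {
  # all cells identical: every matrix vanishes
  em <- em_of(matrix(3, 2, 8))
  cd <- compute_decomposition(em, design_2x2(2), residual = "full")
  for (w in c("M_A", "M_B", "M_AB", "M_e"))
    expect_equal(max(abs(effect_covariance(cd, w))), 0)

  # zero within-type noise: M_e = 0, effects match direct evaluation
  means <- cbind(c(1, 0), c(0, 1), c(2, 2), c(1, 3))
  x <- means[, rep(1:4, each = 2)]
  cd0 <- compute_decomposition(em_of(x), design_2x2(2), residual = "full")
  expect_equal(max(abs(cd0$M_e)), 0)
  nv <- naive_decomposition(x, rep(c("a", "a", "b", "b"), each = 2),
                            rep(c("x", "y", "x", "y"), each = 2))
  expect_equal(unname(effect_covariance(cd0, "M_A")), nv$MA,
               tolerance = 1e-12)

  expect_error(compute_decomposition(em_of(matrix(1:8, 2)), design_2x2(1)),
               "residual dof")
})

test_that("contrast assembly follows the signed covariance combination", {
  d <- random_instance(4, 3, seed = 2)
  cd <- compute_decomposition(d$em, d$fd, residual = "full")
  MA <- effect_covariance(cd, "M_A")
  MB <- effect_covariance(cd, "M_B")
  MAB <- effect_covariance(cd, "M_AB")
  expect_equal(build_contrast(cd, "feature_i", 0, 0), MA,
               tolerance = 1e-12)
  expect_equal(build_contrast(cd, "feature_i", 1, 1), MA - MB - MAB,
               tolerance = 1e-12)
  expect_equal(build_contrast(cd, "feature_j", 0.5, 2), MB - 0.5 * MA -
                 2 * MAB, tolerance = 1e-12)
  expect_equal(build_contrast(cd, "interaction", 1, 1), MAB - MA - MB,
               tolerance = 1e-12)
  nA <- build_contrast(cd, "feature_i")
  expect_lt(max(abs(nA - t(nA))), 1e-12)
})

test_that("top axis beats random directions and coordinate axes", {
  for (seed in 1:3) {
    d <- random_instance(8, 6, seed = seed)
    cd <- compute_decomposition(d$em, d$fd, residual = "full")
    nA <- build_contrast(cd, "feature_i")
    sol <- solve_component(nA, cd, 1, flda_config(residual = "full"))
    best <- rayleigh(sol$axes[, 1], nA, cd$M_e)
    expect_equal(best, sol$eigenvalues[1], tolerance = 1e-8)
    set.seed(seed + 100)
    dirs <- matrix(rnorm(8 * 1000), 8)
    quot <- colSums(dirs * (nA %*% dirs)) / colSums(dirs * (cd$M_e %*% dirs))
    expect_gte(best, max(quot) - 1e-10)
    expect_gte(best, max(sapply(1:8, function(k)
      rayleigh(diag(8)[, k], nA, cd$M_e))))
  }
})

test_that("axes are M_e-orthonormal with the documented sign convention", {
  d <- random_instance(10, 8, seed = 5)
  fit <- fit_flda(d$em, d$fd, flda_config(residual = "full"))
  cd <- compute_decomposition(d$em, d$fd, residual = "full")
  G <- crossprod(fit$axes, cd$M_e %*% fit$axes)
  expect_equal(unname(diag(G)), rep(1, 3), tolerance = 1e-8)

  # multi-axis component: generalized eigenvectors are M_e-orthogonal
  # within their component
  set.seed(6)
  li <- rep(rep(c("M", "L"), each = 4), each = 8)
  lj <- rep(rep(c("a", "b", "c", "d"), 2), each = 8)
  em4 <- em_of(matrix(rnorm(9 * 64), 9, 64))
  fd4 <- factor_design(data.frame(f1 = li, f2 = lj),
                       cell_ids = em4$cell_ids)
  fit4 <- fit_flda(em4, fd4, flda_config(residual = "full"))
  cd4 <- compute_decomposition(em4, fd4, residual = "full")
  Uj <- fit4$axes[, paste0("FLD_j", 1:3)]
  Gj <- crossprod(Uj, cd4$M_e %*% Uj)
  expect_lt(max(abs(Gj - diag(diag(Gj)))), 1e-8)
  # largest-|weight| entry of each axis is positive
  for (k in 1:3) {
    u <- fit$axes[, k]
    expect_gt(u[which.max(abs(u))], 0)
  }
  # eigenvalues non-increasing within each component
  for (co in fit$components)
    expect_true(all(diff(co$eigenvalues) <= 1e-10))
})

test_that("fit is invariant to cell permutation and duplication, and scale-equivariant", {
  d <- random_instance(6, 5, seed = 9)
  fit <- fit_flda(d$em, d$fd, flda_config(residual = "full"))

  set.seed(1); perm <- sample(20)
  emp <- expression_matrix(d$em$values[, perm], d$em$gene_ids,
                           d$em$cell_ids[perm], layer = "log")
  fdp <- factor_design(d$fd$labels[perm, ], cell_ids = d$fd$cell_ids[perm])
  fitp <- fit_flda(emp, fdp, flda_config(residual = "full"))
  expect_equal(fitp$axes, fit$axes, tolerance = 1e-10)

  dup <- expression_matrix(cbind(d$em$values, d$em$values),
                           d$em$gene_ids,
                           c(d$em$cell_ids, paste0("d", 1:20)),
                           layer = "log")
  fdd <- factor_design(rbind(d$fd$labels, d$fd$labels),
                       cell_ids = dup$cell_ids)
  fitd <- fit_flda(dup, fdd, flda_config(residual = "full"))
  # same directions; normalization changes through the residual divisor
  for (k in 1:3) {
    u <- fit$axes[, k]; v <- fitd$axes[, k]
    expect_gt(abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)), 1 - 1e-8)
  }

  sc <- expression_matrix(3.7 * d$em$values, d$em$gene_ids, d$em$cell_ids,
                          layer = "log")
  fits <- fit_flda(sc, d$fd, flda_config(residual = "full"))
  for (k in 1:3) {
    u <- fit$axes[, k]; v <- fits$axes[, k]
    expect_gt(abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)), 1 - 1e-10)
  }
  expect_equal(fits$components$feature_i$eigenvalues,
               fit$components$feature_i$eigenvalues, tolerance = 1e-8)
})

test_that("dense solve_component agrees with the factored fit path", {
  d <- random_instance(7, 6, seed = 13)
  for (mode in c("full", "diagonal")) {
    cfg <- flda_config(residual = mode)
    cd <- compute_decomposition(d$em, d$fd, residual = mode)
    fit <- fit_flda(d$em, d$fd, cfg)
    for (tag in c("feature_i", "feature_j", "interaction")) {
      sol <- solve_component(build_contrast(cd, tag), cd, 1, cfg)
      expect_equal(abs(sum(sol$axes[, 1] *
                             fit$axes[, fit$components[[tag]]$axis_tags[1]])),
                   sum(sol$axes[, 1]^2), tolerance = 1e-6)
      expect_equal(sol$eigenvalues[1],
                   fit$components[[tag]]$eigenvalues[1], tolerance = 1e-8)
    }
  }
})

test_that("a complete 2x4 design yields the 1 + 3 + 3 axis structure", {
  set.seed(3)
  li <- rep(rep(c("M", "L"), each = 4), each = 5)
  lj <- rep(rep(c("a", "b", "c", "d"), 2), each = 5)
  em <- em_of(matrix(rnorm(12 * 40), 12, 40))
  fd <- factor_design(data.frame(dend = li, axon = lj),
                      cell_ids = em$cell_ids)
  fit <- fit_flda(em, fd)
  expect_equal(ncol(fit$axes), 7L)
  expect_equal(fit$axis_tags,
               c("FLD_i", paste0("FLD_j", 1:3), paste0("FLD_ij", 1:3)))
  expect_error(fit_flda(em, fd, flda_config(dims = c(feature_i = 2))),
               "exceeds available dof")
})

test_that("a single informative gene receives all the weight", {
  set.seed(21)
  fd <- design_2x2(10)
  si <- rep(c(1, 1, -1, -1), each = 10)
  x <- matrix(5, 5, 40)                 # constant genes carry no signal
  x[1, ] <- si * 2 + rnorm(40, sd = 0.1)
  em <- em_of(x)
  fit <- fit_flda(em, fd, flda_config(dims = c(feature_i = 1)))
  w <- abs(fit$axes[, "FLD_i"])
  expect_gt(w[1] / sum(w), 1 - 1e-10)
  # projecting tracks gene 1 up to scale and sign
  co <- flda_project(em, fit)$coordinates[1, ]
  expect_gt(abs(cor(co, x[1, ])), 0.999)
})

test_that("feature axis with zeroed penalties matches a two-class LDA", {
  # when the second feature carries no effect the design collapses to a
  # single feature and the factorized axis agrees with plain two-class LDA
  set.seed(31)
  g <- 5; npt <- 100
  fd <- design_2x2(npt)
  si <- rep(c(1, 1, -1, -1), each = npt)
  x <- outer(rnorm(g), si) + matrix(rnorm(g * 4 * npt), g)
  em <- em_of(x)
  cfg <- flda_config(lambda1 = 0, lambda2 = 0, residual = "full",
                     dims = c(feature_i = 1))
  u <- fit_flda(em, fd, cfg)$axes[, 1]
  v <- lda_embed(em, fd$labels$f1, 1, residual = "full")$axes[, 1]
  expect_gt(abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)), 0.995)
})

test_that("partial tables drop the interaction and keep main effects", {
  set.seed(41)
  li <- rep(c("i1", "i1", "i2"), each = 6)
  lj <- rep(c("j1", "j2", "j1"), each = 6)
  x <- matrix(rnorm(4 * 18), 4, 18)
  x[1, li == "i2"] <- x[1, li == "i2"] + 3
  x[2, lj == "j2"] <- x[2, lj == "j2"] + 3
  em <- em_of(x)
  fd <- factor_design(data.frame(f1 = li, f2 = lj), cell_ids = em$cell_ids)
  expect_false(fd$complete)
  expect_error(fit_flda(em, fd), "partial")
  fit <- fit_flda_partial(em, fd)
  expect_equal(fit$axis_tags, c("FLD_i", "FLD_j"))
  expect_error(fit_flda_partial(em, fd, flda_config(
    dims = c(interaction = 1))), "partial table")
})

test_that("partial fit approaches the complete fit on additive data", {
  # additive ground truth: completing the missing cell with data consistent
  # with additivity leaves the feature axis nearly unchanged
  set.seed(51)
  g <- 6; npt <- 40
  li <- rep(c("i1", "i1", "i2", "i2"), each = npt)
  lj <- rep(c("j1", "j2", "j1", "j2"), each = npt)
  alpha <- rnorm(g); beta <- rnorm(g)
  mu <- outer(alpha, ifelse(li == "i1", 1, -1)) +
    outer(beta, ifelse(lj == "j1", 1, -1))
  x <- mu + matrix(rnorm(g * 4 * npt, sd = 0.3), g)
  em_full <- em_of(x)
  fd_full <- factor_design(data.frame(f1 = li, f2 = lj),
                           cell_ids = em_full$cell_ids)
  keep <- !(li == "i2" & lj == "j2")
  em_part <- expression_matrix(x[, keep], em_full$gene_ids,
                               em_full$cell_ids[keep], layer = "log")
  fd_part <- factor_design(fd_full$labels[keep, ],
                           cell_ids = em_full$cell_ids[keep])
  cfg <- flda_config(residual = "full", dims = c(feature_i = 1))
  u_full <- fit_flda(em_full, fd_full, cfg)$axes[, 1]
  u_part <- fit_flda_partial(em_part, fd_part, cfg)$axes[, 1]
  cosang <- abs(sum(u_full * u_part)) /
    sqrt(sum(u_full^2) * sum(u_part^2))
  expect_gt(cosang, 0.98)
})

test_that("partial path on a fully observed table equals lambda2 = 0 full path", {
  d <- random_instance(5, 6, seed = 61)
  cfg <- flda_config(lambda1 = 1, lambda2 = 0, residual = "diagonal",
                     dims = c(feature_i = 1))
  u_full <- fit_flda(d$em, d$fd, cfg)$axes[, 1]
  u_part <- suppressWarnings(
    fit_flda_partial(d$em, d$fd, cfg))$axes[, 1]
  # same direction; the residual divisor differs (N - ab vs N - T equal here)
  expect_equal(abs(sum(u_full * u_part)) /
                 sqrt(sum(u_full^2) * sum(u_part^2)), 1,
               tolerance = 1e-8)
})

test_that("projection is linear and validates gene sets", {
  d <- random_instance(6, 4, seed = 71)
  fit <- fit_flda(d$em, d$fd, flda_config(residual = "full"))
  zero <- expression_matrix(matrix(0, 6, 2), d$em$gene_ids, c("z1", "z2"),
                            layer = "log")
  expect_equal(max(abs(flda_project(zero, fit)$coordinates)), 0)

  cd <- compute_decomposition(d$em, d$fd, residual = "full")
  means_em <- expression_matrix(cd$cell_means, d$em$gene_ids,
                                paste0("t", 1:4), layer = "log")
  grand_em <- expression_matrix(cbind(cd$grand_mean), d$em$gene_ids, "gm",
                                layer = "log")
  lhs <- rowMeans(flda_project(means_em, fit)$coordinates)
  rhs <- flda_project(grand_em, fit)$coordinates[, 1]
  expect_equal(lhs, rhs, tolerance = 1e-10)

  bad <- expression_matrix(matrix(0, 2, 1), c("other1", "other2"), "c",
                           layer = "log")
  expect_error(flda_project(bad, fit), "lacks fitted genes")
})

test_that("balanced designs satisfy the between-type scatter identity", {
  # total between-type scatter splits into the three effect contributions
  d <- random_instance(4, 5, seed = 81)
  cd <- compute_decomposition(d$em, d$fd, residual = "full")
  total <- Reduce(`+`, lapply(1:4, function(t)
    tcrossprod(cd$cell_means[, t] - cd$grand_mean)))
  parts <- cd$b * (cd$a - 1) * effect_covariance(cd, "M_A") +
    cd$a * (cd$b - 1) * effect_covariance(cd, "M_B") +
    (cd$a - 1) * (cd$b - 1) * effect_covariance(cd, "M_AB")
  expect_equal(unname(total), unname(parts), tolerance = 1e-10)
})
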