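# Small in-code fixtures shared across test files.

# expression matrix from a bare matrix with default ids
em_of <- function(m, layer = "log") {
  expression_matrix(m, paste0("g", seq_len(nrow(m))),
                    paste0("c", seq_len(ncol(m))), layer = layer)
}

# balanced 2x2 design over n cells per type, types in blocks
design_2x2 <- function(cells_per_type) {
  n <- 4 * cells_per_type
  li <- rep(c("i1", "i1", "i2", "i2"), each = cells_per_type)
  lj <- rep(c("j1", "j2", "j1", "j2"), each = cells_per_type)
  factor_design(data.frame(f1 = li, f2 = lj),
                cell_ids = paste0("c", seq_len(n)))
}

# tiny hand-checkable dataset: 2 genes, 2x2 design, 2 cells per type
tiny_dataset <- function() {
  x <- matrix(c(1.0, 0.5,   1.2, 0.7,    # type (i1,j1)
                2.0, 1.5,   2.4, 1.1,    # type (i1,j2)
                -1.0, 0.2,  -0.8, 0.6,   # type (i2,j1)
                0.3, 1.9,   0.1, 1.5),   # type (i2,j2)
              nrow = 2)
  list(em = em_of(x), fd = design_2x2(2))
}

# random labeled instance for eigen-solver oracles
random_instance <- function(g, cells_per_type, seed, sigma = 1,
                            effect = 1) {
  set.seed(seed)
  fd <- design_2x2(cells_per_type)
  n <- 4 * cells_per_type
  si <- rep(c(1, 1, -1, -1), each = cells_per_type)
  sj <- rep(c(1, -1, 1, -1), each = cells_per_type)
  mu <- outer(stats::rnorm(g), si) * effect / 2 +
    outer(stats::rnorm(g), sj) * effect / 2
  x <- mu + matrix(stats::rnorm(g * n), g, n) * sigma
  list(em = em_of(x), fd = fd)
}

# literal transcription of the two-way variance partition: unweighted
# marginal means over type means, divisors a-1, b-1, (a-1)(b-1), and the
# residual with inner 1/n_ij weighting and divisor N - a*b (loops, no
# vectorization) -- the independent oracle for compute_decomposition()
naive_decomposition <- function(x, li, lj) {
  a_levels <- unique(li); b_levels <- unique(lj)
  a <- length(a_levels); b <- length(b_levels)
  g <- nrow(x); n <- ncol(x)
  m_ij <- array(0, c(g, a, b))
  n_ij <- matrix(0, a, b)
  for (i in seq_len(a)) for (j in seq_len(b)) {
    sel <- which(li == a_levels[i] & lj == b_levels[j])
    n_ij[i, j] <- length(sel)
    m_ij[, i, j] <- rowMeans(x[, sel, drop = FALSE])
  }
  m_i <- apply(m_ij, c(1, 2), mean)
  m_j <- apply(m_ij, c(1, 3), mean)
  m <- apply(m_ij, 1, mean)
  MA <- matrix(0, g, g); MB <- matrix(0, g, g); MAB <- matrix(0, g, g)
  Me <- matrix(0, g, g)
  for (i in seq_len(a)) MA <- MA + tcrossprod(m_i[, i] - m) / (a - 1)
  for (j in seq_len(b)) MB <- MB + tcrossprod(m_j[, j] - m) / (b - 1)
  for (i in seq_len(a)) for (j in seq_len(b)) {
    d <- m_ij[, i, j] - m_i[, i] - m_j[, j] + m
    MAB <- MAB + tcrossprod(d) / ((a - 1) * (b - 1))
    sel <- which(li == a_levels[i] & lj == b_levels[j])
    inner <- matrix(0, g, g)
    for (k in sel) inner <- inner + tcrossprod(x[, k] - m_ij[, i, j])
    Me <- Me + inner / n_ij[i, j]
  }
  Me <- Me / (n - a * b)
  list(MA = MA, MB = MB, MAB = MAB, Me = Me, m = m, m_i = m_i, m_j = m_j)
}

rayleigh <- function(u, A, B) {
  as.numeric(crossprod(u, A %*% u) / crossprod(u, B %*% u))
}
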