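#' Specification of the factorial synthetic benchmark
#'
#' Describes a dataset of `a * b` cell types from the Cartesian product of
#' two categorical features, with gene blocks tied to the first feature,
#' the second feature, their interaction, or pure noise.  Informative genes
#' carry a balanced `+/- effect_size` mean shift per level sign and
#' within-type Gaussian noise of SD `sigma`; noise-block genes have mean 0
#' and a fixed SD `noise_gene_sd` that does not follow the `sigma` sweep.
#' The defaults for `effect_size` and `noise_gene_sd` are calibration
#' constants stored in `inst/extdata/synthetic_calibration.yaml`.
#'
#' @param a,b Levels of the two features (default 2 x 2).
#' @param cells_per_type Cells per type (default 250).
#' @param g Number of genes (default 1000).
#' @param gene_blocks Named block sizes (`feature_i`, `feature_j`,
#'   `interaction`, `noise`) summing to `g`; defaults to `g / 4` each.
#' @param effect_size Mean shift of informative genes.
#' @param sigma Within-type noise SD of informative genes.
#' @param noise_gene_sd Noise SD of the unstructured noise block.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(a = 2, b = 2, cells_per_type = 250, g = 1000,
                           gene_blocks = NULL, effect_size = NULL,
                           sigma = 2, noise_gene_sd = NULL, seed = 1) {
  cal <- .calibration()
  if (is.null(effect_size)) effect_size <- cal$effect_size
  if (is.null(noise_gene_sd)) noise_gene_sd <- cal$noise_gene_sd
  if (is.null(gene_blocks)) {
    q <- g %/% 4
    gene_blocks <- c(feature_i = q, feature_j = q, interaction = q,
                     noise = g - 3 * q)
  }
  stopifnot(sum(gene_blocks) == g, cells_per_type >= 2, sigma > 0,
            noise_gene_sd > 0, a >= 2, b >= 2,
            setequal(names(gene_blocks),
                     c("feature_i", "feature_j", "interaction", "noise")))
  structure(list(a = a, b = b, cells_per_type = cells_per_type, g = g,
                 gene_blocks = gene_blocks, effect_size = effect_size,
                 sigma = sigma, noise_gene_sd = noise_gene_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.calibration <- function() {
  path <- system.file("extdata", "synthetic_calibration.yaml",
                      package = "flda")
  if (!nzchar(path))  # during development without installation
    path <- file.path("inst", "extdata", "synthetic_calibration.yaml")
  yaml::read_yaml(path)
}

# Orthogonal level-effect patterns: Helmert contrasts with each column
# scaled to unit RMS over levels.  For 2 levels this is the single balanced
# +1/-1 pattern; for more levels the L-1 columns give every level a distinct
# effect pattern of the same average magnitude.
.level_contrasts <- function(n_levels) {
  C <- stats::contr.helmert(n_levels)
  apply(C, 2, function(col) col * sqrt(n_levels / sum(col^2)))
}

#' Generate a factorial synthetic expression dataset
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `expression` (an [expression_matrix()], continuous
#'   log-scale values), `design` (a [factor_design()] with features
#'   `feature_i`, `feature_j`), `gene_blocks` (per-gene block assignment)
#'   and `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  blocks <- rep(names(spec$gene_blocks), spec$gene_blocks)
  g <- spec$g
  n <- spec$a * spec$b * spec$cells_per_type
  li <- rep(rep(seq_len(spec$a), each = spec$b), each = spec$cells_per_type)
  lj <- rep(rep(seq_len(spec$b), times = spec$a), each = spec$cells_per_type)
  Ca <- .level_contrasts(spec$a)          # a x (a-1), unit-RMS columns
  Cb <- .level_contrasts(spec$b)

  # each informative gene carries one contrast pattern (cycling through the
  # available contrasts of its block's factor, or contrast pairs for the
  # interaction block), scaled by the effect size
  mu <- matrix(0, g, n)
  bi <- which(blocks == "feature_i")
  ci <- ((seq_along(bi) - 1) %% (spec$a - 1)) + 1
  mu[bi, ] <- spec$effect_size * Ca[cbind(rep(li, each = length(bi)),
                                          rep(ci, times = n))]
  bj <- which(blocks == "feature_j")
  cj <- ((seq_along(bj) - 1) %% (spec$b - 1)) + 1
  mu[bj, ] <- spec$effect_size * Cb[cbind(rep(lj, each = length(bj)),
                                          rep(cj, times = n))]
  bij <- which(blocks == "interaction")
  combo <- ((seq_along(bij) - 1) %% ((spec$a - 1) * (spec$b - 1)))
  cia <- combo %% (spec$a - 1) + 1
  cjb <- combo %/% (spec$a - 1) + 1
  mu[bij, ] <- spec$effect_size *
    Ca[cbind(rep(li, each = length(bij)), rep(cia, times = n))] *
    Cb[cbind(rep(lj, each = length(bij)), rep(cjb, times = n))]
  sd_g <- ifelse(blocks == "noise", spec$noise_gene_sd, spec$sigma)
  x <- mu + matrix(stats::rnorm(g * n), g, n) * sd_g

  gene_ids <- sprintf("gene%04d", seq_len(g))
  cell_ids <- sprintf("cell%04d", seq_len(n))
  em <- expression_matrix(x, gene_ids, cell_ids, layer = "log")
  fd <- factor_design(
    data.frame(feature_i = paste0("i", li), feature_j = paste0("j", lj)),
    cell_ids = cell_ids)
  list(expression = em, design = fd, gene_blocks = blocks, spec = spec)
}

#' Noise-sweep benchmark across embedding methods
#'
#' For each noise level and replicate, generates a synthetic dataset, fits
#' the factorized embedding restricted to the main-effect axes (the fair
#' comparison on a factorial design) plus the requested baselines at the
#' matching dimensionality, and evaluates the metric suite.  Returns mean
#' and standard-error tables of silhouette, normalized overall SNR and
#' overall modularity per method.
#'
#' @param spec A [synthetic_spec()]; its `sigma` is overridden by `sigmas`
#'   and its `seed` offsets the per-replicate seeds (`seed + rep`).
#' @param sigmas Noise levels to sweep.
#' @param reps Replicates per noise level.
#' @param methods Methods to compare; subset of `flda`, `two_ldas`, `lda`,
#'   `cca`, `pca`.
#' @param reference Method whose overall SNR normalizes the others.
#' @return An object of class `flda_benchmark`: matrices `silhouette`,
#'   `snr_normalized`, `modularity` (and `*_se` companions, rows = sigmas,
#'   columns = methods), plus the long per-replicate table in `raw`.  When
#'   `reps == 1` standard errors are reported as 0 and flagged via the
#'   `se_undefined` attribute.
#' @export
sigma_sweep <- function(spec = synthetic_spec(),
                        sigmas = c(2, 4, 6, 8, 10), reps = 10,
                        methods = c("flda", "two_ldas", "lda", "cca",
                                    "pca"),
                        reference = "lda") {
  stopifnot(reps >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  if (!reference %in% methods)
    stop("reference method must be among the compared methods")
  r_cmp <- (spec$a - 1) + (spec$b - 1)
  rows <- list()
  for (sigma in sigmas) {
    for (rp in seq_len(reps)) {
      sp <- spec
      sp$sigma <- sigma
      sp$seed <- spec$seed + rp
      dat <- generate_synthetic(sp)
      em <- dat$expression; fd <- dat$design
      emb <- list()
      for (m in methods) {
        emb[[m]] <- switch(m,
          flda = flda_project(em, fit_flda(em, fd, flda_config(
            dims = c(feature_i = sp$a - 1, feature_j = sp$b - 1)))),
          two_ldas = two_ldas_embed(em, fd),
          lda = lda_embed(em, design_types(fd), r_cmp),
          cca = cca_embed(em, fd, r_cmp),
          pca = pca_embed(em, r_cmp))
      }
      rep_summary <- overall_report(emb, fd, reference = reference)$summary
      rep_summary$sigma <- sigma
      rep_summary$rep <- rp
      rows[[length(rows) + 1]] <- rep_summary
    }
  }
  raw <- do.call(rbind, rows)
  agg <- function(col, f) {
    m <- tapply(raw[[col]], list(raw$sigma, raw$method), f)
    m[as.character(sigmas), methods, drop = FALSE]
  }
  se <- function(z) if (length(z) < 2) 0 else stats::sd(z) /
    sqrt(length(z))
  out <- list(silhouette = agg("silhouette", mean),
              silhouette_se = agg("silhouette", se),
              snr_normalized = agg("overall_snr_normalized", mean),
              snr_normalized_se = agg("overall_snr_normalized", se),
              modularity = agg("overall_modularity", mean),
              modularity_se = agg("overall_modularity", se),
              raw = raw, reps = reps, reference = reference)
  attr(out, "se_undefined") <- reps == 1
  class(out) <- "flda_benchmark"
  out
}

#' @export
print.flda_benchmark <- function(x, ...) {
  cat("<flda_benchmark> ", x$reps, " reps, reference = ", x$reference,
      "\nmean silhouette:\n", sep = "")
  print(round(x$silhouette, 3))
  invisible(x)
}
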