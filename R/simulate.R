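## Synthetic data generators: draw counts from exactly the model the
## package fits, with every piece of ground truth retained, so that all
## estimation, mapping and cross-validation machinery can be tested
## without external downloads.

## MVN draw with covariance K from a precomputed upper Cholesky factor
## (K = t(U) %*% U); jittered factorization helper.
chol_with_jitter <- function(K, jitter = 1e-8) {
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch))
    ch <- chol(K + diag(jitter * mean(diag(K)), nrow(K)))
  ch
}

grid_coords <- function(n) {
  side <- ceiling(sqrt(n))
  g <- expand.grid(x = seq_len(side), y = seq_len(side))
  as.matrix(g[seq_len(n), , drop = FALSE])
}

#' Simulate single-gene spatial counts from the generative model
#'
#' Draws one gene's spatial counts from the model the package fits:
#' `g ~ MVN(0, sigma2 h2 K)`, `e ~ MVN(0, sigma2 (1 - h2) I)`,
#' `log lambda = alpha + x beta + g + e`, `y_i ~ Poisson(N_i lambda_i)`.
#' Every realized quantity is returned as ground truth.  Rerunning with
#' the same seed reproduces every field exactly.
#'
#' @param n number of pixels.
#' @param coords_layout `"grid"` (default, square lattice) or
#'   `"uniform"` (uniform random on the unit square, scaled by
#'   `sqrt(n)`).
#' @param alpha,beta,sigma2,h2 model parameters (`h2` in `[0, 1]`).
#' @param kernel kernel spec list or `"kernel_matrix"` (see
#'   [make_kernel()]); default CAR with `alpha_s = 0.5` on a 4-nearest
#'   neighbour graph.
#' @param x covariate vector; drawn standard normal when `NULL`.
#' @param size_factors positive offsets `N_i`; drawn
#'   `LogNormal(log 500, 0.3)` when `NULL`.
#' @param seed RNG seed.
#' @return list of class `"glsm_simulation"` with `y`, `x`, `offset`,
#'   `coords`, `kernel`, and `truth` (class `"simulation_truth"`: the
#'   parameters, realized `g`, `e`, `lambda` and the seed).
#' @export
simulate_glsm_counts <- function(n = 400, coords_layout = c("grid", "uniform"),
                                 alpha = 0, beta = 0, sigma2 = 1, h2 = 0.5,
                                 kernel = list(kind = "car", alpha_s = 0.5),
                                 x = NULL, size_factors = NULL, seed = 1) {
  coords_layout <- match.arg(coords_layout)
  stopifnot(n >= 3L, sigma2 >= 0, h2 >= 0, h2 <= 1)
  set.seed(seed)
  coords <- if (coords_layout == "grid") grid_coords(n) else
    cbind(x = stats::runif(n) * sqrt(n), y = stats::runif(n) * sqrt(n))
  km <- make_kernel(coords, kernel)
  U <- chol_with_jitter(km$K)

  if (is.null(x)) x <- stats::rnorm(n)
  if (is.null(size_factors))
    size_factors <- exp(stats::rnorm(n, log(500), 0.3))
  g <- sqrt(sigma2 * h2) * drop(crossprod(U, stats::rnorm(n)))
  e <- stats::rnorm(n, 0, sqrt(sigma2 * (1 - h2)))
  lambda <- exp(alpha + x * beta + g + e)
  y <- stats::rpois(n, size_factors * lambda)

  truth <- structure(list(alpha = alpha, beta = beta, sigma2 = sigma2,
                          h2 = h2, kernel_kind = km$kind,
                          kernel_parameters = km$parameters,
                          g = g, e = e, lambda = lambda, seed = seed),
                     class = "simulation_truth")
  structure(list(y = y, x = x, offset = size_factors, coords = coords,
                 kernel = km, truth = truth),
            class = "glsm_simulation")
}

#' @export
print.glsm_simulation <- function(x, ...) {
  cat(sprintf("Simulated spatial counts: n = %d, alpha = %g, beta = %g, sigma2 = %g, h2 = %g (%s kernel, seed %d)\n",
              length(x$y), x$truth$alpha, x$truth$beta, x$truth$sigma2,
              x$truth$h2, x$truth$kernel_kind, x$truth$seed))
  invisible(x)
}

#' Simulate a paired spatial / scRNA-seq study with known truth
#'
#' Generates the full two-modality input structure: cell-type center
#' profiles, single-cell counts drawn per cell from its type's profile,
#' pixels with true cell types, and per-gene spatial counts drawn from
#' the generative spatial model with the (standardized) true center
#' expression as covariate.
#'
#' A fraction of genes (`null_fraction`) carries `beta = 0` and an
#' independent spatial realization (pure noise genes, for calibration
#' checks).  The remaining signal genes are organized into `n_modules`
#' co-expression modules: genes of one module share both a center profile
#' (up to `profile_noise_sd` perturbation, so they are strongly
#' correlated in single-cell space) and one spatial random-effect
#' realization `u ~ MVN(0, K)` (gene level effect
#' `sqrt(sigma2 h2) u`), which is what makes hold-out genes predictable
#' from their module mates.  Each gene keeps its own independent nugget.
#'
#' @param n_pixels,n_genes,n_cells,n_types study dimensions
#'   (`n_types >= 2`, `n_genes >= 10`).
#' @param n_modules number of signal co-expression modules.
#' @param beta covariate effect for signal genes.
#' @param null_fraction fraction of genes simulated with `beta = 0`.
#' @param sigma2 total random-effect variance.
#' @param h2 spatial variance share; scalar or one value per gene.
#' @param kernel kernel spec list or `"kernel_matrix"`.
#' @param center_sd spread of the per-type center log-expression
#'   (controls cell-type separation).
#' @param profile_noise_sd per-gene perturbation of the module profile.
#' @param module_sharing what module mates share of their random effects:
#'   `"full"` (default) shares the whole realized log-scale deviation
#'   `g + e` (the module's biological signal; genes differ only through
#'   their center-profile perturbation and Poisson measurement noise),
#'   `"spatial"` shares only the spatial component `g`, each gene drawing
#'   its own nugget.
#' @param n_duplicate_pairs number of planted duplicate gene pairs
#'   (gene `2j` copies the center profile of gene `2j - 1` exactly), for
#'   reference-selection tests.
#' @param coords_layout `"grid"` or `"uniform"`.
#' @param mean_depth mean single-cell read depth (log-normal).
#' @param mean_size_factor mean per-pixel total count scale (log-normal).
#' @param seed RNG seed; same seed reproduces everything exactly.
#' @return list with `paired` (a [pair_datasets()] object) and `truth`
#'   (class `"paired_simulation_truth"`): per-gene `beta`, `h2`, module,
#'   signal flag, realized `g`, `e` and `lambda` matrices, true pixel
#'   types, center log-profiles, and the seed.
#' @export
simulate_paired_datasets <- function(n_pixels = 400, n_genes = 100,
                                     n_cells = 500, n_types = 5,
                                     n_modules = 5, beta = 1,
                                     null_fraction = 0.5,
                                     sigma2 = 1, h2 = 0.6,
                                     kernel = list(kind = "car", alpha_s = 0.5),
                                     center_sd = 1, profile_noise_sd = 0.2,
                                     module_sharing = c("full", "spatial"),
                                     n_duplicate_pairs = 0,
                                     coords_layout = c("grid", "uniform"),
                                     mean_depth = 2000,
                                     mean_size_factor = 500,
                                     seed = 1) {
  coords_layout <- match.arg(coords_layout)
  module_sharing <- match.arg(module_sharing)
  stopifnot(n_types >= 2L, n_genes >= 10L, n_modules >= 1L,
            null_fraction >= 0, null_fraction <= 1)
  h2 <- rep(h2, length.out = n_genes)
  stopifnot(all(h2 >= 0), all(h2 <= 1))
  set.seed(seed)

  types <- sprintf("type%02d", seq_len(n_types))
  genes <- sprintf("gene%03d", seq_len(n_genes))
  n_signal <- round((1 - null_fraction) * n_genes)
  is_signal <- seq_len(n_genes) <= n_signal
  module <- ifelse(is_signal,
                   ((seq_len(n_genes) - 1L) %% n_modules) + 1L, NA_integer_)

  ## center log-profiles: gene baseline + (module or own) type profile +
  ## per-gene perturbation
  m <- stats::rnorm(n_genes, 0, 0.75)
  mod_profile <- matrix(stats::rnorm(n_types * n_modules, 0, center_sd),
                        n_types, n_modules)
  own_profile <- matrix(stats::rnorm(n_types * n_genes, 0, center_sd),
                        n_types, n_genes)
  noise <- matrix(stats::rnorm(n_types * n_genes, 0, profile_noise_sd),
                  n_types, n_genes)
  L <- matrix(rep(m, each = n_types), n_types, n_genes)
  for (j in seq_len(n_genes)) {
    L[, j] <- L[, j] +
      (if (is_signal[j]) mod_profile[, module[j]] else own_profile[, j]) +
      noise[, j]
  }
  if (n_duplicate_pairs > 0) {
    for (d in seq_len(n_duplicate_pairs)) {
      orig <- 2L * d - 1L; dup <- 2L * d
      L[, dup] <- L[, orig]
      is_signal[dup] <- is_signal[orig]
      module[dup] <- module[orig]
    }
  }
  dimnames(L) <- list(types, genes)

  ## scRNA-seq counts: per cell, Poisson around depth x type composition
  cell_types <- rep(types, length.out = n_cells)
  depth <- exp(stats::rnorm(n_cells, log(mean_depth), 0.3))
  comp <- exp(L)
  comp <- comp / rowSums(comp)              # type-level gene composition
  mu_sc <- depth * comp[cell_types, , drop = FALSE]
  sc_counts <- matrix(stats::rpois(n_cells * n_genes, mu_sc),
                      n_cells, n_genes,
                      dimnames = list(sprintf("cell%04d", seq_len(n_cells)),
                                      genes))
  if (n_duplicate_pairs > 0) {
    ## duplicates are exact copies in the single-cell matrix, giving a
    ## planted correlation of exactly 1 for reference-selection tests
    for (d in seq_len(n_duplicate_pairs))
      sc_counts[, 2L * d] <- sc_counts[, 2L * d - 1L]
  }

  ## spatial side
  coords <- if (coords_layout == "grid") grid_coords(n_pixels) else
    cbind(x = stats::runif(n_pixels) * sqrt(n_pixels),
          y = stats::runif(n_pixels) * sqrt(n_pixels))
  rownames(coords) <- sprintf("px%04d", seq_len(n_pixels))
  km <- make_kernel(coords, kernel)
  U <- chol_with_jitter(km$K)
  pixel_type <- sample(types, n_pixels, replace = TRUE)
  size_factors <- exp(stats::rnorm(n_pixels, log(mean_size_factor), 0.3))
  u_module <- matrix(0, n_pixels, n_modules)
  for (mmod in seq_len(n_modules))
    u_module[, mmod] <- drop(crossprod(U, stats::rnorm(n_pixels)))
  z_module <- matrix(stats::rnorm(n_pixels * n_modules), n_pixels, n_modules)

  alpha <- log(1 / n_genes)
  beta_g <- ifelse(is_signal, beta, 0)
  X <- matrix(0, n_pixels, n_genes, dimnames = list(rownames(coords), genes))
  G <- E <- LAM <- matrix(0, n_pixels, n_genes)
  Y <- matrix(0L, n_pixels, n_genes,
              dimnames = list(rownames(coords), genes))
  for (j in seq_len(n_genes)) {
    xv <- L[pixel_type, j]
    sdx <- stats::sd(xv)
    xv <- if (sdx > 0) (xv - mean(xv)) / sdx else xv - mean(xv)
    X[, j] <- xv
    u <- if (is_signal[j]) u_module[, module[j]] else
      drop(crossprod(U, stats::rnorm(n_pixels)))
    G[, j] <- sqrt(sigma2 * h2[j]) * u
    z <- if (is_signal[j] && module_sharing == "full")
      z_module[, module[j]] else stats::rnorm(n_pixels)
    E[, j] <- sqrt(sigma2 * (1 - h2[j])) * z
    LAM[, j] <- exp(alpha + xv * beta_g[j] + G[, j] + E[, j])
    Y[, j] <- stats::rpois(n_pixels, size_factors * LAM[, j])
  }

  spatial <- suppressWarnings(spatial_dataset(Y, coords))
  sc <- sc_dataset(sc_counts, cell_types)
  paired <- pair_datasets(spatial, sc)

  truth <- structure(list(
    alpha = alpha, beta = beta_g, h2 = h2, sigma2 = sigma2,
    is_signal = is_signal, module = module,
    kernel_kind = km$kind, kernel_parameters = km$parameters,
    g = G, e = E, lambda = LAM, x = X,
    pixel_type = pixel_type, center_log_profiles = L,
    size_factors = size_factors, genes = genes, seed = seed),
    class = "paired_simulation_truth")
  list(paired = paired, truth = truth)
}
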