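#' Pearson correlation with explicit degeneracy checks
#'
#' Standard product-moment correlation, refusing the undefined cases
#' (length below 3, constant input) instead of returning `NA`.
#'
#' @param a,b numeric vectors of equal length (at least 3).
#' @return correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (length(a) < 3L) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(a, b)
}

## Shared CV engine: given a fixed train/test split, build centers,
## assignment (train genes only -- test genes never touch the fitting
## inputs), reference set, then predict and score every test gene.
run_cv_split <- function(paired, test_genes, train_genes, kernel,
                         p_cut = 0.05, null_permute = FALSE,
                         control = glsm_control()) {
  ## training view of the spatial data: the held-out genes are treated as
  ## unmeasured, so size factors (and any pixel drops) are recomputed from
  ## the training genes alone -- no test-gene count can reach the fits
  sp_train <- suppressWarnings(spatial_dataset(
    paired$spatial$counts[, train_genes, drop = FALSE],
    paired$spatial$coords))
  paired_train <- structure(
    list(spatial = sp_train, sc = paired$sc, shared_genes = train_genes),
    class = "paired_data")
  kernel <- make_kernel(sp_train$coords, kernel)
  centers <- cell_type_centers(paired$sc)
  assignment <- suppressWarnings(
    assign_pixels(sp_train, centers, train_genes))
  refs <- build_reference_set(paired_train, assignment, kernel,
                              p_cut = p_cut, genes = train_genes,
                              control = control)

  sel <- lapply(test_genes, function(g) {
    tryCatch(select_reference_gene(g, refs, paired$sc),
             error = function(e) NULL)
  })
  if (null_permute && length(test_genes) > 1L) {
    ## break the target-reference link: rotate the selected references
    ## across the test genes (a fixed derangement, no extra randomness)
    sel <- sel[c(seq_along(sel)[-1L], 1L)]
  }

  rows <- lapply(seq_along(test_genes), function(i) {
    g <- test_genes[i]
    na_row <- function(note) data.frame(
      gene = g, cor = NA_real_, reference = NA_character_,
      ref_cor_sc = NA_real_, note = note)
    if (is.null(sel[[i]])) return(na_row("no reference selected"))
    obs <- paired$spatial$counts[sp_train$pixel_ids, g]
    if (stats::sd(obs) == 0) return(na_row("constant observed counts"))
    pred <- tryCatch(
      predict_gene(g, refs, assignment, paired$sc,
                   reference_gene = sel[[i]]$gene),
      error = function(e) NULL)
    if (is.null(pred)) return(na_row("prediction failed"))
    r <- tryCatch(pearson_cor(obs, pred$table$predicted_count),
                  error = function(e) NA_real_)
    data.frame(gene = g, cor = r, reference = sel[[i]]$gene,
               ref_cor_sc = sel[[i]]$correlation, note = "")
  })
  per_gene <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), cor = numeric(), reference = character(),
               ref_cor_sc = numeric(), note = character())
  list(per_gene = per_gene, reference_set = refs, assignment = assignment)
}

cv_summary <- function(per_gene) {
  ok <- per_gene$cor[!is.na(per_gene$cor)]
  if (length(ok) == 0L)
    return(list(mean = NA_real_, min = NA_real_, max = NA_real_,
                se = NA_real_, n = 0L, n_excluded = nrow(per_gene)))
  list(mean = mean(ok), min = min(ok), max = max(ok),
       se = stats::sd(ok) / sqrt(length(ok)), n = length(ok),
       n_excluded = sum(is.na(per_gene$cor)))
}

#' Leave-n-genes-out cross-validation
#'
#' Removes `n_test` randomly chosen shared genes, fits the reference set
#' on the remaining genes, predicts each held-out gene from its most
#' correlated reference, and scores the Pearson correlation between the
#' observed spatial counts and the predicted counts.  The held-out genes'
#' spatial counts are excluded from every fitting input (pixel assignment
#' and reference fits alike).
#'
#' @param paired a [pair_datasets()] object.
#' @param n_test number of genes to hold out.
#' @param kernel kernel matrix or spec list ([make_kernel()]).
#' @param seed RNG seed for the gene split.
#' @param p_cut reference-set significance cut.
#' @param null_permute if `TRUE`, the selected references are rotated
#'   across the test genes, breaking the target-reference pairing; used as
#'   a permutation null for the prediction skill.
#' @param control a [glsm_control()] list.
#' @return An object of class `"cv_result"`: `per_gene` (data frame:
#'   `gene`, `cor`, `reference`, `ref_cor_sc`, `note`), `summary` (mean,
#'   min, max, se, n, n_excluded), `test_genes`, `seed`.
#' @export
leave_n_genes_out <- function(paired, n_test, kernel, seed = 1,
                              p_cut = 0.05, null_permute = FALSE,
                              control = glsm_control()) {
  stopifnot(inherits(paired, "paired_data"))
  shared <- paired$shared_genes
  if (n_test >= length(shared))
    stop("'n_test' must be smaller than the number of shared genes")
  set.seed(seed)
  test_genes <- sort(sample(shared, n_test), method = "radix")
  train_genes <- setdiff(shared, test_genes)
  if (n_test == 0L) {
    return(structure(list(
      per_gene = data.frame(gene = character(), cor = numeric(),
                            reference = character(), ref_cor_sc = numeric(),
                            note = character()),
      summary = cv_summary(data.frame(cor = numeric())),
      test_genes = character(), seed = seed),
      class = "cv_result"))
  }
  run <- run_cv_split(paired, test_genes, train_genes, kernel,
                      p_cut = p_cut, null_permute = null_permute,
                      control = control)
  structure(list(per_gene = run$per_gene, summary = cv_summary(run$per_gene),
                 test_genes = test_genes, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Leave-%d-genes-out CV (seed %d): mean r = %.3f (se %.3f), range [%.3f, %.3f], %d scored / %d excluded\n",
              length(x$test_genes), x$seed, s$mean, s$se, s$min, s$max,
              s$n, s$n_excluded))
  invisible(x)
}

#' Training-set downsampling experiment
#'
#' Fixes one test split, then refits the reference set on nested random
#' subsets of the training genes of the requested sizes, recording for
#' each size the mean prediction correlation and the mean single-cell
#' correlation between the test genes and their chosen references.
#' Subsets are nested (a prefix of one seeded permutation), so the
#' reference pool only grows with `train_size`.
#'
#' @param paired a [pair_datasets()] object.
#' @param n_test number of held-out genes.
#' @param train_sizes integer vector of training-set sizes.
#' @param kernel kernel matrix or spec list.
#' @param seed RNG seed (test split and training permutation).
#' @param p_cut reference-set significance cut.
#' @param control a [glsm_control()] list.
#' @return data frame with one row per training size: `train_size`,
#'   `mean_cor`, `mean_ref_cor`, `n_scored`.
#' @export
downsampling_experiment <- function(paired, n_test, train_sizes, kernel,
                                    seed = 1, p_cut = 0.05,
                                    control = glsm_control()) {
  stopifnot(inherits(paired, "paired_data"), length(train_sizes) >= 1L)
  shared <- paired$shared_genes
  if (n_test >= length(shared)) stop("'n_test' too large")
  set.seed(seed)
  test_genes <- sort(sample(shared, n_test), method = "radix")
  pool <- setdiff(shared, test_genes)
  if (max(train_sizes) > length(pool))
    stop("largest 'train_sizes' exceeds the ", length(pool),
         " available training genes")
  perm <- sample(pool)
  rows <- lapply(train_sizes, function(k) {
    train <- sort(perm[seq_len(k)], method = "radix")
    run <- run_cv_split(paired, test_genes, train, kernel,
                        p_cut = p_cut, control = control)
    ok <- !is.na(run$per_gene$cor)
    data.frame(train_size = k,
               mean_cor = mean(run$per_gene$cor[ok]),
               mean_ref_cor = mean(run$per_gene$ref_cor_sc[ok]),
               n_scored = sum(ok))
  })
  do.call(rbind, rows)
}

#' Default kernel-sensitivity grid
#'
#' CAR kernels with spatial dependence 0.1 to 0.9 plus Gaussian kernels at
#' the five default data-adaptive bandwidths ([default_bandwidths()]).
#'
#' @param coords pixel coordinates (used for the Gaussian bandwidths).
#' @return list of kernel spec lists for [make_kernel()].
#' @export
default_kernel_grid <- function(coords) {
  c(lapply(seq(0.1, 0.9, by = 0.1),
           function(a) list(kind = "car", alpha_s = a)),
    lapply(default_bandwidths(coords),
           function(b) list(kind = "gaussian", bandwidth = b)))
}

#' Kernel-sensitivity sweep
#'
#' Reruns the same cross-validation split under each kernel configuration
#' in `kernel_grid`, recording the mean prediction correlation per
#' configuration.  A configuration that fails is recorded as failed and
#' the sweep continues.
#'
#' @param paired a [pair_datasets()] object.
#' @param n_test number of held-out genes.
#' @param kernel_grid list of kernel spec lists (see
#'   [default_kernel_grid()]) or `"kernel_matrix"` objects.
#' @param seed RNG seed for the (shared) test split.
#' @param p_cut reference-set significance cut.
#' @param control a [glsm_control()] list.
#' @return data frame with one row per configuration: `kind`, `parameter`,
#'   `mean_cor`, `n_scored`, `failed`.
#' @export
kernel_sensitivity <- function(paired, n_test, kernel_grid, seed = 1,
                               p_cut = 0.05, control = glsm_control()) {
  stopifnot(inherits(paired, "paired_data"), length(kernel_grid) >= 1L)
  shared <- paired$shared_genes
  set.seed(seed)
  test_genes <- sort(sample(shared, n_test), method = "radix")
  train_genes <- setdiff(shared, test_genes)
  rows <- lapply(kernel_grid, function(spec) {
    kind <- if (inherits(spec, "kernel_matrix")) spec$kind else spec$kind
    par <- if (inherits(spec, "kernel_matrix"))
      unlist(spec$parameters)[1L]
    else if (identical(kind, "car")) spec$alpha_s else spec$bandwidth
    if (is.null(par)) par <- NA_real_
    res <- tryCatch(
      run_cv_split(paired, test_genes, train_genes, spec,
                   p_cut = p_cut, control = control),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(kind = kind, parameter = par, mean_cor = NA_real_,
                        n_scored = 0L, failed = TRUE))
    ok <- !is.na(res$per_gene$cor)
    data.frame(kind = kind, parameter = par,
               mean_cor = mean(res$per_gene$cor[ok]),
               n_scored = sum(ok), failed = FALSE)
  })
  do.call(rbind, rows)
}
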