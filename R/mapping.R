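#' Normalize an expression matrix
#'
#' Depth-normalizes each row (cell or pixel) to `scale_factor` total
#' counts and applies `log1p`; `method = "raw"` returns the counts
#' unchanged.  Used consistently for cell-type centers, pixel profiles and
#' single-cell gene-gene correlations so that all correlation and
#' covariate computations live on one scale.
#'
#' @param counts non-negative matrix, observations in rows.
#' @param method `"lognorm"` (default) or `"raw"`.
#' @param scale_factor library-size target for the normalization.
#' @param depth optional row depths; defaults to the row sums of `counts`.
#' @return numeric matrix of the same shape.
#' @export
normalize_expression <- function(counts, method = c("lognorm", "raw"),
                                 scale_factor = 1e4, depth = NULL) {
  method <- match.arg(method)
  if (method == "raw") return(counts)
  if (is.null(depth)) depth <- rowSums(counts)
  depth[depth == 0] <- 1
  log1p(counts / depth * scale_factor)
}

#' Cell-type expression centers
#'
#' Computes, for every cell type, the average expression profile of the
#' cells carrying that label ("the center").  By default expression is
#' depth-normalized to counts-per-`1e4` and `log1p`-transformed before
#' averaging, because the center enters the spatial model's log-scale
#' linear predictor as the covariate; `normalization = "raw"` averages the
#' raw counts instead.
#'
#' @param sc an [sc_dataset()].
#' @param normalization `"lognorm"` (default) or `"raw"`.
#' @param scale_factor library-size target for the normalization.
#' @return An object of class `"cell_type_centers"`: a types x genes
#'   matrix (rows in lexicographic label order) with attributes
#'   `normalization` and `scale_factor`.
#' @export
cell_type_centers <- function(sc, normalization = c("lognorm", "raw"),
                              scale_factor = 1e4) {
  stopifnot(inherits(sc, "sc_dataset"))
  normalization <- match.arg(normalization)
  types <- sort(unique(sc$cell_types), method = "radix")
  expr <- normalize_expression(sc$counts, normalization, scale_factor)
  centers <- do.call(rbind, lapply(types, function(t) {
    colMeans(expr[sc$cell_types == t, , drop = FALSE])
  }))
  dimnames(centers) <- list(types, sc$gene_names)
  structure(centers, class = c("cell_type_centers", "matrix", "array"),
            normalization = normalization, scale_factor = scale_factor)
}

#' @export
print.cell_type_centers <- function(x, ...) {
  cat(sprintf("Cell-type centers: %d types x %d genes (%s expression)\n",
              nrow(x), ncol(x), attr(x, "normalization")))
  invisible(x)
}

#' Map cell-type centers to spatial pixels
#'
#' Assigns each pixel the cell type whose center profile is most Pearson
#' correlated with the pixel's expression profile over the shared genes;
#' ties are broken by lexicographic type label.  Pixel profiles are put on
#' the same scale as the centers (depth-normalized log1p by default).  A
#' pixel with a constant profile has no defined correlation and is
#' assigned the most common type among the other pixels, with a warning.
#'
#' The result carries the per-pixel covariate table: for any gene `g`,
#' `x[i, g]` is the assigned center's expression of `g`, the covariate the
#' spatial model uses for that gene.
#'
#' @param spatial a [spatial_dataset()].
#' @param centers a [cell_type_centers()] matrix.
#' @param shared_genes genes used for the correlation (must number at
#'   least 3 and be present in both inputs).
#' @return An object of class `"pixel_assignment"`: list with
#'   `assignment` (data frame: `pixel_id`, `cell_type`, `correlation`),
#'   `x` (pixels x genes covariate matrix over all center genes), and
#'   `shared_genes`.
#' @export
assign_pixels <- function(spatial, centers, shared_genes) {
  stopifnot(inherits(spatial, "spatial_dataset"),
            inherits(centers, "cell_type_centers"))
  shared_genes <- as.character(shared_genes)
  if (length(shared_genes) < 3L)
    stop("need at least 3 shared genes to correlate profiles")
  if (!all(shared_genes %in% spatial$gene_names) ||
      !all(shared_genes %in% colnames(centers)))
    stop("some shared genes are missing from the spatial data or the centers")

  px <- normalize_expression(spatial$counts,
                             attr(centers, "normalization"),
                             attr(centers, "scale_factor"),
                             depth = spatial$size_factors)
  px <- px[, shared_genes, drop = FALSE]
  ce <- centers[, shared_genes, drop = FALSE]
  types <- rownames(centers)

  ## n x T correlation matrix between pixel profiles and center profiles
  cors <- suppressWarnings(stats::cor(t(px), t(ce)))
  assigned <- character(nrow(px))
  best_cor <- numeric(nrow(px))
  undefined <- logical(nrow(px))
  for (i in seq_len(nrow(px))) {
    ci <- cors[i, ]
    if (all(is.na(ci))) { undefined[i] <- TRUE; next }
    top <- max(ci, na.rm = TRUE)
    cand <- types[!is.na(ci) & ci == top]
    assigned[i] <- sort(cand, method = "radix")[1L]  # lexicographic ties
    best_cor[i] <- top
  }
  if (any(undefined)) {
    warning(sum(undefined), " pixel(s) with constant profiles assigned ",
            "the most common type")
    tab <- table(assigned[!undefined])
    fallback <- if (length(tab)) {
      winners <- names(tab)[tab == max(tab)]
      sort(winners, method = "radix")[1L]
    } else sort(types, method = "radix")[1L]
    assigned[undefined] <- fallback
    best_cor[undefined] <- NA_real_
  }

  x <- centers[assigned, , drop = FALSE]
  rownames(x) <- spatial$pixel_ids
  structure(list(
    assignment = data.frame(pixel_id = spatial$pixel_ids,
                            cell_type = assigned,
                            correlation = best_cor),
    x = x, shared_genes = shared_genes),
    class = "pixel_assignment")
}

#' @export
print.pixel_assignment <- function(x, ...) {
  tab <- table(x$assignment$cell_type)
  cat(sprintf("Pixel assignment: %d pixels over %d cell types (median r = %.3f)\n",
              nrow(x$assignment), length(tab),
              stats::median(x$assignment$correlation, na.rm = TRUE)))
  print(tab)
  invisible(x)
}

#' Fit the spatial model for every shared gene and keep the significant
#' ones
#'
#' For each candidate gene, fits the Poisson generalized linear spatial
#' model ([glsm()]) with the gene's spatial counts as response and the
#' assigned cell-type center expression of the same gene as covariate,
#' then tests `H0: beta = 0`.  Genes with p-value below `p_cut` (raw by
#' default; `adjust = "BH"` applies Benjamini-Hochberg first) form the
#' reference set used for predicting unmeasured genes.
#'
#' @param paired a [pair_datasets()] object.
#' @param assignment an [assign_pixels()] result.
#' @param kernel a `"kernel_matrix"`, or a short spec list for
#'   [make_kernel()].
#' @param p_cut significance cut in `(0, 1]` (default 0.05).
#' @param adjust `"none"` (raw p-values, the default) or `"BH"`.
#' @param genes candidate genes; defaults to all shared genes.
#' @param control a [glsm_control()] list.
#' @return An object of class `"reference_set"`: list with `fits` (named
#'   list of `glsm` fits for the retained genes), `table` (one row per
#'   candidate: `gene`, `p_value`, `p_used`, `beta`, `h2`, `converged`,
#'   `kept`, `note`), and `p_cut`.
#' @export
build_reference_set <- function(paired, assignment, kernel, p_cut = 0.05,
                                adjust = c("none", "BH"), genes = NULL,
                                control = glsm_control()) {
  stopifnot(inherits(paired, "paired_data"),
            inherits(assignment, "pixel_assignment"))
  adjust <- match.arg(adjust)
  if (!is.numeric(p_cut) || p_cut <= 0 || p_cut > 1)
    stop("'p_cut' must lie in (0, 1]")
  if (is.null(genes)) genes <- paired$shared_genes
  kernel <- make_kernel(paired$spatial$coords, kernel)

  fits <- vector("list", length(genes))
  names(fits) <- genes
  rows <- lapply(genes, function(gene) {
    y <- paired$spatial$counts[, gene]
    x <- assignment$x[, gene]
    fit <- tryCatch(
      suppressWarnings(glsm(y, x, kernel,
                            offset = paired$spatial$size_factors,
                            coords = paired$spatial$coords,
                            control = control)),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(gene = gene, p_value = NA_real_, beta = NA_real_,
                        h2 = NA_real_, converged = FALSE, kept = FALSE,
                        note = conditionMessage(fit)))
    fits[[gene]] <<- fit
    data.frame(gene = gene, p_value = fit$p_value,
               beta = unname(fit$coefficients["beta"]), h2 = fit$h2,
               converged = fit$converged, kept = NA, note = "")
  })
  tab <- do.call(rbind, rows)
  tab$p_used <- if (adjust == "BH") stats::p.adjust(tab$p_value, "BH") else tab$p_value
  tab$kept <- !is.na(tab$p_used) & tab$p_used < p_cut
  if (!any(tab$kept))
    stop("no gene reached p < ", p_cut,
         " in the reference fits; consider a looser cut")
  structure(list(fits = fits[tab$gene[tab$kept]], table = tab, p_cut = p_cut,
                 adjust = adjust),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("Reference set: %d of %d genes kept at p < %g (%s p-values)\n",
              length(x$fits), nrow(x$table), x$p_cut,
              if (x$adjust == "BH") "BH-adjusted" else "raw"))
  invisible(x)
}

#' Pick the reference gene most correlated with a target gene
#'
#' Computes the Pearson correlation, across single cells, between the
#' target gene's expression and each reference gene's expression (on the
#' depth-normalized log1p scale by default) and returns the reference with
#' the largest correlation; exact ties are broken by lexicographic gene
#' name.
#'
#' @param target_gene gene to be predicted (must be in the scRNA-seq
#'   data).
#' @param reference_set a [build_reference_set()] result.
#' @param sc the [sc_dataset()] the reference set was derived from.
#' @param transform correlation scale: `"lognorm"` (default) or `"raw"`.
#' @param scale_factor library-size target for the normalization.
#' @return list with `gene` (chosen reference) and `correlation`.
#' @export
select_reference_gene <- function(target_gene, reference_set, sc,
                                  transform = c("lognorm", "raw"),
                                  scale_factor = 1e4) {
  stopifnot(inherits(reference_set, "reference_set"),
            inherits(sc, "sc_dataset"))
  transform <- match.arg(transform)
  if (!target_gene %in% sc$gene_names)
    stop("target gene '", target_gene, "' is missing from the scRNA-seq data")
  refs <- names(reference_set$fits)
  if (length(refs) == 0L) stop("the reference set is empty")

  expr <- normalize_expression(sc$counts[, c(target_gene, refs), drop = FALSE],
                               transform, scale_factor,
                               depth = rowSums(sc$counts))
  tv <- expr[, 1L]
  if (stats::sd(tv) == 0)
    stop("target gene '", target_gene,
         "' is constant across cells: correlation undefined")
  cors <- suppressWarnings(
    drop(stats::cor(tv, expr[, -1L, drop = FALSE])))
  names(cors) <- refs
  cors <- cors[!is.na(cors)]
  if (length(cors) == 0L)
    stop("no reference gene has a defined correlation with '", target_gene, "'")
  top <- max(cors)
  best <- sort(names(cors)[cors == top], method = "radix")[1L]
  list(gene = best, correlation = unname(cors[best]))
}

#' Predict the spatial expression pattern of an unmeasured gene
#'
#' Implements the reference-gene prediction rule: choose the reference
#' gene most correlated with the target in single-cell expression space
#' (unless `reference_gene` is given), then apply the reference's fitted
#' parameters to the target's covariate profile:
#' `log(lambda_hat_i) = alpha_hat + x_i^(un) beta_hat + g_hat_i + e_hat_i`,
#' where `x^(un)` is the assigned center expression of the target gene and
#' the random-effect BLUPs are reused from the reference fit.  Predicted
#' counts are `N_i * lambda_hat_i`; `mode = "sample"` additionally draws
#' `Poisson(N_i * lambda_hat_i)` with the given seed.
#'
#' @param target_gene gene to predict (present in the scRNA-seq data; need
#'   not be in the spatial data).
#' @param reference_set a [build_reference_set()] result.
#' @param assignment the [assign_pixels()] result the references were
#'   fitted with.
#' @param sc the [sc_dataset()] (used for reference selection).
#' @param mode `"mean"` (deterministic rates, default) or `"sample"`.
#' @param seed seed for the `"sample"` mode draw.
#' @param reference_gene optional: force this reference instead of the
#'   most correlated one.
#' @return An object of class `"prediction_result"`: list with `gene`,
#'   `reference_gene`, `reference_correlation`, `mode`, and `table`
#'   (data frame `pixel_id`, `lambda_hat`, `predicted_count`, and
#'   `sampled_count` in sample mode).
#' @export
predict_gene <- function(target_gene, reference_set, assignment, sc,
                         mode = c("mean", "sample"), seed = 1,
                         reference_gene = NULL) {
  stopifnot(inherits(reference_set, "reference_set"),
            inherits(assignment, "pixel_assignment"))
  mode <- match.arg(mode)
  if (!target_gene %in% colnames(assignment$x))
    stop("target gene '", target_gene, "' has no cell-type center ",
         "(missing from the scRNA-seq data)")
  if (is.null(reference_gene)) {
    sel <- select_reference_gene(target_gene, reference_set, sc)
  } else {
    if (!reference_gene %in% names(reference_set$fits))
      stop("'", reference_gene, "' is not in the reference set")
    sel <- list(gene = reference_gene, correlation = NA_real_)
  }
  fit <- reference_set$fits[[sel$gene]]
  x_un <- assignment$x[, target_gene]
  lambda <- predict(fit, newx = x_un, type = "rate")
  tab <- data.frame(pixel_id = assignment$assignment$pixel_id,
                    lambda_hat = lambda,
                    predicted_count = fit$offset * lambda)
  if (mode == "sample") {
    set.seed(seed)
    tab$sampled_count <- stats::rpois(nrow(tab), tab$predicted_count)
  }
  structure(list(gene = target_gene, reference_gene = sel$gene,
                 reference_correlation = sel$correlation,
                 mode = mode, table = tab),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("Prediction for '%s' via reference '%s' (sc correlation %.3f, %s mode)\n",
              x$gene, x$reference_gene, x$reference_correlation, x$mode))
  cat(sprintf("  %d pixels; predicted counts %.2f-%.2f\n",
              nrow(x$table), min(x$table$predicted_count),
              max(x$table$predicted_count)))
  invisible(x)
}
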