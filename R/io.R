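#' Spatial transcriptomics dataset
#'
#' Bundles a pixels x genes count matrix with 2-D pixel coordinates and
#' per-pixel size factors.  The size factor `N_i` is the total count across
#' all genes at pixel `i` and is used as the Poisson offset by the spatial
#' model.  Pixels whose total count is zero are dropped with a warning: the
#' offset must be positive.
#'
#' @param counts non-negative integer matrix, pixels in rows, genes in
#'   columns; needs row (pixel id) and column (gene) names.
#' @param coords numeric matrix or data frame (n x 2) of pixel coordinates,
#'   rows aligned with `counts`.
#' @return An object of class `"spatial_dataset"` with elements `counts`,
#'   `coords`, `pixel_ids`, `gene_names`, `size_factors`.
#' @export
spatial_dataset <- function(counts, coords) {
  counts <- as_count_matrix(counts, what = "spatial counts")
  if (nrow(counts) < 2L) stop("a spatial dataset needs at least 2 pixels")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("px", seq_len(nrow(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate pixel ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene names")
  coords <- as_coord_matrix(coords)
  if (nrow(coords) != nrow(counts))
    stop("coords and counts disagree on the number of pixels")
  rownames(coords) <- rownames(counts)

  nsz <- rowSums(counts)
  if (any(nsz == 0)) {
    warning("dropping ", sum(nsz == 0), " pixel(s) with zero total count ",
            "(the model offset requires N_i > 0)")
    keep <- nsz > 0
    counts <- counts[keep, , drop = FALSE]
    coords <- coords[keep, , drop = FALSE]
    nsz <- nsz[keep]
    if (nrow(counts) < 2L) stop("fewer than 2 pixels remain after dropping empty pixels")
  }
  structure(list(counts = counts, coords = coords,
                 pixel_ids = rownames(counts), gene_names = colnames(counts),
                 size_factors = nsz),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("Spatial dataset: %d pixels x %d genes; size factors %g-%g\n",
              nrow(x$counts), ncol(x$counts),
              min(x$size_factors), max(x$size_factors)))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$counts)

#' Single-cell RNA-seq dataset
#'
#' Cells x genes count matrix with one cell-type label per cell.
#'
#' @param counts non-negative integer matrix, cells in rows, genes in
#'   columns.
#' @param cell_types character vector of type labels, one per cell.
#' @return An object of class `"sc_dataset"` with elements `counts`,
#'   `cell_ids`, `gene_names`, `cell_types`.
#' @export
sc_dataset <- function(counts, cell_types) {
  counts <- as_count_matrix(counts, what = "scRNA-seq counts")
  if (nrow(counts) < 1L) stop("an scRNA-seq dataset needs at least 1 cell")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("cell", seq_len(nrow(counts)))
  if (anyDuplicated(colnames(counts))) stop("duplicate gene names")
  cell_types <- as.character(cell_types)
  if (length(cell_types) != nrow(counts))
    stop("one cell-type label per cell is required")
  if (any(is.na(cell_types) | cell_types == ""))
    stop("empty or missing cell-type labels")
  structure(list(counts = counts, cell_ids = rownames(counts),
                 gene_names = colnames(counts), cell_types = cell_types),
            class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("scRNA-seq dataset: %d cells x %d genes; %d cell types\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cell_types))))
  invisible(x)
}

#' @export
dim.sc_dataset <- function(x) dim(x$counts)

#' Read a count matrix from disk
#'
#' Two layouts are supported.  `"dense"`: a delimited table (TSV or CSV,
#' sniffed from the extension unless `sep` is given) whose first column
#' holds row ids and whose header row holds gene names.  `"mtx"`:
#' MatrixMarket coordinate format, with the row and column names in two
#' sidecar one-name-per-line files (defaults: `<path>.rows.txt` and
#' `<path>.cols.txt` next to the `.mtx` file).
#'
#' Entries must be non-negative; negative or non-numeric entries raise a
#' validation error naming the first offending line.
#'
#' @param path file to read.
#' @param layout `"auto"` (by extension), `"dense"` or `"mtx"`.
#' @param row_names_file,col_names_file sidecar name files for the mtx
#'   layout.
#' @param sep field separator for the dense layout; default by extension.
#' @return A base integer matrix with row and column names.
#' @export
load_counts <- function(path, layout = c("auto", "dense", "mtx"),
                        row_names_file = NULL, col_names_file = NULL,
                        sep = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (layout == "auto")
    layout <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"

  if (layout == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MatrixMarket file '",
                                           path, "': ", conditionMessage(e)))
    m <- as.matrix(m)
    if (is.null(row_names_file)) row_names_file <- paste0(path, ".rows.txt")
    if (is.null(col_names_file)) col_names_file <- paste0(path, ".cols.txt")
    rn <- readLines(row_names_file)
    cn <- readLines(col_names_file)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("sidecar name files do not match the matrix dimensions")
    dimnames(m) <- list(rn, cn)
  } else {
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, colClasses = "character",
                             comment.char = "")
    if (ncol(tab) < 2L) stop("dense count table '", path,
                             "' needs an id column plus at least one gene column")
    ids <- tab[[1L]]
    body <- as.matrix(tab[, -1L, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(body), nrow(body), ncol(body),
                                   dimnames = dimnames(body)))
    if (anyNA(num)) {
      bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
      stop("non-numeric entry '", body[bad[1L], bad[2L]], "' at line ",
           bad[1L] + 1L, " of '", path, "'")
    }
    m <- num
    rownames(m) <- ids
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at row ", bad[1L], ", column ", bad[2L],
         " of '", path, "'")
  }
  as_count_matrix(m, what = path)
}

#' Read pixel coordinates (TSV with columns pixel_id, x, y)
#'
#' @param path file to read.
#' @return data frame with rownames = pixel ids and numeric columns x, y.
#' @export
read_coords <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("pixel_id", "x", "y")
  if (!all(need %in% names(tab)))
    stop("coordinate table must have columns pixel_id, x, y")
  out <- tab[, c("x", "y")]
  rownames(out) <- as.character(tab$pixel_id)
  out
}

#' Read cell-type annotations (TSV with columns cell_id, cell_type)
#'
#' @param path file to read.
#' @return named character vector of cell types, names = cell ids.
#' @export
read_cell_types <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  need <- c("cell_id", "cell_type")
  if (!all(need %in% names(tab)))
    stop("annotation table must have columns cell_id, cell_type")
  stats::setNames(tab$cell_type, tab$cell_id)
}

#' Filter low-quality cells
#'
#' Removes cells whose read depth (row sum across genes) falls below
#' `min_depth`, and cells carrying any label in `excluded_labels` (such as
#' "No class", "Low Quality", "Ambiguous" or "Unstable").  The gene set is
#' untouched.
#'
#' @param sc an [sc_dataset()].
#' @param min_depth minimum read depth; cells with depth `< min_depth` are
#'   removed (so depth exactly `min_depth` is kept).
#' @param excluded_labels character vector of labels to drop.
#' @return A filtered `"sc_dataset"`.
#' @export
filter_cells <- function(sc, min_depth = 10, excluded_labels = character()) {
  stopifnot(inherits(sc, "sc_dataset"))
  if (!is.numeric(min_depth) || min_depth < 0) stop("'min_depth' must be >= 0")
  depth <- rowSums(sc$counts)
  keep <- depth >= min_depth & !(sc$cell_types %in% excluded_labels)
  if (!any(keep)) stop("filtering removed every cell")
  sc_dataset(sc$counts[keep, , drop = FALSE], sc$cell_types[keep])
}

#' Convert normalized expression back to integer counts
#'
#' Rescales a normalized non-negative expression matrix to pseudo-counts:
#' values are multiplied by `scale` (default 1,000), optionally divided by
#' a per-row volume factor, and the ceiling is taken elementwise.  Zeros
#' map to zeros and exact integers after scaling are preserved.
#'
#' The order of the volume adjustment relative to the x1,000 scaling is not
#' standardized for the datasets this rule comes from, so it is an explicit
#' option: `volume_order = "before"` divides by volume first, `"after"`
#' divides the scaled values.  With the default `volume = NULL` no volume
#' adjustment is performed.
#'
#' @param values non-negative numeric matrix.
#' @param scale positive scaling factor (default 1000).
#' @param volume optional positive per-row divisor (e.g. cell volume).
#' @param volume_order `"before"` or `"after"` the scaling; irrelevant
#'   mathematically (both are multiplicative) but kept explicit so callers
#'   document their convention.
#' @return Integer matrix `ceiling(values * scale / volume)`.
#' @export
rescale_normalized_to_counts <- function(values, scale = 1000, volume = NULL,
                                         volume_order = c("before", "after")) {
  volume_order <- match.arg(volume_order)
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("'values' must be a finite numeric matrix")
  if (any(values < 0)) stop("'values' must be non-negative")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("'scale' must be a single positive number")
  if (!is.null(volume)) {
    if (any(volume <= 0)) stop("'volume' must be positive")
    values <- if (volume_order == "before") values / volume else values
  }
  out <- values * scale
  if (!is.null(volume) && volume_order == "after") out <- out / volume
  out <- ceiling(out)
  storage.mode(out) <- "integer"
  out
}

#' Drop spatial genes with very low expression
#'
#' Removes genes whose counts are nonzero in fewer than `min_prop` of the
#' pixels.  Sparse genes carry little information for spatial pattern
#' estimation and are recommended to be filtered before model fitting.
#'
#' @param spatial a [spatial_dataset()].
#' @param min_prop minimum fraction of pixels with a nonzero count
#'   (default 0.01).
#' @return A filtered `"spatial_dataset"`.
#' @export
filter_low_expression <- function(spatial, min_prop = 0.01) {
  stopifnot(inherits(spatial, "spatial_dataset"))
  prop <- colMeans(spatial$counts > 0)
  keep <- prop >= min_prop
  if (!any(keep)) stop("low-expression filter removed every gene")
  spatial_dataset(spatial$counts[, keep, drop = FALSE], spatial$coords)
}

#' Pair a spatial dataset with an scRNA-seq dataset
#'
#' Matches gene names across the two modalities (exact, case-sensitive,
#' after trimming surrounding whitespace) and records the shared genes in
#' lexicographic order.  The shared genes are the candidates for reference
#' fitting and the ground truth for cross-validation.
#'
#' @param spatial a [spatial_dataset()].
#' @param sc an [sc_dataset()].
#' @return An object of class `"paired_data"`: list with `spatial`, `sc`,
#'   `shared_genes`.
#' @export
pair_datasets <- function(spatial, sc) {
  stopifnot(inherits(spatial, "spatial_dataset"), inherits(sc, "sc_dataset"))
  sp_genes <- trimws(spatial$gene_names)
  sc_genes <- trimws(sc$gene_names)
  colnames(spatial$counts) <- spatial$gene_names <- sp_genes
  colnames(sc$counts) <- sc$gene_names <- sc_genes
  shared <- sort(intersect(sp_genes, sc_genes), method = "radix")
  if (length(shared) == 0L)
    stop("the spatial and scRNA-seq datasets share no gene names")
  structure(list(spatial = spatial, sc = sc, shared_genes = shared),
            class = "paired_data")
}

#' @export
print.paired_data <- function(x, ...) {
  cat(sprintf("Paired data: %d pixels x %d spatial genes; %d cells x %d sc genes; %d shared genes\n",
              nrow(x$spatial$counts), ncol(x$spatial$counts),
              nrow(x$sc$counts), ncol(x$sc$counts), length(x$shared_genes)))
  invisible(x)
}

#' Write a spatial dataset as plain-text tables
#'
#' Writes `counts.tsv` (dense, pixel ids in the first column) and
#' `coords.tsv` (`pixel_id`, `x`, `y`) into `dir`.  Reading these files
#' back with [load_counts()] and [read_coords()] reproduces the dataset
#' exactly.
#'
#' @param spatial a [spatial_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_spatial_dataset <- function(spatial, dir) {
  stopifnot(inherits(spatial, "spatial_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dense_counts(spatial$counts, file.path(dir, "counts.tsv"),
                     id_col = "pixel_id")
  co <- data.frame(pixel_id = spatial$pixel_ids,
                   x = spatial$coords[, 1L], y = spatial$coords[, 2L])
  utils::write.table(co, file.path(dir, "coords.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write an scRNA-seq dataset as plain-text tables
#'
#' Writes `sc_counts.tsv` and `cell_types.tsv` (`cell_id`, `cell_type`)
#' into `dir`; round-trips exactly through [load_counts()] and
#' [read_cell_types()].
#'
#' @param sc an [sc_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sc_dataset <- function(sc, dir) {
  stopifnot(inherits(sc, "sc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dense_counts(sc$counts, file.path(dir, "sc_counts.tsv"),
                     id_col = "cell_id")
  ann <- data.frame(cell_id = sc$cell_ids, cell_type = sc$cell_types)
  utils::write.table(ann, file.path(dir, "cell_types.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

write_dense_counts <- function(counts, path, id_col) {
  tab <- data.frame(id = rownames(counts), counts, check.names = FALSE)
  names(tab)[1L] <- id_col
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_count_matrix <- function(counts, what = "counts") {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop(what, ": matrix must be numeric")
  if (any(!is.finite(counts))) stop(what, ": non-finite entries")
  if (any(counts < 0)) stop(what, ": negative entries are not valid counts")
  if (any(counts != round(counts))) stop(what, ": entries must be integers")
  storage.mode(counts) <- "double"  # double avoids integer overflow in sums
  counts
}
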