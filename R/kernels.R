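#' Build a pixel adjacency graph
#'
#' Constructs the binary adjacency matrix `W` and neighbour-count diagonal
#' `D` used by the conditional autoregressive (CAR) spatial prior.  Two
#' builders are available: a k-nearest-neighbour graph (symmetrized by
#' union, so `i` and `j` are neighbours if either is among the other's `k`
#' nearest) and a fixed-radius graph (neighbours iff Euclidean distance is
#' at most `param`).
#'
#' Pixels that end up with no neighbours are allowed (with a warning); the
#' CAR covariance treats them as spatially independent.
#'
#' @param coords numeric matrix of pixel coordinates (n x 2).
#' @param method `"knn"` or `"radius"`.
#' @param param number of neighbours `k` (knn) or the radius (radius).
#' @return An object of class `"adjacency_graph"`: a list with `W`
#'   (n x n binary symmetric matrix, zero diagonal), `m` (integer vector of
#'   neighbour counts, the diagonal of `D`), `method` and `param`.
#' @examples
#' g <- build_adjacency(cbind(c(0, 1, 3), 0), method = "knn", param = 1)
#' g$W
#' @export
build_adjacency <- function(coords, method = c("knn", "radius"), param = 4) {
  coords <- as_coord_matrix(coords)
  method <- match.arg(method)
  n <- nrow(coords)
  if (n < 2L) stop("adjacency graph needs at least 2 pixels")
  if (!is.numeric(param) || length(param) != 1L || param <= 0)
    stop("'param' must be a single positive number")

  d <- as.matrix(stats::dist(coords))
  W <- matrix(0, n, n)
  if (method == "radius") {
    W[d <= param] <- 1
    diag(W) <- 0
  } else {
    k <- as.integer(param)
    if (k >= n) k <- n - 1L
    for (i in seq_len(n)) {
      # ties broken by pixel order; self excluded
      nb <- order(d[i, ])[-1L][seq_len(k)]
      W[i, nb] <- 1
    }
    W <- pmax(W, t(W))  # union symmetrization
  }
  m <- rowSums(W)
  if (any(m == 0))
    warning(sum(m == 0), " pixel(s) have no neighbours and are treated as isolated")
  dimnames(W) <- list(rownames(coords), rownames(coords))
  structure(list(W = W, m = m, method = method, param = param),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("Adjacency graph (%s, param = %g): %d pixels, %d edges, %d isolated\n",
              x$method, x$param, nrow(x$W), sum(x$W) / 2, sum(x$m == 0)))
  invisible(x)
}

new_kernel_matrix <- function(K, kind, parameters) {
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("kernel matrix is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  structure(list(K = K, kind = kind, parameters = parameters),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("Spatial kernel matrix: kind = %s (%s), dim = %d x %d\n",
              x$kind,
              paste(names(x$parameters), unlist(x$parameters),
                    sep = " = ", collapse = ", "),
              nrow(x$K), ncol(x$K)))
  invisible(x)
}

#' Gaussian spatial kernel
#'
#' `K[i, j] = exp(-||s_i - s_j||^2 / (2 * bandwidth^2))`, a unit-diagonal
#' positive semi-definite covariance structure that decays smoothly with
#' distance.
#'
#' @param coords numeric matrix of pixel coordinates (n x 2).
#' @param bandwidth positive length scale, in the units of `coords`.
#' @return A `"kernel_matrix"` object of kind `"gaussian"`.
#' @examples
#' K <- gaussian_kernel(cbind(c(0, 1), c(0, 0)), bandwidth = 1)
#' K$K[1, 2]  # exp(-1/2)
#' @export
gaussian_kernel <- function(coords, bandwidth) {
  coords <- as_coord_matrix(coords)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("'bandwidth' must be a single positive number")
  d2 <- as.matrix(stats::dist(coords))^2
  K <- exp(-d2 / (2 * bandwidth^2))
  new_kernel_matrix(K, "gaussian", list(bandwidth = bandwidth))
}

#' CAR-derived spatial covariance
#'
#' Covariance structure of a conditional autoregressive prior on a pixel
#' graph: `K = (D - alpha_s W)^{-1}`, where `W` is the binary adjacency
#' matrix, `D = diag(m_i)` holds the neighbour counts, and `alpha_s` in
#' `[0, 1)` controls spatial dependence.  `alpha_s = 0` gives spatial
#' independence (`K = D^{-1}`); `alpha_s = 1` is the intrinsic
#' autoregressive (IAR) limit, whose precision is singular on a connected
#' graph and therefore rejected.  The overall variance scale sigma^2 h^2 is
#' applied by the model, not here.
#'
#' Isolated pixels have `m_i = 0`, which would make `D - alpha_s W`
#' singular; their diagonal entry is replaced by 1, so they keep unit CAR
#' variance and no covariance with other pixels.
#'
#' @param graph an [build_adjacency()] result.
#' @param alpha_s spatial dependence parameter in `[0, 1)`.
#' @return A `"kernel_matrix"` object of kind `"car"`.
#' @examples
#' g <- build_adjacency(cbind(c(0, 1), c(0, 0)), method = "radius", param = 1)
#' car_covariance(g, alpha_s = 0.5)$K  # [[4/3, 2/3], [2/3, 4/3]]
#' @export
car_covariance <- function(graph, alpha_s) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (!is.numeric(alpha_s) || length(alpha_s) != 1L || alpha_s < 0 || alpha_s > 1)
    stop("'alpha_s' must lie in [0, 1)")
  m <- graph$m
  m[m == 0] <- 1  # isolated pixels: unit variance, no covariance
  Q <- diag(m, nrow = length(m)) - alpha_s * graph$W
  ch <- tryCatch(chol(Q), error = function(e) NULL)
  if (is.null(ch)) {
    if (alpha_s >= 1)
      stop("precision matrix D - W is singular: alpha_s = 1 is the ",
           "intrinsic autoregressive (IAR) limit, which has no proper ",
           "covariance on a connected graph")
    stop("precision matrix D - alpha_s * W is not positive definite")
  }
  K <- chol2inv(ch)
  dimnames(K) <- dimnames(graph$W)
  new_kernel_matrix(K, "car", list(alpha_s = alpha_s))
}

#' Default Gaussian bandwidth sweep
#'
#' Data-adaptive set of five Gaussian kernel length scales:
#' `{0.5, 1, 2, 5, 10}` times the median nearest-neighbour distance of the
#' pixel coordinates.  Used by [kernel_sensitivity()].
#'
#' @param coords numeric matrix of pixel coordinates (n x 2).
#' @return numeric vector of five bandwidths.
#' @export
default_bandwidths <- function(coords) {
  coords <- as_coord_matrix(coords)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  med_nn <- stats::median(apply(d, 1L, min))
  if (med_nn == 0) med_nn <- stats::median(d[is.finite(d) & d > 0])
  c(0.5, 1, 2, 5, 10) * med_nn
}

#' Build a spatial kernel from a short specification
#'
#' Convenience dispatcher used by the cross-validation drivers and the CLI:
#' `spec` is a list with `kind = "gaussian"` (plus `bandwidth`) or
#' `kind = "car"` (plus `alpha_s`, and optionally `method`/`param` for the
#' adjacency graph; defaults: k-nearest neighbours with k = 4).
#'
#' @param coords pixel coordinates (n x 2).
#' @param spec list describing the kernel, or an existing `"kernel_matrix"`
#'   (returned unchanged).
#' @return A `"kernel_matrix"` object.
#' @export
make_kernel <- function(coords, spec) {
  if (inherits(spec, "kernel_matrix")) return(spec)
  stopifnot(is.list(spec), !is.null(spec$kind))
  if (spec$kind == "gaussian") {
    bw <- spec$bandwidth
    if (is.null(bw)) bw <- default_bandwidths(coords)[2L]
    gaussian_kernel(coords, bw)
  } else if (spec$kind == "car") {
    method <- if (is.null(spec$method)) "knn" else spec$method
    param <- if (is.null(spec$param)) 4 else spec$param
    g <- withCallingHandlers(
      build_adjacency(coords, method = method, param = param),
      warning = function(w) invokeRestart("muffleWarning"))
    alpha_s <- if (is.null(spec$alpha_s)) 0.5 else spec$alpha_s
    car_covariance(g, alpha_s)
  } else {
    stop("unknown kernel kind: ", spec$kind)
  }
}

#' Export a kernel matrix as dense TSV
#'
#' @param kernel a `"kernel_matrix"`.
#' @param path output file.
#' @export
write_kernel_tsv <- function(kernel, path) {
  stopifnot(inherits(kernel, "kernel_matrix"))
  utils::write.table(kernel$K, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

as_coord_matrix <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) stop("coordinates must have exactly 2 columns")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  coords
}
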