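#' Poisson working pseudodata for penalized quasi-likelihood
#'
#' One approximation step of the PQL scheme: given the current linear
#' predictor `eta`, the Poisson counts are replaced by a continuous working
#' response obtained from a second-order Taylor expansion of the
#' conditional log-likelihood around `eta`.  With a log link and offset
#' `N_i`, the conditional mean is `mu_i = N_i exp(eta_i)`, the pseudodata
#' is `ytilde_i = eta_i + (y_i - mu_i) / mu_i` and the working weight is
#' `w_i = mu_i` (the conditional variance).  The subsequent inference step
#' treats `ytilde` as a Gaussian response with residual covariance
#' `diag(1 / w)`.
#'
#' `eta` is clipped to +/- 30 (with a warning) before exponentiation to
#' keep `mu` finite and positive.
#'
#' @param y non-negative count vector.
#' @param offset positive size factors `N_i`.
#' @param eta current linear predictor.
#' @return A list of class `"pql_state"` with `eta`, `mu`, `pseudodata`,
#'   `weights`.
#' @examples
#' compute_pseudodata(5, 100, -3)$pseudodata  # -2.995723...
#' @export
compute_pseudodata <- function(y, offset, eta) {
  stopifnot(length(offset) %in% c(1L, length(y)), length(eta) == length(y))
  if (any(offset <= 0)) stop("offsets must be positive")
  if (any(!is.finite(eta))) stop("linear predictor must be finite")
  if (any(abs(eta) > 30)) {
    warning("linear predictor clipped at +/- 30 to avoid overflow")
    eta <- pmin(pmax(eta, -30), 30)
  }
  mu <- offset * exp(eta)
  structure(list(eta = eta, mu = mu,
                 pseudodata = eta + (y - mu) / mu,
                 weights = mu),
            class = "pql_state")
}

## Restricted (REML) log-likelihood of the working linear mixed model
##   ytilde ~ N(X b, tg K + te I + diag(1/w)),
## up to an additive constant, together with the GLS fixed effects and the
## quantities the AI update reuses.  tg = sigma2 * h2, te = sigma2 * (1 - h2).
working_lmm <- function(ytil, w, X, K, tg, te) {
  n <- length(ytil)
  V <- tg * K + te * diag(n) + diag(1 / w, n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    V <- V + diag(1e-6, n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
  }
  Vinv <- chol2inv(ch)
  A <- Vinv %*% X
  XtVX <- crossprod(X, A)
  chx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chx)) return(NULL)
  Binv <- chol2inv(chx)           # cov of GLS fixed effects
  b <- drop(Binv %*% crossprod(A, ytil))
  r <- ytil - drop(X %*% b)
  Py <- drop(Vinv %*% r)          # equals P %*% ytil
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                  sum(r * Py))
  list(V = V, Vinv = Vinv, A = A, Binv = Binv, b = b, r = r, Py = Py,
       loglik = ll)
}

## P %*% v without forming P: P = Vinv - A Binv t(A)
apply_P <- function(lmm, v) {
  drop(lmm$Vinv %*% v) - drop(lmm$A %*% (lmm$Binv %*% crossprod(lmm$A, v)))
}

#' One average-information REML update of the variance components
#'
#' Performs a single quasi-Newton step of the average-information (AI)
#' REML algorithm for the working linear mixed model of the PQL scheme:
#' response `pseudodata`, fixed effects intercept + `x`, covariance
#' `sigma2 * h2 * K + sigma2 * (1 - h2) * I + diag(1 / weights)`.  The
#' update is computed on the variance-component scale
#' `(sigma2 * h2, sigma2 * (1 - h2))`, projected back into
#' `sigma2 > 0`, `h2 in [0, 1]`, and step-halved until the working REML
#' log-likelihood does not decrease.
#'
#' When `K` is numerically a scalar multiple of the identity the two
#' components are not separately identifiable (the likelihood is flat in
#' `h2`); the result carries `identifiable = FALSE` and a warning is
#' emitted.
#'
#' @param pseudodata working response vector (see [compute_pseudodata()]).
#' @param weights positive working weights.
#' @param x covariate vector.
#' @param K spatial kernel: a `"kernel_matrix"` or a plain symmetric
#'   matrix.
#' @param theta current `c(sigma2, h2)`.
#' @return list with `sigma2`, `h2`, `theta`, `ai` (2 x 2 average
#'   information matrix), `score`, `loglik` (working REML log-likelihood at
#'   the accepted update), `loglik_old`, `fixef`, `fixef_cov`,
#'   `identifiable`, `step_halvings`.
#' @export
reml_ai_step <- function(pseudodata, weights, x, K, theta) {
  K <- kernel_as_matrix(K)
  n <- length(pseudodata)
  stopifnot(length(weights) == n, length(x) == n, nrow(K) == n,
            length(theta) == 2L)
  if (any(weights <= 0)) stop("weights must be positive")
  sigma2 <- theta[1L]; h2 <- theta[2L]
  if (sigma2 <= 0 || h2 < 0 || h2 > 1)
    stop("'theta' must hold sigma2 > 0 and h2 in [0, 1]")
  X <- cbind(1, x)
  if (stats::var(x) == 0)
    stop("covariate is constant: collinear with the intercept")

  identifiable <- TRUE
  dK <- mean(diag(K))
  if (dK > 0 && max(abs(K - dK * diag(n))) <= 1e-10 * dK) {
    identifiable <- FALSE
    warning("kernel is proportional to the identity: sigma2 and h2 are ",
            "not separately identifiable (REML likelihood is flat in h2)")
  }

  upd <- ai_update(pseudodata, weights, X, K, sigma2 * h2, sigma2 * (1 - h2))
  upd$identifiable <- identifiable
  upd
}

## Internal AI step on (tg, te); returns accepted components + diagnostics.
ai_update <- function(ytil, w, X, K, tg, te) {
  n <- length(ytil)
  lmm <- working_lmm(ytil, w, X, K, tg, te)
  if (is.null(lmm)) stop("working covariance matrix is not positive definite")
  Py <- lmm$Py
  KPy <- drop(K %*% Py)

  ## scores: dl/d tg, dl/d te
  trPK <- sum(lmm$Vinv * K) - sum(lmm$Binv * crossprod(lmm$A, K %*% lmm$A))
  trPI <- sum(diag(lmm$Vinv)) - sum(lmm$Binv * crossprod(lmm$A))
  score <- 0.5 * c(sum(Py * KPy) - trPK, sum(Py * Py) - trPI)

  ## average information
  PKPy <- apply_P(lmm, KPy)
  PPy <- apply_P(lmm, Py)
  ai <- 0.5 * matrix(c(sum(KPy * PKPy), sum(KPy * PPy),
                       sum(KPy * PPy), sum(Py * PPy)), 2L, 2L)

  delta <- tryCatch(solve(ai + diag(1e-10 * max(diag(ai), 1), 2L), score),
                    error = function(e) score / pmax(diag(ai), 1e-8))

  ## step-halving with projection onto tg >= 0, te >= 0
  step <- 1
  accepted <- list(tg = tg, te = te, lmm = lmm)
  halvings <- 0L
  repeat {
    tg_new <- max(tg + step * delta[1L], 0)
    te_new <- max(te + step * delta[2L], 0)
    if (tg_new + te_new < 1e-8) {  # keep a nonzero total variance
      sc <- 1e-8 / max(tg_new + te_new, .Machine$double.xmin)
      tg_new <- tg_new * sc; te_new <- te_new * sc
      if (tg_new + te_new < 1e-8) { tg_new <- 0; te_new <- 1e-8 }
    }
    cand <- working_lmm(ytil, w, X, K, tg_new, te_new)
    if (!is.null(cand) && cand$loglik >= lmm$loglik - 1e-10) {
      accepted <- list(tg = tg_new, te = te_new, lmm = cand)
      break
    }
    step <- step / 2
    halvings <- halvings + 1L
    if (halvings > 30L) break  # no improving step: keep current components
  }

  sigma2 <- accepted$tg + accepted$te
  h2 <- if (sigma2 > 0) accepted$tg / sigma2 else 0
  list(sigma2 = sigma2, h2 = h2, theta = c(sigma2 = sigma2, h2 = h2),
       tg = accepted$tg, te = accepted$te,
       ai = ai, score = score,
       loglik = accepted$lmm$loglik, loglik_old = lmm$loglik,
       fixef = accepted$lmm$b,
       fixef_cov = accepted$lmm$Binv,
       lmm = accepted$lmm, step_halvings = halvings)
}

#' Control parameters for [glsm()]
#'
#' @param max_iter maximum number of outer PQL iterations (default 100).
#' @param tol relative-change convergence tolerance on
#'   `(alpha, beta, sigma2, h2)` (default 1e-5).
#' @param h2_snap boundary band: a fitted `h2` within `h2_snap` of 0 or 1
#'   is snapped exactly onto the boundary (default 1e-4).
#' @param eta_clip linear predictor clip used by the pseudodata step.
#' @return list of class `"glsm_control"`.
#' @export
glsm_control <- function(max_iter = 100L, tol = 1e-5, h2_snap = 1e-4,
                         eta_clip = 30) {
  stopifnot(max_iter >= 1L, tol > 0, h2_snap >= 0, h2_snap < 0.5)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 h2_snap = h2_snap, eta_clip = eta_clip),
            class = "glsm_control")
}

#' Fit a Poisson generalized linear spatial model
#'
#' Fits, for one gene, the count model
#' \deqn{y_i \sim \mathrm{Poisson}(N_i \lambda_i), \quad
#'       \log \lambda_i = \alpha + x_i \beta + g_i + e_i,}
#' where `N_i` is the per-pixel size factor (total counts across genes),
#' `x_i` is the mapped cell-type expression covariate,
#' `g ~ MVN(0, sigma2 * h2 * K)` is a spatial random effect with kernel
#' covariance `K`, and `e ~ MVN(0, sigma2 * (1 - h2) * I)` is an
#' independent nugget capturing non-spatial overdispersion.  `h2 in [0, 1]`
#' is the fraction of the random-effect variance attributed to the spatial
#' component.
#'
#' Estimation is by penalized quasi-likelihood: each outer iteration
#' replaces the counts by a Gaussian working response
#' ([compute_pseudodata()]), applies one average-information REML update of
#' `(sigma2, h2)` ([reml_ai_step()]), re-estimates `(alpha, beta)` by
#' generalized least squares and the random effects by BLUP, and updates
#' the linear predictor.  Iteration stops when the relative change of
#' `(alpha, beta, sigma2, h2)` drops below `control$tol`.  The covariate
#' effect is tested with a Wald statistic `beta / se(beta)` against a
#' standard normal reference.
#'
#' @param y non-negative integer counts, one per pixel.
#' @param x covariate vector (cell-type expression mapped to pixels); must
#'   be non-constant.
#' @param kernel spatial covariance: a `"kernel_matrix"` from
#'   [gaussian_kernel()] / [car_covariance()], or a plain symmetric matrix.
#' @param offset positive size factors `N_i`; defaults to 1 for every
#'   pixel.
#' @param coords optional pixel coordinates, kept for [plot.glsm()].
#' @param control a [glsm_control()] list.
#' @return An object of class `"glsm"`; see Details.  Key elements:
#'   `coefficients` (`alpha`, `beta`), `sigma2`, `h2`, `g` and `e` (BLUPs),
#'   `beta_se`, `wald`, `p_value`, `n_iter`, `converged`, `loglik`
#'   (working REML log-likelihood), `identifiable`.
#' @seealso [summary.glsm()], [predict.glsm()], [simulate.glsm()]
#' @export
glsm <- function(y, x, kernel, offset = NULL, coords = NULL,
                 control = glsm_control()) {
  cl <- match.call()
  y <- as.numeric(y)
  x <- as.numeric(x)
  n <- length(y)
  if (n < 3L) stop("need at least 3 pixels")
  if (length(x) != n) stop("'y' and 'x' lengths differ")
  if (any(y < 0) || any(y != round(y))) stop("'y' must hold non-negative counts")
  if (is.null(offset)) offset <- rep(1, n)
  if (length(offset) == 1L) offset <- rep(offset, n)
  if (length(offset) != n || any(offset <= 0))
    stop("'offset' must be positive, one value per pixel")
  if (stats::var(x) == 0)
    stop("covariate 'x' is constant: collinear with the intercept")
  K <- kernel_as_matrix(kernel)
  if (nrow(K) != n) stop("kernel dimension does not match the data")
  X <- cbind(1, x)

  identifiable <- TRUE
  dK <- mean(diag(K))
  if (dK > 0 && max(abs(K - dK * diag(n))) <= 1e-10 * dK) {
    identifiable <- FALSE
    warning("kernel is proportional to the identity: sigma2 and h2 are ",
            "not separately identifiable")
  }

  ## neutral start: intercept at the mean rate, no covariate effect,
  ## variance split evenly between the spatial and nugget components
  alpha <- log(max(mean(y / offset), 1e-8))
  beta <- 0
  tg <- 0.5; te <- 0.5
  eta <- rep(alpha, n)

  params <- c(alpha, beta, 1, 0.5)
  converged <- FALSE
  iter <- 0L
  upd <- NULL
  ps <- NULL
  clipped <- FALSE
  for (iter in seq_len(control$max_iter)) {
    ps <- withCallingHandlers(
      compute_pseudodata(y, offset, eta),
      warning = function(w) {
        clipped <<- TRUE
        invokeRestart("muffleWarning")
      })
    upd <- ai_update(ps$pseudodata, ps$weights, X, K, tg, te)
    tg <- upd$tg; te <- upd$te
    b <- upd$lmm$b
    g <- tg * drop(K %*% upd$lmm$Py)
    e <- te * upd$lmm$Py
    eta <- drop(X %*% b) + g + e
    new_params <- c(b[1L], b[2L], tg + te, if (tg + te > 0) tg / (tg + te) else 0)
    rel <- max(abs(new_params - params) / pmax(abs(params), 1e-3))
    params <- new_params
    if (rel < control$tol) { converged <- TRUE; break }
  }
  if (clipped) warning("linear predictor clipped at +/- ", control$eta_clip,
                       " during fitting")

  ## snap h2 onto the boundary and refit the working LMM there so the
  ## boundary identities (h2 = 0 => g = 0, h2 = 1 => e = 0) hold exactly
  sigma2 <- tg + te
  h2 <- if (sigma2 > 0) tg / sigma2 else 0
  if (h2 < control$h2_snap) h2 <- 0
  if (h2 > 1 - control$h2_snap) h2 <- 1
  tg <- sigma2 * h2; te <- sigma2 * (1 - h2)
  lmm <- working_lmm(ps$pseudodata, ps$weights, X, K, tg, te)
  b <- lmm$b
  g <- tg * drop(K %*% lmm$Py)
  e <- te * lmm$Py
  eta <- drop(X %*% b) + g + e

  beta_se <- sqrt(lmm$Binv[2L, 2L])
  wald <- b[2L] / beta_se
  p_value <- 2 * stats::pnorm(-abs(wald))

  structure(list(
    coefficients = c(alpha = unname(b[1L]), beta = unname(b[2L])),
    sigma2 = sigma2, h2 = h2,
    g = g, e = e, eta = eta,
    fitted_rate = exp(eta), offset = offset,
    beta_se = beta_se, wald = wald, p_value = p_value,
    fixef_cov = lmm$Binv,
    loglik = lmm$loglik,
    n_iter = iter, converged = converged,
    identifiable = identifiable,
    y = y, x = x, kernel_kind = kernel_kind(kernel), K = K,
    coords = coords,
    pql_state = ps, control = control, call = cl),
    class = "glsm")
}

#' Best linear unbiased predictors of the random effects
#'
#' Recomputes the spatial (`g`) and nugget (`e`) BLUPs from a fitted
#' model's final working linear mixed model:
#' `g = sigma2 h2 K V^{-1} (ytilde - X b)` and
#' `e = sigma2 (1 - h2) V^{-1} (ytilde - X b)` with
#' `V = sigma2 h2 K + sigma2 (1 - h2) I + diag(1 / w)`.
#'
#' @param fit a fitted [glsm()] object.
#' @return list with numeric vectors `g` and `e`.
#' @export
blup_random_effects <- function(fit) {
  stopifnot(inherits(fit, "glsm"))
  ps <- fit$pql_state
  X <- cbind(1, fit$x)
  tg <- fit$sigma2 * fit$h2
  te <- fit$sigma2 * (1 - fit$h2)
  lmm <- working_lmm(ps$pseudodata, ps$weights, X, fit$K, tg, te)
  list(g = tg * drop(fit$K %*% lmm$Py), e = te * lmm$Py)
}

## ---- S3 methods -----------------------------------------------------------

#' @export
print.glsm <- function(x, digits = 4, ...) {
  cat("Poisson generalized linear spatial model (PQL / AI-REML)\n")
  cat(sprintf("  n = %d pixels, kernel = %s\n", length(x$y), x$kernel_kind))
  cat(sprintf("  alpha = %.*g, beta = %.*g (se %.*g, p = %.3g)\n",
              digits, x$coefficients[1L], digits, x$coefficients[2L],
              digits, x$beta_se, x$p_value))
  cat(sprintf("  sigma2 = %.*g, h2 = %.*g\n", digits, x$sigma2, digits, x$h2))
  cat(sprintf("  %s in %d iterations\n",
              if (x$converged) "converged" else "did NOT converge", x$n_iter))
  invisible(x)
}

#' Summarize a fitted spatial count model
#'
#' @param object a [glsm()] fit.
#' @param ... unused.
#' @return An object of class `"summary.glsm"` with a coefficient table
#'   (estimate, standard error, z, p), the variance components and
#'   convergence diagnostics.
#' @export
summary.glsm <- function(object, ...) {
  se <- sqrt(diag(object$fixef_cov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, sigma2 = object$sigma2, h2 = object$h2,
                 kernel_kind = object$kernel_kind, n = length(object$y),
                 n_iter = object$n_iter, converged = object$converged,
                 identifiable = object$identifiable,
                 loglik = object$loglik, call = object$call),
            class = "summary.glsm")
}

#' @export
print.summary.glsm <- function(x, digits = 4, ...) {
  cat("Poisson generalized linear spatial model (PQL / AI-REML)\n\nCall: ")
  print(x$call)
  cat("\nFixed effects:\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nVariance components: sigma2 = %.*g, h2 = %.*g (spatial share)\n",
              digits, x$sigma2, digits, x$h2))
  cat(sprintf("Working REML log-likelihood: %.*g\n", digits + 2, x$loglik))
  cat(sprintf("n = %d pixels, kernel = %s; %s in %d iterations\n",
              x$n, x$kernel_kind,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  if (!x$identifiable)
    cat("Warning: kernel ~ identity, h2 not identifiable\n")
  invisible(x)
}

#' @export
coef.glsm <- function(object, ...) object$coefficients

#' @export
vcov.glsm <- function(object, ...) {
  v <- object$fixef_cov
  dimnames(v) <- list(names(object$coefficients), names(object$coefficients))
  v
}

#' @export
logLik.glsm <- function(object, ...) {
  structure(object$loglik, df = 4L, nobs = length(object$y),
            class = "logLik")
}

#' @export
fitted.glsm <- function(object, type = c("rate", "count", "link"), ...) {
  type <- match.arg(type)
  switch(type,
         rate = object$fitted_rate,
         count = object$offset * object$fitted_rate,
         link = object$eta)
}

#' @export
residuals.glsm <- function(object,
                           type = c("pearson", "response", "working"), ...) {
  type <- match.arg(type)
  mu <- object$offset * object$fitted_rate
  switch(type,
         response = object$y - mu,
         pearson = (object$y - mu) / sqrt(mu),
         working = object$pql_state$pseudodata - object$eta)
}

#' Predict the spatial pattern of a (possibly unmeasured) gene
#'
#' Applies the fitted parameters to a new covariate profile: the predicted
#' log-rate at pixel `i` is `alpha + newx_i * beta + g_i + e_i`, reusing
#' the fit's own random-effect BLUPs (the spatial pattern and nugget
#' estimated from the reference gene).  With `newx` missing, returns the
#' in-sample fit.
#'
#' @param object a [glsm()] fit.
#' @param newx covariate vector of length n (e.g. the mapped cell-type
#'   expression of an unmeasured gene).
#' @param type `"rate"` for `lambda_hat`, `"count"` for
#'   `N_i * lambda_hat`, `"link"` for the linear predictor.
#' @param ... unused.
#' @return numeric vector, one value per pixel.
#' @export
predict.glsm <- function(object, newx = NULL,
                         type = c("rate", "count", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newx)) return(fitted(object, type = type))
  newx <- as.numeric(newx)
  if (length(newx) != length(object$y))
    stop("'newx' must supply one covariate value per pixel")
  eta <- object$coefficients[1L] + newx * object$coefficients[2L] +
    object$g + object$e
  switch(type,
         link = eta,
         rate = exp(eta),
         count = object$offset * exp(eta))
}

#' Simulate counts from a fitted spatial model
#'
#' Draws Poisson counts with mean `N_i * lambda_hat_i` from the fitted
#' rates (the plug-in predictive distribution at the estimated random
#' effects).
#'
#' @param object a [glsm()] fit.
#' @param nsim number of replicate draws.
#' @param seed optional integer seed; with the same seed the draws are
#'   reproduced exactly.
#' @param ... unused.
#' @return data frame with `nsim` columns of simulated counts.
#' @export
simulate.glsm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$offset * object$fitted_rate
  out <- as.data.frame(replicate(nsim, stats::rpois(length(mu), mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted spatial model
#'
#' With pixel coordinates available, draws side-by-side spatial scatter
#' plots of the observed expression (`y / N`) and the fitted rate; without
#' coordinates, plots fitted counts against observed counts.
#'
#' @param x a [glsm()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.glsm <- function(x, ...) {
  if (!is.null(x$coords)) {
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    shade <- function(v) grDevices::hcl.colors(100, "viridis")[
      cut(rank(v, ties.method = "average"), 100, labels = FALSE)]
    graphics::plot(x$coords, col = shade(x$y / x$offset), pch = 16,
                   main = "observed y/N", ...)
    graphics::plot(x$coords, col = shade(x$fitted_rate), pch = 16,
                   main = "fitted rate", ...)
  } else {
    graphics::plot(x$offset * x$fitted_rate, x$y,
                   xlab = "fitted count", ylab = "observed count", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

kernel_as_matrix <- function(kernel) {
  if (inherits(kernel, "kernel_matrix")) return(kernel$K)
  K <- as.matrix(kernel)
  if (nrow(K) != ncol(K) || max(abs(K - t(K))) > 1e-8 * max(abs(K), 1))
    stop("kernel must be a symmetric matrix or a 'kernel_matrix'")
  (K + t(K)) / 2
}

kernel_kind <- function(kernel) {
  if (inherits(kernel, "kernel_matrix"))
    paste0(kernel$kind, " (",
           paste(names(kernel$parameters), unlist(kernel$parameters),
                 sep = " = ", collapse = ", "), ")")
  else "user matrix"
}
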