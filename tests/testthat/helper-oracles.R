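# Independent oracles used to cross-check the package's numerics.  These
# deliberately use direct, naive computations (generic solve(),
# determinant(), grid searches, numerical optimization) rather than any of
# the package's internal code paths.

# REML log-likelihood of the working LMM, computed from the textbook
# formula with dense solves.
oracle_reml_loglik <- function(ytil, w, X, K, sigma2, h2) {
  n <- length(ytil)
  V <- sigma2 * h2 * K + sigma2 * (1 - h2) * diag(n) + diag(1 / w, n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% ytil)
  r <- ytil - X %*% b
  ld <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  -0.5 * (ld(V) + ld(XtViX) + t(r) %*% Vi %*% r)
}

# Grid search over h2 (profiling sigma2 over a geometric grid); returns
# the (sigma2, h2) pair with the largest REML log-likelihood.
oracle_reml_grid <- function(ytil, w, X, K,
                             h2_grid = seq(0, 1, by = 0.05),
                             s2_grid = exp(seq(log(0.02), log(20),
                                               length.out = 40))) {
  best <- c(s2 = NA, h2 = NA, ll = -Inf)
  for (h2 in h2_grid) for (s2 in s2_grid) {
    ll <- oracle_reml_loglik(ytil, w, X, K, s2, h2)
    if (ll > best["ll"]) best <- c(s2 = s2, h2 = h2, ll = ll)
  }
  best
}

# Laplace-approximated maximum likelihood for the Poisson model with a
# combined random effect b ~ MVN(0, tg K + te I): direct numerical
# optimization over (alpha, beta, log tg, log te), with an inner Newton
# solve for the posterior mode of b.
oracle_laplace_loglik <- function(par, y, x, N, K) {
  n <- length(y)
  alpha <- par[1L]; beta <- par[2L]
  tg <- exp(par[3L]); te <- exp(par[4L])
  Sigma <- tg * K + te * diag(n)
  Sigi <- solve(Sigma)
  b <- rep(0, n)
  for (it in 1:100) {
    eta <- alpha + x * beta + b
    mu <- drop(N * exp(pmin(eta, 30)))
    grad <- (y - mu) - drop(Sigi %*% b)
    H <- Sigi + diag(mu, n)
    step <- drop(solve(H, grad))
    b <- b + step
    if (max(abs(step)) < 1e-10) break
  }
  eta <- alpha + x * beta + b
  mu <- drop(N * exp(pmin(eta, 30)))
  ld <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  f <- sum(y * eta - mu - lgamma(y + 1)) - 0.5 * sum(b * (Sigi %*% b))
  as.numeric(f - 0.5 * ld(Sigma) - 0.5 * ld(Sigi + diag(drop(mu), n)))
}

oracle_laplace_fit <- function(y, x, N, K) {
  g0 <- stats::glm(y ~ x, family = stats::poisson(), offset = log(N))
  start <- c(stats::coef(g0), log(0.25), log(0.25))
  opt <- stats::optim(start, function(p) -oracle_laplace_loglik(p, y, x, N, K),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  list(alpha = opt$par[1L], beta = opt$par[2L],
       tg = exp(opt$par[3L]), te = exp(opt$par[4L]),
       loglik = -opt$value, convergence = opt$convergence)
}

# Moran's I statistic with a row-standardized weight matrix; naive double
# loop (only used at small n).
oracle_morans_i <- function(z, W) {
  n <- length(z)
  zc <- z - mean(z)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * zc[i] * zc[j]
  (n / sum(W)) * num / sum(zc^2)
}
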