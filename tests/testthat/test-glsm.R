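test_that("pseudodata follows the working-response formulas", {
  # y equal to the conditional mean: residual term vanishes
  ps <- compute_pseudodata(y = 2, offset = 10, eta = log(0.2))
  expect_equal(ps$pseudodata, log(0.2))
  expect_equal(ps$weights, 2)

  # zero count: ytilde = eta - 1
  ps0 <- compute_pseudodata(y = 0, offset = 50, eta = -2)
  expect_equal(ps0$pseudodata, -3)

  # frozen arithmetic: mu = 100 exp(-3), ytilde = -3 + (5 - mu) / mu
  ps1 <- compute_pseudodata(y = 5, offset = 100, eta = -3)
  expect_equal(ps1$mu, 4.978707, tolerance = 1e-6)
  expect_equal(ps1$pseudodata, -2.995724, tolerance = 1e-6)

  expect_warning(compute_pseudodata(1, 1, 40), "clipped")
  expect_error(compute_pseudodata(1, 0, 0), "positive")
})

test_that("AI-REML steps drive a pure-nugget fit to the h2 = 0 boundary, agreeing with a grid search", {
  set.seed(101)
  n <- 30
  co <- cbind(runif(n), runif(n))
  K <- gaussian_kernel(co, bandwidth = 0.3)
  x <- rnorm(n)
  w <- rep(25, n)
  ytil <- 0.2 + 0.5 * x + rnorm(n, 0, 1) + rnorm(n, 0, sqrt(1 / 25))

  th <- c(1, 0.5)
  for (i in 1:60) {
    st <- reml_ai_step(ytil, w, x, K, th)
    if (max(abs(st$theta - th)) < 1e-8) break
    th <- st$theta
  }
  expect_lt(th[2], 0.05)
  grid <- oracle_reml_grid(ytil, w, cbind(1, x), K$K)
  expect_equal(unname(grid["h2"]), 0)
  expect_equal(unname(th[1]), unname(grid["s2"]), tolerance = 0.1)
})

test_that("accepted AI steps never decrease the working REML log-likelihood and stop at a stationary point", {
  set.seed(202)
  n <- 80
  co <- cbind(runif(n), runif(n))
  K <- gaussian_kernel(co, bandwidth = 0.3)
  U <- chol(K$K + diag(1e-8, n))
  x <- rnorm(n)
  w <- rep(25, n)
  ytil <- 0.2 + 0.5 * x + sqrt(0.6) * drop(crossprod(U, rnorm(n))) +
    rnorm(n, 0, sqrt(0.4)) + rnorm(n, 0, sqrt(1 / 25))

  th <- c(1, 0.5)
  lls <- numeric()
  for (i in 1:200) {
    st <- reml_ai_step(ytil, w, x, K, th)
    lls <- c(lls, st$loglik)
    expect_gte(st$loglik, st$loglik_old - 1e-10)
    if (max(abs(st$theta - th)) < 1e-10) break
    th <- st$theta
  }
  expect_true(all(diff(lls) >= -1e-10))

  # finite-difference REML gradient vanishes at the accepted optimum
  eps <- 1e-5
  X <- cbind(1, x)
  g_s2 <- (oracle_reml_loglik(ytil, w, X, K$K, th[1] + eps, th[2]) -
             oracle_reml_loglik(ytil, w, X, K$K, th[1] - eps, th[2])) / (2 * eps)
  g_h2 <- (oracle_reml_loglik(ytil, w, X, K$K, th[1], th[2] + eps) -
             oracle_reml_loglik(ytil, w, X, K$K, th[1], th[2] - eps)) / (2 * eps)
  expect_lt(abs(g_s2), 1e-3)
  expect_lt(abs(g_h2), 1e-3)
})

test_that("an identity kernel is flagged as non-identifiable", {
  set.seed(4)
  n <- 40
  x <- rnorm(n)
  ytil <- rnorm(n)
  expect_warning(
    st <- reml_ai_step(ytil, rep(10, n), x, diag(n), c(1, 0.5)),
    "not separately identifiable")
  expect_false(st$identifiable)
  y <- rpois(n, 5)
  expect_warning(f <- glsm(y, x, diag(n)), "identifiable")
  expect_false(f$identifiable)
})

test_that("with no overdispersion and large offsets the fit collapses to the Poisson GLM", {
  for (s in 1:2) {
    sim <- simulate_glsm_counts(n = 200, alpha = -1, beta = 0.4,
                                sigma2 = 0, h2 = 0,
                                size_factors = rep(1e5, 200), seed = s)
    f <- suppressWarnings(glsm(sim$y, sim$x, sim$kernel, offset = sim$offset))
    oracle <- stats::glm(sim$y ~ sim$x, family = stats::poisson(),
                         offset = log(sim$offset))
    expect_equal(unname(coef(f)), unname(coef(oracle)), tolerance = 1e-3)
  }
})

test_that("degenerate designs are rejected", {
  y <- rpois(20, 5)
  K <- gaussian_kernel(cbind(1:20, 0), bandwidth = 2)
  expect_error(glsm(y, rep(1, 20), K), "constant")
  expect_error(glsm(y, rnorm(20), K, offset = rep(0, 20)), "positive")
  expect_error(glsm(c(y[-1], -1), rnorm(20), K), "non-negative")
})

test_that("shifting the covariate only moves the intercept", {
  sim <- simulate_glsm_counts(n = 150, alpha = -1, beta = 0.5,
                              sigma2 = 0.5, h2 = 0.5, seed = 8)
  f0 <- suppressWarnings(glsm(sim$y, sim$x, sim$kernel, offset = sim$offset))
  cshift <- 3
  f1 <- suppressWarnings(glsm(sim$y, sim$x + cshift, sim$kernel,
                              offset = sim$offset))
  expect_equal(unname(coef(f1)["beta"]), unname(coef(f0)["beta"]),
               tolerance = 1e-6)
  expect_equal(unname(coef(f1)["alpha"]),
               unname(coef(f0)["alpha"]) - cshift * unname(coef(f0)["beta"]),
               tolerance = 1e-6)
  expect_equal(f1$h2, f0$h2, tolerance = 1e-6)
  expect_equal(f1$p_value, f0$p_value, tolerance = 1e-6)
})

test_that("random-effect BLUPs obey the boundary identities", {
  # fitted h2 snapped to 0 (pure nugget data): spatial BLUP is exactly zero
  sim0 <- simulate_glsm_counts(n = 100, alpha = -1, beta = 0.3,
                               sigma2 = 1, h2 = 0, seed = 1)
  f0 <- suppressWarnings(glsm(sim0$y, sim0$x, sim0$kernel,
                              offset = sim0$offset))
  expect_equal(f0$h2, 0)
  expect_true(all(f0$g == 0))

  # fitted h2 snapped to 1: nugget BLUP is exactly zero
  sim1 <- simulate_glsm_counts(n = 100, alpha = -1, beta = 0.3, sigma2 = 2,
                               h2 = 1, seed = 1,
                               kernel = list(kind = "car", alpha_s = 0.9))
  f1 <- suppressWarnings(glsm(sim1$y, sim1$x, sim1$kernel,
                              offset = sim1$offset))
  expect_equal(f1$h2, 1)
  expect_true(all(f1$e == 0))

  # blup_random_effects reproduces the stored BLUPs
  b <- blup_random_effects(f1)
  expect_equal(b$g, f1$g)
  expect_equal(b$e, f1$e)
})

test_that("the spatial BLUP tracks the true spatial effect", {
  sim <- simulate_glsm_counts(n = 100, alpha = -0.5, beta = 0.5, sigma2 = 1.5,
                              h2 = 0.8, seed = 14,
                              kernel = list(kind = "car", alpha_s = 0.8))
  f <- suppressWarnings(glsm(sim$y, sim$x, sim$kernel, offset = sim$offset))
  r_true <- cor(f$g, sim$truth$g)
  set.seed(99)
  r_perm <- cor(sample(f$g), sim$truth$g)
  expect_gt(r_true, r_perm)
  expect_gt(r_true, 0.2)
})

test_that("model methods are mutually consistent", {
  sim <- simulate_glsm_counts(n = 120, alpha = -1, beta = 0.5, sigma2 = 1,
                              h2 = 0.6, seed = 2)
  f <- suppressWarnings(glsm(sim$y, sim$x, sim$kernel, offset = sim$offset,
                             coords = sim$coords))
  expect_s3_class(f, "glsm")
  expect_equal(fitted(f, "count"), f$offset * exp(f$eta))
  expect_equal(residuals(f, "response"), f$y - fitted(f, "count"))
  expect_equal(predict(f, newx = f$x, type = "rate"), fitted(f, "rate"))
  # prediction formula: alpha + newx * beta + g + e on the link scale
  nx <- rnorm(120)
  expect_equal(predict(f, newx = nx, type = "link"),
               unname(coef(f)["alpha"]) + nx * unname(coef(f)["beta"]) +
                 f$g + f$e)
  s <- summary(f)
  expect_equal(s$coefficients["beta", "Estimate"], unname(coef(f)["beta"]))
  expect_equal(s$coefficients["beta", "Pr(>|z|)"], f$p_value)
  # simulate() is reproducible under a fixed seed
  d1 <- simulate(f, nsim = 2, seed = 5)
  d2 <- simulate(f, nsim = 2, seed = 5)
  expect_identical(d1, d2)
  expect_output(print(f), "generalized linear spatial model")
  expect_output(print(s), "Variance components")
})

test_that("PQL fixed effects stay close to a Laplace-approximated MLE at small n", {
  ok <- 0
  for (s in 1:3) {
    sim <- simulate_glsm_counts(n = 25, alpha = -0.5, beta = 1, sigma2 = 0.5,
                                h2 = 0.5, size_factors = rep(500, 25),
                                seed = s)
    f <- suppressWarnings(glsm(sim$y, sim$x, sim$kernel, offset = sim$offset))
    la <- oracle_laplace_fit(sim$y, sim$x, sim$offset, sim$kernel$K)
    rel <- abs(unname(coef(f)["beta"]) - la$beta) / abs(la$beta)
    expect_lt(rel, 0.15)
  }
})
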