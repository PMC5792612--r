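sim_gls_data <- function(tree, beta, lambda = 1, sigma = 1, seed = 1) {
  set.seed(seed)
  V <- apply_transform(tree, "lambda", lambda)$matrix
  n <- nrow(V)
  x <- rnorm(n)
  y <- beta[1] + beta[2] * x + drop(t(chol(V)) %*% rnorm(n)) * sigma
  tibble::tibble(species = rownames(V), x = x, y = y)
}

test_that("gls_fit with V = identity reproduces the OLS closed form", {
  set.seed(14)
  for (i in 1:25) {
    n <- 50
    p <- sample(2:5, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
    y <- rnorm(n)
    fit <- gls_fit(y, X, diag(n))
    expect_equal(unname(fit$coefficients), drop(bf_ols(y, X)),
                 tolerance = 1e-8)
    expect_equal(fit$sigma2, sum((y - X %*% bf_ols(y, X))^2) / n,
                 tolerance = 1e-8)
  }
  # intercept-only: the GLS mean is the sample mean
  y <- rnorm(30)
  fit <- gls_fit(y, matrix(1, 30, 1), diag(30))
  expect_equal(unname(fit$coefficients), mean(y))
})

test_that("whitened likelihood equals the direct multivariate-normal density", {
  set.seed(6)
  tr <- simulate_tree(30, seed = 6)
  V <- phylo_covariance(tr)$matrix
  X <- cbind(1, rnorm(30))
  y <- rnorm(30)
  fit <- gls_fit(y, X, V)
  e <- y - X %*% matrix(fit$coefficients)
  Vs <- fit$sigma2 * V
  direct <- -0.5 * (30 * log(2 * pi) + determinant(Vs)$modulus[1] +
                      drop(t(e) %*% solve(Vs, e)))
  expect_equal(fit$loglik, direct, tolerance = 1e-8)
})

test_that("degenerate and ill-posed designs are flagged or rejected", {
  X <- cbind(1, 1:10)
  y <- drop(X %*% c(2, 3))  # y exactly in span(X)
  fit <- gls_fit(y, X, diag(10))
  expect_true(fit$degenerate)
  expect_equal(fit$sigma2, 0, tolerance = 1e-12)
  Xr <- cbind(a = rep(1, 10), b = 1:10, c = 2 * (1:10))
  expect_error(gls_fit(rnorm(10), Xr, diag(10)), "collinear.*c")
  expect_error(gls_fit(rnorm(3), cbind(1, 1:3), matrix(0, 3, 3)),
               "positive definite")
})

test_that("AICc follows the small-sample formula and its AIC limit", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  expect_equal(aicc(-12.5, 3, 40), 25 + 6 + 24 / 36)
  expect_lt(abs(aicc(-100, 4, 1e5) - (200 + 8)), 1e-3)
  expect_error(aicc(0, 9, 10), "n - k - 1")
})

test_that("profile ML recovers strong vs destroyed phylogenetic signal", {
  tr <- simulate_tree(150, seed = 50)
  lam_bm <- lam_perm <- numeric(8)
  for (i in 1:8) {
    d <- sim_gls_data(tr, beta = c(0, 0), lambda = 1, seed = 500 + i)
    f1 <- fit_pgls(d, "y", character(0), tr, "lambda")
    lam_bm[i] <- f1$transform_estimate
    set.seed(600 + i)
    d$y <- sample(d$y)  # permuting tips destroys the signal
    f0 <- fit_pgls(d, "y", character(0), tr, "lambda")
    lam_perm[i] <- f0$transform_estimate
  }
  expect_gte(median(lam_bm), 0.9)
  expect_lte(median(lam_perm), 0.1)
})

test_that("parameter counting distinguishes BM from transform families", {
  tr <- simulate_tree(40, seed = 8)
  d <- sim_gls_data(tr, beta = c(1, 0.5), seed = 9)
  f_bm <- fit_pgls(d, "y", "x", tr, "BM")
  f_lam <- fit_pgls(d, "y", "x", tr, "lambda")
  expect_true(is.na(f_bm$transform_estimate))
  expect_equal(f_lam$k, f_bm$k + 1)
  expect_equal(f_bm$k, 2 + 1)  # intercept + slope + sigma2
  expect_equal(f_bm$aicc, aicc(f_bm$loglik, f_bm$k, f_bm$n))
})

test_that("profile optimisation is stable across restart grids", {
  tr <- simulate_tree(60, seed = 70)
  ests <- vapply(1:10, function(i) {
    d <- sim_gls_data(tr, beta = c(0, 1), lambda = 0.6, seed = 700 + i)
    e5 <- fit_pgls(d, "y", "x", tr, "lambda", grid_points = 5)$transform_estimate
    e9 <- fit_pgls(d, "y", "x", tr, "lambda", grid_points = 9)$transform_estimate
    abs(e5 - e9)
  }, numeric(1))
  expect_lt(max(ests), 1e-3)
})

test_that("coefficients are recovered without material bias at n = 200", {
  tr <- simulate_tree(200, seed = 90)
  errs <- vapply(1:20, function(i) {
    d <- sim_gls_data(tr, beta = c(1, 2), lambda = 0.8, sigma = 0.5,
                      seed = 900 + i)
    f <- fit_pgls(d, "y", "x", tr, "lambda")
    f$coefficients[["x"]] - 2
  }, numeric(1))
  expect_lt(abs(mean(errs)) / 2, 0.1)
})

test_that("fits agree with nlme gls under a fixed correlation structure", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(40, seed = 33)
  d <- sim_gls_data(tr, beta = c(1, -1), lambda = 1, seed = 34)
  ours <- fit_pgls(d, "y", "x", tr, "BM")
  df <- as.data.frame(d)
  rownames(df) <- df$species
  ref <- nlme::gls(y ~ x, data = df,
                   correlation = ape::corBrownian(1, tr, form = ~species),
                   method = "ML")
  expect_equal(unname(ours$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(ours$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})
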