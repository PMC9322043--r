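test_that("PLSR recovers an exact single-factor relationship", {
  set.seed(1)
  # centered orthogonal predictors: one component captures y = 2 x3 + 1
  x <- qr.Q(qr(cbind(1, matrix(rnorm(30 * 5), 30))))[, -1]
  y <- 2 * x[, 3] + 1
  fit <- fit_plsr(x, y, 1)
  expect_lt(max(abs(predict(fit, x) - y)), 1e-8)
})

test_that("PLSR equals ordinary least squares at full rank", {
  set.seed(2)
  for (i in 1:10) {
    x <- matrix(rnorm(40 * 8), 40)
    y <- drop(x %*% rnorm(8)) + rnorm(40, 0, 0.3)
    fit <- fit_plsr(x, y, 8)
    # normal-equation oracle on centered data
    xc <- scale(x, scale = FALSE)
    b_ols <- solve(crossprod(xc), crossprod(xc, y - mean(y)))
    expect_lt(max(abs(fit$coef - b_ols)), 1e-6)
  }
})

test_that("PLSR scores are mutually orthogonal and b matches the scores fit", {
  set.seed(3)
  x <- matrix(rnorm(20 * 8), 20)
  y <- rnorm(20)
  fit <- fit_plsr(x, y, 3)
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # deflation identity: X_c b + y_mean equals the scores regression
  fitted_b <- predict(fit, x)
  fitted_s <- drop(fit$scores %*% fit$q) + fit$y_mean
  expect_equal(fitted_b, fitted_s, tolerance = 1e-8)
  # loading weights are unit norm
  expect_equal(colSums(fit$w^2), rep(1, 3), tolerance = 1e-12)
})

test_that("PLSR validates the latent-variable count and rank", {
  x <- matrix(rnorm(10 * 4), 10)
  y <- rnorm(10)
  expect_error(fit_plsr(x, y, 0), class = "ovaspec_domain_error")
  expect_error(fit_plsr(x, y, 5), class = "ovaspec_domain_error")
  expect_error(fit_plsr(matrix(1, 10, 4), y, 1), class = "ovaspec_rank_error")
})

test_that("LSSVM satisfies its KKT system and handles n = 1", {
  set.seed(4)
  x <- matrix(rnorm(25 * 3), 25)
  y <- drop(sin(x[, 1]) + 0.5 * x[, 2]) + rnorm(25, 0, 0.05)
  fit <- fit_lssvm(x, y, gamma = 10, sigma = 2)
  expect_lt(fit$kkt_residual, 1e-8)
  # kernel diagonal is exp(0) = 1: prediction at a training point of a
  # one-sample model returns its own value
  f1 <- fit_lssvm(x[1, , drop = FALSE], y[1], gamma = 100, sigma = 1)
  expect_equal(predict(f1, x[1, , drop = FALSE]), y[1], tolerance = 1e-8)
  expect_error(fit_lssvm(x, y, gamma = -1, sigma = 1),
               class = "ovaspec_domain_error")
})

test_that("LSSVM interpolates at very large gamma", {
  set.seed(5)
  x <- matrix(runif(15 * 2, -2, 2), 15)
  y <- rnorm(15)
  fit <- fit_lssvm(x, y, gamma = 1e8, sigma = 1)
  expect_lt(max(abs(predict(fit, x) - y)), 1e-4)
})

test_that("LSSVM training error is non-increasing in gamma", {
  set.seed(6)
  x <- matrix(rnorm(30 * 4), 30)
  y <- drop(x %*% c(1, -1, 0.5, 0)) + rnorm(30, 0, 0.2)
  rmse <- vapply(c(0.01, 0.1, 1, 10, 100, 1e4), function(g) {
    compute_metrics(y, predict(fit_lssvm(x, y, g, 2), x))$rmse
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-8))
})

test_that("metrics match hand arithmetic and flag degenerate input", {
  m <- compute_metrics(c(0, 10), c(1, 9))
  expect_equal(m$rmse, 1)
  expect_equal(m$r2, 0.96)
  y <- c(1, 2, 3, 4)
  expect_equal(compute_metrics(y, y), tibble::tibble(r2 = 1, rmse = 0))
  expect_equal(compute_metrics(y, rep(mean(y), 4))$r2, 0)
  expect_error(compute_metrics(rep(1, 4), y), class = "ovaspec_domain_error")
})

test_that("k-fold CV is seeded and k = n reproduces brute-force LOO", {
  set.seed(7)
  x <- matrix(rnorm(16 * 3), 16)
  y <- drop(x %*% c(1, 2, -1)) + rnorm(16, 0, 0.1)
  a <- kfold_cv(x, y, "plsr", n_lv = 2, k = 4, seed = 9)
  b <- kfold_cv(x, y, "plsr", n_lv = 2, k = 4, seed = 9)
  expect_identical(a$rmse, b$rmse)
  # brute-force leave-one-out oracle
  loo <- vapply(seq_len(16), function(i) {
    predict(fit_plsr(x[-i, ], y[-i], 2), x[i, , drop = FALSE])
  }, numeric(1))
  cv <- kfold_cv(x, y, "plsr", n_lv = 2, k = 16, seed = 1)
  expect_equal(cv$rmse, sqrt(mean((loo - y)^2)), tolerance = 1e-12)
  # model class containing the truth: near-zero cross-validated error
  y_exact <- drop(x %*% c(1, 2, -1))
  cv_exact <- kfold_cv(x, y_exact, "plsr", n_lv = 3, k = 4, seed = 2)
  expect_lt(cv_exact$rmse, 1e-8)
  expect_error(kfold_cv(x, y, "plsr", n_lv = 2, k = 17),
               class = "ovaspec_domain_error")
})

test_that("latent-variable selection applies the plateau rule", {
  expect_equal(select_from_trace(c(5, 3, 2, 1, 1.5, 2), tol = 0), 4L)
  expect_equal(select_from_trace(rep(2, 8)), 1L)
  expect_equal(select_from_trace(c(3, 1.02, 1.0, 1.0), tol = 0.02), 2L)
  # selected count is reproducible on data and respects the cap
  set.seed(8)
  x <- matrix(rnorm(40 * 20), 40)
  y <- drop(x[, 1:4] %*% c(3, -2, 1, 1)) + rnorm(40, 0, 0.3)
  h1 <- select_n_lv(x, y, max_lv = 10, seed = 5)
  h2 <- select_n_lv(x, y, max_lv = 10, seed = 5)
  expect_identical(as.integer(h1), as.integer(h2))
  expect_lte(as.integer(h1), 10L)
  expect_length(attr(h1, "rmsecv"), 10L)
})

test_that("grid search finds the minimum of a known convex surface", {
  bowl <- function(lg, li) (lg - 2)^2 + (li + 3)^2
  gs <- grid_search_lssvm(objective = bowl)
  expect_equal(gs$log2_gamma, 2, tolerance = 0.1)
  expect_equal(gs$log2_inv_sigma2, -3, tolerance = 0.1)
  expect_equal(nrow(gs$coarse), 289L)          # 17 x 17 step-1 grid
  expect_lte(gs$rmsecv, min(gs$coarse$rmsecv)) # fine contains coarse optimum
})

test_that("grid search improves LSSVM cross-validation on real spectra", {
  truth <- fixture_dataset$truth
  x <- spectra_matrix(fixture_spectra)
  y <- truth$reference_content
  gs <- grid_search_lssvm(x, y, log2_range = c(-4, 4), seed = 3)
  expect_true(gs$gamma > 0 && gs$sigma > 0)
  expect_lte(gs$rmsecv, min(gs$coarse$rmsecv))
  cv <- kfold_cv(x, y, "lssvm", gamma = gs$gamma, sigma = gs$sigma,
                 k = 5, seed = 3)
  expect_gt(cv$r2, 0.8)
})

test_that("models survive a serialisation round trip", {
  set.seed(9)
  x <- matrix(rnorm(20 * 6), 20)
  colnames(x) <- sprintf("%.4f", 500 + 1:6)
  y <- rnorm(20)
  dir <- withr::local_tempdir()
  p1 <- fit_plsr(x, y, 3)
  write_model(p1, file.path(dir, "plsr.json"), meta = list(snv = TRUE))
  p2 <- read_model(file.path(dir, "plsr.json"))
  expect_equal(predict(p2, x), predict(p1, x), tolerance = 1e-12)
  expect_true(attr(p2, "meta")$snv)
  l1 <- fit_lssvm(x, y, 5, 2)
  write_model(l1, file.path(dir, "lssvm.json"))
  l2 <- read_model(file.path(dir, "lssvm.json"))
  expect_equal(predict(l2, x), predict(l1, x), tolerance = 1e-12)
})

test_that("tidiers expose coefficients and fit summaries", {
  set.seed(10)
  x <- matrix(rnorm(20 * 4), 20)
  colnames(x) <- sprintf("%.4f", c(500, 600, 700, 800))
  y <- rnorm(20)
  fit <- fit_plsr(x, y, 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 4L)
  expect_equal(td$wavelength_nm, c(500, 600, 700, 800))
  expect_equal(glance(fit)$n_lv, 2L)
  lfit <- fit_lssvm(x, y, 3, 1)
  expect_equal(nrow(tidy(lfit)), 20L)
  expect_lt(glance(lfit)$kkt_residual, 1e-8)
})
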