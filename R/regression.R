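# PLSR (NIPALS-style deflation loop) and LSSVM (RBF kernel, KKT linear
# system), both implemented from first principles: they are the methods
# under study, not plumbing.

.as_predictor_matrix <- function(x) {
  if (is.data.frame(x)) spectra_matrix(x) else as.matrix(x)
}

# Core PLS loop. Returns loadings and the regression-coefficient path
# (one coefficient vector per number of latent variables 1..h), so
# cross-validation over h needs a single fit.
.pls_fit <- function(x, y, h) {
  x <- .as_predictor_matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (h < 1 || h > min(n - 1, p)) {
    rlang::abort(sprintf("`n_lv` must lie in [1, %d].", min(n - 1, p)),
                 class = "ovaspec_domain_error")
  }
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  xc <- sweep(x, 2, x_mean)
  yc <- y - y_mean
  w_mat <- p_mat <- matrix(0, p, h)
  q_vec <- numeric(h)
  s_mat <- matrix(0, n, h)
  coef_path <- matrix(0, p, h)
  for (t in seq_len(h)) {
    w <- drop(crossprod(xc, yc))          # loading weights w = X'y
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      rlang::abort(sprintf(
        "Rank deficiency: X carries no variance at component %d.", t),
        class = "ovaspec_rank_error")
    }
    w <- w / nw
    s <- drop(xc %*% w)                   # X scores
    ss <- sum(s^2)
    if (ss < 1e-12) {
      rlang::abort(sprintf(
        "Rank deficiency: zero score variance at component %d.", t),
        class = "ovaspec_rank_error")
    }
    pv <- drop(crossprod(xc, s)) / ss     # X loadings
    qv <- sum(yc * s) / ss                # y loading
    w_mat[, t] <- w; p_mat[, t] <- pv; q_vec[t] <- qv; s_mat[, t] <- s
    xc <- xc - tcrossprod(s, pv)          # deflation
    yc <- yc - s * qv
    wt <- w_mat[, 1:t, drop = FALSE]
    pt <- p_mat[, 1:t, drop = FALSE]
    coef_path[, t] <- drop(wt %*% solve(crossprod(pt, wt), q_vec[1:t]))
  }
  list(w = w_mat, p = p_mat, q = q_vec, scores = s_mat,
       coef_path = coef_path, x_mean = x_mean, y_mean = y_mean,
       colnames = colnames(x))
}

#' Fit a partial least squares regression model
#'
#' Projects the (internally mean-centered) predictors onto `n_lv` latent
#' variables that maximise covariance with the response, by the classic
#' deflation loop: loading weights `w = X'y` (normalised), scores
#' `s = X w`, loadings `p = X's / s's`, `q = y's / s's`, deflate
#' `X <- X - s p'`, `y <- y - s q`, repeat; regression coefficients
#' `b = W (P'W)^{-1} Q`.
#'
#' @param x Predictor matrix or spectra table (n x p).
#' @param y Numeric response, length n.
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @return An object of class `plsr_model` with loading weights `w`,
#'   loadings `p`, `q`, training scores, coefficient vector `coef`, and
#'   the centering constants.
#' @seealso [select_n_lv()] for choosing `n_lv` by cross-validation.
#' @export
fit_plsr <- function(x, y, n_lv) {
  fit <- .pls_fit(x, y, n_lv)
  structure(
    list(n_lv = as.integer(n_lv), w = fit$w, p = fit$p, q = fit$q,
         scores = fit$scores, coef = fit$coef_path[, n_lv],
         coef_path = fit$coef_path,
         x_mean = fit$x_mean, y_mean = fit$y_mean,
         wavelengths = suppressWarnings(as.numeric(fit$colnames))),
    class = "plsr_model"
  )
}

#' @param object A `plsr_model`.
#' @param newdata Matrix or spectra table with the training band layout.
#' @param ... Unused.
#' @rdname fit_plsr
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  xn <- .as_predictor_matrix(newdata)
  drop(sweep(xn, 2, object$x_mean) %*% object$coef) + object$y_mean
}

# ---------------------------------------------------------------------------

.rbf_kernel_cross <- function(x1, x2, sigma) {
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

# Solve the LSSVM KKT system [[0, 1'], [1, K + I/gamma]] [b; alpha] = [0; y]
# with one step of iterative refinement to push the residual to solver
# precision.
.solve_lssvm_system <- function(k, y, gamma) {
  n <- length(y)
  a <- rbind(c(0, rep(1, n)), cbind(1, k + diag(n) / gamma))
  rhs <- c(0, y)
  sol <- tryCatch(solve(a, rhs), error = function(e) {
    rlang::abort(
      "LSSVM system is singular; consider a larger gamma jitter.",
      class = "ovaspec_singular_error")
  })
  sol <- sol + solve(a, rhs - drop(a %*% sol))
  list(bias = sol[1], alpha = sol[-1],
       residual = max(abs(rhs - drop(a %*% sol))))
}

#' Fit a least-squares support vector machine (RBF kernel)
#'
#' Kernel regression obtained from the SVM formulation with equality
#' constraints and a squared-error penalty: minimising
#' `w'w / 2 + gamma * sum(xi^2) / 2` subject to
#' `y_i = w' phi(x_i) + b + xi_i` reduces, via the Lagrangian and KKT
#' conditions, to one `(n + 1)`-dimensional linear system in the dual
#' coefficients `alpha` and bias `b`; the feature map is never
#' materialised (kernel trick only). The radial basis kernel
#' `K(x, x') = exp(-||x - x'||^2 / (2 sigma^2))` is used. The response is
#' standardised internally and predictions unscaled, so `gamma` grids have
#' a data-independent meaning.
#'
#' @param x Predictor matrix or spectra table (n x p).
#' @param y Numeric response, length n.
#' @param gamma Regularisation parameter (> 0); larger means less
#'   smoothing.
#' @param sigma RBF kernel width (> 0), in predictor units.
#' @return An object of class `lssvm_model` with dual coefficients
#'   `alpha`, bias, kernel width, the training predictors, the response
#'   scaling, and the KKT residual of the solved system.
#' @export
fit_lssvm <- function(x, y, gamma, sigma) {
  if (gamma <= 0 || sigma <= 0) {
    rlang::abort("`gamma` and `sigma` must be positive.",
                 class = "ovaspec_domain_error")
  }
  xm <- .as_predictor_matrix(x)
  y_center <- mean(y)
  y_scale <- if (length(y) > 1 && stats::sd(y) > 0) stats::sd(y) else 1
  ys <- (y - y_center) / y_scale
  k <- .rbf_kernel_cross(xm, xm, sigma)
  sol <- .solve_lssvm_system(k, ys, gamma)
  structure(
    list(alpha = sol$alpha, bias = sol$bias, gamma = gamma, sigma = sigma,
         x = xm, y_center = y_center, y_scale = y_scale,
         kkt_residual = sol$residual),
    class = "lssvm_model"
  )
}

#' @param object An `lssvm_model`.
#' @param newdata Matrix or spectra table with the training band layout.
#' @param ... Unused.
#' @rdname fit_lssvm
#' @export
predict.lssvm_model <- function(object, newdata, ...) {
  xn <- .as_predictor_matrix(newdata)
  k <- .rbf_kernel_cross(xn, object$x, object$sigma)
  drop(k %*% object$alpha + object$bias) * object$y_scale + object$y_center
}

# ---------------------------------------------------------------------------

#' Regression performance metrics
#'
#' Root-mean-square error `sqrt(mean((pred - obs)^2))` (n denominator) and
#' coefficient of determination `1 - SS_res / SS_tot`.
#'
#' @param y_true Observed values.
#' @param y_pred Predicted values, same length.
#' @return One-row tibble with columns `r2` and `rmse`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    rlang::abort("Zero variance in `y_true`: R^2 is undefined.",
                 class = "ovaspec_domain_error")
  }
  ss_res <- sum((y_pred - y_true)^2)
  tibble::tibble(r2 = 1 - ss_res / ss_tot,
                 rmse = sqrt(ss_res / length(y_true)))
}

.make_folds <- function(n, k, seed = NULL) {
  assign_folds <- function() sample(rep(seq_len(k), length.out = n))
  if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
}

#' k-fold cross-validation of a PLSR or LSSVM specification
#'
#' Seeded random fold assignment (near-equal sizes); the model is refit on
#' each training complement, out-of-fold predictions are pooled, and the
#' metrics are computed once on the pooled vector.
#'
#' @param x Predictor matrix or spectra table.
#' @param y Numeric response.
#' @param learner `"plsr"` or `"lssvm"`.
#' @param n_lv Latent variables (PLSR).
#' @param gamma,sigma LSSVM hyperparameters.
#' @param k Number of folds (`k <= n`); `k = n` gives leave-one-out.
#' @param seed Integer seed for the fold shuffle.
#' @return List with `r2`, `rmse` (cross-validated) and a tibble
#'   `predictions` (`sample`, `fold`, `observed`, `predicted`).
#' @export
kfold_cv <- function(x, y, learner = c("plsr", "lssvm"), n_lv = NULL,
                     gamma = NULL, sigma = NULL, k = 5, seed = NULL) {
  learner <- match.arg(learner)
  xm <- .as_predictor_matrix(x)
  n <- nrow(xm)
  if (k > n) {
    rlang::abort("`k` cannot exceed the number of samples.",
                 class = "ovaspec_domain_error")
  }
  folds <- .make_folds(n, k, seed)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    te <- folds == f
    fit <- if (learner == "plsr") {
      fit_plsr(xm[!te, , drop = FALSE], y[!te], n_lv)
    } else {
      fit_lssvm(xm[!te, , drop = FALSE], y[!te], gamma, sigma)
    }
    pred[te] <- predict(fit, xm[te, , drop = FALSE])
  }
  m <- compute_metrics(y, pred)
  list(r2 = m$r2, rmse = m$rmse,
       predictions = tibble::tibble(sample = seq_len(n), fold = folds,
                                    observed = y, predicted = pred))
}

# Pooled RMSECV for every latent-variable count 1..h_max from one PLS fit
# per fold (the coefficient path makes the h sweep free).
.pls_cv_rmse_trace <- function(x, y, h_max, folds) {
  n <- nrow(x)
  k <- max(folds)
  pred <- matrix(0, n, h_max)
  for (f in seq_len(k)) {
    te <- folds == f
    fit <- .pls_fit(x[!te, , drop = FALSE], y[!te], h_max)
    xc <- sweep(x[te, , drop = FALSE], 2, fit$x_mean)
    pred[te, ] <- xc %*% fit$coef_path + fit$y_mean
  }
  sqrt(colMeans((pred - y)^2))
}

#' Pick a point on an RMSECV trace by the parsimony plateau rule
#'
#' Returns the smallest index whose RMSECV is within a fractional
#' tolerance of the trace minimum — the "no longer significant decrease"
#' rule stated as a testable criterion. `tol = 0` reduces to the argmin
#' (first on ties).
#'
#' @param rmsecv Numeric RMSECV trace.
#' @param tol Fractional tolerance above the minimum.
#' @return Integer index.
#' @export
select_from_trace <- function(rmsecv, tol = 0.02) {
  which(rmsecv <= (1 + tol) * min(rmsecv))[1]
}

#' Choose the number of PLSR latent variables by cross-validation
#'
#' Computes five-fold RMSECV for every latent-variable count up to
#' `max_lv` (capped at `min(n - 1, p)` when the data are smaller) and
#' applies [select_from_trace()].
#'
#' @inheritParams kfold_cv
#' @param max_lv Largest candidate count.
#' @param tol Plateau tolerance passed to [select_from_trace()].
#' @return The selected integer count, with the RMSECV trace attached as
#'   attribute `"rmsecv"`.
#' @export
select_n_lv <- function(x, y, max_lv = 16, tol = 0.02, k = 5, seed = NULL) {
  xm <- .as_predictor_matrix(x)
  h_max <- min(max_lv, ncol(xm),
               nrow(xm) - ceiling(nrow(xm) / k) - 1)
  h_max <- max(h_max, 1)
  folds <- .make_folds(nrow(xm), k, seed)
  trace <- .pls_cv_rmse_trace(xm, y, h_max, folds)
  structure(select_from_trace(trace, tol), rmsecv = trace)
}

# Fast LSSVM cross-validation from a precomputed squared-distance matrix:
# the kernel depends on sigma only through exp(-d2 / (2 sigma^2)).
.lssvm_cv_rmse <- function(d2, y, folds, gamma, sigma) {
  n <- length(y)
  k_folds <- max(folds)
  pred <- numeric(n)
  for (f in seq_len(k_folds)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    y_center <- mean(y[tr])
    y_sd <- stats::sd(y[tr]); if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
    ktr <- exp(-d2[tr, tr, drop = FALSE] / (2 * sigma^2))
    sol <- .solve_lssvm_system(ktr, (y[tr] - y_center) / y_sd, gamma)
    kte <- exp(-d2[te, tr, drop = FALSE] / (2 * sigma^2))
    pred[te] <- drop(kte %*% sol$alpha + sol$bias) * y_sd + y_center
  }
  sqrt(mean((pred - y)^2))
}

#' Two-stage grid search for LSSVM hyperparameters
#'
#' Searches `(log2(gamma), log2(1/sigma^2))` over a coarse step-1.0 grid
#' on the given square range, then a fine step-0.1 grid spanning +/- 1.0
#' around the coarse optimum (clamped to the range). The objective is
#' five-fold RMSECV with a fold assignment fixed once per search, so the
#' surface is smooth in the hyperparameters.
#'
#' @inheritParams kfold_cv
#' @param log2_range Numeric length-2: the search box for both axes, in
#'   log2 units.
#' @param objective Optional replacement objective
#'   `function(log2_gamma, log2_inv_sigma2) -> value` (used for testing
#'   the search itself); default `NULL` uses the RMSECV objective.
#' @return List with the optimum (`log2_gamma`, `log2_inv_sigma2`,
#'   `gamma`, `sigma`, `rmsecv`) and tibbles `coarse` / `fine` holding
#'   every evaluated point.
#' @export
grid_search_lssvm <- function(x, y, log2_range = c(-8, 8), k = 5,
                              seed = NULL, objective = NULL) {
  if (is.null(objective)) {
    xm <- .as_predictor_matrix(x)
    d2 <- outer(rowSums(xm^2), rowSums(xm^2), "+") - 2 * tcrossprod(xm)
    d2[d2 < 0] <- 0
    folds <- .make_folds(nrow(xm), k, seed)
    objective <- function(lg, li) {
      .lssvm_cv_rmse(d2, y, folds, gamma = 2^lg, sigma = sqrt(2^(-li)))
    }
  }
  eval_grid <- function(lg_vals, li_vals) {
    grid <- tidyr::expand_grid(log2_gamma = lg_vals,
                               log2_inv_sigma2 = li_vals)
    grid$rmsecv <- purrr::map2_dbl(grid$log2_gamma, grid$log2_inv_sigma2,
                                   objective)
    grid
  }
  steps <- seq(log2_range[1], log2_range[2], by = 1)
  coarse <- eval_grid(steps, steps)
  best_c <- coarse[which.min(coarse$rmsecv), ]
  fine_axis <- function(center) {
    v <- seq(center - 1, center + 1, by = 0.1)
    v[v >= log2_range[1] & v <= log2_range[2]]
  }
  fine <- eval_grid(fine_axis(best_c$log2_gamma),
                    fine_axis(best_c$log2_inv_sigma2))
  best <- fine[which.min(fine$rmsecv), ]
  list(log2_gamma = best$log2_gamma,
       log2_inv_sigma2 = best$log2_inv_sigma2,
       gamma = 2^best$log2_gamma,
       sigma = sqrt(2^(-best$log2_inv_sigma2)),
       rmsecv = best$rmsecv,
       coarse = coarse, fine = fine)
}
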