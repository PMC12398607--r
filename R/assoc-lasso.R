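# Internal standardization with population (1/n) variance, so that on the
# standardized scale lambda_max = max_j |<x_j, y>| / n is exact.
std_cols <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  s <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  if (any(s == 0)) {
    abort(paste0("zero-variance column(s): ",
                 paste(colnames(m)[s == 0], collapse = ", ")))
  }
  list(z = sweep(sweep(m, 2L, mu), 2L, s, `/`), mu = mu, s = s)
}

as_design <- function(data, outcome, features) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(features %in% names(data)))
  x <- as.matrix(data[, features, drop = FALSE])
  y <- data[[outcome]]
  if (anyNA(x) || anyNA(y)) abort("missing values in the design matrix")
  if (sd(y) == 0) abort("degenerate outcome: zero variance")
  list(x = x, y = y)
}

#' Regularization-path grid for the penalized fits
#'
#' 100 log-spaced values from the critical penalty
#' `lambda_max = max_j |<x_j, y>| / (n * alpha)` (computed on the
#' internally standardized scale, at which all coefficients are exactly
#' zero) down to `1e-4 * lambda_max`.
#'
#' @param data Data frame holding outcome and features.
#' @param outcome,features Column names.
#' @param alpha Elastic-net mixing parameter (1 = LASSO).
#' @param n_lambda Grid size (default 100).
#' @return Decreasing numeric vector of penalty values.
#' @export
lambda_grid <- function(data, outcome, features, alpha = 1,
                        n_lambda = 100L) {
  d <- as_design(data, outcome, features)
  xs <- std_cols(d$x)$z
  ys <- as.numeric(scale(d$y, scale = sqrt(mean((d$y - mean(d$y))^2))))
  lmax <- max(abs(crossprod(xs, ys))) / (nrow(xs) * alpha)
  exp(seq(log(lmax), log(lmax * 1e-4), length.out = n_lambda))
}

#' Penalized least-squares fit at a fixed penalty
#'
#' Solves `argmin_beta { (1/2n) sum_i (y_i - x_i' beta)^2 +
#' lambda * [ alpha * ||beta||_1 + (1-alpha)/2 * ||beta||_2^2 ] }` with an
#' unpenalized intercept. Features and outcome are standardized internally
#' (configurable); coefficients are reported back-transformed to the
#' original feature scale. Zeros are exact (soft-thresholding), never
#' post-hoc thresholded.
#'
#' @inheritParams lambda_grid
#' @param lambda Non-negative penalty (on the standardized scale).
#' @param alpha Elastic-net mixing parameter in (0, 1]; 1 (default) is the
#'   LASSO penalty.
#' @param standardize Standardize internally (default TRUE).
#' @return Object of class `lasso_fit`: list with `lambda`, `alpha`,
#'   `coefficients` (named, original scale), `coefficients_std`,
#'   `intercept`, `selected` (names with exactly non-zero coefficients).
#' @export
lasso_fit <- function(data, outcome, features, lambda, alpha = 1,
                      standardize = TRUE) {
  stopifnot(lambda >= 0, alpha > 0, alpha <= 1)
  d <- as_design(data, outcome, features)
  n <- nrow(d$x)
  if (standardize) {
    xs <- std_cols(d$x)
    mu_y <- mean(d$y)
    s_y <- sqrt(mean((d$y - mu_y)^2))
    z <- xs$z
    yz <- (d$y - mu_y) / s_y
  } else {
    z <- d$x; yz <- d$y
    xs <- list(mu = rep(0, ncol(z)), s = rep(1, ncol(z)))
    mu_y <- 0; s_y <- 1
  }
  if (ncol(z) == 1L) {
    # univariate closed form: soft-threshold of the centred inner product
    zc <- z[, 1L] - mean(z[, 1L]); yc <- yz - mean(yz)
    rho <- sum(zc * yc) / n
    denom <- sum(zc^2) / n + lambda * (1 - alpha)
    b <- sign(rho) * max(abs(rho) - lambda * alpha, 0) / denom
    beta_std <- setNames(b, colnames(d$x))
    beta <- beta_std * s_y / xs$s
    int_std <- mean(yz) - b * mean(z[, 1L])
    intercept <- int_std * s_y + mu_y - sum(beta * xs$mu)
    return(structure(list(
      lambda = lambda, alpha = alpha,
      coefficients = beta, coefficients_std = beta_std,
      intercept = intercept,
      selected = names(beta_std)[beta_std != 0],
      n = n, outcome = outcome
    ), class = "lasso_fit"))
  }
  # path fit, then exact solution at the requested penalty
  path <- sort(unique(c(lambda_grid_std(z, yz, alpha), lambda)),
               decreasing = TRUE)
  fit <- glmnet::glmnet(z, yz, alpha = alpha, lambda = path,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-14, maxit = 1e6)
  cf <- as.numeric(coef(fit, s = lambda, exact = TRUE, x = z, y = yz,
                        alpha = alpha, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-14, maxit = 1e6))
  beta_std <- setNames(cf[-1L], colnames(d$x))
  beta <- beta_std * s_y / xs$s
  intercept <- cf[1L] * s_y + mu_y - sum(beta * xs$mu)
  structure(list(
    lambda = lambda, alpha = alpha,
    coefficients = beta, coefficients_std = beta_std,
    intercept = intercept,
    selected = names(beta_std)[beta_std != 0],
    n = n, outcome = outcome
  ), class = "lasso_fit")
}

lambda_grid_std <- function(z, yz, alpha, n_lambda = 100L) {
  lmax <- max(abs(crossprod(z, yz))) / (nrow(z) * alpha)
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * 1e-4), length.out = n_lambda))
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat("<lasso_fit> lambda =", format(x$lambda, digits = 5),
      " alpha =", x$alpha, "\n")
  cat("selected (", length(x$selected), "):",
      paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Cross-validated penalty selection
#'
#' 10-fold (by default) cross-validation over the penalty grid: the data are
#' split into a seeded random partition of near-equal folds; for each
#' candidate penalty the held-out mean squared error is averaged over folds;
#' the penalty minimising the mean CV-MSE is returned (ties broken toward
#' the larger, more regularized penalty). Standardization statistics are
#' computed on each training set and applied to its validation fold.
#'
#' @inheritParams lambda_grid
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the fold partition.
#' @param grid Optional penalty grid; defaults to [lambda_grid()] on the
#'   full data.
#' @return List with `lambda` (the argmin), `cv_trace` (tibble: `lambda`,
#'   `mean_mse`) and `folds` (the fold assignment).
#' @export
cv_lambda <- function(data, outcome, features, n_folds = 10L, seed = 1L,
                      alpha = 1, grid = NULL) {
  d <- as_design(data, outcome, features)
  n <- nrow(d$x)
  stopifnot(n >= n_folds, n_folds >= 2L)
  if (is.null(grid)) grid <- lambda_grid(data, outcome, features, alpha)
  grid <- sort(grid, decreasing = TRUE)
  folds <- withr::with_seed(seed, sample(rep(seq_len(n_folds),
                                             length.out = n)))
  mse <- matrix(NA_real_, n_folds, length(grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    xs <- std_cols(d$x[tr, , drop = FALSE])
    mu_y <- mean(d$y[tr])
    s_y <- sqrt(mean((d$y[tr] - mu_y)^2))
    fit <- glmnet::glmnet(xs$z, (d$y[tr] - mu_y) / s_y, alpha = alpha,
                          lambda = grid, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-10, maxit = 1e6)
    zv <- sweep(sweep(d$x[!tr, , drop = FALSE], 2L, xs$mu), 2L, xs$s, `/`)
    pred_std <- predict(fit, newx = zv, s = grid)
    pred <- pred_std * s_y + mu_y
    mse[f, ] <- colMeans((d$y[!tr] - pred)^2)
  }
  mean_mse <- colMeans(mse)
  best <- which(mean_mse == min(mean_mse))[1L]  # grid decreasing: larger wins ties
  list(lambda = grid[best],
       cv_trace = tibble(lambda = grid, mean_mse = mean_mse),
       folds = folds)
}

#' Iteration-averaged cross-validated penalty
#'
#' The CV-optimal penalty fluctuates with the random fold partition; this
#' repeats [cv_lambda()] for `n_iterations` independently seeded partitions
#' and returns the arithmetic mean of the per-iteration optima.
#'
#' @inheritParams cv_lambda
#' @param n_iterations Number of fold-partition iterations (default 100).
#' @return List with `lambda` (mean), `per_iteration` (numeric vector) and
#'   `grid`.
#' @export
average_lambda <- function(data, outcome, features, n_iterations = 100L,
                           n_folds = 10L, seed = 1L, alpha = 1) {
  stopifnot(n_iterations >= 1L)
  grid <- lambda_grid(data, outcome, features, alpha)
  lams <- vapply(seq_len(n_iterations), function(i) {
    cv_lambda(data, outcome, features, n_folds = n_folds,
              seed = derive_seed(as.double(seed) + i, "folds"),
              alpha = alpha, grid = grid)$lambda
  }, numeric(1))
  list(lambda = mean(lams), per_iteration = lams, grid = grid)
}
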