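make_lm_data <- function(n = 50, p = 3, beta = c(1, -2, 0.5), seed = 1,
                         noise = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- paste0("x", seq_len(p))
    y <- as.numeric(x %*% beta + noise * rnorm(n))
    data.frame(y = y, x)
  })
}

test_that("penalties at or above the critical value zero every coefficient", {
  d <- make_lm_data(n = 40)
  feats <- paste0("x", 1:3)
  g <- lambda_grid(d, "y", feats)
  expect_length(g, 100)
  expect_true(all(diff(g) < 0))
  f <- lasso_fit(d, "y", feats, lambda = g[1])
  expect_length(f$selected, 0)
  expect_true(all(f$coefficients == 0))
  f2 <- lasso_fit(d, "y", feats, lambda = g[1] * 2)
  expect_length(f2$selected, 0)
  # just below the critical value, something enters
  f3 <- lasso_fit(d, "y", feats, lambda = g[2])
  expect_gt(length(f3$selected), 0)
})

test_that("the unpenalized fit equals ordinary least squares", {
  d <- make_lm_data(n = 10, p = 3, seed = 2)
  f <- lasso_fit(d, "y", paste0("x", 1:3), lambda = 0)
  ols <- coef(lm(y ~ x1 + x2 + x3, d))
  expect_equal(unname(f$coefficients), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(unname(f$intercept), unname(ols[1]), tolerance = 1e-6)
})

test_that("a single standardized predictor soft-thresholds exactly", {
  d <- make_lm_data(n = 30, p = 1, beta = 0.6, seed = 3)
  x <- d$x1
  xs <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  ys <- (d$y - mean(d$y)) / sqrt(mean((d$y - mean(d$y))^2))
  rho <- mean(xs * ys)
  for (lam in c(0, 0.05, abs(rho) - 1e-3, abs(rho) + 0.1)) {
    f <- lasso_fit(d, "y", "x1", lambda = lam)
    st <- sign(rho) * max(abs(rho) - lam, 0)
    expect_equal(unname(f$coefficients_std), st, tolerance = 1e-8)
  }
})

test_that("enlarging the penalty never adds the single predictor back", {
  d <- make_lm_data(n = 30, p = 1, beta = 0.6, seed = 4)
  lams <- seq(0, 1, by = 0.05)
  sel <- vapply(lams, function(l) {
    length(lasso_fit(d, "y", "x1", lambda = l)$selected)
  }, integer(1))
  expect_true(all(diff(sel) <= 0))
})

test_that("the penalized objective beats a brute-force coefficient grid", {
  # tiny instance; the fit's objective must be <= the best grid objective
  d <- make_lm_data(n = 12, p = 2, beta = c(0.8, -0.4), seed = 5)
  feats <- c("x1", "x2")
  des <- effortconn:::as_design(d, "y", feats)
  xs <- effortconn:::std_cols(des$x)$z
  ys <- (des$y - mean(des$y)) / sqrt(mean((des$y - mean(des$y))^2))
  objective <- function(b, lam) {
    mean((ys - xs %*% b)^2) / 2 + lam * sum(abs(b))
  }
  grid <- seq(-1.5, 1.5, by = 0.01)
  for (lam in c(0.05, 0.2)) {
    f <- lasso_fit(d, "y", feats, lambda = lam)
    best_grid <- min(outer(grid, grid, Vectorize(function(a, b) {
      objective(c(a, b), lam)
    })))
    expect_lte(objective(unname(f$coefficients_std), lam),
               best_grid + 1e-6)
  }
})

test_that("cross-validated penalty selection behaves across regimes", {
  # single dominant feature: moderate penalties beat the grid maximum
  d <- make_lm_data(n = 60, p = 5, beta = c(2, 0, 0, 0, 0), seed = 6,
                    noise = 1)
  feats <- paste0("x", 1:5)
  cv <- cv_lambda(d, "y", feats, seed = 1)
  tr <- cv$cv_trace
  expect_lt(min(tr$mean_mse), tr$mean_mse[1])
  expect_true(cv$lambda %in% tr$lambda)
  # two fold seeds may disagree but stay on the grid
  cv2 <- cv_lambda(d, "y", feats, seed = 2)
  expect_true(cv2$lambda %in% tr$lambda)
  expect_error(cv_lambda(d[1:5, ], "y", feats), "n >= n_folds|n_subjects")
})

test_that("pure-noise outcomes select almost nothing after refit", {
  sel_sizes <- vapply(1:20, function(s) {
    d <- withr::with_seed(s, {
      x <- matrix(rnorm(200 * 19), 200, 19)
      colnames(x) <- paste0("f", 1:19)
      data.frame(y = rnorm(200), x)
    })
    cv <- cv_lambda(d, "y", paste0("f", 1:19), seed = s)
    length(lasso_fit(d, "y", paste0("f", 1:19), cv$lambda)$selected)
  }, numeric(1))
  expect_lte(mean(sel_sizes), 2)
})

test_that("iteration-averaged penalties reduce and bound correctly", {
  d <- make_lm_data(n = 45, p = 6, beta = c(1.5, rep(0, 5)), seed = 7)
  feats <- paste0("x", 1:6)
  a1 <- average_lambda(d, "y", feats, n_iterations = 1, seed = 10)
  direct <- cv_lambda(d, "y", feats,
                      seed = effortconn:::derive_seed(11, "folds"),
                      grid = a1$grid)
  expect_equal(a1$lambda, direct$lambda)
  a <- average_lambda(d, "y", feats, n_iterations = 20, seed = 10)
  b <- average_lambda(d, "y", feats, n_iterations = 20, seed = 10)
  expect_identical(a$lambda, b$lambda)
  expect_gte(a$lambda, min(a$per_iteration))
  expect_lte(a$lambda, max(a$per_iteration))
})

test_that("partial correlation matches the recursive closed form", {
  withr::with_seed(8, {
    x <- rnorm(60)
    z <- rnorm(60)
    y <- 0.4 * x + 0.5 * z + rnorm(60)
  })
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  closed <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  pc <- partial_correlation(x, y, data.frame(z = z))
  expect_equal(pc$r, closed, tolerance = 1e-12)
  expect_equal(pc$df, 60 - 3)
  # no controls reduces exactly to Pearson (including the p-value)
  pc0 <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_identical(pc0$r, cor(x, y))
  expect_equal(pc0$p, ct$p.value, tolerance = 1e-12)
  # identity
  pcid <- partial_correlation(x, x)
  expect_equal(pcid$r, 1)
  expect_equal(pcid$p, 0)
  expect_error(partial_correlation(x, y, data.frame(z = z, z2 = 2 * z)),
               "collinear")
})

test_that("partial correlation is invariant to affine rescaling", {
  withr::with_seed(9, {
    x <- rnorm(40); y <- 0.3 * x + rnorm(40)
    ctrl <- data.frame(a = rnorm(40), b = rnorm(40))
  })
  r1 <- partial_correlation(x, y, ctrl)$r
  r2 <- partial_correlation(5 * x - 2, -0.1 * y + 7,
                            data.frame(a = 3 * ctrl$a + 1,
                                       b = -ctrl$b / 2))$r
  expect_equal(abs(r1), abs(r2), tolerance = 1e-12)
})

test_that("the correlation Bayes factor matches an independent quadrature", {
  withr::with_seed(10, {
    x <- rnorm(45); y <- 0.2 * x + rnorm(45)
    ctrl <- data.frame(a = rnorm(45), b = rnorm(45))
  })
  bf <- bayes_factor_null(x, y, ctrl)
  # independent oracle: the Gaussian prior on the Fisher scale integrates
  # in closed form, N(z; 0, se^2 + prior_sd^2)
  pc <- partial_correlation(x, y, ctrl)
  se <- 1 / sqrt(45 - 3 - 2)
  z <- atanh(pc$r)
  oracle <- dnorm(z, 0, se) / dnorm(z, 0, sqrt(se^2 + 0.5))
  expect_equal(bf$bf01, oracle, tolerance = 1e-8)
  expect_equal(bf$bf01 * bf$bf10, 1, tolerance = 1e-10)
  expect_identical(bf, bayes_factor_null(x, y, ctrl))
})

test_that("the Bayes factor favours the null under the null", {
  bf01 <- vapply(1:200, function(i) {
    withr::with_seed(3000 + i, {
      x <- rnorm(45); y <- rnorm(45)
    })
    bayes_factor_null(x, y)$bf01
  }, numeric(1))
  expect_gt(median(bf01), 1)
})

test_that("the elastic net replication nests the LASSO limit", {
  d <- make_lm_data(n = 45, p = 6, beta = c(1.5, -1, rep(0, 4)), seed = 11)
  feats <- paste0("x", 1:6)
  lam <- 0.1
  l1 <- lasso_fit(d, "y", feats, lambda = lam, alpha = 1)$selected
  en <- lasso_fit(d, "y", feats, lambda = lam, alpha = 1 - 1e-9)$selected
  expect_setequal(en, l1)
  # above the elastic-net critical value the selection is empty
  g05 <- lambda_grid(d, "y", feats, alpha = 0.5)
  f <- lasso_fit(d, "y", feats, lambda = g05[1] * 1.001, alpha = 0.5)
  expect_length(f$selected, 0)
})

test_that("stepwise selection is deterministic and finds dominant signals", {
  d <- make_lm_data(n = 100, p = 6, beta = c(3, rep(0, 5)), seed = 12)
  feats <- paste0("x", 1:6)
  s1 <- replicate_stepwise(d, "y", feats)
  expect_true("x1" %in% s1)
  expect_identical(s1, replicate_stepwise(d, "y", feats))
  # all-noise: small final sets
  sizes <- vapply(1:10, function(s) {
    dn <- withr::with_seed(100 + s, {
      x <- matrix(rnorm(200 * 19), 200, 19)
      colnames(x) <- paste0("f", 1:19)
      data.frame(y = rnorm(200), x)
    })
    length(replicate_stepwise(dn, "y", paste0("f", 1:19)))
  }, numeric(1))
  expect_lte(median(sizes), 2)
})

test_that("a duplicated outcome is always selected and confirmed", {
  d <- make_design(n = 45, seed = 13)
  d$self <- d$apathy
  rep <- run_two_step(d, "apathy", c(tract_pairs()$feature, "self"),
                      n_iterations = 10, seed = 1, replications = FALSE)
  expect_true("self" %in% rep$selected)
  expect_true("self" %in% rep$confirmed)
})

test_that("the two-step report is deterministic under the master seed", {
  d <- make_design(n = 45, seed = 14, r_planted = 0.4,
                   planted = c("OFC_dCaudate", "SMA_NAcc"))
  r1 <- run_two_step(d, "apathy", tract_pairs()$feature,
                     n_iterations = 10, seed = 5, replications = FALSE)
  r2 <- run_two_step(d, "apathy", tract_pairs()$feature,
                     n_iterations = 10, seed = 5, replications = FALSE)
  expect_identical(r1$lambda, r2$lambda)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$partial, r2$partial)
  # tidy/glance shapes
  td <- tidy(r1)
  expect_equal(nrow(td), 19)
  expect_true(all(r1$confirmed %in% td$feature[td$confirmed %in% TRUE]))
  gl <- glance(r1)
  expect_equal(gl$n_selected, length(r1$selected))
})

test_that("Bayes-factor scope follows the anatomical family of selections", {
  d <- make_design(n = 45, seed = 15, r_planted = 0.5,
                   planted = "OFC_dCaudate")
  rep <- run_two_step(d, "apathy", tract_pairs()$feature,
                      n_iterations = 10, seed = 2, replications = FALSE,
                      bf_scope = "family")
  if (length(rep$selected) > 0) {
    fams <- effortconn:::feature_family(rep$selected)
    expect_true(all(effortconn:::feature_family(rep$bf01$feature) %in% fams))
    expect_length(intersect(rep$bf01$feature, rep$selected), 0)
  }
  rep_all <- run_two_step(d, "apathy", tract_pairs()$feature,
                          n_iterations = 10, seed = 2,
                          replications = FALSE, bf_scope = "all")
  expect_equal(nrow(rep_all$bf01), 19 - length(rep_all$selected))
})

test_that("second-level subscore correlations cover the requested grid", {
  d <- make_design(n = 45, seed = 16)
  out <- subscore_correlations(d, features = c("SMA_M1", "OFC_M1"))
  expect_equal(nrow(out), 6)
  expect_setequal(unique(out$outcome),
                  c("apathy_action", "apathy_emotion", "apathy_cognitive"))
  expect_true(all(is.finite(out$r)))
})
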