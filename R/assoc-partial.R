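#' Confound-adjusted partial correlation
#'
#' Pearson correlation between the residuals of `x` and `y` after each is
#' regressed on an intercept plus the control variables; the p-value comes
#' from the t transform with `n - 2 - k` degrees of freedom (two-sided),
#' `k` the number of controls. With no controls this reduces exactly to the
#' plain Pearson correlation. Spearman (rank) flavour available.
#'
#' @param x,y Numeric vectors of equal length.
#' @param controls Data frame / matrix of control variables (or NULL).
#' @param method `"pearson"` (default) or `"spearman"` (ranks taken before
#'   residualization).
#' @return One-row tibble: `r`, `p`, `df`, `n`, `n_controls`.
#' @export
partial_correlation <- function(x, y, controls = NULL, method = "pearson") {
  stopifnot(length(x) == length(y), method %in% c("pearson", "spearman"))
  n <- length(x)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
    if (!is.null(controls)) controls <- as.data.frame(lapply(
      as.data.frame(controls), rank))
  }
  k <- if (is.null(controls)) 0L else ncol(as.data.frame(controls))
  if (n <= k + 2L) abort("need n > n_controls + 2 observations")
  if (k > 0L) {
    cm <- as.matrix(as.data.frame(controls))
    if (qr(cbind(1, cm))$rank < ncol(cm) + 1L) {
      abort("collinear control variables")
    }
    rx <- residuals(lm(x ~ cm))
    ry <- residuals(lm(y ~ cm))
  } else {
    rx <- x; ry <- y
  }
  r <- cor(rx, ry)
  df <- n - 2L - k
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df)
  }
  tibble(r = r, p = p, df = df, n = n, n_controls = k)
}

#' Bayes factor for the null over a (partial) correlation
#'
#' Evidence for the null hypothesis of zero (partial) correlation,
#' `BF01 > 1` favouring the null. The sampling model is the Fisher-z
#' approximation `atanh(r) ~ N(atanh(rho), 1/(n - 3 - k))`; the alternative
#' places a Normal(0, `prior_sd`) prior on the Fisher scale
#' `zeta = atanh(rho)` (default width `1/sqrt(2)`), and the marginal
#' likelihood is obtained by numerical integration over `zeta`.
#'
#' @inheritParams partial_correlation
#' @param prior_sd Prior SD on the Fisher scale (default `1/sqrt(2)`).
#' @return One-row tibble: `bf01`, `bf10`, `r`, `n`, `n_controls`.
#' @export
bayes_factor_null <- function(x, y, controls = NULL,
                              prior_sd = 1 / sqrt(2)) {
  pc <- partial_correlation(x, y, controls)
  n <- pc$n; k <- pc$n_controls
  if (n - 3L - k <= 0L) abort("too few observations for the Fisher-z model")
  se <- 1 / sqrt(n - 3 - k)
  z <- atanh(min(max(pc$r, -1 + 1e-12), 1 - 1e-12))
  like_null <- dnorm(z, 0, se)
  marg <- integrate(function(zeta) dnorm(z, zeta, se) * dnorm(zeta, 0, prior_sd),
                    -Inf, Inf, rel.tol = 1e-10)$value
  tibble(bf01 = like_null / marg, bf10 = marg / like_null,
         r = pc$r, n = n, n_controls = k)
}
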