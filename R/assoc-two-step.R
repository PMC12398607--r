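# Anatomical family of a feature name: leading region for tract pairs
# (SMA_*, OFC_*, *_GP, ...), circuit group for MEP ratio columns.
feature_family <- function(feature) {
  vapply(feature, function(f) {
    if (f %in% mep_circuits()) return("circuit")
    strsplit(f, "_", fixed = TRUE)[[1L]][1L]
  }, character(1))
}

#' Conservative two-step feature-outcome association procedure
#'
#' Step 1 selects features by LASSO at the iteration-averaged
#' cross-validated penalty ([average_lambda()] then [lasso_fit()]); the
#' selection is the exactly-non-zero coefficient set. Step 2 confirms each
#' selected feature with a confound-adjusted partial correlation at the
#' two-sided `alpha` level. Step 3 quantifies null evidence (BF01) for
#' non-selected features (by default those sharing an anatomical family
#' with a selected feature) and, optionally, replicates the selection with
#' a less conservative Elastic Net and a bidirectional AIC stepwise
#' regression. No multiple-testing correction is applied across the
#' selected features' partial correlations (each is tested at `alpha`);
#' the report surfaces this.
#'
#' @param data Data frame with one row per subject.
#' @param outcome Outcome column name.
#' @param features Character vector of feature column names.
#' @param confounds Character vector of confound column names (default
#'   `c("age", "gender", "depression", "anhedonia")`).
#' @param n_iterations Fold-partition iterations for the averaged penalty
#'   (default 100).
#' @param n_folds CV folds (default 10).
#' @param seed Master integer seed.
#' @param alpha Two-sided significance level for Step 2 (default 0.05).
#' @param bf_scope Which non-selected features get a BF01: `"family"`
#'   (default: same anatomical family as a selected feature), `"all"`, or
#'   `"none"`.
#' @param replications Run Elastic Net and stepwise replications (default
#'   TRUE).
#' @param enet_alpha Elastic-net mixing parameter (default 0.5).
#' @return Object of class `association_report`: list with `outcome`,
#'   `lambda` (averaged penalty), `lasso` (the [lasso_fit()]), `selected`,
#'   `partial` (per-selected-feature tibble: r, p, confirmed), `bf01`
#'   (per-scoped-feature tibble), `confirmed`, `replication` (selected sets
#'   and agreement flags), `alpha`.
#' @export
run_two_step <- function(data, outcome, features,
                         confounds = c("age", "gender", "depression",
                                       "anhedonia"),
                         n_iterations = 100L, n_folds = 10L, seed = 1L,
                         alpha = 0.05, bf_scope = "family",
                         replications = TRUE, enet_alpha = 0.5) {
  stopifnot(all(confounds %in% names(data)),
            bf_scope %in% c("family", "all", "none"))
  if (nrow(data) <= length(confounds) + 2L) {
    abort("need more subjects than confounds + 2")
  }

  avg <- average_lambda(data, outcome, features, n_iterations = n_iterations,
                        n_folds = n_folds, seed = derive_seed(seed, "assoc"))
  fit <- lasso_fit(data, outcome, features, lambda = avg$lambda)
  selected <- fit$selected

  ctrl <- data[, confounds, drop = FALSE]
  partial <- purrr::map_dfr(selected, function(f) {
    partial_correlation(data[[f]], data[[outcome]], ctrl) %>%
      mutate(feature = f, .before = 1L)
  })
  if (nrow(partial) > 0) {
    partial <- partial %>% mutate(confirmed = .data$p < alpha)
  } else {
    partial <- tibble(feature = character(), r = numeric(), p = numeric(),
                      df = integer(), n = integer(), n_controls = integer(),
                      confirmed = logical())
  }
  confirmed <- partial$feature[partial$confirmed]

  scope <- switch(bf_scope,
    none = character(),
    all = setdiff(features, selected),
    family = {
      fams <- feature_family(selected)
      cand <- setdiff(features, selected)
      cand[feature_family(cand) %in% fams]
    })
  bf <- purrr::map_dfr(scope, function(f) {
    bayes_factor_null(data[[f]], data[[outcome]], ctrl) %>%
      mutate(feature = f, .before = 1L)
  })
  if (nrow(bf) == 0L) {
    bf <- tibble(feature = character(), bf01 = numeric(), bf10 = numeric(),
                 r = numeric(), n = integer(), n_controls = integer())
  }

  replication <- NULL
  if (replications) {
    enet <- replicate_elastic_net(data, outcome, features,
                                  n_iterations = n_iterations,
                                  n_folds = n_folds, seed = seed,
                                  enet_alpha = enet_alpha)
    sw <- replicate_stepwise(data, outcome, features)
    replication <- list(
      elastic_net = enet,
      stepwise = sw,
      enet_contains_lasso = all(selected %in% enet),
      stepwise_contains_lasso = all(selected %in% sw)
    )
  }

  structure(list(
    outcome = outcome, lambda = avg$lambda, lambda_iterations = avg$per_iteration,
    lasso = fit, selected = selected, partial = partial, bf01 = bf,
    confirmed = confirmed, replication = replication, alpha = alpha,
    confounds = confounds, seed = seed
  ), class = "association_report")
}

#' Elastic Net replication of the LASSO selection
#'
#' Same CV/averaging machinery as Step 1 with the mixed L1/L2 penalty
#' (mixing parameter `enet_alpha`, default 0.5) — a less conservative
#' selector used to check the LASSO selection for false negatives.
#'
#' @inheritParams run_two_step
#' @return Character vector: the non-zero coefficient set.
#' @export
replicate_elastic_net <- function(data, outcome, features,
                                  n_iterations = 100L, n_folds = 10L,
                                  seed = 1L, enet_alpha = 0.5) {
  stopifnot(enet_alpha > 0, enet_alpha <= 1)
  avg <- average_lambda(data, outcome, features, n_iterations = n_iterations,
                        n_folds = n_folds,
                        seed = derive_seed(as.double(seed) + 1, "assoc"),
                        alpha = enet_alpha)
  lasso_fit(data, outcome, features, lambda = avg$lambda,
            alpha = enet_alpha)$selected
}

#' Stepwise-regression replication of the LASSO selection
#'
#' Bidirectional stepwise ordinary least squares starting from the
#' intercept-only model with the features as the candidate scope.
#' Deterministic given the data. The default criterion is BIC
#' (`k = log(n)` in the step penalty), matching the conservative character
#' of the main selection; AIC is available.
#'
#' @inheritParams run_two_step
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return Character vector: the final model's variable set.
#' @export
replicate_stepwise <- function(data, outcome, features, criterion = "bic") {
  stopifnot(criterion %in% c("bic", "aic"))
  df <- as.data.frame(data[, c(outcome, features), drop = FALSE])
  # syntactic names for the formula interface; mapped back afterwards
  safe <- make.names(names(df))
  map <- setNames(names(df), safe)
  names(df) <- safe
  null_f <- as.formula(paste(safe[1L], "~ 1"))
  full_f <- as.formula(paste(safe[1L], "~",
                             paste(safe[-1L], collapse = " + ")))
  fit0 <- lm(null_f, data = df)
  kpen <- if (criterion == "bic") log(nrow(df)) else 2
  sel <- step(fit0, scope = list(lower = null_f, upper = full_f),
              direction = "both", trace = 0, k = kpen)
  terms_sel <- attr(terms(sel), "term.labels")
  unname(map[terms_sel])
}

#' Second-level apathy-subscore partial correlations
#'
#' For features already identified at the first level, tests whether they
#' relate to specific apathy dimensions: plain confound-adjusted partial
#' correlations of each named feature against each subscore outcome, with
#' no fresh selection step.
#'
#' @param data Data frame with one row per subject.
#' @param features Character vector of feature columns to test.
#' @param outcomes Character vector of subscore columns (default the three
#'   apathy subscores).
#' @inheritParams run_two_step
#' @return Tibble: `outcome`, `feature`, `r`, `p`, `df`, `n`, `n_controls`.
#' @export
subscore_correlations <- function(data, features,
                                  outcomes = c("apathy_action",
                                               "apathy_emotion",
                                               "apathy_cognitive"),
                                  confounds = c("age", "gender",
                                                "depression", "anhedonia")) {
  ctrl <- data[, confounds, drop = FALSE]
  tidyr::expand_grid(outcome = outcomes, feature = features) %>%
    dplyr::rowwise() %>%
    dplyr::group_map(function(row, key) {
      partial_correlation(data[[row$feature]], data[[row$outcome]], ctrl) %>%
        mutate(outcome = row$outcome, feature = row$feature, .before = 1L)
    }) %>%
    bind_rows()
}

#' @export
print.association_report <- function(x, ...) {
  cat("<association_report> outcome:", x$outcome, "\n")
  cat("  averaged lambda:", format(x$lambda, digits = 5), "\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat("  confirmed (partial r, p <", x$alpha, ", no multiplicity correction):",
      if (length(x$confirmed)) paste(x$confirmed, collapse = ", ")
      else "(none)", "\n")
  if (!is.null(x$replication)) {
    cat("  replication: elastic net contains LASSO set:",
        x$replication$enet_contains_lasso,
        "| stepwise contains LASSO set:",
        x$replication$stepwise_contains_lasso, "\n")
  }
  invisible(x)
}

#' Tidy an association report
#'
#' @param x An `association_report`.
#' @param ... Unused.
#' @return One row per feature involved in any step: coefficient, selection
#'   flag, partial r/p, confirmation flag, BF01 where computed.
#' @export
tidy.association_report <- function(x, ...) {
  all_feats <- names(x$lasso$coefficients)
  base <- tibble(
    outcome = x$outcome,
    feature = all_feats,
    coefficient = as.numeric(x$lasso$coefficients),
    selected = all_feats %in% x$selected
  )
  base %>%
    left_join(x$partial %>% select("feature", "r", "p", "confirmed"),
              by = "feature") %>%
    left_join(x$bf01 %>% select("feature", "bf01"), by = "feature")
}

#' Summarise an association report
#'
#' @param x An `association_report`.
#' @param ... Unused.
#' @return One-row tibble of counts and the averaged penalty.
#' @export
glance.association_report <- function(x, ...) {
  tibble(outcome = x$outcome, lambda = x$lambda,
         n_features = length(x$lasso$coefficients),
         n_selected = length(x$selected),
         n_confirmed = length(x$confirmed),
         enet_contains_lasso = x$replication$enet_contains_lasso %||% NA,
         stepwise_contains_lasso = x$replication$stepwise_contains_lasso %||% NA)
}
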