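#' Cost-family grid for the effort-discounting model comparison
#'
#' The candidate model family crosses three effort-cost shapes (linear,
#' quadratic, exponential) with the presence or absence of a trial-wise
#' time-modulation parameter on the cost term, giving six candidates. The
#' exponential shape uses `beta_effort * (exp(k_e * effort) - 1)` with a
#' fitted positive shape parameter `k_e`.
#'
#' @return A tibble with one row per candidate family: `family` (cost shape),
#'   `time_modulated` (logical), `n_par` (free parameters) and `label`.
#' @export
#' @examples
#' cost_families()
cost_families <- function() {
  tibble(
    family = rep(c("linear", "quadratic", "exponential"), each = 2L),
    time_modulated = rep(c(FALSE, TRUE), times = 3L)
  ) %>%
    mutate(
      n_par = 3L + as.integer(.data$time_modulated) +
        as.integer(.data$family == "exponential"),
      label = paste0(.data$family, ifelse(.data$time_modulated, "+time", ""))
    )
}

check_family <- function(family, time_modulated) {
  if (!family %in% c("linear", "quadratic", "exponential")) {
    abort(paste0("unknown cost family '", family, "'"))
  }
  stopifnot(is.logical(time_modulated), length(time_modulated) == 1L)
  invisible(TRUE)
}

param_names <- function(family, time_modulated) {
  nm <- c("beta_effort", "beta_reward", "beta_time", "beta_0")
  if (family == "exponential") nm <- c(nm, "k_e")
  nm
}

# Fitting bounds commensurate with the plausible behavioral range of the
# task (values stay O(10) across the 4x4 design); much wider boxes let
# flat-likelihood directions of near-separable sessions drift to arbitrarily
# large estimates without ever triggering the boundary flag. beta_time is
# fixed at 0 (both bounds) when the family is not time-modulated.
param_bounds <- function(family, time_modulated) {
  lower <- c(beta_effort = -40, beta_reward = 0, beta_time = -0.05, beta_0 = -5)
  upper <- c(beta_effort = 0, beta_reward = 2, beta_time = 0.05, beta_0 = 5)
  if (!time_modulated) {
    lower["beta_time"] <- 0
    upper["beta_time"] <- 0
  }
  if (family == "exponential") {
    lower <- c(lower, k_e = 1e-6)
    upper <- c(upper, k_e = 10)
  }
  list(lower = lower, upper = upper)
}

effort_cost_base <- function(effort, family, k_e = 1) {
  switch(family,
    linear = effort,
    quadratic = effort^2,
    exponential = exp(k_e * effort) - 1,
    abort(paste0("unknown cost family '", family, "'"))
  )
}

#' Subjective value of an effort/reward offer
#'
#' Computes `beta_effort * cost(effort) * (1 + beta_time * t) +
#' beta_reward * reward + beta_0`, where `cost()` is the family's effort
#' transform (effort, effort squared, or `exp(k_e * effort) - 1`). With
#' `time_modulated = FALSE` the time factor is identically 1.
#'
#' @param params Named list or vector with `beta_effort`, `beta_reward`,
#'   `beta_time`, `beta_0` and, for the exponential family, `k_e`.
#' @param effort Effort level as a fraction of maximal voluntary contraction,
#'   in (0, 1]. Vectorised.
#' @param reward Reward in euro cents, positive. Vectorised.
#' @param t 1-based trial index. Vectorised.
#' @param family One of `"linear"`, `"quadratic"`, `"exponential"`.
#' @param time_modulated Logical; whether the cost term carries the
#'   `(1 + beta_time * t)` factor.
#' @return Numeric vector of subjective values.
#' @export
#' @examples
#' p <- list(beta_effort = -1, beta_reward = 0.5, beta_time = 0, beta_0 = 0)
#' subjective_value(p, effort = 0.8, reward = 20, t = 1,
#'                  family = "quadratic", time_modulated = FALSE)
subjective_value <- function(params, effort, reward, t,
                             family = "quadratic", time_modulated = TRUE) {
  check_family(family, time_modulated)
  params <- as.list(params)
  vals <- c(effort, reward, t, params$beta_effort, params$beta_reward,
            params$beta_0)
  if (!all(is.finite(vals))) abort("non-finite inputs to subjective_value()")
  k_e <- if (family == "exponential") params$k_e else 1
  bt <- if (time_modulated) params$beta_time else 0
  cost <- effort_cost_base(effort, family, k_e = k_e)
  params$beta_effort * cost * (1 + bt * t) +
    params$beta_reward * reward + params$beta_0
}

#' Softmax (logistic) acceptance probability
#'
#' Maps a subjective value to an acceptance probability via the logistic
#' function `1 / (1 + exp(-value))`. Numerically stable for large `|value|`.
#'
#' @param value Numeric vector of subjective values.
#' @return Probabilities strictly in (0, 1).
#' @export
#' @examples
#' p_accept(0)       # 0.5
#' p_accept(log(3))  # 0.75
p_accept <- function(value) {
  if (!all(is.finite(value))) abort("non-finite value in p_accept()")
  stats::plogis(value)
}

check_trials <- function(trials) {
  need <- c("trial_index", "effort_frac", "reward_cents", "choice")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    abort(paste0("trials table missing columns: ", paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

# Probability clipping inside the log; prevents -log(0) without materially
# moving optima.
P_EPS <- 1e-12

#' Negative log-likelihood of a choice model on a trial table
#'
#' Sums `-log p(observed choice)` over decided trials; trials with a missing
#' choice (`NA`: no decision recorded) are skipped. Probabilities are clipped
#' to `[1e-12, 1 - 1e-12]` inside the log.
#'
#' @param params Named parameter list/vector (see [subjective_value()]).
#' @param trials Data frame with columns `trial_index`, `effort_frac`,
#'   `reward_cents`, `choice` (1 = accept, 0 = reject, `NA` = missed).
#' @inheritParams subjective_value
#' @return Non-negative scalar negative log-likelihood.
#' @export
choice_nll <- function(params, trials, family = "quadratic",
                       time_modulated = TRUE) {
  check_trials(trials)
  decided <- trials[!is.na(trials$choice), , drop = FALSE]
  if (nrow(decided) == 0L) abort("no decided trials: likelihood undefined")
  v <- subjective_value(params, decided$effort_frac, decided$reward_cents,
                        decided$trial_index, family, time_modulated)
  p <- pmin(pmax(p_accept(v), P_EPS), 1 - P_EPS)
  -sum(ifelse(decided$choice == 1, log(p), log(1 - p)))
}

# Analytic gradient of the negative log-likelihood in the full parameter
# order of param_names(); the standard logistic-regression form
# sum_i (p_i - y_i) * dv_i/dtheta.
choice_nll_grad <- function(params, trials, family, time_modulated) {
  decided <- trials[!is.na(trials$choice), , drop = FALSE]
  params <- as.list(params)
  k_e <- if (family == "exponential") params$k_e else 1
  bt <- if (time_modulated) params$beta_time else 0
  e <- decided$effort_frac; r <- decided$reward_cents; t <- decided$trial_index
  cost <- effort_cost_base(e, family, k_e = k_e)
  tf <- 1 + bt * t
  v <- params$beta_effort * cost * tf + params$beta_reward * r + params$beta_0
  resid <- p_accept(v) - decided$choice
  g <- c(
    beta_effort = sum(resid * cost * tf),
    beta_reward = sum(resid * r),
    beta_time = if (time_modulated) sum(resid * params$beta_effort * cost * t) else 0,
    beta_0 = sum(resid)
  )
  if (family == "exponential") {
    g <- c(g, k_e = sum(resid * params$beta_effort * e * exp(k_e * e) * tf))
  }
  g
}

#' Simulate choices from the generative model
#'
#' Generative twin of the likelihood: each choice is drawn
#' Bernoulli(`p_accept(value)`). Deterministic under `seed`.
#'
#' @param params Named parameter list/vector.
#' @param design Data frame with columns `trial_index`, `effort_frac`,
#'   `reward_cents` (one row per offer).
#' @inheritParams subjective_value
#' @param seed Integer seed.
#' @return The design as a tibble with added columns `p_accept` and `choice`.
#' @export
simulate_choices <- function(params, design, family = "quadratic",
                             time_modulated = TRUE, seed = 1L) {
  if (nrow(design) == 0L) abort("empty design")
  v <- subjective_value(params, design$effort_frac, design$reward_cents,
                        design$trial_index, family, time_modulated)
  p <- p_accept(v)
  ch <- withr::with_seed(seed, rbinom(length(p), 1L, p))
  as_tibble(design) %>% mutate(p_accept = p, choice = ch)
}

#' Standard 4x4 effort-by-reward trial design
#'
#' Builds the full factorial session design: every (effort, reward) condition
#' repeated `trials_per_condition` times, in a seeded random trial order.
#'
#' @param effort_levels Effort levels as fractions of MVC.
#' @param reward_levels Reward levels in euro cents.
#' @param trials_per_condition Repeats per cell (default 10; 160 trials total
#'   under the default 4x4 design).
#' @param seed Integer seed for the trial-order shuffle.
#' @return Tibble with `trial_index`, `effort_frac`, `reward_cents`.
#' @export
trial_design <- function(effort_levels = c(0.2, 0.4, 0.6, 0.8),
                         reward_levels = c(1, 5, 10, 20),
                         trials_per_condition = 10L, seed = 1L) {
  stopifnot(all(effort_levels > 0), all(effort_levels <= 1),
            all(reward_levels > 0), trials_per_condition >= 1L)
  grid <- tidyr::expand_grid(effort_frac = effort_levels,
                             reward_cents = reward_levels)
  full <- grid[rep(seq_len(nrow(grid)), times = trials_per_condition), ]
  ord <- withr::with_seed(seed, sample.int(nrow(full)))
  full[ord, ] %>% mutate(trial_index = row_number(), .before = 1L)
}
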