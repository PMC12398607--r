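test_that("subjective value matches hand evaluation of the model equation", {
  p <- list(beta_effort = -1, beta_reward = 0.5, beta_time = 0, beta_0 = 0)
  expect_equal(
    subjective_value(p, effort = 0.8, reward = 20, t = 1,
                     family = "quadratic", time_modulated = FALSE),
    (-1) * 0.64 + 10, tolerance = 1e-12)
  # zero parameters give zero value for any offer
  expect_equal(subjective_value(zero_params, 0.37, 13, 88), 0)
  # without time modulation, value is independent of trial index
  expect_equal(
    subjective_value(typical_params, 0.6, 5, 1, time_modulated = FALSE),
    subjective_value(typical_params, 0.6, 5, 160, time_modulated = FALSE))
  # linear family uses effort to the first power
  expect_equal(
    subjective_value(p, 0.8, 0, 1, family = "linear",
                     time_modulated = FALSE), -0.8)
  # exponential family uses exp(k_e * effort) - 1
  pe <- c(p, k_e = 2)
  expect_equal(
    subjective_value(pe, 0.5, 0, 1, family = "exponential",
                     time_modulated = FALSE), -(exp(1) - 1))
  expect_error(subjective_value(p, NaN, 5, 1), "non-finite")
})

test_that("softmax acceptance probability is the logistic map", {
  expect_equal(p_accept(0), 0.5)
  expect_equal(p_accept(log(3)), 0.75, tolerance = 1e-12)
  expect_gt(p_accept(30), 1 - 1e-12)
  expect_lt(p_accept(-30), 1e-12)
  v <- seq(-5, 5, by = 0.25)
  expect_true(all(diff(p_accept(v)) > 0))
})

test_that("negative log-likelihood matches independent hand computation", {
  tr <- make_session(seed = 2)
  n <- sum(!is.na(tr$choice))
  expect_equal(choice_nll(zero_params, tr), n * log(2), tolerance = 1e-10)

  # 4-trial mixed example, hand-computed -log p terms
  small <- tibble::tibble(
    trial_index = 1:4, effort_frac = c(0.2, 0.8, 0.4, 0.6),
    reward_cents = c(5, 20, 1, 10), choice = c(1, 0, 1, 0))
  p <- list(beta_effort = -3, beta_reward = 0.25, beta_time = 0.01,
            beta_0 = 0.5)
  v <- -3 * small$effort_frac^2 * (1 + 0.01 * small$trial_index) +
    0.25 * small$reward_cents + 0.5
  pr <- 1 / (1 + exp(-v))
  hand <- -sum(log(ifelse(small$choice == 1, pr, 1 - pr)))
  expect_equal(choice_nll(p, small), hand, tolerance = 1e-10)

  # missed trials are skipped
  with_na <- small
  with_na$choice[2] <- NA
  v3 <- v[-2]; pr3 <- pr[-2]; ch3 <- small$choice[-2]
  expect_equal(choice_nll(p, with_na),
               -sum(log(ifelse(ch3 == 1, pr3, 1 - pr3))),
               tolerance = 1e-10)
  all_na <- small
  all_na$choice <- NA
  expect_error(choice_nll(p, all_na), "no decided trials")
})

test_that("NLL approaches zero as the baseline dominates accepted data", {
  tr <- make_session(seed = 3)
  tr$choice <- 1L
  nlls <- vapply(c(1, 3, 4.9), function(b0) {
    choice_nll(list(beta_effort = 0, beta_reward = 0, beta_time = 0,
                    beta_0 = b0), tr)
  }, numeric(1))
  expect_true(all(diff(nlls) < 0))
  expect_lt(nlls[3], 2)
})

test_that("analytic gradient agrees with finite differences", {
  tr <- make_session(seed = 4)
  for (fam in c("linear", "quadratic", "exponential")) {
    p <- list(beta_effort = -2.5, beta_reward = 0.15, beta_time = 0.008,
              beta_0 = 0.3, k_e = 1.7)
    g <- effortconn:::choice_nll_grad(p, tr, fam, TRUE)
    nm <- effortconn:::param_names(fam, TRUE)
    num <- vapply(nm, function(k) {
      h <- 1e-5
      pp <- p; pp[[k]] <- p[[k]] + h
      pm <- p; pm[[k]] <- p[[k]] - h
      (choice_nll(pp, tr, fam, TRUE) - choice_nll(pm, tr, fam, TRUE)) / (2 * h)
    }, numeric(1))
    expect_equal(unname(g[nm]), unname(num), tolerance = 1e-5)
  }
})

test_that("NLL is permutation-invariant exactly when time-modulation is off", {
  tr <- make_session(seed = 5)
  shuf <- tr[withr::with_seed(9, sample.int(nrow(tr))), ]
  p <- list(beta_effort = -3, beta_reward = 0.2, beta_time = 0, beta_0 = 0.2)
  expect_identical(choice_nll(p, tr, time_modulated = FALSE),
                   choice_nll(p, shuf, time_modulated = FALSE))
  # but shuffling trial indices matters through the time term
  shuf2 <- tr
  shuf2$trial_index <- rev(shuf2$trial_index)
  p2 <- list(beta_effort = -3, beta_reward = 0.2, beta_time = 0.01,
             beta_0 = 0.2)
  expect_false(isTRUE(all.equal(choice_nll(p2, tr), choice_nll(p2, shuf2))))
})

test_that("multi-start fitting is deterministic and an NLL fixed point", {
  tr <- make_session(seed = 6)
  f1 <- fit_choice_model(tr, n_starts = 8, seed = 11)
  f2 <- fit_choice_model(tr, n_starts = 8, seed = 11)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$nll, f2$nll)
  # refitting from the solution leaves the NLL unchanged
  nll_at_fit <- choice_nll(as.list(f1$params), tr)
  expect_equal(nll_at_fit, f1$nll, tolerance = 1e-8)
  # MLE optimality: generating parameters cannot beat the fit
  expect_gte(choice_nll(typical_params, tr) - f1$nll, -1e-6)
})

test_that("all-accept sessions are fit but flagged as boundary solutions", {
  tr <- make_session(seed = 7)
  tr$choice <- 1L
  f <- fit_choice_model(tr, n_starts = 5, seed = 1)
  expect_true(f$boundary)
  expect_gt(f$params["beta_0"], 2)
  expect_error(fit_choice_model(tr[1:10, ], n_starts = 2, seed = 1),
               "decided trials")
})

test_that("acceptance probability is monotone in reward and effort", {
  for (fam in c("linear", "quadratic", "exponential")) {
    p <- list(beta_effort = -4, beta_reward = 0.3, beta_time = 0.005,
              beta_0 = 0.2, k_e = 2)
    rewards <- c(1, 5, 10, 20)
    pv <- p_accept(subjective_value(p, 0.5, rewards, 10, fam, TRUE))
    expect_true(all(diff(pv) > 0))
    efforts <- c(0.2, 0.4, 0.6, 0.8)
    pe <- p_accept(subjective_value(p, efforts, 10, 10, fam, TRUE))
    expect_true(all(diff(pe) < 0))
  }
})

test_that("BIC table satisfies the closed-form identity and picks argmin", {
  tr <- make_session(seed = 8)
  sel <- select_choice_model(tr, n_starts = 5, seed = 2)
  n <- sum(!is.na(tr$choice))
  expect_equal(sel$table$bic, 2 * sel$table$nll + sel$table$n_par * log(n),
               tolerance = 1e-12)
  expect_equal(sel$winner, sel$table$label[which.min(sel$table$bic)])
  expect_setequal(sel$table$label, cost_families()$label)
})

test_that("exact BIC ties break toward fewer parameters then family order", {
  # force a tie by inflating tie_tol so several families are candidates:
  # with a huge tolerance all six tie and the 3-parameter families win,
  # with 'linear' first in the fixed ordering
  tr <- make_session(seed = 12)
  sel <- select_choice_model(tr, n_starts = 5, seed = 2, tie_tol = 1e6)
  expect_true(sel$tie)
  expect_identical(sel$winner, "linear")
})

test_that("choice simulation is seeded, Bernoulli and respects extremes", {
  des <- trial_design(seed = 1)
  s1 <- simulate_choices(typical_params, des, seed = 42)
  s2 <- simulate_choices(typical_params, des, seed = 42)
  expect_identical(s1, s2)
  sure <- simulate_choices(list(beta_effort = 0, beta_reward = 0,
                                beta_time = 0, beta_0 = 50), des, seed = 1)
  expect_true(all(sure$choice == 1))
  big <- trial_design(trials_per_condition = 625L, seed = 2)  # 10^4 trials
  half <- simulate_choices(zero_params, big, seed = 3)
  expect_gt(mean(half$choice), 0.485)
  expect_lt(mean(half$choice), 0.515)
})

test_that("reported effort weight flips sign and is an involution", {
  p <- c(beta_effort = -2.5, beta_reward = 0.3)
  expect_equal(unname(flip_effort_sign(p)["beta_effort"]), 2.5)
  expect_equal(unname(flip_effort_sign(c(beta_effort = 0))["beta_effort"]), 0)
  expect_equal(flip_effort_sign(flip_effort_sign(p)), p)
})

test_that("tidy and glance summarise a fit consistently", {
  tr <- make_session(seed = 9)
  f <- fit_choice_model(tr, n_starts = 5, seed = 3)
  td <- tidy(f)
  expect_equal(nrow(td), length(f$params))
  expect_equal(td$reported[td$term == "beta_effort"],
               -td$estimate[td$term == "beta_effort"])
  gl <- glance(f)
  expect_equal(gl$bic, f$bic)
  expect_equal(gl$n_par, 4L)
})
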