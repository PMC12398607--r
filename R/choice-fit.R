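#' Fit a choice model by multi-start bounded maximum likelihood
#'
#' Minimises the negative log-likelihood with L-BFGS-B from `n_starts`
#' starting points drawn uniformly within the fitting bounds under `seed`,
#' and returns the best (lowest-NLL) solution. Degenerate sessions in which
#' every decided trial is an accept (or every one a reject) are fit but
#' flagged as boundary solutions.
#'
#' @inheritParams choice_nll
#' @param n_starts Number of random restarts (default 20).
#' @param seed Integer seed for the restart draws.
#' @param min_decided Minimum number of decided trials required (default 20).
#' @return An object of class `choice_fit`: a list with `params` (named
#'   vector, raw model scale), `family`, `time_modulated`, `nll`, `bic`,
#'   `n_trials_used`, `n_par`, `n_starts`, `converged`, `best_start`,
#'   `boundary` and `start_diagnostics` (per-start tibble).
#' @export
fit_choice_model <- function(trials, family = "quadratic",
                             time_modulated = TRUE, n_starts = 20L,
                             seed = 1L, min_decided = 20L) {
  check_family(family, time_modulated)
  check_trials(trials)
  decided <- trials[!is.na(trials$choice), , drop = FALSE]
  n_used <- nrow(decided)
  if (n_used < min_decided) {
    abort(paste0("only ", n_used, " decided trials; need >= ", min_decided))
  }
  all_accept <- all(decided$choice == 1)
  all_reject <- all(decided$choice == 0)

  bounds <- param_bounds(family, time_modulated)
  nm <- param_names(family, time_modulated)
  free <- bounds$lower != bounds$upper
  k <- sum(free)

  # optimize over free parameters only; pinned ones (beta_time = 0 when the
  # family is not time-modulated) are re-inserted at evaluation
  full_par <- function(theta) {
    p <- bounds$lower
    p[free] <- theta
    setNames(as.list(p), nm)
  }
  obj <- function(theta) choice_nll(full_par(theta), decided, family,
                                    time_modulated)
  grad <- function(theta) {
    choice_nll_grad(full_par(theta), decided, family, time_modulated)[free]
  }

  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      runif(k, bounds$lower[free], bounds$upper[free])
    })
  })

  fits <- lapply(seq_len(n_starts), function(i) {
    res <- tryCatch(
      optim(starts[[i]], obj, gr = grad, method = "L-BFGS-B",
            lower = bounds$lower[free], upper = bounds$upper[free],
            control = list(maxit = 500L, factr = 1e7)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      list(ok = FALSE, nll = Inf, par = starts[[i]], conv = FALSE,
           msg = "optim error")
    } else {
      list(ok = TRUE, nll = res$value, par = res$par,
           conv = res$convergence == 0L, msg = res$message %||% "")
    }
  })

  diag <- tibble(
    start = seq_len(n_starts),
    nll = vapply(fits, function(f) f$nll, numeric(1)),
    converged = vapply(fits, function(f) f$conv, logical(1)),
    ok = vapply(fits, function(f) f$ok, logical(1))
  )
  if (!any(diag$ok)) {
    abort("all optimizer starts failed", body = utils::capture.output(print(diag)))
  }
  best_i <- which.min(diag$nll)
  best <- fits[[best_i]]
  par <- bounds$lower
  par[free] <- as.numeric(best$par)
  par <- setNames(as.numeric(par), nm)

  # Boundary detection on free parameters only (beta_time is pinned at 0 when
  # the family is not time-modulated).
  tol <- 1e-6
  at_bound <- free & (abs(par - bounds$lower) < tol | abs(par - bounds$upper) < tol)

  structure(list(
    params = par,
    family = family,
    time_modulated = time_modulated,
    nll = best$nll,
    bic = 2 * best$nll + k * log(n_used),
    n_trials_used = n_used,
    n_par = k,
    n_starts = n_starts,
    converged = best$conv,
    best_start = best_i,
    boundary = all_accept || all_reject || any(at_bound),
    start_diagnostics = diag
  ), class = "choice_fit")
}

#' @export
print.choice_fit <- function(x, ...) {
  cat("<choice_fit> ", x$family, if (x$time_modulated) "+time" else "",
      "  k=", x$n_par, "\n", sep = "")
  print(round(x$params, 4))
  cat("NLL =", format(x$nll, digits = 8), " BIC =", format(x$bic, digits = 8),
      " trials =", x$n_trials_used,
      if (x$boundary) " [boundary]" else "", "\n")
  invisible(x)
}

#' Tidy a fitted choice model
#'
#' @param x A `choice_fit` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate` (raw scale) and
#'   `reported` (sign convention applied: `beta_effort` flipped so larger
#'   values mean stronger effort aversion).
#' @export
tidy.choice_fit <- function(x, ...) {
  rep <- flip_effort_sign(x$params)
  tibble(term = names(x$params),
         estimate = as.numeric(x$params),
         reported = as.numeric(rep[names(x$params)]))
}

#' Glance at a fitted choice model
#'
#' @param x A `choice_fit` object.
#' @param ... Unused.
#' @return One-row tibble with family, fit statistics and flags.
#' @export
glance.choice_fit <- function(x, ...) {
  tibble(family = x$family, time_modulated = x$time_modulated,
         n_par = x$n_par, nll = x$nll, bic = x$bic,
         n_trials_used = x$n_trials_used, converged = x$converged,
         boundary = x$boundary)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Reporting sign convention for the effort weight
#'
#' The raw effort weight is non-positive for effort-averse subjects; for
#' reporting and statistics it is multiplied by -1 so that larger reported
#' values mean stronger effort aversion. Applying the function twice restores
#' the raw vector.
#'
#' @param params Named parameter vector/list containing `beta_effort`.
#' @return The same vector with `beta_effort` negated.
#' @export
#' @examples
#' flip_effort_sign(c(beta_effort = -2.5, beta_reward = 0.3))
flip_effort_sign <- function(params) {
  p <- unlist(params)
  if (!"beta_effort" %in% names(p)) abort("no beta_effort in params")
  p["beta_effort"] <- -p["beta_effort"]
  p
}

#' Fit all candidate families and select the winner by BIC
#'
#' Fits each of the six candidate families (see [cost_families()]) to one
#' subject's trials and selects the family with the lowest BIC. Ties (within
#' `tie_tol`) are broken toward fewer free parameters, then by the fixed
#' family ordering of [cost_families()].
#'
#' @inheritParams fit_choice_model
#' @param tie_tol Absolute BIC difference treated as a tie (default 1e-9).
#' @return A list of class `choice_model_selection` with `winner` (label),
#'   `table` (per-family tibble of fit statistics, ordered as fitted),
#'   `fits` (named list of `choice_fit` objects) and `tie` (logical).
#' @export
select_choice_model <- function(trials, n_starts = 20L, seed = 1L,
                                min_decided = 20L, tie_tol = 1e-9) {
  fams <- cost_families()
  fits <- purrr::pmap(list(fams$family, fams$time_modulated, fams$label),
    function(f, tm, lab) {
      tryCatch(
        fit_choice_model(trials, family = f, time_modulated = tm,
                         n_starts = n_starts, seed = seed,
                         min_decided = min_decided),
        error = function(e) {
          abort(paste0("fit failed for family '", lab, "': ",
                       conditionMessage(e)))
        })
    })
  names(fits) <- fams$label
  tab <- purrr::map_dfr(fits, glance) %>%
    mutate(label = fams$label, .before = 1L)

  best_bic <- min(tab$bic)
  cand <- which(tab$bic <= best_bic + tie_tol)
  tie <- length(cand) > 1L
  # tie-break: fewer free parameters, then fixed family order
  cand <- cand[order(tab$n_par[cand], cand)]
  winner <- tab$label[cand[1L]]

  structure(list(winner = winner, table = tab, fits = fits, tie = tie),
            class = "choice_model_selection")
}

#' @export
print.choice_model_selection <- function(x, ...) {
  cat("<choice_model_selection> winner:", x$winner,
      if (x$tie) "(tie, broken by parsimony/order)" else "", "\n")
  print(x$table %>% select("label", "n_par", "nll", "bic", "boundary"))
  invisible(x)
}

#' Fit the choice model to every subject in a trials table
#'
#' @param trials Data frame with `subject_id` plus the per-trial columns of
#'   [choice_nll()].
#' @inheritParams fit_choice_model
#' @return Tibble with one row per subject: reported and raw parameter
#'   estimates, `nll`, `bic`, `converged`, `boundary`.
#' @export
fit_cohort_choices <- function(trials, family = "quadratic",
                               time_modulated = TRUE, n_starts = 20L,
                               seed = 1L, min_decided = 20L) {
  stopifnot("subject_id" %in% names(trials))
  trials %>%
    group_by(.data$subject_id) %>%
    dplyr::group_modify(function(df, key) {
      fit <- fit_choice_model(df, family = family,
                              time_modulated = time_modulated,
                              n_starts = n_starts, seed = seed,
                              min_decided = min_decided)
      rep <- flip_effort_sign(fit$params)
      tibble(
        family = family, time_modulated = time_modulated,
        beta_effort_reported = unname(rep["beta_effort"]),
        beta_effort_raw = unname(fit$params["beta_effort"]),
        beta_reward = unname(fit$params["beta_reward"]),
        beta_time = unname(fit$params["beta_time"]),
        beta_0 = unname(fit$params["beta_0"]),
        k_e = if ("k_e" %in% names(fit$params)) unname(fit$params["k_e"]) else NA_real_,
        nll = fit$nll, bic = fit$bic, n_trials_used = fit$n_trials_used,
        converged = fit$converged, boundary = fit$boundary
      )
    }) %>%
    ungroup()
}
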