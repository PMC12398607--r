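#' Observed vs model-predicted acceptance by design cell
#'
#' Plots the empirical acceptance rate in each (effort, reward) cell of a
#' subject's session against the fitted model's mean predicted probability,
#' with acceptance curves over effort faceted... one line per reward level.
#'
#' @param fit A `choice_fit`.
#' @param trials The subject's trial table.
#' @return A ggplot object.
#' @export
plot_choice_fit <- function(fit, trials) {
  stopifnot(inherits(fit, "choice_fit"))
  decided <- trials[!is.na(trials$choice), , drop = FALSE]
  decided$pred <- p_accept(subjective_value(
    as.list(fit$params), decided$effort_frac, decided$reward_cents,
    decided$trial_index, fit$family, fit$time_modulated))
  cell <- decided %>%
    group_by(.data$effort_frac, .data$reward_cents) %>%
    summarise(observed = mean(.data$choice), predicted = mean(.data$pred),
              .groups = "drop")
  ggplot2::ggplot(cell, ggplot2::aes(x = .data$effort_frac)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted,
                                    colour = factor(.data$reward_cents))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = factor(.data$reward_cents))) +
    ggplot2::labs(x = "effort (fraction of MVC)", y = "P(accept)",
                  colour = "reward (cents)",
                  title = paste0("choice fit: ", fit$family,
                                 if (fit$time_modulated) "+time" else "")) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Cross-validation error trace over the penalty grid
#'
#' @param cv Result of [cv_lambda()].
#' @return A ggplot object with the mean CV-MSE against log lambda and the
#'   selected penalty marked.
#' @export
plot_cv_trace <- function(cv) {
  ggplot2::ggplot(cv$cv_trace,
                  ggplot2::aes(x = log(.data$lambda), y = .data$mean_mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(cv$lambda), linetype = "dashed") +
    ggplot2::labs(x = "log(lambda)", y = "mean CV MSE") +
    ggplot2::theme_minimal()
}

#' True vs recovered choice parameters across a simulated cohort
#'
#' @param true_params Tibble with `subject_id` and true parameter columns
#'   (as in a synthetic cohort's `true_params`).
#' @param fits Tibble from [fit_cohort_choices()].
#' @param params Which reported parameters to plot.
#' @return A ggplot object, one facet per parameter.
#' @export
plot_recovery <- function(true_params, fits,
                          params = c("beta_effort_reported", "beta_reward")) {
  joined <- true_params %>%
    select("subject_id", all_of(params)) %>%
    tidyr::pivot_longer(-"subject_id", names_to = "param",
                        values_to = "true") %>%
    left_join(
      fits %>% select("subject_id", all_of(params)) %>%
        tidyr::pivot_longer(-"subject_id", names_to = "param",
                            values_to = "recovered"),
      by = c("subject_id", "param"))
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(x = "generating value", y = "recovered value") +
    ggplot2::theme_minimal()
}

#' Coefficient-and-confirmation plot for an association report
#'
#' @param object An `association_report`.
#' @param ... Unused.
#' @return A ggplot object: LASSO coefficients (standardized scale) per
#'   feature, confirmed features highlighted.
#' @method autoplot association_report
#' @export
autoplot.association_report <- function(object, ...) {
  df <- tibble(
    feature = names(object$lasso$coefficients_std),
    coefficient = as.numeric(object$lasso$coefficients_std)
  ) %>%
    mutate(status = dplyr::case_when(
      .data$feature %in% object$confirmed ~ "confirmed",
      .data$feature %in% object$selected ~ "selected",
      TRUE ~ "not selected"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coefficient,
                                   y = stats::reorder(.data$feature,
                                                      .data$coefficient),
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "LASSO coefficient (standardized)", y = NULL,
                  title = paste0("outcome: ", object$outcome)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
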