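#' Peak-to-peak amplitude of an EMG trace within the response window
#'
#' @param waveform Data frame with columns `time_ms` (relative to the TMS
#'   pulse) and `amplitude_mv`.
#' @param window Two-element numeric vector, ms post-pulse, closed interval.
#'   Default 15-60 ms, the motor-evoked-potential response window.
#' @return Max minus min of the trace within the window (mV), non-negative.
#' @export
peak_to_peak <- function(waveform, window = c(15, 60)) {
  stopifnot(all(c("time_ms", "amplitude_mv") %in% names(waveform)),
            length(window) == 2L, window[1] < window[2])
  inw <- waveform$time_ms >= window[1] & waveform$time_ms <= window[2]
  if (!any(inw)) abort("no samples in the response window")
  x <- waveform$amplitude_mv[inw]
  max(x) - min(x)
}

#' Pre-stimulus root-mean-square of an EMG trace
#'
#' RMS over the half-open pre-stimulus window `[-250, -50)` ms relative to
#' the pulse; used to detect background muscle activity that invalidates a
#' stimulation trial.
#'
#' @inheritParams peak_to_peak
#' @param window Two-element numeric vector, ms relative to the pulse;
#'   half-open `[window[1], window[2])`. Default `c(-250, -50)`.
#' @return RMS amplitude in the units of `amplitude_mv`.
#' @export
pre_stimulus_rms <- function(waveform, window = c(-250, -50)) {
  stopifnot(all(c("time_ms", "amplitude_mv") %in% names(waveform)),
            length(window) == 2L, window[1] < window[2])
  if (min(waveform$time_ms) > window[1]) {
    abort("trace does not cover the pre-stimulus window")
  }
  inw <- waveform$time_ms >= window[1] & waveform$time_ms < window[2]
  if (!any(inw)) abort("no samples in the pre-stimulus window")
  sqrt(mean(waveform$amplitude_mv[inw]^2))
}

#' Clean stimulation trials with the RMS-artifact and 3-SD outlier rules
#'
#' Within each `(circuit, pulse_type)` condition, two rules are applied in
#' order. Rule 1 removes trials whose pre-stimulus RMS exceeds `rms_limit`
#' (background EMG activity). Rule 2 then removes, in a single non-iterative
#' pass, trials whose amplitude deviates from the mean of the Rule-1
#' survivors of the same condition by strictly more than `sd_limit` standard
#' deviations (mean and SD computed on the survivors, candidate included). A
#' trial violating both rules is logged once, under Rule 1. If the survivor
#' SD is zero no Rule-2 exclusion can occur.
#'
#' @param trials Data frame with columns `circuit`, `pulse_type`,
#'   `pre_rms_uv`, `amplitude_mv` (plus any identifier columns, carried
#'   through).
#' @param rms_limit Pre-stimulus RMS threshold in microvolts (default 200).
#' @param sd_limit Amplitude outlier bound in SD units (default 3);
#'   exclusion is strict (`> sd_limit`).
#' @param floor Minimum retained trials per condition before a low-count
#'   flag is raised (default 17).
#' @return List with `retained` (tibble of surviving trials), `exclusions`
#'   (tibble with the rule that fired per excluded trial) and `flags`
#'   (per-condition tibble with retained counts and `low_count` flag).
#' @export
clean_mep_trials <- function(trials, rms_limit = 200, sd_limit = 3,
                             floor = 17L) {
  need <- c("circuit", "pulse_type", "pre_rms_uv", "amplitude_mv")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    abort(paste0("mep trials missing columns: ", paste(miss, collapse = ", ")))
  }
  trials <- as_tibble(trials) %>% mutate(.row = row_number())

  rule1 <- trials$pre_rms_uv > rms_limit
  surv1 <- trials[!rule1, , drop = FALSE]

  stats1 <- surv1 %>%
    group_by(.data$circuit, .data$pulse_type) %>%
    summarise(.m = mean(.data$amplitude_mv), .s = sd(.data$amplitude_mv),
              .groups = "drop")
  surv1 <- surv1 %>% left_join(stats1, by = c("circuit", "pulse_type"))
  # sd() is NA for a single survivor; treat as zero spread (no exclusion)
  s <- ifelse(is.na(surv1$.s), 0, surv1$.s)
  rule2 <- s > 0 & abs(surv1$amplitude_mv - surv1$.m) > sd_limit * s

  retained <- surv1[!rule2, , drop = FALSE] %>% select(-".m", -".s")

  exclusions <- bind_rows(
    trials[rule1, , drop = FALSE] %>% mutate(rule = "rms_artifact"),
    surv1[rule2, , drop = FALSE] %>% select(-".m", -".s") %>%
      mutate(rule = "amplitude_outlier")
  ) %>% arrange(.data$.row)

  flags <- retained %>%
    group_by(.data$circuit, .data$pulse_type) %>%
    summarise(n_retained = n(), .groups = "drop") %>%
    mutate(low_count = .data$n_retained < floor)

  list(
    retained = retained %>% select(-".row"),
    exclusions = exclusions %>% select(-".row"),
    flags = flags
  )
}

#' Conditioned/test MEP amplitude ratio for one circuit
#'
#' `mean(CS+TS amplitudes) / mean(TS-only amplitudes)` over retained trials:
#' condition means are computed first, then divided. Ratios above 1 indicate
#' a facilitatory influence of the conditioning stimulus, below 1 a
#' suppressive one.
#'
#' @param retained Data frame of retained trials for a single circuit, with
#'   `pulse_type` in `{"TS", "CSTS"}` and `amplitude_mv`.
#' @param floor Minimum retained trials per pulse type before the ratio is
#'   flagged (still computed) (default 17).
#' @return One-row tibble: `ratio`, `n_ts`, `n_csts`, `low_count`.
#' @export
mep_ratio <- function(retained, floor = 17L) {
  stopifnot(all(c("pulse_type", "amplitude_mv") %in% names(retained)))
  ts <- retained$amplitude_mv[retained$pulse_type == "TS"]
  cs <- retained$amplitude_mv[retained$pulse_type == "CSTS"]
  if (length(ts) == 0L || length(cs) == 0L) {
    abort("both pulse types must have retained trials")
  }
  m_ts <- mean(ts)
  if (m_ts == 0) abort("TS-only mean amplitude is zero: ratio undefined")
  tibble(ratio = mean(cs) / m_ts, n_ts = length(ts), n_csts = length(cs),
         low_count = length(ts) < floor || length(cs) < floor)
}

#' Per-subject MEP ratios for all probed circuits
#'
#' Runs [clean_mep_trials()] then [mep_ratio()] per `(subject_id, circuit)`.
#'
#' @param trials Data frame with `subject_id`, `circuit`, `pulse_type`,
#'   `pre_rms_uv`, `amplitude_mv`.
#' @inheritParams clean_mep_trials
#' @return List with `ratios` (tibble: subject_id, circuit, ratio, n_ts,
#'   n_csts, low_count) and `exclusions` (rule-attributed exclusion log).
#' @export
compute_mep_ratios <- function(trials, rms_limit = 200, sd_limit = 3,
                               floor = 17L) {
  stopifnot("subject_id" %in% names(trials))
  per_subj <- trials %>%
    group_by(.data$subject_id) %>%
    dplyr::group_map(function(df, key) {
      cl <- clean_mep_trials(df, rms_limit = rms_limit, sd_limit = sd_limit,
                             floor = floor)
      ratios <- cl$retained %>%
        group_by(.data$circuit) %>%
        dplyr::group_modify(function(d, k) mep_ratio(d, floor = floor)) %>%
        ungroup() %>%
        mutate(subject_id = key$subject_id, .before = 1L)
      excl <- cl$exclusions %>% mutate(subject_id = key$subject_id)
      list(ratios = ratios, exclusions = excl)
    })
  list(
    ratios = purrr::map_dfr(per_subj, "ratios"),
    exclusions = purrr::map_dfr(per_subj, "exclusions")
  )
}

#' Reshape per-subject MEP ratios to one column per circuit
#'
#' @param ratios The `ratios` tibble from [compute_mep_ratios()].
#' @return Wide tibble, one row per subject, one column per circuit.
#' @export
mep_ratio_features <- function(ratios) {
  ratios %>%
    select("subject_id", "circuit", "ratio") %>%
    tidyr::pivot_wider(names_from = "circuit", values_from = "ratio")
}
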