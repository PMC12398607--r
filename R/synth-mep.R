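#' Generate a synthetic MEP trial table with planted artifacts and outliers
#'
#' Builds `n_per_condition` trials for each pulse type (`TS`, `CSTS`) of one
#' circuit. Clean amplitudes follow a log-normal model (winsorised at 2
#' sample-SD around the sample mean so the planted counts below are exact by
#' construction); clean pre-stimulus RMS is drawn well under the artifact
#' threshold. Exactly `planted_artifacts` trials per pulse type are given a
#' pre-stimulus RMS above 200 uV, and exactly `planted_outliers` trials per
#' pulse type an amplitude 6 clean-SD above the clean-trial mean (>= 5 SD,
#' so the 3-SD cleaning rule is guaranteed to catch them).
#'
#' @param n_per_condition Trials per (circuit, pulse type) condition.
#' @param planted_artifacts Number of pre-stimulus-RMS artifact trials.
#' @param planted_outliers Number of extreme-amplitude outlier trials.
#' @param seed Integer seed.
#' @param circuit Circuit code (default `"GLUT"`).
#' @param ratio Target conditioned/test ratio: CSTS clean amplitudes are
#'   drawn at `ratio` times the TS scale (default 1).
#' @param ts_mean_mv Median TS amplitude, mV (default 1).
#' @param sdlog Log-normal shape parameter of clean amplitudes (default
#'   0.35; 0 gives identical amplitudes).
#' @return Tibble with `circuit`, `pulse_type`, `trial`, `pre_rms_uv`,
#'   `amplitude_mv`, `planted` (`"clean"`, `"rms_artifact"`, or
#'   `"amplitude_outlier"`).
#' @export
generate_mep_trials <- function(n_per_condition, planted_artifacts = 0L,
                                planted_outliers = 0L, seed = 1L,
                                circuit = "GLUT", ratio = 1,
                                ts_mean_mv = 1, sdlog = 0.35) {
  stopifnot(n_per_condition >= planted_artifacts + planted_outliers + 2L,
            planted_artifacts >= 0L, planted_outliers >= 0L, ratio > 0,
            ts_mean_mv > 0, sdlog >= 0)
  withr::with_seed(seed, {
    purrr::map_dfr(c("TS", "CSTS"), function(pt) {
      scale_mv <- if (pt == "TS") ts_mean_mv else ts_mean_mv * ratio
      n_clean <- n_per_condition - planted_outliers
      amp <- scale_mv * exp(rnorm(n_clean, 0, sdlog))
      if (sdlog > 0 && n_clean >= 2L) {
        # winsorise so no clean draw can itself trip the 3-SD rule
        m <- mean(amp); s <- sd(amp)
        amp <- pmin(pmax(amp, m - 2 * s), m + 2 * s)
      }
      clean_m <- mean(amp)
      clean_s <- if (n_clean >= 2L) sd(amp) else 0
      out_amp <- rep(clean_m + 6 * max(clean_s, 0.05 * scale_mv),
                     planted_outliers)
      amplitude <- c(amp, out_amp)
      pre_rms <- runif(n_per_condition, 5, 50)
      planted <- rep(c("clean", "amplitude_outlier"),
                     c(n_clean, planted_outliers))
      if (planted_artifacts > 0L) {
        # artifacts overwrite clean slots (a trial violating both rules
        # would be logged once, under the RMS rule; keep the counts disjoint)
        idx <- seq_len(planted_artifacts)
        pre_rms[idx] <- runif(planted_artifacts, 230, 320)
        planted[idx] <- "rms_artifact"
      }
      tibble(circuit = circuit, pulse_type = pt,
             trial = seq_len(n_per_condition),
             pre_rms_uv = pre_rms, amplitude_mv = amplitude,
             planted = planted)
    })
  })
}

#' Generate a synthetic EMG waveform for a single stimulation trial
#'
#' A minimal trace for exercising the waveform operations: baseline noise
#' before the pulse and a damped-sine motor response inside the response
#' window. Labelled synthetic; no claim of electrophysiological realism.
#'
#' @param amplitude_mv Target peak-to-peak response amplitude.
#' @param baseline_rms_uv Pre-stimulus noise RMS in uV.
#' @param sample_rate_hz Sampling rate (default 5000 Hz).
#' @param t_start_ms,t_end_ms Trace extent around the pulse at time 0.
#' @param seed Integer seed.
#' @return Tibble with `time_ms`, `amplitude_mv`.
#' @export
generate_mep_waveform <- function(amplitude_mv = 1, baseline_rms_uv = 20,
                                  sample_rate_hz = 5000,
                                  t_start_ms = -300, t_end_ms = 100,
                                  seed = 1L) {
  dt <- 1000 / sample_rate_hz
  t <- seq(t_start_ms, t_end_ms, by = dt)
  noise <- withr::with_seed(seed, rnorm(length(t), 0, baseline_rms_uv / 1000))
  resp <- numeric(length(t))
  inw <- t >= 20 & t <= 45
  ph <- 2 * pi * (t[inw] - 20) / 25
  resp[inw] <- (amplitude_mv / 2) * sin(ph) * exp(-(t[inw] - 20) / 40)
  tibble(time_ms = t, amplitude_mv = noise + resp)
}
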