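# Shared fixtures, all generated in code.

zero_params <- list(beta_effort = 0, beta_reward = 0, beta_time = 0,
                    beta_0 = 0)

typical_params <- list(beta_effort = -4, beta_reward = 0.2,
                       beta_time = 0.005, beta_0 = 0.4)

# One simulated 160-trial session from the quadratic+time model.
make_session <- function(seed = 1L, params = typical_params) {
  des <- trial_design(seed = seed)
  simulate_choices(params, des, family = "quadratic",
                   time_modulated = TRUE, seed = seed + 1L)
}

# Labelled symmetric zero-diagonal count matrix over the canonical regions.
make_mean_matrix <- function(seed = 1L, scale = 500) {
  regions <- tract_regions()
  p <- length(regions)
  m <- withr::with_seed(seed, matrix(runif(p * p, 50, scale), p, p))
  m <- round((m + t(m)) / 2)
  diag(m) <- 0
  dimnames(m) <- list(regions, regions)
  m
}

# Small analysis table: features + outcome + confounds with known structure.
make_design <- function(n = 45, seed = 1L, r_planted = 0,
                        planted = character()) {
  pa <- if (length(planted) > 0) {
    tibble::tibble(feature = planted, outcome = "apathy", r = r_planted)
  } else NULL
  cfg <- cohort_config(n_subjects = n, seed = seed,
                       planted_associations = pa)
  co <- generate_cohort(cfg, include_trials = FALSE,
                        include_mep_trials = FALSE)
  dplyr::left_join(co$features, co$phenotype, by = "subject_id")
}

confound_cols <- c("age", "gender", "depression", "anhedonia")

# Gaussian linear-model instance with named feature columns.
make_lm_data_acc <- function(n = 50, p = 3, beta = NULL, seed = 1,
                             noise = 1) {
  if (is.null(beta)) beta <- rep_len(c(1, -2, 0.5), p)
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- paste0("x", seq_len(p))
    y <- as.numeric(x %*% beta + noise * rnorm(n))
    data.frame(y = y, x)
  })
}
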