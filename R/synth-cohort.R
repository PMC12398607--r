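#' Apathy score from rating-scale item responses
#'
#' Scores an extended Lille Apathy Rating Scale (LARS-e) style response set:
#' each of the items is graded 1-5 (higher grade = higher motivation); the
#' apathy score is the mean over items of `(5 - grade)`, so it ranges over
#' `[0, 4]` with higher values indicating more apathy.
#'
#' @param grades Integer vector of item grades, each in 1..5, non-empty.
#' @return Scalar apathy score in `[0, 4]`.
#' @export
#' @examples
#' score_lars(c(5, 3, 4, 2))  # mean(0, 2, 1, 3) = 1.5
score_lars <- function(grades) {
  if (length(grades) == 0L) abort("empty item response list")
  if (any(!is.finite(grades)) || any(grades != round(grades)) ||
      any(grades < 1) || any(grades > 5)) {
    abort("all item grades must be integers in 1..5")
  }
  mean(5 - grades)
}

#' The seven probed effective-connectivity circuits
#'
#' Dual-coil circuits (SMA and OFC conditioning at 7 or 15 ms inter-stimulus
#' interval) and single-coil intracortical circuits (GABAa, GABAb,
#' glutamatergic).
#'
#' @return Character vector of circuit codes.
#' @export
mep_circuits <- function() {
  c("SMA7", "SMA15", "OFC7", "OFC15", "GABAA", "GABAB", "GLUT")
}

# circuit-typical conditioned/test ratio centres used by the generator:
# mild facilitation for dual-coil fronto-M1 circuits, strong suppression for
# the inhibitory single-coil circuits, facilitation for the glutamatergic one
circuit_ratio_centres <- function() {
  c(SMA7 = 1.20, SMA15 = 1.10, OFC7 = 0.90, OFC15 = 1.10,
    GABAA = 0.40, GABAB = 0.20, GLUT = 1.25)
}

#' Configuration for a synthetic cohort
#'
#' Bundles every constant of the emulated study design: cohort size, the
#' 4x4 effort-by-reward task grid, numbers of connectivity and circuit
#' features, the population distributions of the choice-model parameters,
#' the confound model, and any planted feature-outcome associations.
#'
#' @param n_subjects Cohort size (default 45).
#' @param effort_levels Effort levels, fractions of MVC in (0, 1].
#' @param reward_levels Reward levels, euro cents, positive.
#' @param trials_per_condition Trials per design cell (default 10).
#' @param planted_associations Tibble (or data frame) with columns `feature`
#'   (a tract-pair or circuit name), `outcome` (one of `"apathy"`,
#'   `"beta_effort"`, `"beta_reward"`) and `r` (target confound-adjusted
#'   partial correlation, strictly inside (-1, 1)). Default: none.
#' @param param_means,param_sds Named numeric vectors (names `beta_effort`,
#'   `beta_reward`, `beta_time`, `beta_0`) giving the population location
#'   and spread of each choice parameter. The effort and reward weights are
#'   log-normal in magnitude — the canonical population model for
#'   discounting parameters, which vary over an order of magnitude across
#'   subjects while keeping one sign — so for those two, `param_means` is
#'   the population *median* (signed) and `param_sds` the log-scale SD;
#'   `beta_time` and `beta_0` are truncated normals with the usual mean/SD
#'   meaning. Defaults describe an effort-averse, reward-sensitive
#'   population with a weak time-on-task cost drift.
#' @param param_lower,param_upper Truncation bounds for the per-subject
#'   parameter draws (inverse-CDF truncation). Defaults span the full
#'   behavioral range from near-indifferent to extremely effort-averse
#'   subjects.
#' @param confound_means,confound_sds Named vectors for `age`, `depression`,
#'   `anhedonia` (gender is a balanced binary code, no mean/SD).
#' @param confound_cor Correlation between the depression and anhedonia
#'   latents (default 0.3); other confounds independent.
#' @param seed Master integer seed (mandatory).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 45L,
                          effort_levels = c(0.2, 0.4, 0.6, 0.8),
                          reward_levels = c(1, 5, 10, 20),
                          trials_per_condition = 10L,
                          planted_associations = NULL,
                          param_means = c(beta_effort = -4, beta_reward = 0.2,
                                          beta_time = 0.005, beta_0 = 0.4),
                          param_sds = c(beta_effort = 0.9, beta_reward = 0.7,
                                        beta_time = 0.003, beta_0 = 0.5),
                          param_lower = c(beta_effort = -35,
                                          beta_reward = 0.03,
                                          beta_time = -0.004, beta_0 = -1),
                          param_upper = c(beta_effort = -0.4,
                                          beta_reward = 1.2,
                                          beta_time = 0.014, beta_0 = 1.5),
                          confound_means = c(age = 24, depression = 3,
                                             anhedonia = 1.5),
                          confound_sds = c(age = 3, depression = 2.5,
                                           anhedonia = 1.2),
                          confound_cor = 0.3,
                          seed = 1L) {
  stopifnot(n_subjects >= 1L,
            all(effort_levels > 0), all(effort_levels <= 1),
            all(reward_levels > 0), trials_per_condition >= 1L,
            abs(confound_cor) < 1)
  if (is.null(planted_associations)) {
    planted_associations <- tibble(feature = character(),
                                   outcome = character(), r = numeric())
  }
  planted_associations <- as_tibble(planted_associations)
  stopifnot(all(c("feature", "outcome", "r") %in% names(planted_associations)))
  if (any(abs(planted_associations$r) >= 1)) {
    abort("planted partial correlations must lie strictly inside (-1, 1): a target of magnitude >= 1 would require negative noise variance")
  }
  bad <- setdiff(planted_associations$outcome,
                 c("apathy", "beta_effort", "beta_reward"))
  if (length(bad) > 0) {
    abort(paste0("unknown planted outcome(s): ", paste(bad, collapse = ", ")))
  }
  known <- c(tract_pairs()$feature, mep_circuits())
  badf <- setdiff(planted_associations$feature, known)
  if (length(badf) > 0) {
    abort(paste0("unknown planted feature(s): ", paste(badf, collapse = ", ")))
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    effort_levels = effort_levels, reward_levels = reward_levels,
    trials_per_condition = as.integer(trials_per_condition),
    planted_associations = planted_associations,
    param_means = param_means, param_sds = param_sds,
    param_lower = param_lower, param_upper = param_upper,
    confound_means = confound_means, confound_sds = confound_sds,
    confound_cor = confound_cor,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Strong-effect cohort configuration for model-recovery studies
#'
#' A [cohort_config()] variant in which every subject carries a clearly
#' expressed quadratic effort cost and a strong time-on-task drift
#' (`beta_time` around 0.02, i.e. the cost roughly quadruples by the end of
#' the 160-trial session). Model-recovery questions — does BIC identify the
#' generating cost family? — are posed under strong effects, where the
#' families make discriminably different predictions; under weak effects
#' BIC correctly prefers the smaller families.
#'
#' @inheritParams cohort_config
#' @param ... Passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
strong_effects_config <- function(n_subjects = 100L, seed = 1L, ...) {
  cohort_config(
    n_subjects = n_subjects, seed = seed,
    param_means = c(beta_effort = -6.5, beta_reward = 0.3,
                    beta_time = 0.02, beta_0 = 0.5),
    param_sds = c(beta_effort = 0.35, beta_reward = 0.4,
                  beta_time = 0.002, beta_0 = 0.4),
    param_lower = c(beta_effort = -12, beta_reward = 0.1,
                    beta_time = 0.016, beta_0 = -0.6),
    param_upper = c(beta_effort = -3.5, beta_reward = 0.8,
                    beta_time = 0.024, beta_0 = 1.4),
    ...
  )
}

# Draw confounds: age and gender independent, depression/anhedonia latents
# correlated; gender is a balanced 0/1 code from a latent normal.
draw_confounds <- function(cfg, n, seed) {
  withr::with_seed(seed, {
    z_age <- rnorm(n); z_gen <- rnorm(n)
    z_dep <- rnorm(n)
    z_anh <- cfg$confound_cor * z_dep +
      sqrt(1 - cfg$confound_cor^2) * rnorm(n)
    tibble(
      age = cfg$confound_means["age"] + cfg$confound_sds["age"] * z_age,
      gender = as.integer(z_gen > 0),
      depression = pmax(0, cfg$confound_means["depression"] +
                          cfg$confound_sds["depression"] * z_dep),
      anhedonia = pmax(0, cfg$confound_means["anhedonia"] +
                         cfg$confound_sds["anhedonia"] * z_anh),
      .z_dep = z_dep, .z_anh = z_anh
    )
  })
}

# Linear-Gaussian planted feature on the standardized scale: the outcome's
# confound-orthogonal residual (scaled to unit variance) enters with weight r,
# independent noise with weight sqrt(1 - r^2), so the population
# confound-adjusted partial correlation equals r exactly; a confound loading
# is added on top (removed again by the adjustment).
planted_feature_z <- function(r, outcome, confounds_std, noise,
                              confound_loading = 0.2) {
  res <- residuals(lm(outcome ~ ., data = as.data.frame(confounds_std)))
  u <- res / sd(res)
  x <- r * u + sqrt(1 - r^2) * noise
  x + as.matrix(confounds_std) %*% rep(confound_loading, ncol(confounds_std))
}

# baseline streamline-count scale per tract pair (plausible magnitudes:
# heavier cortico-striatal and thalamo-cortical bundles, sparser OFC-M1)
tract_count_centres <- function() {
  p <- tract_pairs()$feature
  setNames(c(620, 340, 280, 520, 260, 150,
             90, 310, 330, 240, 300, 280,
             410, 360, 480, 330, 220, 560, 700), p)
}

#' Generate a seeded synthetic cohort
#'
#' Produces a full synthetic dataset with the structure the analysis
#' expects: per-subject phenotypes and true choice parameters, choice trials
#' simulated from the quadratic+time generative model, connectivity (tract
#' streamline-count) and effective-connectivity (MEP ratio) feature tables
#' with optional planted confound-adjusted associations, MEP trial tables,
#' and (optionally) per-iteration connectivity matrix stacks. Deterministic
#' under the config seed.
#'
#' @param config A [cohort_config()] object.
#' @param include_trials Simulate per-subject choice trials (default TRUE).
#' @param include_mep_trials Generate per-subject MEP trial tables whose
#'   cleaned condition means reproduce the subject's circuit ratios up to
#'   sampling noise (default TRUE).
#' @param include_stacks Generate per-subject connectivity matrix stacks
#'   whose iteration average embeds the subject's tract features (default
#'   FALSE: the stacks are the bulkiest component).
#' @param n_iterations Iterations per connectivity stack (default 50).
#' @return A list of class `synthetic_cohort` with tibbles `phenotype`
#'   (subject_id, apathy + subscores, depression, anhedonia, age, gender),
#'   `true_params` (generating choice parameters, incl. the sign-flipped
#'   `beta_effort_reported`), `features` (subject_id + 19 tract + 7 circuit
#'   columns), `trials`, `mep_trials`, and list `stacks`; plus the `config`.
#' @export
generate_cohort <- function(config, include_trials = TRUE,
                            include_mep_trials = TRUE,
                            include_stacks = FALSE, n_iterations = 50L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(n))

  conf <- draw_confounds(config, n, derive_seed(config$seed, "cohort"))

  # true choice parameters: log-normal magnitudes for the discounting
  # weights, truncated normals for drift and baseline (inverse-CDF draws)
  pm <- config$param_means; ps <- config$param_sds
  lo <- config$param_lower; hi <- config$param_upper
  rtnorm <- function(n, nm) {
    pa <- stats::pnorm(lo[nm], pm[nm], ps[nm])
    pb <- stats::pnorm(hi[nm], pm[nm], ps[nm])
    stats::qnorm(runif(n, pa, pb), pm[nm], ps[nm])
  }
  rtlnorm <- function(n, nm) {
    # truncated log-normal on the magnitude; sign restored from the median
    sgn <- sign(pm[nm]); ml <- log(abs(pm[nm])); sl <- ps[nm]
    a <- sort(abs(c(lo[nm], hi[nm])))
    pa <- stats::plnorm(a[1L], ml, sl); pb <- stats::plnorm(a[2L], ml, sl)
    sgn * stats::qlnorm(runif(n, pa, pb), ml, sl)
  }
  tp <- withr::with_seed(derive_seed(config$seed, "params"), tibble(
    subject_id = ids,
    beta_effort = rtlnorm(n, "beta_effort"),
    beta_reward = rtlnorm(n, "beta_reward"),
    beta_time = rtnorm(n, "beta_time"),
    beta_0 = rtnorm(n, "beta_0")
  )) %>%
    mutate(beta_effort_reported = -.data$beta_effort)

  # phenotype: apathy loads weakly on the depression/anhedonia latents
  phen <- withr::with_seed(derive_seed(config$seed, "phenotype"), {
    lo <- c(dep = 0.25, anh = 0.20)
    w <- sqrt(1 - sum(lo^2))
    az <- lo["dep"] * conf$.z_dep + lo["anh"] * conf$.z_anh + w * rnorm(n)
    sub <- function(rho) rho * az + sqrt(1 - rho^2) * rnorm(n)
    tibble(
      subject_id = ids,
      apathy = pmin(4, pmax(0, 1.2 + 0.35 * az)),
      apathy_action = pmin(4, pmax(0, 1.1 + 0.40 * sub(0.6))),
      apathy_emotion = pmin(4, pmax(0, 1.3 + 0.45 * sub(0.5))),
      apathy_cognitive = pmin(4, pmax(0, 1.0 + 0.40 * sub(0.5))),
      depression = conf$depression, anhedonia = conf$anhedonia,
      age = conf$age, gender = conf$gender
    )
  })

  # feature tables: standardized construction, then affine map to the
  # feature's natural scale (partial correlations are affine-invariant)
  outcomes <- list(apathy = phen$apathy,
                   beta_effort = tp$beta_effort_reported,
                   beta_reward = tp$beta_reward)
  conf_std <- tibble(
    age = as.numeric(scale(conf$age)),
    gender = as.numeric(scale(conf$gender)),
    depression = as.numeric(scale(conf$depression)),
    anhedonia = as.numeric(scale(conf$anhedonia))
  )
  feat_names <- c(tract_pairs()$feature, mep_circuits())
  dup <- config$planted_associations$feature[
    duplicated(config$planted_associations$feature)]
  if (length(dup) > 0) {
    abort(paste0("feature planted more than once: ", paste(dup, collapse = ", ")))
  }
  feats_z <- withr::with_seed(derive_seed(config$seed, "features"), {
    vapply(feat_names, function(f) {
      noise <- rnorm(n)
      hit <- which(config$planted_associations$feature == f)
      if (length(hit) == 1L) {
        pa <- config$planted_associations[hit, ]
        as.numeric(planted_feature_z(pa$r, outcomes[[pa$outcome]],
                                     conf_std, noise))
      } else {
        as.numeric(as.matrix(conf_std) %*% rep(0.2, 4L)) + noise
      }
    }, numeric(n))
  })
  centres <- c(tract_count_centres(), circuit_ratio_centres())
  scales <- centres * 0.15
  feats <- sweep(sweep(feats_z, 2L, scales[feat_names], `*`),
                 2L, centres[feat_names], `+`)
  features <- dplyr::bind_cols(tibble(subject_id = ids),
                               as_tibble(as.data.frame(feats)))

  trials <- NULL
  if (include_trials) {
    trials <- purrr::map_dfr(seq_len(n), function(i) {
      s <- derive_seed(as.double(config$seed) + i, "choices")
      des <- trial_design(config$effort_levels, config$reward_levels,
                          config$trials_per_condition, seed = s)
      simulate_choices(as.list(tp[i, c("beta_effort", "beta_reward",
                                       "beta_time", "beta_0")]),
                       des, family = "quadratic", time_modulated = TRUE,
                       seed = s + 1L) %>%
        mutate(subject_id = ids[i], .before = 1L) %>%
        select(-"p_accept")
    })
  }

  mep_trials <- NULL
  if (include_mep_trials) {
    mep_trials <- purrr::map_dfr(seq_len(n), function(i) {
      s <- derive_seed(as.double(config$seed) + i, "mep")
      purrr::map_dfr(seq_along(mep_circuits()), function(ci) {
        circ <- mep_circuits()[ci]
        target <- features[[circ]][i]
        generate_mep_trials(n_per_condition = 24L, planted_artifacts = 0L,
                            planted_outliers = 0L, seed = s + ci,
                            circuit = circ, ratio = max(target, 0.02))
      }) %>% mutate(subject_id = ids[i], .before = 1L)
    })
  }

  stacks <- NULL
  if (include_stacks) {
    stacks <- setNames(purrr::map(seq_len(n), function(i) {
      m <- subject_mean_matrix(as.numeric(features[i, tract_pairs()$feature]))
      generate_connectivity_stack(n_iterations = n_iterations,
                                  mean_matrix = m, dispersion = 0.02,
                                  seed = derive_seed(as.double(config$seed) + i,
                                                     "connectivity"))
    }), ids)
  }

  structure(list(
    phenotype = phen, true_params = tp, features = features,
    trials = trials, mep_trials = mep_trials, stacks = stacks,
    config = config
  ), class = "synthetic_cohort")
}

# Embed the 19 tract-pair values in a symmetric labelled 9-region matrix;
# unlisted pairs get a small constant background count.
subject_mean_matrix <- function(pair_values, background = 20) {
  regions <- tract_regions()
  m <- matrix(background, length(regions), length(regions),
              dimnames = list(regions, regions))
  diag(m) <- 0
  tp <- tract_pairs()
  for (j in seq_len(nrow(tp))) {
    v <- max(pair_values[j], 0)
    m[tp$region_a[j], tp$region_b[j]] <- v
    m[tp$region_b[j], tp$region_a[j]] <- v
  }
  m
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n =", x$config$n_subjects, "subjects\n")
  cat("  features:", ncol(x$features) - 1L, " trials:",
      if (is.null(x$trials)) 0L else nrow(x$trials),
      " mep trials:", if (is.null(x$mep_trials)) 0L else nrow(x$mep_trials),
      " stacks:", length(x$stacks %||% list()), "\n")
  invisible(x)
}
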