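#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates the end-to-end analysis in dependency order: cohort
#' simulation, per-subject choice-model fitting, MEP trial cleaning and
#' ratio computation, connectivity averaging and tract-feature extraction,
#' and the two-step association procedure for each outcome (apathy and the
#' reported effort and reward weights) against both feature sets (tract
#' streamline counts; circuit MEP ratios). All randomness derives from the
#' config seed, so a rerun with the same config produces byte-identical
#' outputs. Writes the standard CSV/JSON artifact set plus a manifest of
#' output file hashes.
#'
#' @param config A [cohort_config()] (its seed is the master seed).
#' @param out_dir Output directory (created; existing files overwritten).
#' @param use_stacks Compute tract features by averaging per-iteration
#'   connectivity stacks (slower, exercises the full chain); otherwise the
#'   cohort's feature table is used directly (default FALSE).
#' @param n_iterations_stack Iterations per connectivity stack when
#'   `use_stacks` (default 50).
#' @param n_starts Optimizer restarts per subject fit (default 10).
#' @param n_lambda_iterations Fold-partition iterations for the averaged
#'   penalty (default 100).
#' @param replications Run Elastic Net / stepwise replications (default
#'   TRUE).
#' @return Invisibly, a list of class `pipeline_result`: the in-memory
#'   results of every stage plus `manifest` (per-file md5 hashes, config
#'   echo, timestamps).
#' @export
run_all <- function(config, out_dir, use_stacks = FALSE,
                    n_iterations_stack = 50L, n_starts = 10L,
                    n_lambda_iterations = 100L, replications = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  message("stage 1/5: simulating cohort (n = ", config$n_subjects, ")")
  cohort <- generate_cohort(config, include_stacks = use_stacks,
                            n_iterations = n_iterations_stack)
  readr::write_csv(cohort$phenotype, file.path(out_dir, "phenotype.csv"))
  readr::write_csv(cohort$trials, file.path(out_dir, "trials.csv"))
  readr::write_csv(cohort$mep_trials, file.path(out_dir, "mep_trials.csv"))

  message("stage 2/5: fitting choice models (", n_starts, " starts/subject)")
  fits <- fit_cohort_choices(cohort$trials, n_starts = n_starts,
                             seed = derive_seed(config$seed, "starts"))
  readr::write_csv(fits, file.path(out_dir, "choice_fits.csv"))

  message("stage 3/5: MEP cleaning and ratios")
  mep <- compute_mep_ratios(cohort$mep_trials)
  readr::write_csv(mep$ratios, file.path(out_dir, "mep_ratios.csv"))
  readr::write_csv(mep$exclusions, file.path(out_dir, "mep_exclusions.csv"))
  mep_wide <- mep_ratio_features(mep$ratios)

  message("stage 4/5: tract features")
  if (use_stacks) {
    tract <- compute_tract_features(cohort$stacks)
  } else {
    tract <- cohort$features %>%
      select("subject_id", all_of(tract_pairs()$feature))
  }
  readr::write_csv(tract, file.path(out_dir, "tract_features.csv"))

  # dataflow integrity: identical subject sets at every stage
  sets <- list(phenotype = cohort$phenotype$subject_id,
               fits = fits$subject_id, mep = mep_wide$subject_id,
               tract = tract$subject_id)
  for (nm in names(sets)[-1L]) {
    if (!setequal(sets[[1L]], sets[[nm]])) {
      abort(paste0("subject set mismatch between phenotype and ", nm,
                   " stages"))
    }
  }

  message("stage 5/5: two-step associations")
  analysis <- cohort$phenotype %>%
    left_join(fits %>% select("subject_id", "beta_effort_reported",
                              "beta_reward"),
              by = "subject_id") %>%
    left_join(tract, by = "subject_id") %>%
    left_join(mep_wide, by = "subject_id")
  outcomes <- c(apathy = "apathy", beta_effort = "beta_effort_reported",
                beta_reward = "beta_reward")
  feature_sets <- list(tracts = tract_pairs()$feature,
                       circuits = mep_circuits())
  reports <- list()
  for (oc in names(outcomes)) {
    for (fs in names(feature_sets)) {
      key <- paste(oc, fs, sep = ".")
      reports[[key]] <- run_two_step(
        analysis, outcomes[[oc]], feature_sets[[fs]],
        n_iterations = n_lambda_iterations,
        seed = derive_seed(config$seed, "assoc") + match(key, paste(
          rep(names(outcomes), each = 2L), rep(names(feature_sets), 3L),
          sep = ".")),
        replications = replications)
    }
  }
  assoc_tab <- purrr::map_dfr(reports, tidy) %>%
    mutate(feature_set = rep(vapply(names(reports), function(k) {
      strsplit(k, ".", fixed = TRUE)[[1L]][2L]
    }, character(1)), times = vapply(reports, function(r) {
      length(r$lasso$coefficients)
    }, integer(1))), .after = "outcome")
  readr::write_csv(assoc_tab, file.path(out_dir, "association_report.csv"))
  assoc_json <- lapply(reports, function(r) {
    list(outcome = r$outcome, lambda = r$lambda, selected = r$selected,
         confirmed = r$confirmed,
         partial = r$partial, bf01 = r$bf01,
         replication = if (is.null(r$replication)) NULL else list(
           elastic_net = r$replication$elastic_net,
           stepwise = r$replication$stepwise,
           enet_contains_lasso = r$replication$enet_contains_lasso,
           stepwise_contains_lasso = r$replication$stepwise_contains_lasso))
  })
  jsonlite::write_json(assoc_json, file.path(out_dir, "association_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  data_files <- c("phenotype.csv", "trials.csv", "mep_trials.csv",
                  "choice_fits.csv", "mep_ratios.csv", "mep_exclusions.csv",
                  "tract_features.csv", "association_report.csv",
                  "association_report.json")
  manifest <- list(
    config = list(n_subjects = config$n_subjects, seed = config$seed,
                  effort_levels = config$effort_levels,
                  reward_levels = config$reward_levels,
                  trials_per_condition = config$trials_per_condition),
    stages = c("simulate", "fit-choice", "mep-ratios", "connectivity",
               "associate"),
    file_hashes = as.list(tools::md5sum(file.path(out_dir, data_files))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  names(manifest$file_hashes) <- data_files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(structure(list(
    cohort = cohort, fits = fits, mep = mep, tract = tract,
    reports = reports, manifest = manifest, out_dir = out_dir
  ), class = "pipeline_result"))
}

#' Human-readable summary of a pipeline run
#'
#' One section per outcome/feature-set pair: the LASSO-selected features,
#' the confound-adjusted partial correlations that survive the
#' significance check, Bayes-factor null evidence for the scoped
#' non-selected features, and replication agreement.
#'
#' @param result A `pipeline_result` from [run_all()].
#' @return Character vector of report lines (invisibly printed-friendly).
#' @export
make_report <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  lines <- c("Two-step association report",
             paste0("cohort n = ", result$manifest$config$n_subjects,
                    ", master seed = ", result$manifest$config$seed), "")
  for (key in names(result$reports)) {
    r <- result$reports[[key]]
    lines <- c(lines, paste0("== ", key, " (outcome: ", r$outcome, ") =="),
               paste0("  averaged lambda: ", format(r$lambda, digits = 5)),
               paste0("  selected: ", if (length(r$selected))
                 paste(r$selected, collapse = ", ") else "(none)"))
    if (nrow(r$partial) > 0) {
      for (i in seq_len(nrow(r$partial))) {
        pr <- r$partial[i, ]
        lines <- c(lines, sprintf("    %s: partial R = %.3f, p = %.4f%s",
                                  pr$feature, pr$r, pr$p,
                                  if (pr$confirmed) " *" else ""))
      }
    }
    if (nrow(r$bf01) > 0) {
      lines <- c(lines, paste0("  null evidence (BF01): ",
                               paste(sprintf("%s=%.2f", r$bf01$feature,
                                             r$bf01$bf01), collapse = ", ")))
    }
    if (!is.null(r$replication)) {
      lines <- c(lines, paste0("  replication agreement: elastic net ",
                               r$replication$enet_contains_lasso,
                               ", stepwise ",
                               r$replication$stepwise_contains_lasso))
    }
    lines <- c(lines, "")
  }
  lines
}
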