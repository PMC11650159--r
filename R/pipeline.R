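#' End-to-end synthetic study pipeline
#'
#' Runs simulate -> QC -> MVT fit (+ optional group-difference refit) ->
#' model-agnostic exit regression -> symptom generation and scoring ->
#' clinical statistics -> recovery report, fully deterministic under the
#' master seed. Any stage failure aborts with the stage name and cause.
#'
#' @param n_mdd,n_comparison Group sizes.
#' @param config A [foraging_config()].
#' @param rng_seed Master seed.
#' @param distributions A [cohort_distributions()].
#' @param couplings Symptom couplings passed to [simulate_cohort()].
#' @param exclusions An [exclusion_config()].
#' @param sampler List of MCMC settings (`chains`, `warmup`, `iter`).
#' @param symptom_config A [symptom_gen_config()].
#' @param fit_group_difference Also refit with explicit group shifts.
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @return List of class `ef_pipeline` with elements `cohort`, `qc`, `fit`,
#'   `group_fit`, `exit_reg`, `thresholds`, `scores`, `stats`, `recovery`.
#' @export
run_pipeline <- function(n_mdd = 20, n_comparison = 10,
                         config = foraging_config(), rng_seed = 1L,
                         distributions = cohort_distributions(),
                         couplings = list(),
                         exclusions = exclusion_config(),
                         sampler = list(chains = 2L, warmup = 400L, iter = 400L),
                         symptom_config = symptom_gen_config(),
                         fit_group_difference = FALSE,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (config$n_blocks_per_condition < 1) stop("config must include at least one block")

  cohort <- stage("simulate",
                  simulate_cohort(n_mdd, n_comparison, distributions, config,
                                  rng_seed = rng_seed, couplings = couplings))
  qc <- stage("qc", apply_exclusions(cohort$trials, exclusions))
  fit <- stage("fit", fit_mvt_hierarchical(
    qc$logs, config, chains = sampler$chains, warmup = sampler$warmup,
    iter = sampler$iter, rng_seed = derive_seed(rng_seed, 21L)))
  group_fit <- NULL
  if (fit_group_difference) {
    group_fit <- stage("fit-group-difference", fit_mvt_group_difference(
      qc$logs, config, groups = cohort$participants,
      chains = sampler$chains, warmup = sampler$warmup, iter = sampler$iter,
      rng_seed = derive_seed(rng_seed, 22L)))
  }
  exit_reg <- stage("fit-exit-regression",
                    exit_regression(qc$logs, effort_level = "low"))
  thresholds <- stage("overall-thresholds", overall_thresholds(exit_reg))
  items <- stage("symptom-items",
                 generate_symptom_items(cohort, symptom_config,
                                        rng_seed = derive_seed(rng_seed, 23L)))
  scores <- stage("score", score_factors(items, population = "mdd_only",
                                         groups = cohort$participants))
  merged <- stage("merge", {
    est <- mvt_point_estimates(fit)
    df <- merge(cohort$participants, est, by = "participant_id")
    df <- merge(df, thresholds[, c("participant_id", "threshold", "log_threshold")],
                by = "participant_id", all.x = TRUE)
    df$overall_depression <- df$hamd_total
    sw <- scores_wide(scores)
    if (nrow(sw)) df <- merge(df, sw, by = "participant_id", all.x = TRUE)
    df
  })
  stats_out <- stage("stats", {
    mdd <- merged$group == "mdd"
    batteries <- list()
    scored <- intersect(symptom_factor_names(), names(merged))
    if (length(scored) >= 1L && sum(mdd) > 8L) {
      batteries$cognitive <- run_symptom_battery(
        merged, "c_high_cognitive", scored,
        covariates = c("dprime_3back", "years_education", "age"), subset = mdd)
      batteries$physical <- run_symptom_battery(
        merged, "c_high_physical", scored,
        covariates = c("pct_presses_completed", "bmi", "years_education", "age"),
        subset = mdd)
    }
    batteries
  })
  recovery <- stage("recover", {
    est <- mvt_point_estimates(fit)
    tv <- merge(cohort$truth, est, by = "participant_id",
                suffixes = c("_true", "_fit"))
    cors <- vapply(c("c_low_cognitive", "c_high_cognitive",
                     "c_low_physical", "c_high_physical"), function(pn) {
      suppressWarnings(stats::cor(tv[[paste0(pn, "_true")]], tv[[paste0(pn, "_fit")]],
                                  use = "pairwise.complete.obs"))
    }, numeric(1))
    data.frame(parameter = names(cors), truth_correlation = unname(cors),
               stringsAsFactors = FALSE)
  })

  out <- structure(list(cohort = cohort, qc = qc, fit = fit,
                        group_fit = group_fit, exit_reg = exit_reg,
                        thresholds = thresholds, scores = scores,
                        merged = merged, stats = stats_out,
                        recovery = recovery, rng_seed = rng_seed),
                   class = "ef_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trial_log(cohort$trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    utils::write.csv(cohort$participants, file.path(out_dir, "participants.csv"),
                     row.names = FALSE)
    utils::write.csv(qc$report, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
    utils::write.csv(fit$summary, file.path(out_dir, "posterior_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(thresholds, file.path(out_dir, "overall_thresholds.csv"),
                     row.names = FALSE)
    if (nrow(scores$scores)) {
      utils::write.csv(scores$scores, file.path(out_dir, "symptom_scores.csv"),
                       row.names = FALSE)
    }
    for (nm in names(stats_out)) {
      utils::write.csv(as.data.frame(stats_out[[nm]]),
                       file.path(out_dir, sprintf("battery_%s.csv", nm)),
                       row.names = FALSE)
    }
    utils::write.csv(recovery, file.path(out_dir, "recovery.csv"), row.names = FALSE)
  }
  out
}

#' @export
print.ef_pipeline <- function(x, ...) {
  cat("<ef_pipeline>\n")
  print(x$cohort)
  cat(sprintf("  max R-hat     : %.3f\n", x$fit$max_rhat))
  cat("  recovery correlations (truth vs posterior mean):\n")
  for (i in seq_len(nrow(x$recovery))) {
    cat(sprintf("    %-18s r = %.3f\n", x$recovery$parameter[i],
                x$recovery$truth_correlation[i]))
  }
  invisible(x)
}
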