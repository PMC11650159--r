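# Reduced sampler settings keep these fits to a few seconds each; the
# full-scale recovery experiment lives in test-acceptance.R.

small_fit <- function(coh, cfg, ...) {
  suppressWarnings(fit_mvt_hierarchical(coh$trials, cfg, chains = 2L,
                                        warmup = 150L, iter = 150L,
                                        sweeps = 4L, rng_seed = 8, ...))
}

test_that("hierarchical fit returns a coherent posterior summary", {
  cfg <- quick_config()
  coh <- simulate_cohort(6, 0, config = cfg, rng_seed = 31)
  fit <- small_fit(coh, cfg)
  s <- fit$summary
  expect_s3_class(fit, "mvt_fit")
  expect_setequal(unique(s$parameter),
                  c("c_low_cognitive", "c_high_cognitive", "c_low_physical",
                    "c_high_physical", "log_beta", "rho_cognitive_low",
                    "rho_cognitive_high", "rho_physical_low",
                    "rho_physical_high", "log_posterior_likelihood"))
  # HDI brackets the mean, R-hat reported for every sampled parameter
  ok <- !is.na(s$mean)
  expect_true(all(s$hdi_lower[ok] <= s$mean[ok] & s$mean[ok] <= s$hdi_upper[ok]))
  expect_true(all(is.finite(s$rhat[ok])))
  # cost-correlation posterior present with HDI
  expect_true(all(c("mean", "lower", "upper") %in% names(fit$cost_correlation)))
  # threshold identity rho = A - B * c holds for posterior means (linearity)
  est <- mvt_point_estimates(fit)
  sm <- condition_summaries(coh$trials, cfg)
  i <- match(est$participant_id, sm$participant_id[sm$effort_type == "cognitive" &
                                                     sm$effort_level == "low"])
  sml <- sm[sm$effort_type == "cognitive" & sm$effort_level == "low", ][i, ]
  expect_equal(est$rho_cognitive_low,
               (sml$total_rewards - sml$n_travels * est$c_low_cognitive) / sml$T,
               tolerance = 1e-8)
})

test_that("participants with too few exits are dropped per effort type", {
  cfg <- quick_config()
  coh <- simulate_cohort(4, 0, config = cfg, rng_seed = 33)
  logs <- coh$trials
  # participant 1: remove all cognitive exits except one (turn them into harvests)
  sel <- logs$participant_id == "mdd_01" & logs$effort_type == "cognitive" &
    logs$action == "exit"
  idx <- which(sel)
  logs$action[idx[-1]] <- "harvest"
  logs$reward[idx[-1]] <- logs$expected_reward[idx[-1]]
  fit <- suppressMessages(small_fit(list(trials = logs), cfg))
  expect_true(nrow(fit$dropped) >= 1)
  expect_true(all(fit$excluded$effort_type == "cognitive"))
  s <- fit$summary
  na_params <- s$parameter[s$participant_id == "mdd_01" & is.na(s$mean)]
  expect_true("c_high_cognitive" %in% na_params)
  # the physical side of the same participant is retained
  expect_false("c_high_physical" %in% na_params)
})

test_that("group-difference variant needs two groups and reports shifts", {
  cfg <- quick_config()
  coh <- simulate_cohort(5, 4, config = cfg, rng_seed = 35)
  expect_error(
    fit_mvt_group_difference(coh$trials, cfg,
                             groups = data.frame(
                               participant_id = coh$participants$participant_id,
                               group = "mdd")),
    "two groups")
  fit <- suppressWarnings(fit_mvt_group_difference(
    coh$trials, cfg, groups = coh$participants, chains = 2L, warmup = 150L,
    iter = 150L, sweeps = 4L, rng_seed = 9))
  gs <- group_shift_summary(fit)
  expect_equal(nrow(gs), 5L)
  expect_true(all(is.finite(gs$mean)))
  # plain fit refuses the accessor
  plain <- small_fit(coh, cfg)
  expect_error(group_shift_summary(plain), "group_difference")
})

test_that("posterior predictive check flags corrupted choice data", {
  cfg <- quick_config()
  coh <- simulate_cohort(6, 0, config = cfg, rng_seed = 37)
  fit <- small_fit(coh, cfg)
  expect_error(posterior_predictive_check(fit, n_rep = 0), "n_rep")
  ppc <- posterior_predictive_check(fit, n_rep = 100, rng_seed = 1)
  # model-generated data: observed statistic inside the replicate spread
  expect_gt(ppc$pd, 0.01)
  expect_true(ppc$observed > 0 && ppc$observed < 1)
  expect_true(all(c("condition", "observed", "replicate_mean") %in%
                    names(ppc$exit_thresholds)))
  # corrupt the data: force ~40% of free harvests into exits at random
  logs <- coh$trials
  set.seed(4)
  free_h <- which(!logs$first_harvest & logs$action == "harvest")
  flip <- sample(free_h, round(0.4 * length(free_h)))
  logs$action[flip] <- "exit"
  ppc_bad <- posterior_predictive_check(fit, logs = logs, n_rep = 100,
                                        rng_seed = 1)
  expect_lt(ppc_bad$pd, 0.01)
})

test_that("log posterior likelihood group comparison is a Welch t-test", {
  cfg <- quick_config()
  coh <- simulate_cohort(5, 5, config = cfg, rng_seed = 39)
  fit <- small_fit(coh, cfg)
  groups <- stats::setNames(coh$participants$group,
                            coh$participants$participant_id)
  res <- loglik_group_compare(fit, groups)
  expect_true(is.finite(res$t))
  expect_gt(res$df, 1)
  expect_false(res$df == round(res$df))  # Welch df is non-integer
  expect_true(res$p > 0 && res$p <= 1)
  # a strong shift in one group's likelihoods must be detected
  s <- fit$summary
  ll <- s$mean[s$parameter == "log_posterior_likelihood"]
  fake <- fit
  fake$summary$mean[fake$summary$parameter == "log_posterior_likelihood"] <-
    ll + ifelse(groups[fit$participants] == "mdd", 5 * sd(ll), 0)
  res2 <- loglik_group_compare(fake, groups)
  expect_lt(res2$p, 0.05)
  bad <- groups
  bad[] <- "mdd"
  bad[1] <- "comparison"
  expect_error(loglik_group_compare(fit, bad), "at least 2")
})

test_that("sampler input validation catches bad settings", {
  cfg <- quick_config()
  coh <- simulate_cohort(2, 0, config = cfg, rng_seed = 41)
  expect_error(fit_mvt_hierarchical(coh$trials, cfg, fix_beta = -1), "fix_beta")
  expect_error(fit_mvt_hierarchical(coh$trials, cfg, chains = 0))
})
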