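test_that("exit regression validates inputs and degenerate cases", {
  log <- hand_log()
  no_exit <- log[log$action != "exit", ]
  expect_error(exit_regression(no_exit), "no exit trials")
  # single participant: fixed-effects fallback with a warning
  expect_warning(res <- exit_regression(log, effort_type = "cognitive"),
                 "single participant")
  expect_s3_class(res, "exit_regression")
  expect_equal(res$intercept, mean(log(c(7.04, 7.92))))
})

test_that("null effort effect gives a near-zero effort coefficient", {
  logs <- fixed_threshold_cohort(20, thresholds_low = 5, thresholds_high = 5,
                                 beta = 5, seed = 2)
  res <- exit_regression(logs, effort_type = "cognitive")
  expect_lt(abs(res$effort_t), 2.5)
})

test_that("a 20% lower high-effort threshold is recovered on the log scale", {
  logs <- fixed_threshold_cohort(40, thresholds_low = 5, thresholds_high = 4,
                                 beta = 12, config = quick_config(), seed = 3)
  res_c <- exit_regression(logs, effort_type = "cognitive")
  res_p <- exit_regression(logs, effort_type = "physical")
  expect_lt(abs(res_c$effort_coefficient - log(0.8)), 0.05)
  expect_lt(abs(res_p$effort_coefficient - log(0.8)), 0.05)
  expect_lt(res_c$effort_t, -2)
})

test_that("overall thresholds approach the generating threshold for sharp agents", {
  cfg <- quick_config()
  logs <- fixed_threshold_cohort(12, thresholds_low = 5, thresholds_high = 5,
                                 beta = 30, config = cfg, seed = 4)
  reg <- exit_regression(logs, effort_level = "low")
  th <- overall_thresholds(reg)
  expect_equal(nrow(th), 12L)
  # deterministic limit: recovered threshold within one decay step of rho*
  kappa <- decay_mean(cfg)
  expect_true(all(abs(log(th$threshold) - log(5)) <= -log(kappa) + 0.05))
  # exponentiation preserves ranking
  expect_identical(order(th$log_threshold), order(th$threshold))
})

test_that("forced first harvests cannot contaminate the regression", {
  logs <- fixed_threshold_cohort(8, thresholds_low = 5, thresholds_high = 5,
                                 beta = 10, seed = 5)
  reg <- exit_regression(logs, effort_level = "low")
  # plant an absurd forced-harvest row flagged first_harvest: must not matter
  planted <- logs[1, ]
  planted$action <- "exit"
  planted$first_harvest <- TRUE
  planted$expected_reward <- 1e6
  reg2 <- exit_regression(rbind(planted, logs), effort_level = "low")
  expect_equal(reg$intercept, reg2$intercept)
})

test_that("MVT and model-agnostic thresholds agree in rank", {
  # scaled down from n = 40 to n = 16 for test-suite runtime (rank agreement
  # at full scale is ~0.9; the bound here leaves room for the smaller sample)
  cfg <- foraging_config()
  coh <- simulate_cohort(16, 0, config = cfg, rng_seed = 51)
  fit <- suppressWarnings(fit_mvt_hierarchical(coh$trials, cfg, chains = 2L,
                                               warmup = 250L, iter = 250L,
                                               sweeps = 6L, rng_seed = 6))
  est <- mvt_point_estimates(fit)
  reg <- exit_regression(coh$trials, effort_level = "low")
  th <- overall_thresholds(reg)
  m <- merge(est, th, by = "participant_id")
  mvt_low <- (m$rho_cognitive_low + m$rho_physical_low) / 2
  expect_gt(cor(mvt_low, m$threshold, method = "spearman"), 0.8)
})
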