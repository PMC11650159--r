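test_that("config validation rejects bad fields by name", {
  expect_error(foraging_config(reward_floor = 0), "reward_floor")
  expect_error(foraging_config(decay_alpha = -1), "decay_alpha")
  expect_error(foraging_config(block_duration = 0), "block_duration")
  expect_error(foraging_config(n_blocks_per_condition = 0), "n_blocks_per_condition")
  expect_error(foraging_config(missed_rate = 1.2), "missed_rate")
  expect_error(
    foraging_config(conditions = data.frame(effort_type = "mental",
                                            effort_level = "low")),
    "conditions")
})

test_that("analytic decay mean of the default orchard is 0.88", {
  expect_equal(round(decay_mean(foraging_config()), 2), 0.88)
})

test_that("sample_patch draws from the initial-reward distribution", {
  cfg <- foraging_config()
  draws <- with(list(), {
    set.seed(1)
    replicate(10000, sample_patch(cfg)$current_reward)
  })
  expect_lt(abs(mean(draws) - 15), 0.05)
  # degenerate distribution
  cfg0 <- foraging_config(initial_reward_sd = 0)
  expect_identical(sample_patch(cfg0, 3)$current_reward, 15)
  # determinism under a fixed seed
  expect_identical(sample_patch(cfg, 42), sample_patch(cfg, 42))
})

test_that("harvest_patch multiplies by the decay draw and floors at 0.5", {
  cfg <- foraging_config()
  p <- structure(list(current_reward = 10, n_harvests = 1L),
                 class = "foraging_patch")
  set.seed(5)
  d <- rbeta(1, cfg$decay_alpha, cfg$decay_beta)
  h <- harvest_patch(p, cfg, rng_seed = 5)
  expect_equal(h$reward, 10 * d)
  expect_equal(h$patch$n_harvests, 2L)
  # long harvesting runs into the floor and never drops below it
  p <- sample_patch(cfg, 1)
  rewards <- numeric(200)
  for (i in 1:200) {
    h <- harvest_patch(p, cfg)
    p <- h$patch
    rewards[i] <- h$reward
  }
  expect_equal(min(rewards), 0.5)
  expect_true(all(rewards >= 0.5))
})

test_that("decay draws match the analytic mean (property)", {
  cfg <- foraging_config()
  set.seed(7)
  d <- rbeta(1e5, cfg$decay_alpha, cfg$decay_beta)
  expect_lt(abs(mean(d) - decay_mean(cfg)), 0.005)
})

test_that("simulated blocks respect timing and schema", {
  cfg <- quick_config()
  ag <- agent_spec(mvt_params(2, 3, 2, 3, beta = 3))
  log <- simulate_participant(ag, cfg, rng_seed = 9)
  expect_true(all(c("participant_id", "block", "effort_type", "effort_level",
                    "trial", "last_reward", "expected_reward", "action",
                    "first_harvest") %in% names(log)))
  # block time never exceeds block_duration by more than one trial's duration
  for (b in unique(log$block)) {
    d <- log[log$block == b, ]
    t_total <- sum(d$action %in% c("harvest", "missed")) * cfg$harvest_duration +
      sum(d$action == "exit") * cfg$travel_duration
    expect_lte(t_total, cfg$block_duration + max(cfg$harvest_duration,
                                                 cfg$travel_duration))
  }
  # expected reward on free trials is last reward times the decay mean
  free <- log[!log$first_harvest & log$action != "missed", ]
  expect_equal(free$expected_reward, free$last_reward * decay_mean(cfg))
  # first harvest per patch is forced and unflagged trials follow it
  firsts <- tapply(log$first_harvest, paste(log$block, log$patch), sum)
  expect_true(all(firsts == 1))
  # determinism
  log2 <- simulate_participant(ag, cfg, rng_seed = 9)
  expect_identical(log, log2)
})

test_that("missed trials are emitted at the configured rate and excluded from totals", {
  cfg <- quick_config(missed_rate = 0.2)
  ag <- agent_spec(mvt_params(beta = 3), threshold_mode = "fixed",
                   thresholds = c(cognitive_low = 5, cognitive_high = 5,
                                  physical_low = 5, physical_high = 5))
  log <- simulate_participant(ag, cfg, rng_seed = 11)
  rate <- mean(log$action == "missed")
  expect_gt(rate, 0.08)
  expect_lt(rate, 0.35)
  s <- condition_summaries(log, cfg)
  expect_true(all(s$n_free_trials ==
                    tapply(!log$first_harvest & log$action != "missed",
                           paste(log$effort_type, log$effort_level), sum)[
                             paste(s$effort_type, s$effort_level)]))
})

test_that("self-consistent thresholds decrease with marginal cost (property)", {
  cfg <- quick_config()
  grid <- c(0, 3, 6, 9, 12)
  rho_high <- vapply(grid, function(ch) {
    p <- mvt_params(c_low_cognitive = 2, c_high_cognitive = ch,
                    c_low_physical = 2, c_high_physical = ch, beta = 3)
    rho <- solve_agent_thresholds(p, cfg, rng_seed = 13)
    mean(rho[c("cognitive_high", "physical_high")])
  }, numeric(1))
  # high-effort threshold gap widens monotonically as marginal cost grows
  expect_true(all(diff(rho_high) < 0))
})

test_that("higher-cost agents exit later in high-effort blocks", {
  cfg <- quick_config()
  mean_exit_re <- function(ch, seeds) {
    logs <- lapply(seeds, function(sd) {
      ag <- agent_spec(mvt_params(2, ch, 2, ch, beta = 3))
      simulate_participant(ag, cfg, rng_seed = sd)
    })
    log <- do.call(rbind, logs)
    ex <- log[log$action == "exit" & log$effort_level == "high", ]
    mean(ex$expected_reward)
  }
  lo <- mean_exit_re(0, 1:25)
  hi <- mean_exit_re(10, 1:25)
  expect_gt(lo - hi, 0.1)  # larger cost -> lower exit threshold (more staying)
})

test_that("cohort simulation is reproducible and couplings plant slopes", {
  cfg <- quick_config()
  coh1 <- simulate_cohort(5, 3, config = cfg, rng_seed = 2)
  coh2 <- simulate_cohort(5, 3, config = cfg, rng_seed = 2)
  expect_identical(coh1$trials, coh2$trials)
  expect_identical(coh1$truth, coh2$truth)
  expect_error(simulate_cohort(0, 5, config = cfg), "n_mdd")
  # coupling: standardized slope of the true parameter on the latent factor
  coh <- simulate_cohort(300, 0, config = cfg, rng_seed = 3,
                         simulate_trials = FALSE,
                         couplings = list(list(param = "c_high_cognitive",
                                               factor = "anxiety", b = -0.6)))
  sl <- coef(lm(scale(coh$truth$c_high_cognitive) ~
                  scale(coh$participants$latent_anxiety)))[2]
  expect_lt(abs(sl - (-0.6)), 0.1)
  # null coupling: slope near zero
  coh0 <- simulate_cohort(300, 0, config = cfg, rng_seed = 3,
                          simulate_trials = FALSE)
  sl0 <- coef(lm(scale(coh0$truth$c_high_cognitive) ~
                   scale(coh0$participants$latent_anxiety)))[2]
  expect_lt(abs(sl0), 0.15)
})

test_that("symptom item generator has the stated factor structure", {
  coh <- simulate_cohort(60, 0, config = quick_config(), rng_seed = 4,
                         simulate_trials = FALSE)
  # noiseless, unit-loading items equal the latent exactly
  it0 <- generate_symptom_items(coh, symptom_gen_config(items_per_factor = 2,
                                                        loadings = 1,
                                                        noise_sd = 0),
                                rng_seed = 1)
  one <- it0[it0$item == "anhedonia_item1", ]
  expect_equal(one$value[match(coh$participants$participant_id, one$participant_id)],
               coh$participants$latent_anhedonia)
  # bad items carry (almost) no signal
  it <- generate_symptom_items(coh, symptom_gen_config(n_bad_items = 1),
                               rng_seed = 2)
  bad <- it[it$item == "anxiety_bad1", ]
  r <- cor(bad$value[match(coh$participants$participant_id, bad$participant_id)],
           coh$participants$latent_anxiety)
  expect_lt(abs(r), 0.3)
})
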