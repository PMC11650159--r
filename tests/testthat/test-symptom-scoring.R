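test_that("item-total filter removes weak items deterministically", {
  set.seed(1)
  n <- 200
  latent <- rnorm(n)
  X <- cbind(i1 = 0.8 * latent + rnorm(n, 0, 0.5),
             i2 = 0.8 * latent + rnorm(n, 0, 0.5),
             i3 = 0.8 * latent + rnorm(n, 0, 0.5),
             bad = rnorm(n))
  flt <- item_total_filter(X)
  expect_setequal(flt$retained, c("i1", "i2", "i3"))
  expect_named(flt$removed, "bad")
  expect_false(flt$empty)
  # fixed point: re-running on the retained set removes nothing further
  flt2 <- item_total_filter(X[, flt$retained])
  expect_identical(flt2$retained, flt$retained)
  expect_length(flt2$removed, 0)
  # perfectly correlated items are all retained
  Y <- cbind(a = latent, b = latent, c = latent)
  expect_setequal(item_total_filter(Y)$retained, c("a", "b", "c"))
  # two items correlated at ~0.1: factor cannot be scored
  set.seed(2)
  Z <- cbind(a = latent, b = 0.1 * latent + rnorm(n))
  flt3 <- item_total_filter(Z)
  expect_true(flt3$empty)
  expect_error(item_total_filter(X[, 1, drop = FALSE]), "2 items")
})

test_that("cronbach alpha matches the 2-item Spearman-Brown form exactly", {
  set.seed(3)
  n <- 500
  x1 <- rnorm(n)
  x2 <- 0.5 * x1 + sqrt(1 - 0.25) * rnorm(n)
  X <- scale(cbind(x1, x2))  # unit variances make the identity exact
  r <- cor(x1, x2)
  expect_equal(cronbach_alpha(X), 2 * r / (1 + r), tolerance = 1e-12)
  # identical items: alpha = 1
  expect_equal(cronbach_alpha(cbind(x1, x1)), 1)
  # uncorrelated items: alpha near 0
  set.seed(4)
  U <- matrix(rnorm(4 * 2000), ncol = 4)
  expect_lt(abs(cronbach_alpha(U)), 0.1)
  expect_error(cronbach_alpha(matrix(1, 10, 2)), "zero variance")
  expect_error(cronbach_alpha(matrix(rnorm(4), 2, 2)), "3 complete")
})

test_that("planted bad items are removed across simulated cohorts", {
  removed <- 0L
  reps <- 40L
  for (i in seq_len(reps)) {
    coh <- simulate_cohort(40, 0, config = quick_config(), rng_seed = 100 + i,
                           simulate_trials = FALSE)
    it <- generate_symptom_items(
      coh, symptom_gen_config(items_per_factor = 4, n_bad_items = 1,
                              factors = "anhedonia"), rng_seed = i)
    sc <- score_factors(it, groups = coh$participants)
    if (!"anhedonia_bad1" %in% sc$retained$anhedonia) removed <- removed + 1L
  }
  expect_gte(removed / reps, 0.9)
})

test_that("factor scoring recovers latents and applies all gates", {
  coh <- simulate_cohort(80, 40, config = quick_config(), rng_seed = 61,
                         simulate_trials = FALSE)
  it <- generate_symptom_items(
    coh, symptom_gen_config(items_per_factor = 10, loadings = 0.7,
                            noise_sd = 0.5), rng_seed = 7)
  sc <- score_factors(it, groups = coh$participants)
  expect_s3_class(sc, "symptom_scores")
  wide <- scores_wide(sc)
  m <- merge(wide, coh$participants, by = "participant_id")
  for (f in symptom_factor_names()) {
    expect_gt(cor(m[[f]], m[[paste0("latent_", f)]]), 0.9)
    expect_gte(sc$alphas[[f]], 0.6)
  }
  # scores are z-scaled within the scoring population
  expect_lt(max(abs(colMeans(wide[, -1]))), 0.05)
  # mdd-only vs all-participants scoring differ by an affine map per factor
  sc_all <- score_factors(it, population = "all", groups = coh$participants)
  wide_all <- scores_wide(sc_all)
  both <- merge(wide, wide_all, by = "participant_id")
  r <- cor(both$anhedonia.x, both$anhedonia.y)
  expect_gt(r, 0.999)
})

test_that("unreliable factors are excluded by the alpha gate", {
  coh <- simulate_cohort(60, 0, config = quick_config(), rng_seed = 63,
                         simulate_trials = FALSE)
  good <- generate_symptom_items(
    coh, symptom_gen_config(items_per_factor = 6, loadings = 0.8,
                            noise_sd = 0.5, factors = "anhedonia"), rng_seed = 1)
  # a noisy factor: items pass the 0.2 item-total gate only marginally but
  # alpha stays low
  weak <- generate_symptom_items(
    coh, symptom_gen_config(items_per_factor = 2, loadings = 0.45,
                            noise_sd = 1.0, factors = "anxiety"), rng_seed = 2)
  sc <- score_factors(rbind(good, weak), groups = coh$participants)
  expect_true("anhedonia" %in% names(sc$retained))
  expect_false("anxiety" %in% names(sc$retained))
  expect_true("anxiety" %in% names(sc$excluded_factors))
})

test_that("participants missing most items of a factor are not scored", {
  coh <- simulate_cohort(30, 0, config = quick_config(), rng_seed = 65,
                         simulate_trials = FALSE)
  it <- generate_symptom_items(
    coh, symptom_gen_config(items_per_factor = 6, factors = "anhedonia"),
    rng_seed = 3)
  drop_id <- coh$participants$participant_id[1]
  it$value[it$participant_id == drop_id &
             it$item %in% paste0("anhedonia_item", 1:4)] <- NA
  sc <- score_factors(it, groups = coh$participants)
  s <- sc$scores
  expect_true(is.na(s$score[s$participant_id == drop_id]))
  expect_false(anyNA(s$score[s$participant_id != drop_id]))
})
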