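make_reg_data <- function(n = 52, slope = 0.4, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    symptom = rnorm(n),
    performance = rnorm(n),
    age = rnorm(n, 30, 8),
    education = rnorm(n, 15, 2)
  )
  d$cost <- slope * d$symptom + 0.2 * d$performance +
    sqrt(max(0, 1 - slope^2 - 0.04)) * rnorm(n)
  d
}

test_that("standardized regression recovers a planted slope at n = 52", {
  # single planted instance at the stated tolerance (sampling SE at n = 52 is
  # ~0.12, so the +/-0.15 claim is about an instance, not every replicate)
  d1 <- make_reg_data(slope = 0.4, seed = 5)
  est1 <- fit_spec(d1, "cost", "symptom",
                   c("performance", "age", "education"))$estimate
  expect_lt(abs(est1 - 0.4), 0.15)
  # and the estimator is unbiased across replicates
  ests <- vapply(1:20, function(i) {
    d <- make_reg_data(slope = 0.4, seed = i)
    fit_spec(d, "cost", "symptom", c("performance", "age", "education"))$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.4), 0.07)
  # null predictor: small coefficient, roughly uniform p
  d0 <- make_reg_data(slope = 0, seed = 99)
  r0 <- fit_spec(d0, "cost", "symptom", c("performance", "age", "education"))
  expect_lt(abs(r0$estimate), 0.3)
  # scale invariance of standardized coefficients
  d <- make_reg_data(seed = 5)
  r1 <- fit_spec(d, "cost", "symptom", "performance")
  d$cost <- d$cost * 10
  d$symptom <- d$symptom / 3 + 100
  r2 <- fit_spec(d, "cost", "symptom", "performance")
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("regression errors are informative", {
  d <- make_reg_data(n = 30)
  expect_error(fit_spec(d, "cost", "nope", "age"), "missing columns")
  d$dup <- d$performance
  expect_error(fit_spec(d, "cost", "symptom", c("performance", "dup")),
               "collinear|rank")
  expect_error(fit_spec(d[1:4, ], "cost", "symptom",
                        c("performance", "age", "education")), "too few")
})

test_that("BH step-up matches hand-computed cases", {
  # all i: p_(i) > i/m * q, so nothing is rejected
  res <- fdr_correct(c(.01, .02, .03, .04, .05, .06, .07), q = 0.05)
  expect_false(any(res$reject))
  expect_equal(res$adjusted[1], 0.07)
  res2 <- fdr_correct(rep(0.001, 7))
  expect_true(all(res2$reject))
  # m = 1: identical to the raw threshold
  expect_true(fdr_correct(0.049)$reject)
  expect_false(fdr_correct(0.051)$reject)
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_correct(numeric(0)), "m")
})

test_that("Meng z test has the stated symmetries and guards", {
  expect_equal(compare_dependent_correlations(0.4, 0.4, 0.2, 50)$z, 0)
  expect_equal(compare_dependent_correlations(0.4, 0.4, 0.2, 50)$p, 1)
  a <- compare_dependent_correlations(0.5, 0.2, 0.1, 79)
  b <- compare_dependent_correlations(0.2, 0.5, 0.1, 79)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_error(compare_dependent_correlations(1, 0.2, 0.1, 50), "r1")
  expect_error(compare_dependent_correlations(0.5, 0.2, 0.1, 3), "n")
})

test_that("performance covariates attenuate ability-mediated confounds", {
  set.seed(11)
  n <- 300
  perf <- rnorm(n)
  symptom <- 0.7 * perf + sqrt(1 - 0.49) * rnorm(n)  # symptom tracks ability
  cost <- 0.8 * perf + sqrt(1 - 0.64) * rnorm(n)     # cost driven by ability only
  d <- data.frame(cost = cost, symptom = symptom, performance = perf)
  unadj <- fit_spec(d, "cost", "symptom", character())
  adj <- fit_spec(d, "cost", "symptom", "performance")
  expect_gt(abs(unadj$estimate), 0.4)
  expect_lt(abs(adj$estimate), abs(unadj$estimate) / 2)
})

test_that("the symptom battery applies FDR over the fitted models only", {
  set.seed(21)
  n <- 60
  d <- as.data.frame(matrix(rnorm(n * 7), n,
                            dimnames = list(NULL, symptom_factor_names())))
  d$performance <- rnorm(n)
  d$age <- rnorm(n)
  d$cost <- 0.6 * d$anxiety + 0.8 * rnorm(n)
  tab <- run_symptom_battery(d, "cost", symptom_factor_names(),
                             covariates = c("performance", "age"))
  expect_s3_class(tab, "symptom_battery")
  expect_equal(attr(tab, "m"), 7L)
  expect_true(tab$significant[tab$predictor == "anxiety"])
  # missing factor: model skipped, family size reduced
  d2 <- d[, setdiff(names(d), "social_apathy")]
  tab2 <- run_symptom_battery(d2, "cost", symptom_factor_names(),
                              covariates = c("performance", "age"))
  expect_equal(attr(tab2, "m"), 6L)
  expect_named(attr(tab2, "skipped"), "social_apathy")
  # anxiety-adjusted variant drops anxiety's own row and controls for it
  tab3 <- run_symptom_battery(d, "cost", symptom_factor_names(),
                              covariates = c("performance", "age"),
                              anxiety_adjusted = TRUE)
  expect_false("anxiety" %in% tab3$predictor)
  expect_equal(attr(tab3, "m"), 6L)
  # with anxiety controlled, no other symptom should be flagged
  expect_false(any(tab3$significant))
})
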