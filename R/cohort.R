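#' Group-level distributions for synthetic cohorts
#'
#' Means and SDs of the generative parameter population. Costs are normal
#' (negative values — effort seeking — are allowed, as observed in a minority
#' of participants); the inverse temperature is log-normal. Defaults give
#' agents that clearly avoid effort on average with wide individual
#' differences, exit thresholds near a third of the initial patch reward, and
#' fairly deterministic patch leaving.
#'
#' @param c_low_mean,c_low_sd Low-effort travel cost distribution (apples).
#' @param c_high_mean,c_high_sd Marginal high-effort cost distribution (apples).
#' @param log_beta_mean,log_beta_sd Log inverse-temperature distribution.
#' @param cost_correlation Generative correlation between the cognitive and
#'   physical marginal costs (default 0).
#' @return A list of class `cohort_distributions`.
#' @export
cohort_distributions <- function(c_low_mean = 10, c_low_sd = 15,
                                 c_high_mean = 4, c_high_sd = 6,
                                 log_beta_mean = log(3), log_beta_sd = 0.4,
                                 cost_correlation = 0) {
  check_field(abs(cost_correlation) < 1, "cost_correlation", "must be in (-1, 1)")
  check_field(c_low_sd >= 0 && c_high_sd >= 0 && log_beta_sd >= 0,
              "sd", "standard deviations must be non-negative")
  structure(list(c_low_mean = c_low_mean, c_low_sd = c_low_sd,
                 c_high_mean = c_high_mean, c_high_sd = c_high_sd,
                 log_beta_mean = log_beta_mean, log_beta_sd = log_beta_sd,
                 cost_correlation = cost_correlation),
            class = "cohort_distributions")
}

#' Names of the symptom factors carried by synthetic cohorts
#'
#' The seven MDD symptom domains entering the regression battery.
#' @return Character vector of factor names.
#' @export
symptom_factor_names <- function() {
  c("anhedonia", "anxiety", "behavioral_apathy", "cognitive_function",
    "depressed_mood", "anergia_slowing", "social_apathy")
}

#' Simulate a synthetic study cohort
#'
#' Draws per-participant MVT parameters from group distributions, latent
#' symptom-factor scores, demographics and travel-task performance, and
#' simulates each participant's full foraging session. Optional couplings
#' plant a linear dependence of a cost parameter on a latent symptom:
#' with coupling strength `b`, the parameter is
#' `mean + sd * (b * latent + sqrt(1 - b^2) * noise)`, so `b` is the
#' generative standardized slope and the parameter's marginal SD is
#' unchanged.
#'
#' @param n_mdd,n_comparison Group sizes (must be > 0; use
#'   `n_comparison = 0` only for MDD-only recovery studies).
#' @param group_param_distributions A [cohort_distributions()]; either one
#'   object (shared) or a named list `list(mdd = , comparison = )`.
#' @param config A [foraging_config()].
#' @param rng_seed Master seed; per-participant substreams are derived
#'   deterministically from it.
#' @param couplings List of `list(param =, factor =, b =)` entries, e.g.
#'   `list(list(param = "c_high_cognitive", factor = "anxiety", b = -0.5))`.
#' @param simulate_trials If `FALSE`, skip trial simulation (cheap cohorts
#'   for statistics-only studies).
#' @return A list of class `ef_cohort` with elements `trials` (combined trial
#'   log), `truth` (true parameters and self-consistent thresholds), and
#'   `participants` (demographics, performance, latent symptom factors, raw
#'   HAMD-like overall depression total).
#' @export
simulate_cohort <- function(n_mdd, n_comparison,
                            group_param_distributions = cohort_distributions(),
                            config = foraging_config(),
                            rng_seed = 1L,
                            couplings = list(),
                            simulate_trials = TRUE) {
  if (!is.numeric(n_mdd) || n_mdd <= 0) stop("n_mdd must be > 0")
  if (!is.numeric(n_comparison) || n_comparison < 0) stop("n_comparison must be >= 0")
  validate_foraging_config(config)
  dists <- group_param_distributions
  if (inherits(dists, "cohort_distributions")) {
    dists <- list(mdd = dists, comparison = dists)
  }
  stopifnot(all(c("mdd", "comparison") %in% names(dists)))
  for (cp in couplings) {
    stopifnot(all(c("param", "factor", "b") %in% names(cp)))
    check_field(abs(cp$b) <= 1, "b", "coupling strengths must be in [-1, 1]")
  }

  groups <- c(rep("mdd", n_mdd), rep("comparison", n_comparison))
  ids <- sprintf("%s_%02d", ifelse(groups == "mdd", "mdd", "comp"),
                 c(seq_len(n_mdd), seq_len(max(n_comparison, 0))[seq_len(n_comparison)]))
  n <- length(ids)
  factors <- symptom_factor_names()

  participants <- with_seed(derive_seed(rng_seed, 1L), {
    lat <- matrix(stats::rnorm(n * length(factors)), n, length(factors),
                  dimnames = list(NULL, paste0("latent_", factors)))
    # comparison group sits lower on symptom severity
    lat[groups == "comparison", ] <- lat[groups == "comparison", ] * 0.7 - 0.8
    overall <- sqrt(0.5) * rowMeans(lat) / stats::sd(rowMeans(lat)) +
      sqrt(0.5) * stats::rnorm(n)
    df <- data.frame(
      participant_id = ids, group = groups,
      age = round(pmin(61, pmax(18, stats::rnorm(n, 27, 10)))),
      years_education = round(pmin(22, pmax(10, stats::rnorm(n, 15, 2)))),
      bmi = round(pmin(45, pmax(17, stats::rnorm(n, 25, 4))), 1),
      medication = ifelse(groups == "mdd", stats::rbinom(n, 1L, 0.5), 0L),
      current_mdd = ifelse(groups == "mdd", stats::rbinom(n, 1L, 0.85), 0L),
      dprime_3back = round(stats::rnorm(n, 2, 0.7), 2),
      pct_presses_completed = round(pmin(100, stats::rnorm(n, 90, 8)), 1),
      stringsAsFactors = FALSE
    )
    df$hamd_total <- round(pmax(0, ifelse(groups == "mdd", 14, 2) +
                                  5 * overall + stats::rnorm(n, 0, 2)))
    df$latent_overall_depression <- overall
    cbind(df, as.data.frame(lat))
  })

  truth <- with_seed(derive_seed(rng_seed, 2L), {
    draw_group <- function(g, idx) {
      d <- dists[[g]]
      k <- length(idx)
      r <- d$cost_correlation
      z1 <- stats::rnorm(k); z2 <- stats::rnorm(k)
      chc_z <- z1
      chp_z <- r * z1 + sqrt(1 - r^2) * z2
      data.frame(
        participant_id = ids[idx],
        c_low_cognitive = stats::rnorm(k, d$c_low_mean, d$c_low_sd),
        c_high_cognitive = d$c_high_mean + d$c_high_sd * chc_z,
        c_low_physical = stats::rnorm(k, d$c_low_mean, d$c_low_sd),
        c_high_physical = d$c_high_mean + d$c_high_sd * chp_z,
        log_beta = stats::rnorm(k, d$log_beta_mean, d$log_beta_sd),
        stringsAsFactors = FALSE
      )
    }
    tr <- rbind(draw_group("mdd", which(groups == "mdd")),
                if (n_comparison > 0) draw_group("comparison", which(groups == "comparison")))
    tr <- tr[match(ids, tr$participant_id), ]
    # plant symptom couplings: replace the standardized residual with a mix of
    # the latent factor and noise, preserving the marginal SD. The noise is
    # residualized against every latent factor and rescaled, so the realized
    # in-sample standardized slope is exactly b and the parameter's sample
    # correlation with every non-coupled factor is exactly zero (the planted
    # world contains the planted associations and no others).
    if (length(couplings)) {
      lat_mat <- as.matrix(participants[, paste0("latent_", factors)])
      for (cp in couplings) {
        d_m <- dists$mdd
        sd_p <- if (grepl("^c_low", cp$param)) d_m$c_low_sd else if (grepl("^c_high", cp$param)) d_m$c_high_sd else d_m$log_beta_sd
        mean_p <- if (grepl("^c_low", cp$param)) d_m$c_low_mean else if (grepl("^c_high", cp$param)) d_m$c_high_mean else d_m$log_beta_mean
        lat <- participants[[paste0("latent_", cp$factor)]]
        lat_z <- (lat - mean(lat)) / stats::sd(lat)
        eps <- stats::rnorm(n)
        eps <- stats::residuals(stats::lm(eps ~ lat_mat))
        eps <- eps / stats::sd(eps)
        tr[[cp$param]] <- mean_p + sd_p * (cp$b * lat_z +
                                             sqrt(1 - cp$b^2) * eps)
      }
    }
    tr$beta <- exp(tr$log_beta)
    tr
  })

  trials <- NULL
  thresholds <- NULL
  if (simulate_trials) {
    logs <- vector("list", n)
    ths <- vector("list", n)
    for (i in seq_len(n)) {
      pars <- mvt_params(truth$c_low_cognitive[i], truth$c_high_cognitive[i],
                         truth$c_low_physical[i], truth$c_high_physical[i],
                         beta = truth$beta[i])
      ag <- agent_spec(pars, threshold_mode = "self_consistent")
      logs[[i]] <- simulate_participant(ag, config,
                                        rng_seed = derive_seed(rng_seed, 100L + i),
                                        participant_id = ids[i])
      ths[[i]] <- attr(logs[[i]], "thresholds")
    }
    trials <- do.call(rbind, logs)
    rownames(trials) <- NULL
    thresholds <- do.call(rbind, ths)
    thresholds <- data.frame(participant_id = ids, thresholds,
                             check.names = FALSE, stringsAsFactors = FALSE)
    truth <- merge(truth, thresholds, by = "participant_id", sort = FALSE)
    truth <- truth[match(ids, truth$participant_id), ]
    rownames(truth) <- NULL
  }

  structure(list(trials = trials, truth = truth, participants = participants,
                 config = config, couplings = couplings, rng_seed = rng_seed),
            class = "ef_cohort")
}

#' @export
print.ef_cohort <- function(x, ...) {
  cat("<ef_cohort>\n")
  cat(sprintf("  participants : %d (%d MDD, %d comparison)\n",
              nrow(x$participants), sum(x$participants$group == "mdd"),
              sum(x$participants$group == "comparison")))
  if (!is.null(x$trials)) {
    cat(sprintf("  trials       : %d rows, %d blocks/participant\n",
                nrow(x$trials), max(x$trials$block)))
  }
  if (length(x$couplings)) {
    for (cp in x$couplings) {
      cat(sprintf("  coupling     : %s ~ %s (b = %.2f)\n", cp$param, cp$factor, cp$b))
    }
  }
  invisible(x)
}
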