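# Hierarchical Bayesian MVT model: adaptive Metropolis-within-Gibbs sampler.
#
# Per participant i the sampled parameters are
#   theta[i, ] = (c_low_cog, c_high_cog, c_low_phys, c_high_phys, log_beta)
# with likelihood over free trials
#   y ~ Bernoulli(plogis(beta * (R_e - rho_cond))),
#   rho_cond = A_cond - B_cond * c_cond,   c_cond = c_low (+ c_high if high)
# where A and B come from the participant's observed condition totals.
# Group level: independent normals for the low costs and log beta, and a
# bivariate normal with an LKJ(2) correlation prior for the two marginal
# high-effort costs (this exposes the cognitive-physical cost-correlation
# posterior). An optional group-difference variant adds a shift `delta` to
# the second group's means for every parameter.

PARAM_NAMES <- c("c_low_cognitive", "c_high_cognitive",
                 "c_low_physical", "c_high_physical", "log_beta")

#' Prior settings for the hierarchical MVT model
#'
#' Group-level cost means are Normal(0, 5 apples) with half-Normal(2.5) SDs;
#' log inverse temperature has a Normal(0, 1.5) mean and half-Normal(1) SD;
#' the correlation between the two marginal high-effort costs has an LKJ(2)
#' prior; group-difference shifts are Normal(0, 2.5).
#'
#' @param mu_c_sd,sigma_c_scale,mu_logbeta_sd,sigma_logbeta_scale,lkj_eta,delta_sd
#'   Prior hyperparameters (see description).
#' @return List of class `mvt_priors`.
#' @export
mvt_priors <- function(mu_c_sd = 5, sigma_c_scale = 2.5,
                       mu_logbeta_sd = 1.5, sigma_logbeta_scale = 1,
                       lkj_eta = 2, delta_sd = 2.5) {
  structure(list(mu_c_sd = mu_c_sd, sigma_c_scale = sigma_c_scale,
                 mu_logbeta_sd = mu_logbeta_sd,
                 sigma_logbeta_scale = sigma_logbeta_scale,
                 lkj_eta = lkj_eta, delta_sd = delta_sd),
            class = "mvt_priors")
}

# log density of a bivariate normal, vectorized over (x1, x2)
log_dbvn <- function(x1, x2, m1, m2, s1, s2, r) {
  z1 <- (x1 - m1) / s1
  z2 <- (x2 - m2) / s2
  -log(2 * pi) - log(s1) - log(s2) - 0.5 * log1p(-r^2) -
    (z1^2 - 2 * r * z1 * z2 + z2^2) / (2 * (1 - r^2))
}

#' Fit the hierarchical Bayesian MVT model
#'
#' Estimates per-participant effort costs, exit thresholds and inverse
#' temperatures from a trial log by MCMC (adaptive random-walk
#' Metropolis-within-Gibbs; scales adapt during warmup only). Point estimates
#' are posterior means. Convergence is gated on split-R-hat: any parameter
#' above `rhat_limit` raises a warning, never a silent pass.
#'
#' Participants with fewer than `min_exits` exit trials in any condition of
#' an effort type are dropped from that effort type (their trials are
#' ignored and the affected cost parameters reported as `NA`), with the
#' reason recorded in the returned `dropped` table.
#'
#' @param logs Trial-log data frame or CSV path (canonical schema).
#' @param config The [foraging_config()] the log was collected under.
#' @param groups Optional named vector or data frame mapping participants to
#'   diagnostic groups (needed for `group_difference`).
#' @param group_difference If `TRUE`, additionally sample a group-mean shift
#'   for every parameter (two groups required).
#' @param chains,warmup,iter MCMC settings (post-warmup draws per chain =
#'   `iter`).
#' @param sweeps Internal Metropolis sweeps per recorded iteration
#'   (thinning; improves mixing at fixed draw count).
#' @param rng_seed Integer seed.
#' @param priors An [mvt_priors()] object.
#' @param flat_priors If `TRUE`, drop the group level entirely and give every
#'   participant-level parameter an independent uniform prior over
#'   `c_bounds` (`log_beta` over `log_beta_bounds`); used for small-instance
#'   validation against grid integration.
#' @param fix_beta Optional positive number: fix every participant's inverse
#'   temperature instead of sampling it.
#' @param min_exits Minimum exit trials per condition (default 2).
#' @param rhat_limit Convergence gate (default 1.01).
#' @param c_bounds,log_beta_bounds Support bounds used by flat priors.
#' @return An object of class `mvt_fit`; see [mvt_point_estimates()],
#'   [posterior_predictive_check()], [loglik_group_compare()].
#' @export
fit_mvt_hierarchical <- function(logs, config,
                                 groups = NULL, group_difference = FALSE,
                                 chains = 2L, warmup = 500L, iter = 500L,
                                 sweeps = 10L,
                                 rng_seed = 1L, priors = mvt_priors(),
                                 flat_priors = FALSE, fix_beta = NULL,
                                 min_exits = 2L, rhat_limit = 1.01,
                                 c_bounds = c(-60, 60),
                                 log_beta_bounds = c(-4, 4)) {
  if (is.character(logs)) logs <- read_trial_log(logs)
  validate_foraging_config(config)
  stopifnot(chains >= 1L, warmup >= 10L, iter >= 10L)
  if (!is.null(fix_beta)) {
    check_field(is.numeric(fix_beta) && is.finite(fix_beta) && fix_beta > 0,
                "fix_beta", "must be a finite positive number")
  }
  logs <- ensure_log_columns(logs, config)
  participants <- unique(logs$participant_id)

  group_vec <- NULL
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      group_vec <- stats::setNames(as.character(groups$group), groups$participant_id)[participants]
    } else {
      group_vec <- as.character(groups[participants])
    }
  }
  if (group_difference) {
    if (is.null(group_vec) || length(unique(stats::na.omit(group_vec))) != 2L) {
      stop("group_difference requires exactly two groups")
    }
  }

  dat <- prepare_mvt_data(logs, config, participants)
  P <- dat$P
  ncond <- length(dat$conds)

  # effort-type exclusion: too few exits in any condition of that type
  dropped <- data.frame(participant_id = character(), effort_type = character(),
                        reason = character(), stringsAsFactors = FALSE)
  for (k in seq_len(ncond)) {
    cd <- dat$conds[[k]]
    bad <- which(cd$n_exits < min_exits)
    for (i in bad) {
      dropped <- rbind(dropped, data.frame(
        participant_id = participants[i], effort_type = cd$effort_type,
        reason = sprintf("%d exit(s) in %s %s (min %d)", cd$n_exits[i],
                         cd$effort_type, cd$effort_level, min_exits),
        stringsAsFactors = FALSE))
    }
  }
  excluded <- unique(dropped[, c("participant_id", "effort_type")])
  for (k in seq_len(ncond)) {
    cd <- dat$conds[[k]]
    bad <- excluded$participant_id[excluded$effort_type == cd$effort_type]
    idx <- match(bad, participants)
    if (length(idx)) dat$conds[[k]]$W[idx, ] <- 0
  }
  if (nrow(dropped)) {
    message(sprintf("dropped %d participant x effort-type combinations (see $dropped)",
                    nrow(excluded)))
  }

  cost_idx <- list(c(1L, 2L), c(3L, 4L))  # (low, high marginal) per effort type
  type_of_cond <- vapply(dat$conds, function(cd)
    match(cd$effort_type, c("cognitive", "physical")), integer(1))
  high_of_cond <- vapply(dat$conds, function(cd)
    identical(cd$effort_level, "high"), logical(1))

  cond_cost_vec <- function(theta, k) {
    ci <- cost_idx[[type_of_cond[k]]]
    theta[, ci[1L]] + if (high_of_cond[k]) theta[, ci[2L]] else 0
  }
  all_cond_loglik <- function(theta, beta_vec) {
    matrix(vapply(seq_len(ncond), function(k)
      cond_loglik(dat$conds[[k]], cond_cost_vec(theta, k), beta_vec),
      numeric(P)), P, ncond)
  }

  # --- prior machinery ------------------------------------------------------
  np_group <- if (flat_priors) 0L else (11L + if (group_difference) 5L else 0L)
  group_names <- if (np_group) {
    c(paste0("mu_", PARAM_NAMES), paste0("log_sigma_", PARAM_NAMES), "z_cost_cor",
      if (group_difference) paste0("delta_", PARAM_NAMES))
  } else character()

  grp2 <- if (group_difference) {
    lv <- sort(unique(stats::na.omit(group_vec)))
    as.numeric(group_vec == lv[2L])
  } else rep(0, P)

  part_means <- function(g) {
    mu <- g[1:5]
    if (group_difference) {
      outer(grp2, g[12:16]) + matrix(mu, P, 5L, byrow = TRUE)
    } else {
      matrix(mu, P, 5L, byrow = TRUE)
    }
  }

  # per-participant log prior, component-wise where possible
  logprior_theta <- function(theta, g) {
    if (flat_priors) {
      ok <- theta[, 1:4, drop = FALSE] >= c_bounds[1L] & theta[, 1:4, drop = FALSE] <= c_bounds[2L]
      okb <- theta[, 5L] >= log_beta_bounds[1L] & theta[, 5L] <= log_beta_bounds[2L]
      return(ifelse(rowSums(ok) == 4L & okb, 0, -Inf))
    }
    m <- part_means(g)
    s <- exp(g[6:10])
    r <- tanh(g[11L])
    stats::dnorm(theta[, 1L], m[, 1L], s[1L], log = TRUE) +
      stats::dnorm(theta[, 3L], m[, 3L], s[3L], log = TRUE) +
      stats::dnorm(theta[, 5L], m[, 5L], s[5L], log = TRUE) +
      log_dbvn(theta[, 2L], theta[, 4L], m[, 2L], m[, 4L], s[2L], s[4L], r)
  }

  logprior_group <- function(g) {
    if (flat_priors) return(0)
    s <- exp(g[6:10])
    r <- tanh(g[11L])
    lp <- sum(stats::dnorm(g[1:4], 0, priors$mu_c_sd, log = TRUE)) +
      stats::dnorm(g[5L], 0, priors$mu_logbeta_sd, log = TRUE) +
      # half-normal on sigma, with log-scale Jacobian
      sum(stats::dnorm(s[1:4], 0, priors$sigma_c_scale, log = TRUE) + g[6:9]) +
      stats::dnorm(s[5L], 0, priors$sigma_logbeta_scale, log = TRUE) + g[10L] +
      # LKJ(eta) on the 2x2 correlation, with tanh Jacobian
      (priors$lkj_eta - 1) * log1p(-r^2) + log1p(-r^2)
    if (group_difference) lp <- lp + sum(stats::dnorm(g[12:16], 0, priors$delta_sd, log = TRUE))
    lp
  }

  sample_beta <- is.null(fix_beta)
  n_draw_par <- P * 5L + np_group

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    theta <- cbind(matrix(stats::rnorm(P * 4L, 0, 1), P, 4L),
                   if (sample_beta) stats::rnorm(P, 0, 0.3) else rep(log(fix_beta), P))
    g <- if (np_group) c(rep(0, 5L), rep(0, 5L), 0, rep(0, np_group - 11L)) else numeric()
    beta_vec <- exp(theta[, 5L])
    CL <- all_cond_loglik(theta, beta_vec)
    scales <- matrix(c(rep(2, 4L), 0.3), P, 5L, byrow = TRUE)
    gscales <- rep(0.25, np_group)

    th_draws <- array(NA_real_, c(iter, P, 5L))
    g_draws <- if (np_group) matrix(NA_real_, iter, np_group) else NULL
    ll_draws <- matrix(NA_real_, iter, P)
    rho_draws <- array(NA_real_, c(iter, P, ncond))

    total <- warmup + iter
    sweep_count <- 0L
    blocks <- list(list(cols = 1L, conds = which(type_of_cond == 1L)),
                   list(cols = 3L, conds = which(type_of_cond == 2L)),
                   list(cols = c(2L, 4L), conds = which(high_of_cond)),
                   if (sample_beta) list(cols = 5L, conds = seq_len(ncond)))
    blocks <- Filter(Negate(is.null), blocks)

    for (s in seq_len(total)) {
      adapt <- s <= warmup
      for (sw in seq_len(sweeps)) {
      sweep_count <- sweep_count + 1L
      gam <- if (adapt) 1 / sweep_count^0.6 else 0
      for (b in blocks) {
        cols <- b$cols
        prop <- theta
        for (cl in cols) prop[, cl] <- theta[, cl] + scales[, cl] * stats::rnorm(P)
        beta_prop <- if (5L %in% cols) exp(prop[, 5L]) else beta_vec
        dll <- numeric(P)
        newCL <- CL
        for (k in b$conds) {
          newCL[, k] <- cond_loglik(dat$conds[[k]], cond_cost_vec(prop, k), beta_prop)
          dll <- dll + newCL[, k] - CL[, k]
        }
        dlp <- logprior_theta(prop, g) - logprior_theta(theta, g)
        lr <- dll + dlp
        lr[!is.finite(lr)] <- -Inf
        acc <- log(stats::runif(P)) < lr
        if (any(acc)) {
          theta[acc, cols] <- prop[acc, cols, drop = FALSE]
          CL[acc, b$conds] <- newCL[acc, b$conds, drop = FALSE]
          if (5L %in% cols) beta_vec[acc] <- beta_prop[acc]
        }
        if (adapt) {
          target <- if (length(cols) > 1L) 0.3 else 0.44
          scales[, cols] <- scales[, cols] *
            exp(gam * (pmin(1, exp(lr)) - target))
        }
      }
      if (np_group) {
        lp_theta <- sum(logprior_theta(theta, g))
        lp_g <- logprior_group(g)
        for (j in seq_len(np_group)) {
          gp <- g
          gp[j] <- g[j] + gscales[j] * stats::rnorm(1L)
          lp_theta_p <- sum(logprior_theta(theta, gp))
          lp_g_p <- logprior_group(gp)
          lr <- (lp_theta_p + lp_g_p) - (lp_theta + lp_g)
          if (!is.finite(lr)) lr <- -Inf
          a <- log(stats::runif(1L)) < lr
          if (a) {
            g <- gp
            lp_theta <- lp_theta_p
            lp_g <- lp_g_p
          }
          if (adapt) gscales[j] <- gscales[j] * exp(gam * (min(1, exp(lr)) - 0.44))
        }
      }
      }
      if (s > warmup) {
        d <- s - warmup
        th_draws[d, , ] <- theta
        if (np_group) g_draws[d, ] <- g
        ll_draws[d, ] <- rowSums(CL)
        for (k in seq_len(ncond)) {
          rho_draws[d, , k] <- dat$conds[[k]]$A - dat$conds[[k]]$B * cond_cost_vec(theta, k)
        }
      }
    }
    list(theta = th_draws, g = g_draws, ll = ll_draws, rho = rho_draws)
  }

  chains_out <- lapply(seq_len(chains), function(ch)
    run_chain(derive_seed(rng_seed, 1000L + ch)))

  build_mvt_fit(chains_out, dat, config, participants, group_vec,
                group_difference, group_names, flat_priors, fix_beta,
                excluded, dropped, priors, rhat_limit,
                settings = list(chains = chains, warmup = warmup, iter = iter,
                                sweeps = sweeps, rng_seed = rng_seed,
                                min_exits = min_exits))
}

# Assemble summaries, diagnostics and the S3 object from raw chain output.
build_mvt_fit <- function(chains_out, dat, config, participants, group_vec,
                          group_difference, group_names, flat_priors, fix_beta,
                          excluded, dropped, priors, rhat_limit, settings) {
  P <- dat$P
  ncond <- length(dat$conds)
  chains <- length(chains_out)
  iter <- dim(chains_out[[1L]]$theta)[1L]

  gather <- function(f) do.call(rbind, lapply(chains_out, f))  # pooled draws
  chain_mat <- function(f) vapply(chains_out, f, numeric(iter)) # iter x chains

  summarize_param <- function(get_draws) {
    pooled <- gather(get_draws)
    rh <- split_rhat(chain_mat(get_draws))
    c(mean = mean(pooled), sd = stats::sd(pooled),
      hdi_interval(pooled), rhat = rh)
  }

  rows <- list()
  excl_key <- paste(excluded$participant_id, excluded$effort_type)
  for (i in seq_len(P)) {
    for (j in seq_along(PARAM_NAMES)) {
      pn <- PARAM_NAMES[j]
      et <- if (grepl("cognitive", pn)) "cognitive" else if (grepl("physical", pn)) "physical" else NA
      is_excl <- !is.na(et) && paste(participants[i], et) %in% excl_key
      if (pn == "log_beta" && !is.null(fix_beta)) {
        st <- c(mean = log(fix_beta), sd = 0, lower = log(fix_beta),
                upper = log(fix_beta), rhat = 1)
      } else if (is_excl) {
        st <- c(mean = NA, sd = NA, lower = NA, upper = NA, rhat = NA)
      } else {
        st <- summarize_param(function(ch) ch$theta[, i, j])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = participants[i], parameter = pn,
        mean = st[[1L]], sd = st[[2L]], hdi_lower = st[[3L]],
        hdi_upper = st[[4L]], rhat = st[[5L]], stringsAsFactors = FALSE)
    }
    for (k in seq_len(ncond)) {
      cd <- dat$conds[[k]]
      is_excl <- paste(participants[i], cd$effort_type) %in% excl_key
      st <- if (is_excl) c(NA, NA, NA, NA, NA) else
        summarize_param(function(ch) ch$rho[, i, k])
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = participants[i],
        parameter = paste0("rho_", cond_key(cd$effort_type, cd$effort_level)),
        mean = st[[1L]], sd = st[[2L]], hdi_lower = st[[3L]],
        hdi_upper = st[[4L]], rhat = st[[5L]], stringsAsFactors = FALSE)
    }
    st <- summarize_param(function(ch) ch$ll[, i])
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = participants[i], parameter = "log_posterior_likelihood",
      mean = st[[1L]], sd = st[[2L]], hdi_lower = st[[3L]], hdi_upper = st[[4L]],
      rhat = st[[5L]], stringsAsFactors = FALSE)
  }
  summary_df <- do.call(rbind, rows)

  group_summary <- NULL
  correlation <- NULL
  if (length(group_names)) {
    grows <- lapply(seq_along(group_names), function(j) {
      st <- summarize_param(function(ch) ch$g[, j])
      data.frame(parameter = group_names[j], mean = st[[1L]], sd = st[[2L]],
                 hdi_lower = st[[3L]], hdi_upper = st[[4L]], rhat = st[[5L]],
                 stringsAsFactors = FALSE)
    })
    group_summary <- do.call(rbind, grows)
    # natural-scale rows for SDs and the cost correlation
    r_draws <- tanh(gather(function(ch) ch$g[, 11L]))
    correlation <- c(mean = mean(r_draws), hdi_interval(r_draws))
  }

  max_rhat <- suppressWarnings(max(summary_df$rhat, na.rm = TRUE))
  if (is.finite(max_rhat) && max_rhat > rhat_limit) {
    warning(sprintf("convergence not reached: max split-R-hat = %.3f (limit %.2f); increase warmup/iter",
                    max_rhat, rhat_limit))
  }

  structure(list(summary = summary_df, group_summary = group_summary,
                 cost_correlation = correlation,
                 chains_out = chains_out, data = dat, config = config,
                 participants = participants, groups = group_vec,
                 group_difference = group_difference,
                 group_names = group_names,
                 dropped = dropped, excluded = excluded,
                 flat_priors = flat_priors, fix_beta = fix_beta,
                 priors = priors, settings = settings,
                 max_rhat = max_rhat),
            class = "mvt_fit")
}

#' @export
print.mvt_fit <- function(x, ...) {
  cat("<mvt_fit>\n")
  cat(sprintf("  participants : %d (%d effort-type exclusions)\n",
              length(x$participants), nrow(x$excluded)))
  cat(sprintf("  draws        : %d chains x %d post-warmup\n",
              x$settings$chains, x$settings$iter))
  cat(sprintf("  max R-hat    : %.3f\n", x$max_rhat))
  if (!is.null(x$cost_correlation)) {
    cat(sprintf("  cog-phys marginal cost correlation: %.3f [%.3f, %.3f] (95%% HDI)\n",
                x$cost_correlation[["mean"]], x$cost_correlation[["lower"]],
                x$cost_correlation[["upper"]]))
  }
  if (x$group_difference) cat("  group-difference shifts sampled (delta_*)\n")
  invisible(x)
}

#' Per-participant posterior-mean point estimates
#'
#' @param fit An `mvt_fit`.
#' @return Wide data frame: one row per participant with posterior means of
#'   costs, `beta` (posterior mean of `exp(log_beta)`), per-condition exit
#'   thresholds and the per-participant log posterior likelihood.
#' @export
mvt_point_estimates <- function(fit) {
  stopifnot(inherits(fit, "mvt_fit"))
  s <- fit$summary
  wide <- stats::reshape(s[, c("participant_id", "parameter", "mean")],
                         idvar = "participant_id", timevar = "parameter",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  # beta on the natural scale (posterior mean of exp(log_beta))
  beta_means <- vapply(seq_along(fit$participants), function(i) {
    mean(exp(unlist(lapply(fit$chains_out, function(ch) ch$theta[, i, 5L]))))
  }, numeric(1))
  wide$beta <- if (is.null(fit$fix_beta)) beta_means else fit$fix_beta
  wide[match(fit$participants, wide$participant_id), , drop = FALSE]
}

#' Fit the MVT model with explicit group-mean differences
#'
#' Convenience wrapper around [fit_mvt_hierarchical()] with
#' `group_difference = TRUE`: for every model parameter a shift between the
#' two groups' means is sampled directly inside the hierarchy (guarding the
#' frequentist group contrasts against hierarchical shrinkage artefacts).
#'
#' @inheritParams fit_mvt_hierarchical
#' @param ... Passed to [fit_mvt_hierarchical()].
#' @return An `mvt_fit`; shift posteriors are the `delta_*` rows of
#'   `$group_summary`, also returned tidily by [group_shift_summary()].
#' @export
fit_mvt_group_difference <- function(logs, config, groups, ...) {
  fit_mvt_hierarchical(logs, config, groups = groups, group_difference = TRUE, ...)
}

#' Tidy table of group-shift posteriors
#'
#' @param fit An `mvt_fit` fitted with `group_difference = TRUE`.
#' @return Data frame of the `delta_*` shift parameters with posterior mean,
#'   SD and 95% HDI; `covers_zero` flags HDIs containing 0.
#' @export
group_shift_summary <- function(fit) {
  stopifnot(inherits(fit, "mvt_fit"))
  if (!fit$group_difference) stop("fit was not run with group_difference = TRUE")
  gs <- fit$group_summary
  out <- gs[grepl("^delta_", gs$parameter), , drop = FALSE]
  out$covers_zero <- out$hdi_lower <= 0 & out$hdi_upper >= 0
  rownames(out) <- NULL
  out
}
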