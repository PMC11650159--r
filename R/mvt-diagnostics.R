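#' Posterior predictive check of the fitted MVT model
#'
#' Simulates replicated choice data from posterior draws at the observed
#' expected-reward trials and compares the observed overall harvest rate
#' (across participants and free trials) to its replicate distribution. Also
#' returns per-condition replicate distributions of the mean expected reward
#' on exit trials (an exit-threshold proxy).
#'
#' @param fit An `mvt_fit`.
#' @param logs Optional trial log to compute the observed statistics on
#'   (defaults to the data the model was fitted to); lets the fitted model
#'   be checked against external or corrupted data.
#' @param n_rep Number of replicated datasets (posterior draws used).
#' @param rng_seed Integer seed.
#' @return List of class `mvt_ppc`: `observed` (harvest rate), `replicates`,
#'   `pd` (tail probability: the smaller of the two one-sided replicate tail
#'   fractions at the observed value), and `exit_thresholds` (per-condition
#'   observed mean exit expected reward with replicate mean and 95% interval).
#' @export
posterior_predictive_check <- function(fit, logs = NULL, n_rep = 200L,
                                       rng_seed = 1L) {
  stopifnot(inherits(fit, "mvt_fit"))
  if (n_rep <= 0) stop("n_rep must be a positive number of posterior draws")
  dat <- if (is.null(logs)) fit$data else
    prepare_mvt_data(logs, fit$config, fit$participants)
  ncond <- length(dat$conds)
  P <- dat$P
  theta_all <- do.call(rbind, lapply(fit$chains_out, function(ch) {
    matrix(ch$theta, nrow = dim(ch$theta)[1L])
  }))
  ndraw <- nrow(theta_all)
  obs_harv <- 0
  obs_n <- 0
  obs_exit_re <- numeric(ncond)
  for (k in seq_len(ncond)) {
    cd <- dat$conds[[k]]
    obs_harv <- obs_harv + sum(cd$W * (cd$S == 1))
    obs_n <- obs_n + sum(cd$W)
    ex <- cd$W == 1 & cd$S == -1
    obs_exit_re[k] <- if (any(ex)) mean(cd$Re[ex]) else NA_real_
  }
  observed <- obs_harv / obs_n

  with_seed(rng_seed, {
    idx <- sample.int(ndraw, n_rep, replace = n_rep > ndraw)
    rep_rate <- numeric(n_rep)
    rep_exit <- matrix(NA_real_, n_rep, ncond)
    for (r in seq_len(n_rep)) {
      th <- matrix(theta_all[idx[r], ], P, 5L)
      beta_vec <- exp(th[, 5L])
      tot_h <- 0
      tot_n <- 0
      for (k in seq_len(ncond)) {
        cd <- dat$conds[[k]]
        cc <- th[, if (cd$effort_type == "cognitive") 1L else 3L] +
          (if (cd$effort_level == "high")
            th[, if (cd$effort_type == "cognitive") 2L else 4L] else 0)
        p <- stats::plogis(beta_vec * (cd$Re - (cd$A - cd$B * cc)))
        y <- matrix(stats::runif(length(p)) < p, nrow(p), ncol(p))
        tot_h <- tot_h + sum(cd$W * y)
        tot_n <- tot_n + sum(cd$W)
        ex <- cd$W == 1 & !y
        rep_exit[r, k] <- if (any(ex)) mean(cd$Re[ex]) else NA_real_
      }
      rep_rate[r] <- tot_h / tot_n
    }
    pd <- min(mean(rep_rate >= observed), mean(rep_rate <= observed))
    exit_tab <- data.frame(
      condition = dat$keys,
      observed = obs_exit_re,
      replicate_mean = colMeans(rep_exit, na.rm = TRUE),
      replicate_lower = apply(rep_exit, 2, stats::quantile, 0.025, na.rm = TRUE),
      replicate_upper = apply(rep_exit, 2, stats::quantile, 0.975, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
    structure(list(observed = observed, replicates = rep_rate, pd = pd,
                   exit_thresholds = exit_tab, n_rep = n_rep),
              class = "mvt_ppc")
  })
}

#' @export
print.mvt_ppc <- function(x, ...) {
  cat("<mvt_ppc>\n")
  cat(sprintf("  observed harvest rate : %.4f\n", x$observed))
  cat(sprintf("  replicate range       : [%.4f, %.4f] (%d reps)\n",
              min(x$replicates), max(x$replicates), x$n_rep))
  cat(sprintf("  pd                    : %.3f\n", x$pd))
  invisible(x)
}

#' Compare model goodness of fit between diagnostic groups
#'
#' Welch unpaired t-test on the per-participant log posterior likelihoods.
#'
#' @param fit An `mvt_fit`.
#' @param groups Named vector or `participant_id`/`group` data frame.
#' @return List with `t`, `df` (non-integer, Welch), `p`, and group means.
#' @export
loglik_group_compare <- function(fit, groups) {
  stopifnot(inherits(fit, "mvt_fit"))
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$participant_id)
  }
  s <- fit$summary
  ll <- s$mean[s$parameter == "log_posterior_likelihood"]
  gl <- as.character(groups[fit$participants])
  keep <- !is.na(gl) & !is.na(ll)
  gl <- gl[keep]
  ll <- ll[keep]
  tab <- table(gl)
  if (length(tab) != 2L) stop("exactly two groups required")
  if (any(tab < 2L)) stop("each group needs at least 2 participants")
  tt <- stats::t.test(ll ~ gl)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, group_means = tapply(ll, gl, mean))
}
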