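#' Per-participant MVT parameters
#'
#' Travel (effort) costs are in apples. High-effort costs are *marginal*: the
#' total travel cost in a high-effort block is `c_low + c_high` for that
#' effort type, so `c_high` isolates the extra subjective cost of the harder
#' travel task. Costs may be negative (effort seeking). `beta` is the softmax
#' inverse temperature (1/apples); larger values give more deterministic
#' patch-leaving around the threshold.
#'
#' @param c_low_cognitive,c_high_cognitive,c_low_physical,c_high_physical
#'   Travel costs (apples); `c_high_*` are marginal increases over the
#'   low-effort cost.
#' @param beta Inverse temperature (> 0).
#' @return An object of class `mvt_params`.
#' @export
mvt_params <- function(c_low_cognitive = 0, c_high_cognitive = 0,
                       c_low_physical = 0, c_high_physical = 0,
                       beta = 1) {
  for (f in c("c_low_cognitive", "c_high_cognitive", "c_low_physical", "c_high_physical")) {
    v <- get(f)
    check_field(is.numeric(v) && length(v) == 1L && is.finite(v), f, "must be finite")
  }
  check_field(is.numeric(beta) && length(beta) == 1L && is.finite(beta) && beta > 0,
              "beta", "must be a finite positive number")
  structure(list(c_low_cognitive = c_low_cognitive,
                 c_high_cognitive = c_high_cognitive,
                 c_low_physical = c_low_physical,
                 c_high_physical = c_high_physical,
                 beta = beta),
            class = "mvt_params")
}

cond_key <- function(effort_type, effort_level) paste(effort_type, effort_level, sep = "_")

# Total travel cost applying to one condition (low cost, plus the marginal
# high cost in high-effort blocks).
condition_cost <- function(params, effort_type, effort_level) {
  base <- params[[paste0("c_low_", effort_type)]]
  if (identical(effort_level, "high")) base + params[[paste0("c_high_", effort_type)]] else base
}

#' Specify a simulated foraging agent
#'
#' An agent harvests while the expected next reward exceeds its per-condition
#' exit threshold, choosing stochastically through a softmax with its inverse
#' temperature. Thresholds are either supplied (`threshold_mode = "fixed"`,
#' named `type_level` vector) or solved self-consistently: the threshold that
#' the fitted model defines from realized condition totals must match the
#' threshold the agent used to generate them, so we iterate
#' simulate-recompute to a fixed point (see [solve_agent_thresholds()]).
#'
#' @param params An [mvt_params()] object (the agent's true parameters).
#' @param threshold_mode `"self_consistent"` (default) or `"fixed"`.
#' @param thresholds Named numeric vector (names like `"cognitive_low"`)
#'   required when `threshold_mode = "fixed"`.
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(params, threshold_mode = c("self_consistent", "fixed"),
                       thresholds = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(inherits(params, "mvt_params"))
  if (threshold_mode == "fixed") {
    check_field(is.numeric(thresholds) && !is.null(names(thresholds)) &&
                  all(is.finite(thresholds)),
                "thresholds", "fixed mode needs a named finite numeric vector")
  }
  structure(list(params = params, threshold_mode = threshold_mode,
                 thresholds = thresholds),
            class = "agent_spec")
}

# Simulate one timed block under a fixed threshold. Uses the current RNG
# stream; callers are responsible for seeding. Returns a data.frame in the
# canonical trial-log schema plus `reward` and `patch` columns.
simulate_block <- function(params, rho, effort_type, effort_level, config,
                           participant_id = "p1", block_id = 1L,
                           block_seed = NULL) {
  kappa <- config$decay_alpha / (config$decay_alpha + config$decay_beta)
  beta <- params$beta
  if (!is.finite(rho)) stop("non-finite threshold 'rho' for condition ",
                            cond_key(effort_type, effort_level))
  if (!is.finite(beta)) stop("non-finite parameter 'beta'")
  rows <- vector("list", 512L)
  n <- 0L
  t <- 0
  trial <- 0L
  patch_id <- 0L
  emit <- function(action, first, last_reward, expected, reward) {
    n <<- n + 1L
    if (n > length(rows)) length(rows) <<- 2L * n
    rows[[n]] <<- list(trial = trial, last_reward = last_reward,
                       expected_reward = expected, action = action,
                       first_harvest = first, reward = reward,
                       patch = patch_id)
  }
  enter_patch <- function() {
    patch_id <<- patch_id + 1L
    # per-patch substreams: under common random numbers a threshold change
    # merely truncates or extends individual patches instead of cascading
    # through the whole block, keeping the self-consistency fixed point tame
    if (!is.null(block_seed)) set.seed(derive_seed(block_seed, 1000L + patch_id))
    p <- sample_patch(config)
    trial <<- trial + 1L
    t <<- t + config$harvest_duration
    emit("harvest", TRUE, NA_real_, NA_real_, p$current_reward)
    p
  }
  patch <- enter_patch()
  while (t < config$block_duration) {
    last <- patch$current_reward
    expected <- last * kappa
    trial <- trial + 1L
    if (config$missed_rate > 0 && stats::runif(1L) < config$missed_rate) {
      t <- t + config$harvest_duration
      emit("missed", FALSE, last, expected, NA_real_)
      next
    }
    p_harvest <- stats::plogis(beta * (expected - rho))
    if (stats::runif(1L) < p_harvest) {
      res <- harvest_patch(patch, config)
      patch <- res$patch
      t <- t + config$harvest_duration
      emit("harvest", FALSE, last, expected, res$reward)
    } else {
      emit("exit", FALSE, last, expected, NA_real_)
      t <- t + config$travel_duration
      if (t < config$block_duration) patch <- enter_patch()
    }
  }
  rows <- rows[seq_len(n)]
  out <- data.frame(
    participant_id = participant_id,
    block = block_id,
    effort_type = effort_type,
    effort_level = effort_level,
    trial = vapply(rows, `[[`, integer(1), "trial"),
    last_reward = vapply(rows, `[[`, numeric(1), "last_reward"),
    expected_reward = vapply(rows, `[[`, numeric(1), "expected_reward"),
    action = vapply(rows, `[[`, character(1), "action"),
    first_harvest = vapply(rows, `[[`, logical(1), "first_harvest"),
    reward = vapply(rows, `[[`, numeric(1), "reward"),
    patch = vapply(rows, `[[`, integer(1), "patch"),
    stringsAsFactors = FALSE
  )
  out
}

# Simulate a whole session (all blocks of the given plan) with fixed
# thresholds, using the current RNG stream.
simulate_session <- function(params, rho, plan, config, participant_id = "p1",
                             base_seed = NULL) {
  logs <- vector("list", nrow(plan))
  for (b in seq_len(nrow(plan))) {
    key <- cond_key(plan$effort_type[b], plan$effort_level[b])
    # per-block substreams: one condition's threshold cannot perturb another
    # condition's random draws, which keeps the threshold fixed point stable
    bs <- if (is.null(base_seed)) NULL else derive_seed(base_seed, 70L + b)
    logs[[b]] <- with_seed(
      bs,
      simulate_block(params, rho[[key]], plan$effort_type[b],
                     plan$effort_level[b], config,
                     participant_id = participant_id, block_id = b,
                     block_seed = bs))
  }
  do.call(rbind, logs)
}

# Realized thresholds implied by a session log: (sum rewards - n_travels * c) / T
implied_thresholds <- function(log, params, config) {
  conds <- config$conditions
  keys <- cond_key(conds$effort_type, conds$effort_level)
  Tp <- config$n_blocks_per_condition * config$block_duration / config$harvest_duration
  out <- stats::setNames(numeric(nrow(conds)), keys)
  for (i in seq_len(nrow(conds))) {
    d <- log[log$effort_type == conds$effort_type[i] &
               log$effort_level == conds$effort_level[i], , drop = FALSE]
    ccond <- condition_cost(params, conds$effort_type[i], conds$effort_level[i])
    total_r <- sum(d$reward[d$action == "harvest"], na.rm = TRUE)
    n_travel <- sum(d$action == "exit")
    out[keys[i]] <- (total_r - n_travel * ccond) / Tp
  }
  out
}

#' Solve self-consistent agent thresholds by fixed-point iteration
#'
#' The per-condition exit threshold is defined from realized condition totals
#' as `rho = (sum(rewards) - n_travels * c_cond) / T`, with
#' `T = condition duration / harvest duration` the number of harvest periods.
#' An agent's behaviour depends on `rho`, and `rho` on behaviour, so we
#' iterate: simulate the full session at the current `rho`, recompute `rho`
#' from the realized totals, and repeat until the largest discrepancy is
#' below `tol` apples or `max_iter` iterations. Common random numbers (the
#' session is replayed from the same seed every iteration) make the iterated
#' map deterministic; because the map is piecewise constant in `rho`
#' (trajectories change in discrete jumps), iterations either converge
#' exactly or settle into a small cycle, in which case damped steps are used
#' and the residual discrepancy is reported.
#'
#' @param params [mvt_params()].
#' @param config [foraging_config()].
#' @param rng_seed Seed for the common-random-number session replays.
#' @param tol,max_iter Convergence controls (defaults 1e-3 apples, 50).
#' @param plan Optional block plan (data frame of `effort_type`,
#'   `effort_level` per block); defaults to the config's conditions in order.
#' @return Named numeric vector of thresholds (apples) with attributes
#'   `"iterations"`, `"converged"`, `"delta"` (final residual, apples) and
#'   `"log"` (the session simulated at the returned thresholds). A warning
#'   is raised only when the residual exceeds 0.05 apples.
#' @export
solve_agent_thresholds <- function(params, config, rng_seed = 1L,
                                   tol = 1e-3, max_iter = 50L, plan = NULL) {
  validate_foraging_config(config)
  conds <- config$conditions
  keys <- cond_key(conds$effort_type, conds$effort_level)
  if (is.null(plan)) {
    plan <- conds[rep(seq_len(nrow(conds)), each = config$n_blocks_per_condition), ,
                  drop = FALSE]
  }
  rho <- stats::setNames(rep(config$initial_reward_mean * 0.3, nrow(conds)), keys)
  converged <- FALSE
  delta <- Inf
  log <- NULL
  best <- list(delta = Inf, rho = rho, log = NULL, it = 0L)
  for (it in seq_len(max_iter)) {
    log <- simulate_session(params, rho, plan, config,
                            base_seed = derive_seed(rng_seed, 7L))
    implied <- implied_thresholds(log, params, config)
    delta <- max(abs(implied - rho))
    if (delta < best$delta) best <- list(delta = delta, rho = rho, log = log, it = it)
    if (delta < tol) {
      converged <- TRUE
      break
    }
    # the map is piecewise constant in rho, so full steps either land on an
    # exact fixed point or enter a small cycle; stop once a cycle is evident
    if (it - best$it >= 8L) break
    step <- if (it <= 20L) 1 else 0.5
    rho <- rho + step * (implied - rho)
  }
  if (!converged) {
    rho <- best$rho
    log <- best$log
    delta <- best$delta
    it <- best$it
  }
  if (!converged && delta > 0.05) {
    warning(sprintf("threshold fixed point residual %.3g apples after %d iterations (tol %g)",
                    delta, max_iter, tol))
  }
  attr(rho, "iterations") <- it
  attr(rho, "converged") <- converged
  attr(rho, "delta") <- delta
  attr(rho, "log") <- log
  rho
}

#' Simulate one participant's full session
#'
#' Plays every block of every condition (block order randomly permuted per
#' participant) with MVT-softmax choices: on each free trial the probability
#' of harvesting is `plogis(beta * (expected_reward - rho_condition))`; the
#' first harvest of each patch is forced and flagged. In
#' `"self_consistent"` mode the thresholds are solved on the session itself
#' (see [solve_agent_thresholds()]), so the returned log realizes the
#' thresholds it was generated under.
#'
#' @param agent An [agent_spec()].
#' @param config A [foraging_config()].
#' @param rng_seed Integer seed.
#' @param participant_id Identifier written into the log.
#' @return A trial-log data frame (canonical schema plus `reward`, `patch`),
#'   with the resolved thresholds in attribute `"thresholds"`.
#' @export
simulate_participant <- function(agent, config, rng_seed = NULL,
                                 participant_id = "p1") {
  stopifnot(inherits(agent, "agent_spec"))
  validate_foraging_config(config)
  conds <- config$conditions
  keys <- cond_key(conds$effort_type, conds$effort_level)
  seed <- if (is.null(rng_seed)) stats::runif(1L, 1, 2^30) else rng_seed
  plan <- with_seed(derive_seed(seed, 3L), {
    p <- conds[rep(seq_len(nrow(conds)), each = config$n_blocks_per_condition), ,
               drop = FALSE]
    p[sample.int(nrow(p)), , drop = FALSE]
  })
  if (agent$threshold_mode == "fixed") {
    missing <- setdiff(keys, names(agent$thresholds))
    if (length(missing)) stop("fixed thresholds missing for: ", paste(missing, collapse = ", "))
    rho <- agent$thresholds[keys]
    out <- simulate_session(agent$params, rho, plan, config,
                            participant_id = participant_id,
                            base_seed = derive_seed(seed, 7L))
  } else {
    rho <- solve_agent_thresholds(agent$params, config, rng_seed = seed,
                                  plan = plan)
    out <- attr(rho, "log")
    out$participant_id <- participant_id
    attr(rho, "log") <- NULL
  }
  out$block <- as.integer(factor(out$block, levels = unique(out$block)))
  attr(out, "thresholds") <- rho
  out
}
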