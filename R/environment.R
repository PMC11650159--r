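#' Foraging environment configuration
#'
#' Builds the orchard environment used by the Effort Foraging Task. A block is
#' a timed sequence of patches. The first harvest of each patch is forced and
#' yields an initial reward drawn from a normal distribution; each later
#' harvest returns the previous reward multiplied by a beta-distributed decay
#' draw, floored at `reward_floor`. Exiting a patch costs `travel_duration`
#' seconds of effortful travel; each harvest costs `harvest_duration` seconds.
#'
#' Defaults reproduce the published orchard: initial reward N(15, 1), decay
#' Beta(14.90873, 2.033008) with mean 0.88, a 0.5-apple floor, and eight
#' 7-minute blocks (two per condition across the four cognitive/physical x
#' low/high conditions). Trial timings are configurable; the defaults (3 s
#' harvest, 24 s travel) give agents roughly 10-20 patch visits per block.
#'
#' @param initial_reward_mean,initial_reward_sd Mean and SD (apples) of the
#'   first harvest in a fresh patch.
#' @param decay_alpha,decay_beta Shape parameters of the beta decay
#'   distribution; the analytic decay mean is `decay_alpha/(decay_alpha+decay_beta)`.
#' @param reward_floor Smallest obtainable harvest (apples).
#' @param harvest_duration,travel_duration,block_duration Timings in seconds.
#' @param n_blocks_per_condition Blocks per effort condition.
#' @param conditions Data frame with columns `effort_type`
#'   (`"cognitive"`/`"physical"`) and `effort_level` (`"low"`/`"high"`).
#' @param missed_rate Probability a foraging trial misses the response
#'   deadline (emitted as `action == "missed"`); default 0.
#'
#' @return An object of class `foraging_config`.
#' @export
#' @examples
#' cfg <- foraging_config()
#' decay_mean(cfg)
foraging_config <- function(initial_reward_mean = 15,
                            initial_reward_sd = 1,
                            decay_alpha = 14.90873,
                            decay_beta = 2.033008,
                            reward_floor = 0.5,
                            harvest_duration = 3,
                            travel_duration = 24,
                            block_duration = 420,
                            n_blocks_per_condition = 2,
                            conditions = default_conditions(),
                            missed_rate = 0) {
  cfg <- list(
    initial_reward_mean = initial_reward_mean,
    initial_reward_sd = initial_reward_sd,
    decay_alpha = decay_alpha,
    decay_beta = decay_beta,
    reward_floor = reward_floor,
    harvest_duration = harvest_duration,
    travel_duration = travel_duration,
    block_duration = block_duration,
    n_blocks_per_condition = n_blocks_per_condition,
    conditions = conditions,
    missed_rate = missed_rate
  )
  class(cfg) <- "foraging_config"
  validate_foraging_config(cfg)
  cfg
}

default_conditions <- function() {
  data.frame(
    effort_type = rep(c("cognitive", "physical"), each = 2L),
    effort_level = rep(c("low", "high"), times = 2L),
    stringsAsFactors = FALSE
  )
}

validate_foraging_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  check_field(num1(cfg$initial_reward_mean), "initial_reward_mean", "must be a finite number")
  check_field(num1(cfg$initial_reward_sd) && cfg$initial_reward_sd >= 0,
              "initial_reward_sd", "must be a non-negative number")
  check_field(num1(cfg$decay_alpha) && cfg$decay_alpha > 0, "decay_alpha", "must be > 0")
  check_field(num1(cfg$decay_beta) && cfg$decay_beta > 0, "decay_beta", "must be > 0")
  check_field(num1(cfg$reward_floor) && cfg$reward_floor > 0, "reward_floor", "must be > 0")
  for (f in c("harvest_duration", "travel_duration", "block_duration")) {
    check_field(num1(cfg[[f]]) && cfg[[f]] > 0, f, "must be > 0")
  }
  check_field(num1(cfg$n_blocks_per_condition) && cfg$n_blocks_per_condition >= 1,
              "n_blocks_per_condition", "must be >= 1")
  check_field(num1(cfg$missed_rate) && cfg$missed_rate >= 0 && cfg$missed_rate < 1,
              "missed_rate", "must be in [0, 1)")
  check_field(is.data.frame(cfg$conditions) &&
                all(c("effort_type", "effort_level") %in% names(cfg$conditions)) &&
                nrow(cfg$conditions) >= 1,
              "conditions", "must be a data frame with effort_type and effort_level")
  check_field(all(cfg$conditions$effort_type %in% c("cognitive", "physical")),
              "conditions", "effort_type must be 'cognitive' or 'physical'")
  check_field(all(cfg$conditions$effort_level %in% c("low", "high")),
              "conditions", "effort_level must be 'low' or 'high'")
  km <- cfg$decay_alpha / (cfg$decay_alpha + cfg$decay_beta)
  check_field(km > 0 && km < 1, "decay_alpha", "decay mean must lie in (0, 1)")
  invisible(cfg)
}

#' Analytic mean of the decay distribution
#'
#' @param config A [foraging_config()].
#' @return `decay_alpha / (decay_alpha + decay_beta)` (the depletion rate
#'   kappa used to form expected rewards).
#' @export
decay_mean <- function(config) {
  validate_foraging_config(config)
  config$decay_alpha / (config$decay_alpha + config$decay_beta)
}

#' @export
print.foraging_config <- function(x, ...) {
  cat("<foraging_config>\n")
  cat(sprintf("  initial reward : N(%.3g, %.3g) apples\n",
              x$initial_reward_mean, x$initial_reward_sd))
  cat(sprintf("  decay          : Beta(%.6g, %.6g), mean %.3f\n",
              x$decay_alpha, x$decay_beta, decay_mean(x)))
  cat(sprintf("  reward floor   : %.2g apples\n", x$reward_floor))
  cat(sprintf("  timings        : harvest %gs, travel %gs, block %gs\n",
              x$harvest_duration, x$travel_duration, x$block_duration))
  cat(sprintf("  conditions     : %d (%d block(s) each)\n",
              nrow(x$conditions), x$n_blocks_per_condition))
  invisible(x)
}

#' Draw a fresh patch
#'
#' Samples the initial (forced) harvest reward of a new patch from
#' `Normal(initial_reward_mean, initial_reward_sd)`.
#'
#' @param config A [foraging_config()].
#' @param rng_seed Optional integer seed for reproducibility.
#' @return A list of class `foraging_patch` with fields `current_reward`
#'   (the last obtained harvest, apples) and `n_harvests`.
#' @export
#' @examples
#' p <- sample_patch(foraging_config(), rng_seed = 1)
#' p$current_reward
sample_patch <- function(config, rng_seed = NULL) {
  validate_foraging_config(config)
  r <- with_seed(rng_seed,
                 stats::rnorm(1L, config$initial_reward_mean, config$initial_reward_sd))
  structure(list(current_reward = r, n_harvests = 1L), class = "foraging_patch")
}

#' Harvest a patch once
#'
#' The obtained reward is the previous reward times a decay draw
#' `d ~ Beta(decay_alpha, decay_beta)`, floored at `reward_floor`.
#'
#' @param patch A `foraging_patch` (from [sample_patch()] or a previous
#'   harvest).
#' @param config A [foraging_config()].
#' @param rng_seed Optional integer seed.
#' @return A list with `reward` (apples obtained) and `patch` (updated state).
#' @export
harvest_patch <- function(patch, config, rng_seed = NULL) {
  validate_foraging_config(config)
  stopifnot(inherits(patch, "foraging_patch"))
  d <- with_seed(rng_seed, stats::rbeta(1L, config$decay_alpha, config$decay_beta))
  reward <- max(config$reward_floor, patch$current_reward * d)
  patch$current_reward <- reward
  patch$n_harvests <- patch$n_harvests + 1L
  list(reward = reward, patch = patch)
}
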