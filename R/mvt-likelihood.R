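#' Expected reward of the next harvest
#'
#' The forager's expectation for the next harvest is the last obtained reward
#' multiplied by the mean depletion rate `kappa`. For the first free decision
#' after a forced harvest, `last_reward` is that forced harvest's reward.
#' Flooring applies to obtained rewards only, never to expectations.
#'
#' @param last_reward Last obtained reward (apples), >= 0.
#' @param kappa Mean depletion rate, in (0, 1).
#' @return Expected reward (apples).
#' @export
#' @examples
#' expected_reward(10, 0.88)  # 8.8
expected_reward <- function(last_reward, kappa) {
  if (any(!is.finite(kappa)) || any(kappa <= 0) || any(kappa >= 1)) {
    stop("kappa must lie in (0, 1)")
  }
  if (any(last_reward < 0, na.rm = TRUE)) stop("last_reward must be >= 0")
  last_reward * kappa
}

#' Per-condition exit threshold from condition totals
#'
#' The exit threshold is the average net reward per harvest period:
#' `rho = (total_rewards - n_travels * c_condition) / T`, where `T` is the
#' number of harvest periods (condition duration / harvest time) and
#' `c_condition` the travel cost applying to that condition (`c_low` in low
#' blocks, `c_low + c_high` in high blocks). Totals run across all blocks of
#' the condition and include forced harvests.
#'
#' @param summary List or one-row data frame with `total_rewards` (apples),
#'   `n_travels` (count) and `T` (harvest periods, > 0).
#' @param c_condition Travel cost for the condition (apples).
#' @return Threshold `rho` (apples).
#' @export
#' @examples
#' condition_threshold(list(total_rewards = 100, n_travels = 4, T = 40), 5)  # 2
condition_threshold <- function(summary, c_condition) {
  tr <- summary$total_rewards
  nt <- summary$n_travels
  Tp <- summary$T
  stopifnot(is.numeric(tr), is.numeric(nt), is.numeric(Tp), is.numeric(c_condition))
  if (any(Tp <= 0)) stop("T (number of harvest periods) must be > 0")
  (tr - nt * c_condition) / Tp
}

#' Softmax probability of harvesting
#'
#' `P(harvest) = plogis(beta * (R_e - rho))`: the probability of staying in
#' the patch given the expected next reward and the condition threshold.
#' Forced first harvests never enter the likelihood.
#'
#' @param R_e Expected reward (apples).
#' @param rho Exit threshold (apples).
#' @param beta Inverse temperature (1/apples).
#' @return Probability in (0, 1).
#' @export
harvest_likelihood <- function(R_e, rho, beta) {
  stopifnot(all(is.finite(R_e)), all(is.finite(rho)), all(is.finite(beta)))
  stats::plogis(beta * (R_e - rho))
}

# Ensure the trial log carries obtained rewards and patch indices, both
# reconstructable from the canonical nine columns: patch = running count of
# forced harvests within a block; a harvest's obtained reward is the next
# row's last_reward within the same patch (approximated by its own expected
# reward when a block ends on a harvest).
ensure_log_columns <- function(logs, config) {
  need <- c("participant_id", "block", "effort_type", "effort_level", "trial",
            "last_reward", "expected_reward", "action", "first_harvest")
  missing <- setdiff(need, names(logs))
  if (length(missing)) stop("trial log missing columns: ", paste(missing, collapse = ", "))
  logs$first_harvest <- as.logical(logs$first_harvest)
  key <- paste(logs$participant_id, logs$block)
  ord <- order(logs$participant_id, logs$block, logs$trial)
  logs <- logs[ord, , drop = FALSE]
  if (!"patch" %in% names(logs)) {
    logs$patch <- stats::ave(as.integer(logs$first_harvest),
                             paste(logs$participant_id, logs$block),
                             FUN = cumsum)
  }
  if (!"reward" %in% names(logs)) {
    logs$reward <- NA_real_
    pk <- paste(logs$participant_id, logs$block, logs$patch)
    nxt <- c(pk[-1L], "")
    same <- pk == nxt
    is_harv <- logs$action == "harvest"
    logs$reward[is_harv & same] <- logs$last_reward[c(seq_len(nrow(logs))[-1L], NA)][is_harv & same]
    # trailing harvests with no successor: fall back on their expectation
    open <- is_harv & is.na(logs$reward)
    logs$reward[open & logs$first_harvest] <- NA_real_
    logs$reward[open & !logs$first_harvest] <- logs$expected_reward[open & !logs$first_harvest]
  }
  rownames(logs) <- NULL
  logs
}

#' Condition totals per participant
#'
#' Aggregates a trial log into the per-condition totals that define exit
#' thresholds: total obtained rewards (including forced harvests), number of
#' travels (exit trials), and the number of harvest periods
#' `T = condition duration / harvest duration`.
#'
#' @param logs Trial-log data frame (canonical schema).
#' @param config The [foraging_config()] the log was collected under.
#' @return Data frame: `participant_id`, `effort_type`, `effort_level`,
#'   `total_rewards`, `n_travels`, `n_free_trials`, `T`.
#' @export
condition_summaries <- function(logs, config) {
  validate_foraging_config(config)
  logs <- ensure_log_columns(logs, config)
  Tp <- config$n_blocks_per_condition * config$block_duration / config$harvest_duration
  sp <- split(logs, list(logs$participant_id, logs$effort_type, logs$effort_level),
              drop = TRUE)
  out <- lapply(sp, function(d) {
    data.frame(
      participant_id = d$participant_id[1L],
      effort_type = d$effort_type[1L],
      effort_level = d$effort_level[1L],
      total_rewards = sum(d$reward[d$action == "harvest"], na.rm = TRUE),
      n_travels = sum(d$action == "exit"),
      n_free_trials = sum(!d$first_harvest & d$action %in% c("harvest", "exit")),
      T = Tp,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$participant_id, out$effort_type, out$effort_level), , drop = FALSE]
}

# Pack the trial log into padded matrices for fast vectorized likelihoods.
# Returns, per condition: Re (P x M expected rewards), S (+1 harvest / -1
# exit), W (inclusion weights), and vectors A = total_rewards/T and
# B = n_travels/T so that rho = A - B * c_condition.
prepare_mvt_data <- function(logs, config, participants = NULL) {
  logs <- ensure_log_columns(logs, config)
  if (is.null(participants)) participants <- unique(logs$participant_id)
  P <- length(participants)
  conds <- config$conditions
  keys <- cond_key(conds$effort_type, conds$effort_level)
  summ <- condition_summaries(logs, config)
  conds_list <- vector("list", nrow(conds))
  names(conds_list) <- keys
  for (k in seq_len(nrow(conds))) {
    et <- conds$effort_type[k]
    el <- conds$effort_level[k]
    d <- logs[logs$effort_type == et & logs$effort_level == el &
                !logs$first_harvest & logs$action %in% c("harvest", "exit"), ,
              drop = FALSE]
    lst <- split(d, factor(d$participant_id, levels = participants))
    M <- max(1L, max(vapply(lst, nrow, integer(1))))
    Re <- matrix(0, P, M)
    S <- matrix(1, P, M)
    W <- matrix(0, P, M)
    for (i in seq_len(P)) {
      di <- lst[[i]]
      m <- nrow(di)
      if (m) {
        Re[i, seq_len(m)] <- di$expected_reward
        S[i, seq_len(m)] <- ifelse(di$action == "harvest", 1, -1)
        W[i, seq_len(m)] <- 1
      }
    }
    si <- summ[summ$effort_type == et & summ$effort_level == el, , drop = FALSE]
    si <- si[match(participants, si$participant_id), , drop = FALSE]
    A <- ifelse(is.na(si$total_rewards), 0, si$total_rewards / si$T)
    B <- ifelse(is.na(si$n_travels), 0, si$n_travels / si$T)
    conds_list[[k]] <- list(effort_type = et, effort_level = el,
                            Re = Re, S = S, W = W, A = A, B = B,
                            n_exits = ifelse(is.na(si$n_travels), 0L, si$n_travels))
  }
  list(participants = participants, P = P, conds = conds_list,
       keys = keys, summaries = summ)
}

# Vectorized condition log-likelihood for all participants.
cond_loglik <- function(cd, c_cond, beta) {
  rho <- cd$A - cd$B * c_cond
  eta <- beta * (cd$Re - rho)      # column-major recycling over participants
  rowSums(cd$W * stats::plogis(cd$S * eta, log.p = TRUE))
}
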