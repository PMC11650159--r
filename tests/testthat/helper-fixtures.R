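# Shared fixtures: small, fast environments and hand-built logs.

# Short blocks and travel so unit tests stay fast; same reward structure as
# the default orchard.
quick_config <- function(...) {
  foraging_config(block_duration = 150, travel_duration = 12,
                  n_blocks_per_condition = 1, ...)
}

# A deterministic hand-built two-patch block for one participant/condition.
# Rewards chosen so totals are easy to verify by hand.
hand_log <- function(participant_id = "p1", effort_type = "cognitive",
                     effort_level = "low") {
  data.frame(
    participant_id = participant_id,
    block = 1L,
    effort_type = effort_type,
    effort_level = effort_level,
    trial = 1:6,
    last_reward = c(NA, 10, 8, NA, 12, 9),
    expected_reward = c(NA, 8.8, 7.04, NA, 10.56, 7.92),
    action = c("harvest", "harvest", "exit", "harvest", "harvest", "exit"),
    first_harvest = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    reward = c(10, 8, NA, 12, 9, NA),
    patch = c(1L, 1L, 1L, 2L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}

# Simulate a small cohort of fixed-threshold agents (cheap: no fixed-point
# iteration) and return the combined log plus the thresholds used.
fixed_threshold_cohort <- function(n, thresholds_low = 5, thresholds_high = 5,
                                   beta = 8, config = quick_config(),
                                   seed = 1L) {
  th <- c(cognitive_low = thresholds_low, cognitive_high = thresholds_high,
          physical_low = thresholds_low, physical_high = thresholds_high)
  logs <- lapply(seq_len(n), function(i) {
    ag <- agent_spec(mvt_params(beta = beta), threshold_mode = "fixed",
                     thresholds = th)
    simulate_participant(ag, config, rng_seed = 1000 * seed + i,
                         participant_id = sprintf("p%02d", i))
  })
  do.call(rbind, logs)
}
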