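#' Participant exclusion rules
#'
#' Mirrors the QC applied before model fitting: participants missing the
#' response deadline on too many foraging trials are excluded entirely;
#' participants with very few exit trials in some condition are excluded
#' from that effort type's analyses only (they can remain in the other
#' effort type).
#'
#' @param max_missed_fraction Exclude a participant outright when the
#'   fraction of missed trials exceeds this (default 0.25).
#' @param min_exits_per_condition Minimum exit trials per condition; fewer
#'   excludes the participant from that effort type (default 4).
#' @return List of class `exclusion_config`.
#' @export
exclusion_config <- function(max_missed_fraction = 0.25,
                             min_exits_per_condition = 4L) {
  check_field(is.numeric(max_missed_fraction) &&
                max_missed_fraction >= 0 && max_missed_fraction <= 1,
              "max_missed_fraction", "must be in [0, 1]")
  check_field(is.numeric(min_exits_per_condition) && min_exits_per_condition >= 1,
              "min_exits_per_condition", "must be >= 1")
  structure(list(max_missed_fraction = max_missed_fraction,
                 min_exits_per_condition = as.integer(min_exits_per_condition)),
            class = "exclusion_config")
}

#' Apply QC exclusions to a trial log
#'
#' @param logs Trial-log data frame or CSV path.
#' @param config An [exclusion_config()].
#' @return List of class `exclusion_report`: `included` (data frame
#'   `participant_id`, `effort_type` combinations retained), `report` (one
#'   row per triggered rule: participant, rule, scope, value), and the
#'   filtered `logs` (rows belonging to retained participant x effort-type
#'   combinations).
#' @export
apply_exclusions <- function(logs, config = exclusion_config()) {
  if (is.character(logs)) logs <- read_trial_log(logs)
  stopifnot(inherits(config, "exclusion_config"))
  ids <- unique(logs$participant_id)
  report <- list()
  full_excluded <- character()

  for (id in ids) {
    d <- logs[logs$participant_id == id, , drop = FALSE]
    frac_missed <- mean(d$action == "missed")
    if (frac_missed > config$max_missed_fraction) {
      full_excluded <- c(full_excluded, id)
      report[[length(report) + 1L]] <- data.frame(
        participant_id = id, rule = "max_missed_fraction", scope = "all",
        value = frac_missed, stringsAsFactors = FALSE)
    }
  }

  combos <- expand.grid(participant_id = ids,
                        effort_type = unique(logs$effort_type),
                        stringsAsFactors = FALSE)
  combos$included <- !combos$participant_id %in% full_excluded
  for (i in seq_len(nrow(combos))) {
    if (!combos$included[i]) next
    d <- logs[logs$participant_id == combos$participant_id[i] &
                logs$effort_type == combos$effort_type[i], , drop = FALSE]
    exits_by_level <- tapply(d$action == "exit", d$effort_level, sum)
    low <- min(exits_by_level)
    if (low < config$min_exits_per_condition) {
      combos$included[i] <- FALSE
      report[[length(report) + 1L]] <- data.frame(
        participant_id = combos$participant_id[i], rule = "min_exits_per_condition",
        scope = combos$effort_type[i], value = low, stringsAsFactors = FALSE)
    }
  }

  included <- combos[combos$included, c("participant_id", "effort_type"), drop = FALSE]
  rownames(included) <- NULL
  keep <- paste(logs$participant_id, logs$effort_type) %in%
    paste(included$participant_id, included$effort_type)
  structure(list(
    included = included,
    report = if (length(report)) do.call(rbind, report) else
      data.frame(participant_id = character(), rule = character(),
                 scope = character(), value = numeric()),
    logs = logs[keep, , drop = FALSE]
  ), class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report>\n")
  cat(sprintf("  retained combinations: %d\n", nrow(x$included)))
  if (nrow(x$report)) {
    cat("  exclusions:\n")
    for (i in seq_len(nrow(x$report))) {
      cat(sprintf("    %s [%s, scope %s] value %.3g\n", x$report$participant_id[i],
                  x$report$rule[i], x$report$scope[i], x$report$value[i]))
    }
  } else cat("  no exclusions triggered\n")
  invisible(x)
}
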