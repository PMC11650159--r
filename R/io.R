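# Plain-text interchange: trial-log CSV and JSON/YAML configs.

TRIAL_LOG_COLUMNS <- c("participant_id", "block", "effort_type", "effort_level",
                       "trial", "last_reward", "expected_reward", "action",
                       "first_harvest")

#' Write a trial log to CSV
#'
#' Writes the canonical columns (`participant_id, block, effort_type,
#' effort_level, trial, last_reward, expected_reward, action,
#' first_harvest`) first, followed by any extra columns present (`reward`,
#' `patch`).
#'
#' @param logs Trial-log data frame.
#' @param path Output CSV path.
#' @export
write_trial_log <- function(logs, path) {
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(logs))
  if (length(missing)) stop("trial log missing columns: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(logs), TRIAL_LOG_COLUMNS)
  utils::write.csv(logs[, c(TRIAL_LOG_COLUMNS, extra), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a trial log CSV
#'
#' @param path CSV path with at least the canonical columns.
#' @return Trial-log data frame (`first_harvest` coerced to logical).
#' @export
read_trial_log <- function(path) {
  logs <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(logs))
  if (length(missing)) stop("trial log missing columns: ", paste(missing, collapse = ", "))
  logs$first_harvest <- as.logical(logs$first_harvest)
  logs
}

#' Read an environment configuration from JSON or YAML
#'
#' Field names mirror [foraging_config()] exactly; absent fields keep their
#' defaults. `conditions`, if given, is a list/table of `effort_type` and
#' `effort_level`.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A [foraging_config()].
#' @export
read_foraging_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(foraging_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  if (!is.null(vals$conditions)) vals$conditions <- as.data.frame(vals$conditions)
  do.call(foraging_config, vals)
}

#' Write an environment configuration to JSON
#'
#' @param config A [foraging_config()].
#' @param path Output `.json` path.
#' @export
write_foraging_config <- function(config, path) {
  validate_foraging_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
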