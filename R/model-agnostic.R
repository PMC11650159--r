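#' Model-agnostic exit regression
#'
#' Mixed-effects regression of log expected reward on exit trials:
#' `log(R_e) ~ effort_level + (1 | participant)` (natural log, random
#' intercepts only). Fitted separately per effort type, or on low-effort
#' conditions of both types to estimate overall exit thresholds. Forced
#' first harvests are excluded by construction (only exit decisions enter),
#' and the second-harvest expectation is last reward times the decay mean,
#' exactly as in the trial log.
#'
#' @param logs Trial-log data frame or CSV path.
#' @param effort_type `"cognitive"`, `"physical"`, or a vector of both.
#' @param effort_level Optional filter, e.g. `"low"` for the overall
#'   threshold regression; default uses both levels.
#' @return Object of class `exit_regression`: fixed effects with standard
#'   errors, per-participant random intercepts, fitted participant-level
#'   predictions on the log scale, and the underlying model.
#'   Falls back to a fixed-effects `lm` (with a warning) when only one
#'   participant is present.
#' @export
exit_regression <- function(logs, effort_type = c("cognitive", "physical"),
                            effort_level = c("low", "high")) {
  if (is.character(logs) && length(logs) == 1L && file.exists(logs)) {
    logs <- read_trial_log(logs)
  }
  effort_type <- match.arg(effort_type, several.ok = TRUE)
  effort_level <- match.arg(effort_level, several.ok = TRUE)
  d <- logs[logs$action == "exit" & !logs$first_harvest &
              logs$effort_type %in% effort_type &
              logs$effort_level %in% effort_level, , drop = FALSE]
  if (!nrow(d)) stop("no exit trials in the requested conditions")
  if (any(d$expected_reward <= 0, na.rm = TRUE)) {
    stop("non-positive expected rewards cannot be log-transformed")
  }
  d$log_re <- log(d$expected_reward)
  d$effort_high <- as.numeric(d$effort_level == "high")
  two_level <- length(unique(d$effort_level)) == 2L
  form_fixed <- if (two_level) log_re ~ effort_high else log_re ~ 1
  n_part <- length(unique(d$participant_id))
  if (n_part < 2L) {
    warning("single participant: falling back to fixed-effects regression")
    fit <- stats::lm(form_fixed, data = d)
    co <- summary(fit)$coefficients
    ranefs <- stats::setNames(0, unique(d$participant_id))
    part_pred <- stats::setNames(rep(co["(Intercept)", "Estimate"],
                                     n_part), unique(d$participant_id))
    model <- fit
  } else {
    form <- stats::update(form_fixed, . ~ . + (1 | participant_id))
    model <- lme4::lmer(form, data = d, REML = TRUE)
    co <- stats::coef(summary(model))
    re <- lme4::ranef(model)$participant_id
    ranefs <- stats::setNames(re[, "(Intercept)"], rownames(re))
    part_pred <- co["(Intercept)", "Estimate"] + ranefs
  }
  structure(list(
    coefficients = co,
    intercept = co["(Intercept)", "Estimate"],
    effort_coefficient = if (two_level) co["effort_high", "Estimate"] else NA_real_,
    effort_se = if (two_level) co["effort_high", "Std. Error"] else NA_real_,
    effort_t = if (two_level) co["effort_high", "t value"] else NA_real_,
    ranef = ranefs,
    participant_log_threshold = part_pred,
    effort_type = effort_type, effort_level = effort_level,
    n_exits = nrow(d), model = model
  ), class = "exit_regression")
}

#' @export
print.exit_regression <- function(x, ...) {
  cat("<exit_regression>\n")
  cat(sprintf("  conditions : %s x %s (%d exit trials)\n",
              paste(x$effort_type, collapse = "/"),
              paste(x$effort_level, collapse = "/"), x$n_exits))
  cat(sprintf("  intercept  : %.3f (log apples)\n", x$intercept))
  if (!is.na(x$effort_coefficient)) {
    cat(sprintf("  effort coef: %.3f (SE %.3f, t = %.2f)\n",
                x$effort_coefficient, x$effort_se, x$effort_t))
  }
  invisible(x)
}

#' Per-participant overall exit thresholds
#'
#' Exponentiates the participant-level prediction (fixed intercept plus
#' random intercept) of an exit regression fitted on low-effort conditions,
#' giving each participant's overall exit threshold on the apples scale —
#' the model-agnostic proxy for subjective opportunity cost of time.
#'
#' @param regression An [exit_regression()] result (fit on
#'   `effort_level = "low"`).
#' @return Data frame: `participant_id`, `log_threshold`, `threshold`
#'   (apples).
#' @export
overall_thresholds <- function(regression) {
  stopifnot(inherits(regression, "exit_regression"))
  lt <- regression$participant_log_threshold
  data.frame(participant_id = names(lt),
             log_threshold = unname(lt),
             threshold = unname(exp(lt)),
             stringsAsFactors = FALSE)
}
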