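#' Covariate-adjusted standardized regression
#'
#' Ordinary least squares of an outcome (effort cost, overall threshold,
#' inverse temperature, or performance) on a predictor (group indicator,
#' overall depression, or a symptom factor), adjusting for covariates. All
#' variables are standardized (z-scored) before fitting, so the reported
#' predictor coefficient is a standardized effect. Complete-case analysis.
#'
#' @param data Data frame holding all variables as columns.
#' @param outcome,predictor Column names.
#' @param covariates Character vector of column names (can be empty).
#' @return One-row data frame: `outcome`, `predictor`, `n`, `estimate`
#'   (standardized coefficient), `se`, `t`, `p`, `r_squared`,
#'   `adj_r_squared`.
#' @export
fit_spec <- function(data, outcome, predictor, covariates = character()) {
  vars <- c(outcome, predictor, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) stop("missing columns: ", paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  if (nrow(d) <= length(covariates) + 2L) {
    stop(sprintf("too few complete cases (%d) for %d covariates", nrow(d), length(covariates)))
  }
  dz <- as.data.frame(lapply(d, function(x) zscore(as.numeric(x))))
  names(dz) <- vars
  form <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- stats::lm(form, data = dz)
  al <- stats::alias(fit)
  if (!is.null(al$Complete)) {
    stop("rank-deficient model; collinear columns: ",
         paste(rownames(al$Complete), collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  data.frame(outcome = outcome, predictor = predictor, n = nrow(d),
             estimate = co[predictor, "Estimate"], se = co[predictor, "Std. Error"],
             t = co[predictor, "t value"], p = co[predictor, "Pr(>|t|)"],
             r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure: order the m p-values, find the largest i with
#' `p_(i) <= i/m * q`, reject hypotheses 1..i. Adjusted p-values are the
#' cumulative minima of `m/i * p_(i)` from the largest rank down.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (1 <= m <= 1000).
#' @param q FDR level (default 0.05).
#' @return List: `adjusted` (BH-adjusted p-values, original order) and
#'   `reject` (logical flags at level `q`).
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (length(p) < 1L || length(p) > 1000L) stop("need 1 <= m <= 1000 p-values")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj_sorted <- rev(cummin(rev(m / seq_len(m) * ranked)))
  adj_sorted <- pmin(adj_sorted, 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  # step-up rejection at level q
  passes <- which(ranked <= seq_len(m) / m * q)
  reject <- rep(FALSE, m)
  if (length(passes)) reject[o[seq_len(max(passes))]] <- TRUE
  list(adjusted = adjusted, reject = reject)
}

#' Compare two dependent overlapping correlations (Meng-Rosenthal-Rubin)
#'
#' Tests whether `corr(x1, y)` differs from `corr(x2, y)` when both are
#' computed on the same participants and share the variable `y` (here: the
#' cognitive and physical effort costs' correlations with one symptom).
#' `z = (z1 - z2) * sqrt((n - 3) / (2 * (1 - r_x) * h))` with Fisher
#' transforms `z1`, `z2`, the cost-cost correlation `r_x`,
#' `rbar2 = (r1^2 + r2^2)/2`, `f = min(1, (1 - r_x) / (2 (1 - rbar2)))`, and
#' `h = (1 - f * rbar2) / (1 - rbar2)`.
#'
#' @param r1,r2 The two correlations sharing a variable (|r| < 1).
#' @param r_x Correlation between the two non-shared variables (|r| < 1).
#' @param n Sample size (> 3).
#' @return List: `z`, `p` (two-sided).
#' @export
compare_dependent_correlations <- function(r1, r2, r_x, n) {
  for (nm in c("r1", "r2", "r_x")) {
    v <- get(nm)
    check_field(is.numeric(v) && length(v) == 1L && abs(v) < 1, nm, "must satisfy |r| < 1")
  }
  check_field(is.numeric(n) && n > 3, "n", "must be > 3")
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min(1, (1 - r_x) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r_x) * h))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Run a battery of symptom regressions with FDR control
#'
#' Fits one covariate-adjusted standardized regression per symptom factor
#' (see [fit_spec()]) and applies Benjamini-Hochberg correction across the
#' battery. Missing factors are skipped with a logged reason and the FDR
#' family size reduced accordingly. Sensitivity variants: restrict to the
#' currently depressed subset, add a medication covariate, or add anxiety as
#' a covariate to every other symptom's model (effort-type specificity
#' follow-up).
#'
#' @param data Merged participant-level data frame (costs, thresholds,
#'   performance, demographics, symptom scores).
#' @param outcome Outcome column name (e.g. `"c_high_cognitive"`).
#' @param symptoms Character vector of symptom columns (the battery; 7 in
#'   the canonical analysis).
#' @param covariates Covariates for every model (performance, education,
#'   age, BMI for physical outcomes, ...).
#' @param q FDR level (default 0.05).
#' @param subset Optional logical vector selecting rows (e.g. current MDD).
#' @param medication_covariate If `TRUE`, add `"medication"` to the
#'   covariates.
#' @param anxiety_adjusted If `TRUE`, add the anxiety score as a covariate
#'   to each other symptom's model (anxiety's own row is dropped).
#' @param anxiety_col Column holding the anxiety score.
#' @return Data frame of class `symptom_battery`: one row per symptom model
#'   with standardized estimate, p, BH-adjusted p and `significant` flag;
#'   skipped models are reported in attribute `"skipped"`.
#' @export
run_symptom_battery <- function(data, outcome, symptoms, covariates,
                                q = 0.05, subset = NULL,
                                medication_covariate = FALSE,
                                anxiety_adjusted = FALSE,
                                anxiety_col = "anxiety") {
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  covs <- covariates
  if (medication_covariate) covs <- union(covs, "medication")
  if (anxiety_adjusted) {
    symptoms <- setdiff(symptoms, anxiety_col)
    covs <- union(covs, anxiety_col)
  }
  rows <- list()
  skipped <- character()
  for (s in symptoms) {
    res <- tryCatch(fit_spec(data, outcome, s, covs), error = function(e) e)
    if (inherits(res, "error")) {
      skipped[s] <- conditionMessage(res)
      next
    }
    rows[[s]] <- res
  }
  if (!length(rows)) stop("no symptom model could be fitted")
  tab <- do.call(rbind, rows)
  fdr <- fdr_correct(tab$p, q = q)
  tab$p_adjusted <- fdr$adjusted
  tab$significant <- fdr$reject
  rownames(tab) <- NULL
  attr(tab, "skipped") <- skipped
  attr(tab, "m") <- nrow(tab)
  class(tab) <- c("symptom_battery", class(tab))
  tab
}

#' @export
print.symptom_battery <- function(x, ...) {
  cat(sprintf("Symptom battery for outcome '%s' (m = %d, BH-FDR)\n",
              x$outcome[1L], attr(x, "m")))
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, 3)
  df$p <- signif(df$p, 3)
  df$p_adjusted <- signif(df$p_adjusted, 3)
  df$flag <- ifelse(df$significant, "*", "")
  print(df[, c("predictor", "n", "estimate", "p", "p_adjusted", "flag")],
        row.names = FALSE)
  sk <- attr(x, "skipped")
  if (length(sk)) {
    for (s in names(sk)) cat(sprintf("  skipped %s: %s\n", s, sk[[s]]))
  }
  invisible(x)
}
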