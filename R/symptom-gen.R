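#' Configuration for the synthetic symptom-item generator
#'
#' Each latent factor is measured by `items_per_factor` items with the given
#' loadings plus `n_bad_items` near-zero-loading items (to exercise the
#' item-total filter downstream). Item responses are
#' `loading * latent + Normal(0, noise_sd)`.
#'
#' @param items_per_factor Number of informative items per factor (>= 2).
#' @param loadings Numeric vector (recycled to `items_per_factor`) of item
#'   loadings in `[0, 1]`.
#' @param noise_sd Item noise SD.
#' @param n_bad_items Items per factor with loading ~ 0.
#' @param factors Factor names; defaults to [symptom_factor_names()].
#' @return A list of class `symptom_gen_config`.
#' @export
symptom_gen_config <- function(items_per_factor = 6, loadings = 0.75,
                               noise_sd = 0.6, n_bad_items = 0,
                               factors = symptom_factor_names()) {
  check_field(items_per_factor >= 2, "items_per_factor", "must be >= 2")
  check_field(all(loadings >= 0 & loadings <= 1), "loadings", "must be in [0, 1]")
  check_field(noise_sd >= 0, "noise_sd", "must be >= 0")
  check_field(n_bad_items >= 0, "n_bad_items", "must be >= 0")
  structure(list(items_per_factor = items_per_factor,
                 loadings = rep_len(loadings, items_per_factor),
                 noise_sd = noise_sd, n_bad_items = n_bad_items,
                 factors = factors),
            class = "symptom_gen_config")
}

#' Generate synthetic symptom-item responses
#'
#' Produces a long-format item table (one row per participant x item) from a
#' cohort's latent factor scores, mimicking multi-instrument questionnaire
#' data with a known one-factor-per-domain structure.
#'
#' @param cohort An `ef_cohort` from [simulate_cohort()], or any data frame
#'   with `participant_id` and `latent_<factor>` columns.
#' @param config A [symptom_gen_config()].
#' @param rng_seed Integer seed.
#' @return Data frame with columns `participant_id`, `instrument`, `item`,
#'   `value`. Bad items are named `<factor>_bad<j>` (their generative loading
#'   is 0.02, i.e. essentially pure noise).
#' @export
generate_symptom_items <- function(cohort, config = symptom_gen_config(),
                                   rng_seed = NULL) {
  stopifnot(inherits(config, "symptom_gen_config"))
  df <- if (inherits(cohort, "ef_cohort")) cohort$participants else cohort
  stopifnot(is.data.frame(df), "participant_id" %in% names(df))
  with_seed(rng_seed, {
    out <- list()
    for (f in config$factors) {
      col <- paste0("latent_", f)
      if (!col %in% names(df)) stop("cohort lacks latent factor column: ", col)
      latent <- df[[col]]
      n <- length(latent)
      loads <- c(config$loadings, rep(0.02, config$n_bad_items))
      item_names <- c(sprintf("%s_item%d", f, seq_len(config$items_per_factor)),
                      if (config$n_bad_items > 0)
                        sprintf("%s_bad%d", f, seq_len(config$n_bad_items)))
      for (j in seq_along(loads)) {
        out[[length(out) + 1L]] <- data.frame(
          participant_id = df$participant_id,
          instrument = paste0(f, "_scale"),
          item = item_names[j],
          value = loads[j] * latent + stats::rnorm(n, 0, config$noise_sd),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  })
}
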