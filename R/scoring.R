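#' Iterative item-total reliability filter
#'
#' Removes items whose corrected item-total correlation (correlation of the
#' item with the mean of the remaining items, excluding itself) falls below
#' `threshold`. Removal is iterative and deterministic: the single lowest
#' item is removed, correlations are recomputed, and the process repeats
#' until all retained items pass. Re-running the filter on its own output is
#' a fixed point.
#'
#' @param items Numeric matrix or data frame (respondents x items).
#' @param threshold Minimum corrected item-total correlation (default 0.2).
#' @return List: `retained` (item names), `removed` (named vector of the
#'   correlations at removal time), `empty` (TRUE when fewer than 2 items
#'   survive, i.e. the factor cannot be scored).
#' @export
item_total_filter <- function(items, threshold = 0.2) {
  items <- as.matrix(items)
  if (ncol(items) < 2L) stop("need at least 2 items")
  if (is.null(colnames(items))) colnames(items) <- paste0("item", seq_len(ncol(items)))
  removed <- numeric()
  repeat {
    if (ncol(items) < 2L) break
    r_it <- vapply(seq_len(ncol(items)), function(j) {
      rest <- rowMeans(items[, -j, drop = FALSE], na.rm = TRUE)
      suppressWarnings(stats::cor(items[, j], rest, use = "pairwise.complete.obs"))
    }, numeric(1))
    r_it[is.na(r_it)] <- -Inf  # constant items can never pass
    if (all(r_it >= threshold)) break
    worst <- which.min(r_it)
    removed[colnames(items)[worst]] <- r_it[worst]
    items <- items[, -worst, drop = FALSE]
  }
  retained <- colnames(items)
  empty <- length(retained) < 2L
  if (empty) {
    # a lone survivor cannot form a scale either
    if (length(retained) == 1L) {
      removed[retained] <- NA_real_
      retained <- character()
    }
  }
  list(retained = retained, removed = removed, empty = empty)
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(var_i) / var(total))` over complete cases.
#' For two items with inter-item correlation `r` this reduces to the
#' Spearman-Brown form `2r / (1 + r)` when the items have equal variance.
#'
#' @param items Numeric matrix or data frame (respondents x items).
#' @return Alpha (scalar).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2L) stop("need at least 2 items")
  items <- items[stats::complete.cases(items), , drop = FALSE]
  if (nrow(items) < 3L) stop("need at least 3 complete respondents")
  total_var <- stats::var(rowSums(items))
  if (!is.finite(total_var) || total_var == 0) {
    stop("total score has zero variance: alpha undefined")
  }
  k <- ncol(items)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}

#' Score symptom factors from an item table
#'
#' Applies the scale-construction rules: per factor, (1) drop items with
#' corrected item-total correlation below `item_threshold`; (2) exclude the
#' whole factor when Cronbach's alpha on the retained items is below
#' `alpha_threshold`; (3) z-score the retained items within the scoring
#' population and average them. Participants with fewer than half of a
#' factor's retained items present get a missing score. Scoring can use the
#' MDD group only (the primary analysis population) or all participants.
#'
#' @param items Long-format data frame: `participant_id`, `instrument`,
#'   `item`, `value` (or a CSV path).
#' @param assignments Named list mapping factor name to item ids; by default
#'   every instrument's items form one factor named after the instrument
#'   prefix.
#' @param population `"mdd_only"` (default) or `"all"`.
#' @param groups Named vector / data frame mapping `participant_id` to
#'   `"mdd"`/`"comparison"`; required for `population = "mdd_only"`.
#' @param item_threshold,alpha_threshold Filter gates (0.2 and 0.6).
#' @return List of class `symptom_scores`: `scores` (long data frame
#'   `participant_id`, `factor`, `score`), `retained`, `removed`, `alphas`,
#'   `excluded_factors`, `population`.
#' @export
score_factors <- function(items, assignments = NULL,
                          population = c("mdd_only", "all"), groups = NULL,
                          item_threshold = 0.2, alpha_threshold = 0.6) {
  population <- match.arg(population)
  if (is.character(items) && length(items) == 1L) {
    items <- utils::read.csv(items, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("participant_id", "item", "value") %in% names(items)))
  if (is.null(assignments)) {
    if (!"instrument" %in% names(items)) stop("need 'instrument' or explicit assignments")
    assignments <- split(unique(items$item),
                         sub("_scale$", "", items$instrument[match(unique(items$item), items$item)]))
  }
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$participant_id)
  }
  ids <- unique(items$participant_id)
  score_ids <- if (population == "mdd_only") {
    if (is.null(groups)) stop("population = 'mdd_only' requires group labels")
    ids[groups[ids] == "mdd" & !is.na(groups[ids])]
  } else ids

  wide <- stats::reshape(items[, c("participant_id", "item", "value")],
                         idvar = "participant_id", timevar = "item",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- wide$participant_id

  scores <- list()
  retained <- list()
  removed <- list()
  alphas <- c()
  excluded <- c()
  for (f in names(assignments)) {
    it_names <- intersect(assignments[[f]], names(wide))
    if (length(it_names) < 2L) {
      excluded <- c(excluded, stats::setNames("fewer than 2 items", f))
      next
    }
    X_score <- as.matrix(wide[match(score_ids, wide$participant_id), it_names, drop = FALSE])
    flt <- item_total_filter(X_score, threshold = item_threshold)
    removed[[f]] <- flt$removed
    if (flt$empty) {
      excluded <- c(excluded, stats::setNames("all items removed by item-total filter", f))
      next
    }
    Xr <- X_score[, flt$retained, drop = FALSE]
    a <- tryCatch(cronbach_alpha(Xr), error = function(e) NA_real_)
    alphas[f] <- a
    if (!is.finite(a) || a < alpha_threshold) {
      excluded <- c(excluded, stats::setNames(sprintf("alpha %.3f < %.2f", a, alpha_threshold), f))
      next
    }
    retained[[f]] <- flt$retained
    mu <- colMeans(Xr, na.rm = TRUE)
    sdv <- apply(Xr, 2, stats::sd, na.rm = TRUE)
    Z <- sweep(sweep(Xr, 2, mu), 2, sdv, "/")
    n_present <- rowSums(!is.na(Z))
    sc <- rowMeans(Z, na.rm = TRUE)
    sc[n_present < length(flt$retained) / 2] <- NA_real_
    scores[[f]] <- data.frame(participant_id = score_ids, factor = f,
                              score = unname(sc), stringsAsFactors = FALSE)
  }
  structure(list(scores = if (length(scores)) do.call(rbind, scores) else
                   data.frame(participant_id = character(), factor = character(),
                              score = numeric()),
                 retained = retained, removed = removed, alphas = alphas,
                 excluded_factors = excluded, population = population),
            class = "symptom_scores")
}

#' @export
print.symptom_scores <- function(x, ...) {
  cat("<symptom_scores>\n")
  cat(sprintf("  population : %s\n", x$population))
  cat(sprintf("  factors    : %d scored, %d excluded\n",
              length(x$retained), length(x$excluded_factors)))
  if (length(x$excluded_factors)) {
    for (f in names(x$excluded_factors)) {
      cat(sprintf("    excluded %s: %s\n", f, x$excluded_factors[[f]]))
    }
  }
  invisible(x)
}

#' Wide table of factor scores
#'
#' @param scores A `symptom_scores` object.
#' @return Data frame with one row per participant and one column per factor.
#' @export
scores_wide <- function(scores) {
  stopifnot(inherits(scores, "symptom_scores"))
  s <- scores$scores
  if (!nrow(s)) return(data.frame(participant_id = character()))
  wide <- stats::reshape(s, idvar = "participant_id", timevar = "factor",
                         direction = "wide")
  names(wide) <- sub("^score\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
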