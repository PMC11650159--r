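# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed if non-NULL, restoring the caller's RNG state afterwards so
#' that seeded package functions do not perturb the global random stream.
#'
#' @param seed Integer seed or `NULL` (use current stream).
#' @param expr Expression to evaluate.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed derivation: keeps derived seeds positive and
# below 2^31 - 1 so they are valid R integer seeds.
derive_seed <- function(master_seed, index) {
  stopifnot(is.numeric(master_seed), is.numeric(index))
  ((as.double(master_seed) %% 2147483647) * 48271 + as.double(index) * 16807) %% 2147483629 + 1
}

# Stop with a message naming the offending field.
check_field <- function(ok, field, what) {
  if (!isTRUE(ok)) stop(sprintf("invalid field '%s': %s", field, what), call. = FALSE)
}

#' Standardize a numeric vector to mean 0, SD 1
#' @noRd
zscore <- function(x, center = NULL, scale = NULL) {
  center <- if (is.null(center)) mean(x, na.rm = TRUE) else center
  scale <- if (is.null(scale)) stats::sd(x, na.rm = TRUE) else scale
  if (!is.finite(scale) || scale == 0) stop("cannot z-score: zero or undefined variance")
  (x - center) / scale
}

# Shortest (highest-density) interval from a sample.
hdi_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) return(c(lower = NA_real_, upper = NA_real_))
  m <- max(1L, floor(prob * n))
  if (m >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[(m + 1L):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

# Split-R-hat (Gelman et al.) for a draws matrix [iterations x chains].
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (!is.finite(w) || w <= 0) {
    # all-constant chains: identical constants are converged by definition
    return(if (stats::var(as.vector(sub)) == 0) 1 else NA_real_)
  }
  sqrt(((half - 1) / half * w + b / half) / w)
}

# Crude effective sample size from lag-autocorrelations (initial positive
# sequence), summed across chains.
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 8L) return(NA_real_)
  per_chain <- apply(draws, 2, function(x) {
    if (stats::var(x) == 0) return(n)
    ac <- stats::acf(x, lag.max = min(n - 2L, 200L), plot = FALSE)$acf[-1]
    pos <- which(ac < 0.05)
    k <- if (length(pos)) pos[1L] - 1L else length(ac)
    n / (1 + 2 * sum(ac[seq_len(k)]))
  })
  sum(per_chain)
}
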