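## Small shared utilities.

## Evaluate an expression under a fixed RNG seed without disturbing the
## caller's random-number stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Derive a child seed from a base seed and a stream label, keeping the
## result inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + stream * 12289) %% 2147483647)
}

#' Tukey outlier fences
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). The lower fence is Q1 - k * IQR, the
#' upper Q3 + k * IQR.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @return List with `lower`, `upper`, `q1`, `q3`.
#' @export
tukey_fences <- function(values, k = 1.5) {
  v <- values[is.finite(values)]
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  list(lower = q[1] - k * iqr, upper = q[2] + k * iqr, q1 = q[1], q3 = q[2])
}

#' Lower Tukey fence with flags
#'
#' Used for frame rejection: flags values strictly below
#' Q1 - k * IQR. With fewer than 4 finite values no rejection is
#' attempted (a warning is raised instead).
#'
#' @param values Numeric vector.
#' @param k Fence multiplier; `Inf` flags nothing.
#' @return List with `threshold` and logical `flags` (same length as
#'   `values`; non-finite values are never flagged).
#' @export
tukey_lower_fence <- function(values, k = 1.5) {
  fin <- is.finite(values)
  if (sum(fin) < 4) {
    warning("fewer than 4 finite values: no outlier rejection performed")
    return(list(threshold = -Inf, flags = rep(FALSE, length(values))))
  }
  if (!is.finite(k)) {
    return(list(threshold = -Inf, flags = rep(FALSE, length(values))))
  }
  f <- tukey_fences(values[fin], k)
  list(threshold = f$lower, flags = fin & values < f$lower)
}

## Adjusted Rand index between two partitions (label vectors).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
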