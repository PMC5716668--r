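# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards. All stochastic generators in the
## package go through this so that they are pure functions of (params, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ..., class = "skcsd_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stopf("`%s` must be a single positive finite number", name,
          class = "skcsd_argument_error")
  }
  invisible(x)
}

## Centered moving average with windows that shrink at the edges, so that
## constants are preserved exactly and there is no phase delay. `half` is the
## half-width in samples; the window at sample t is [t - half, t + half]
## clipped to the trace.
rolling_mean_centered <- function(x, half) {
  n <- length(x)
  if (half <= 0L) return(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Euclidean norms of the rows of a matrix difference to a point.
dist_to_point <- function(xyz, p) {
  sqrt((xyz[, 1L] - p[1L])^2 + (xyz[, 2L] - p[2L])^2 + (xyz[, 3L] - p[3L])^2)
}
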