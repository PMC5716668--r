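#' Gaussian current-source basis on the morphology loop
#'
#' Defines `M` Gaussian basis functions of width `R` with centres uniformly
#' spaced on the closed loop: `b_i(s) = exp(-d(s, s_i)^2 / R^2)`, where
#' `s_i = (i - 1) * l / M` and `d` is the circular (modulo-`l`) distance,
#' so that coverage is seamless across the seam `s = 0 == l`. Amplitudes
#' are unnormalized (peak 1); physical units (nA/um of loop) are carried by
#' the weights combining the basis functions.
#'
#' @param M number of basis sources; for `N` electrodes `M >= 2N` is
#'   recommended (the default used throughout validation is 512).
#' @param R basis width (micrometres).
#' @param l loop length (micrometres), typically `loop$l`.
#' @return An object of class `basis_config`.
#' @export
basis_config <- function(M, R, l) {
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != round(M)) {
    stopf("`M` must be a positive integer", class = "skcsd_argument_error")
  }
  check_scalar_pos(R, "R")
  check_scalar_pos(l, "l")
  structure(list(M = as.integer(M), R = as.numeric(R), l = as.numeric(l),
                 centers = (seq_len(M) - 1) * l / M),
            class = "basis_config")
}

#' @export
print.basis_config <- function(x, ...) {
  cat(sprintf("basis_config: M = %d Gaussian sources, R = %g um on a %g um loop\n",
              x$M, x$R, x$l))
  invisible(x)
}

## circular distance on a loop of circumference l
circ_dist <- function(s, t, l) {
  d <- abs((s %% l) - (t %% l))
  pmin(d, l - d)
}

#' Evaluate one basis function
#'
#' @param cfg a [basis_config()].
#' @param i basis index in `1:M`.
#' @param s numeric vector of arc lengths (micrometres; wrapped modulo `l`).
#' @return `exp(-d(s, s_i)^2 / R^2)`, values in `(0, 1]`.
#' @export
eval_basis <- function(cfg, i, s) {
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i > cfg$M || i != round(i)) {
    stopf("basis index `i` must be in 1..%d", cfg$M,
          class = "skcsd_argument_error")
  }
  d <- circ_dist(s, cfg$centers[i], cfg$l)
  exp(-d^2 / cfg$R^2)
}

## M x length(s) matrix of all basis functions evaluated on a grid
basis_matrix <- function(cfg, s) {
  d <- abs(outer(cfg$centers, s %% cfg$l, "-"))
  d <- pmin(d, cfg$l - d)
  exp(-(d / cfg$R)^2)
}

#' Current-source profile from basis weights
#'
#' Evaluates `C(s) = sum_i a_i b_i(s)` on a grid of arc lengths. Weights
#' carry the physical units (nA per micrometre of loop).
#'
#' @param cfg a [basis_config()].
#' @param a numeric weight vector of length `M`.
#' @param s arc-length grid (micrometres).
#' @return Numeric vector of the same length as `s`.
#' @export
csd_from_weights <- function(cfg, a, s) {
  if (length(a) != cfg$M) {
    stopf("length(a) = %d but M = %d", length(a), cfg$M,
          class = "skcsd_argument_error")
  }
  drop(crossprod(basis_matrix(cfg, s), a))
}
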