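#' Recording sets
#'
#' Bundles electrode positions with an N x T matrix of extracellular
#' potentials (microvolts) and a time axis (milliseconds).
#'
#' @param electrodes an [electrode_array()].
#' @param potentials numeric N x T matrix, rows matching the electrodes.
#' @param times numeric length-T time stamps (ms); defaults to `1:T`.
#' @return An object of class `recording_set`.
#' @export
recording_set <- function(electrodes, potentials, times = NULL) {
  potentials <- as.matrix(potentials)
  if (nrow(potentials) != nrow(as.data.frame(electrodes))) {
    stopf("potentials have %d rows but there are %d electrodes",
          nrow(potentials), nrow(as.data.frame(electrodes)),
          class = "skcsd_argument_error")
  }
  if (any(!is.finite(potentials))) {
    stopf("non-finite values in the potentials matrix",
          class = "skcsd_data_error")
  }
  if (is.null(times)) times <- seq_len(ncol(potentials))
  if (length(times) != ncol(potentials)) {
    stopf("length(times) != number of timepoints", class = "skcsd_argument_error")
  }
  structure(list(electrodes = electrodes, potentials = potentials,
                 times = as.numeric(times)),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("recording_set: %d electrodes x %d timepoints (%.4g..%.4g ms)\n",
              nrow(x$potentials), ncol(x$potentials),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Drop channels from a recording set
#' @param rec a [recording_set()].
#' @param labels channel labels to exclude (e.g. broken contacts).
#' @return The reduced [recording_set()].
#' @export
exclude_channels <- function(rec, labels) {
  keep <- !(rec$electrodes$label %in% labels)
  if (!any(keep)) stopf("all channels excluded", class = "skcsd_data_error")
  recording_set(electrode_array(as.matrix(rec$electrodes[keep, c("x", "y", "z")]),
                                labels = rec$electrodes$label[keep]),
                rec$potentials[keep, , drop = FALSE], rec$times)
}

#' Ridge solve in electrode space
#'
#' Solves `(K + lambda I) beta = V` by a symmetric positive-definite
#' (Cholesky) factorization; the factorization is computed once and reused
#' across all columns of `V`.
#'
#' @param kset a [build_kernels()] result (or a plain symmetric matrix `K`).
#' @param v numeric N-vector or N x T matrix of measured potentials.
#' @param lambda ridge regularization parameter, `>= 0`.
#' @return `beta` with the same shape as `v`.
#' @export
solve_beta <- function(kset, v, lambda) {
  K <- if (inherits(kset, "kernel_set")) kset$K else as.matrix(kset)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stopf("`lambda` must be a single non-negative number",
          class = "skcsd_argument_error")
  }
  was_vector <- is.null(dim(v))
  v <- as.matrix(v)
  if (nrow(v) != nrow(K)) {
    stopf("length of the measurement vector (%d) != electrode count (%d)",
          nrow(v), nrow(K), class = "skcsd_argument_error")
  }
  A <- K + diag(lambda, nrow(K))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    stopf("(K + lambda I) is numerically singular; increase lambda",
          class = "skcsd_numeric_error")
  }
  tri_solve <- function(rhs) backsolve(ch, forwardsolve(t(ch), rhs))
  beta <- tri_solve(v)
  ## iterative refinement: cheap triangular re-solves reduce the residual of
  ## ill-conditioned systems (small lambda) until it stagnates at the
  ## conditioning floor
  vn <- sqrt(colSums(v^2))
  prev <- Inf
  for (it in 1:6) {
    r <- v - A %*% beta
    rn <- max(sqrt(colSums(r^2)) / pmax(vn, .Machine$double.xmin))
    if (rn <= 1e-10 || rn >= 0.5 * prev) break
    prev <- rn
    beta <- beta + tri_solve(r)
  }
  res <- sqrt(colSums((A %*% beta - v)^2))
  bad <- vn > 0 & res > 1e-8 * vn
  if (any(bad)) {
    warning(sprintf(
      "ridge solve residual %.3g exceeds 1e-8 relative (condition limit at lambda = %g)",
      max(res[bad] / vn[bad]), lambda))
  }
  if (was_vector) drop(beta) else beta
}

#' skCSD estimation
#'
#' Applies the regularized kernel solution per timepoint:
#' `C(s) = Kt^T(s) (K + lambda I)^{-1} V`. The factorization of
#' `(K + lambda I)` is performed once and reused across all timepoints; the
#' method is local in time, so each column of the potentials matrix is
#' processed independently. The loop CSD is then folded back onto the
#' morphology: summing the estimated density over all arc-length samples
#' that map to a segment gives the segment's current, and dividing by the
#' segment length gives the physical line density at that part of the cell
#' (the two traversals of the loop both contribute, as they must).
#'
#' @param kset a [build_kernels()] result.
#' @param rec a [recording_set()] (or a bare N x T matrix of potentials in
#'   microvolts) over the same electrodes.
#' @param lambda ridge regularization parameter.
#' @return An object of class `skcsd_estimate` with elements
#'   `s_grid`, `csd_loop` (G x T, nA/um of loop), `segment_current`
#'   (n_seg x T, nA), `segment_density` (n_seg x T, nA/um of cable),
#'   `times`, and `params` (M, R, lambda, sigma, ds).
#' @export
skcsd_estimate <- function(kset, rec, lambda) {
  V <- if (inherits(rec, "recording_set")) rec$potentials else as.matrix(rec)
  times <- if (inherits(rec, "recording_set")) rec$times else seq_len(ncol(V))
  if (nrow(V) != nrow(kset$K)) {
    stopf("recording has %d electrodes but kernels were built for %d",
          nrow(V), nrow(kset$K), class = "skcsd_argument_error")
  }
  beta <- solve_beta(kset, V / UV_PER_V, lambda)      # measurements in volts
  csd_loop <- kset$Ktilde %*% beta * NA_UM_PER_A_M    # G x T, nA/um
  fold <- fold_matrix(kset$loop, kset$s_grid)         # n_seg x G indicator
  seg_current <- (fold %*% csd_loop) * kset$ds        # nA per segment
  lens <- kset$loop$tree$segments$length
  structure(list(s_grid = kset$s_grid, csd_loop = csd_loop,
                 segment_current = seg_current,
                 segment_density = seg_current / lens,
                 times = times,
                 params = list(M = kset$cfg$M, R = kset$cfg$R,
                               lambda = lambda, sigma = kset$sigma,
                               ds = kset$ds)),
            class = "skcsd_estimate")
}

#' @export
print.skcsd_estimate <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "skcsd_estimate: %d segments x %d timepoints (M = %d, R = %g um, lambda = %g)\n",
    nrow(x$segment_current), ncol(x$segment_current), p$M, p$R, p$lambda))
  invisible(x)
}

## n_seg x G 0/1 matrix mapping quadrature grid points to segments; row
## order follows the segment table. Each segment's row selects the grid
## points of both of its loop traversals.
fold_matrix <- function(loop, s_grid) {
  loc <- loop_locate(loop, s_grid)
  ids <- loop$tree$segments$id
  F <- matrix(0, length(ids), length(s_grid))
  F[cbind(match(loc$seg, ids), seq_along(s_grid))] <- 1
  per_seg <- rowSums(F)
  if (any(per_seg < 4)) {
    warning(sprintf(
      "%d segment(s) receive fewer than 4 arc-length samples; decrease ds",
      sum(per_seg < 4)))
  }
  F
}

#' Fold a loop CSD onto the morphology
#'
#' Sums a sampled loop current density over the arc-length samples mapped
#' to each segment (both traversals), yielding the per-segment current.
#' The fold conserves total current:
#' `sum over segments == ds * sum over the grid`.
#'
#' @param csd_loop numeric G-vector or G x T matrix of line density
#'   (nA/um) on `s_grid`.
#' @param loop a [build_loop()] result.
#' @param s_grid the uniform arc-length grid the density is sampled on.
#' @return n_seg (x T) matrix of currents (nA), rows ordered as
#'   `loop$tree$segments`.
#' @export
fold_to_morphology <- function(csd_loop, loop, s_grid) {
  ds <- loop$l / length(s_grid)
  fold_matrix(loop, s_grid) %*% as.matrix(csd_loop) * ds
}
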