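#' Normalized L1 reconstruction error
#'
#' `sum |C - C*| / sum |C|` over all segments and timepoints, where `C` is
#' the (smoothed) ground truth and `C*` the reconstruction. The measure is
#' invariant under joint rescaling of both arguments.
#'
#' @param est reconstruction, n_seg x T matrix (or vector).
#' @param truth ground truth of the same shape; must not be all zero.
#' @return A single dimensionless error; 0 for a perfect reconstruction,
#'   1 for an all-zero one.
#' @export
l1_error <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  if (!identical(dim(est), dim(truth))) {
    stopf("est is %dx%d but truth is %dx%d", nrow(est), ncol(est),
          nrow(truth), ncol(truth), class = "skcsd_argument_error")
  }
  denom <- sum(abs(truth))
  if (denom == 0) {
    stopf("all-zero ground truth: L1 normalization undefined",
          class = "skcsd_argument_error")
  }
  sum(abs(truth - est)) / denom
}

## Spread per-segment currents (nA) onto the loop quadrature grid as a line
## density (nA/um): each segment's current is distributed uniformly over the
## grid points of its two traversals.
spread_to_loop <- function(seg_current, loop, s_grid) {
  seg_current <- as.matrix(seg_current)
  if (nrow(seg_current) != nrow(loop$tree$segments)) {
    stopf("ground truth has %d rows but the tree has %d segments",
          nrow(seg_current), nrow(loop$tree$segments),
          class = "skcsd_argument_error")
  }
  ds <- loop$l / length(s_grid)
  F <- fold_matrix(loop, s_grid)
  npts <- rowSums(F)                          # grid points per segment
  dens <- seg_current / (npts * ds)           # so the fold returns the input
  crossprod(F, dens)                          # G x T
}

#' Smooth a per-segment ground truth along the loop
#'
#' The estimator can only recover a coarse-grained version of an irregular
#' ground truth, so before computing [l1_error()] the ground truth is
#' convolved with a Gaussian kernel along the loop coordinate (circularly,
#' i.e. seamlessly across `s = 0`). The kernel follows the same convention
#' as the basis functions, `exp(-d^2 / width^2)` (half-max half-width
#' `width * sqrt(log(2))`), and is normalized to unit mass, so total
#' current is conserved. Validation protocols use a width of 15 um for the
#' ball-and-stick cell and 30 um for branched cells.
#'
#' @param seg_current n_seg x T matrix of per-segment currents (nA).
#' @param loop a [build_loop()] result for the same tree.
#' @param width Gaussian width parameter (micrometres).
#' @param ds grid step used for the convolution (micrometres); defaults to
#'   `min(width / 4, l / 4096)`.
#' @return Smoothed n_seg x T matrix of per-segment currents.
#' @export
smooth_ground_truth <- function(seg_current, loop, width, ds = NULL) {
  check_scalar_pos(width, "width")
  if (is.null(ds)) ds <- min(width / 4, loop$l / 4096)
  grid <- loop_grid(loop, ds)
  dens <- spread_to_loop(seg_current, loop, grid$s)        # G x T
  G <- grid$G
  ## circular Gaussian kernel centred at index 1
  off <- (seq_len(G) - 1) * grid$ds
  d <- pmin(off, loop$l - off)
  kern <- exp(-d^2 / width^2)
  kern <- kern / sum(kern)
  fk <- stats::fft(kern)
  sm <- Re(stats::mvfft(stats::mvfft(dens) * fk, inverse = TRUE)) / G
  fold_to_morphology(sm, loop, grid$s)
}

#' Leave-one-out cross-validation error
#'
#' For each electrode `k`, a kernel-interpolation model of the potential is
#' fitted from the other `N - 1` electrodes with the same `lambda`, the
#' potential at the held-out position is predicted as
#' `V^(x_k) = K[k, -k] (K[-k, -k] + lambda I)^{-1} V[-k]`, and squared
#' prediction errors are accumulated over electrodes and timepoints.
#' Because the potential basis does not depend on the electrode set, every
#' fold reuses submatrices of the full kernel. Both the raw sum and the
#' value normalized by the electrode count (comparable across setups of
#' different size) are returned, along with the per-(N*T) mean. Squared
#' errors are accumulated in SI units (volts squared), matching the scale
#' on which `lambda` acts.
#'
#' @param kset a [build_kernels()] result.
#' @param rec a [recording_set()] (or N x T potentials matrix).
#' @param lambda ridge parameter used inside every fold.
#' @return A list with `cv_error` (summed squared error), `cv_normalized`
#'   (`cv_error / N`), `cv_mean` (`cv_error / (N * T)`), and
#'   `per_electrode` contributions.
#' @export
loocv_error <- function(kset, rec, lambda) {
  V <- if (inherits(rec, "recording_set")) rec$potentials else as.matrix(rec)
  V <- V / UV_PER_V                      # microvolts -> volts, the kernel scale
  K <- kset$K
  N <- nrow(K)
  if (N < 2L) stopf("cross-validation needs at least 2 electrodes",
                    class = "skcsd_argument_error")
  if (nrow(V) != N) {
    stopf("recording has %d electrodes but kernels were built for %d",
          nrow(V), N, class = "skcsd_argument_error")
  }
  per <- numeric(N)
  for (k in seq_len(N)) {
    idx <- setdiff(seq_len(N), k)
    A <- K[idx, idx, drop = FALSE] + diag(lambda, N - 1L)
    beta <- tryCatch(solve(A, V[idx, , drop = FALSE]),
                     error = function(e) {
                       stopf("singular fold system at lambda = %g", lambda,
                             class = "skcsd_numeric_error")
                     })
    pred <- K[k, idx, drop = FALSE] %*% beta
    per[k] <- sum((V[k, ] - pred)^2)
  }
  list(cv_error = sum(per), cv_normalized = sum(per) / N,
       cv_mean = sum(per) / (N * ncol(V)), per_electrode = per)
}

#' Grid search over basis width and regularization
#'
#' Evaluates every `(R, lambda)` pair on the given recording, computing the
#' leave-one-out CV error, and -- when a ground truth is supplied -- the L1
#' error of the reconstruction against the smoothed ground truth. A
#' train/validation split over time is supported: parameters are selected
#' on `train_idx` and the reported `l1_validation` is computed on the
#' remaining timepoints. The default grids are `R = 8, 16, 32, 64, 128` um
#' and `lambda = 1e-5 ... 1e-1` (decades); ties are broken towards the
#' smallest `lambda`, then the smallest `R`.
#'
#' @param loop a [build_loop()] result.
#' @param rec a [recording_set()].
#' @param truth optional n_seg x T per-segment ground-truth currents (nA).
#' @param R_grid,lambda_grid parameter grids.
#' @param M number of basis functions (default 512).
#' @param sigma conductivity (S/m).
#' @param smooth_width Gaussian width (um) applied to the ground truth
#'   before the L1 comparison.
#' @param train_idx optional indices of the timepoints used for selection;
#'   default: all.
#' @param ds quadrature step override (um); default `min(R/10, l/4096)`
#'   per grid cell.
#' @return An object of class `selection_result`: list with `grid` (data
#'   frame: R, lambda, cv_error, cv_error_normalized and, with truth,
#'   l1_train, l1_validation), `best_by_cv`, `best_by_l1` (rows of the
#'   grid), and `n_electrodes`.
#' @export
grid_search <- function(loop, rec, truth = NULL,
                        R_grid = c(8, 16, 32, 64, 128),
                        lambda_grid = 10^(-5:-1),
                        M = 512, sigma = 0.3, smooth_width = 30,
                        train_idx = NULL, ds = NULL) {
  if (length(R_grid) == 0L || length(lambda_grid) == 0L) {
    stopf("parameter grids must be nonempty", class = "skcsd_argument_error")
  }
  V <- rec$potentials
  Tn <- ncol(V)
  if (is.null(train_idx)) train_idx <- seq_len(Tn)
  val_idx <- setdiff(seq_len(Tn), train_idx)
  truth_sm <- NULL
  if (!is.null(truth)) {
    truth_sm <- smooth_ground_truth(as.matrix(truth), loop, smooth_width)
  }
  rows <- list()
  for (R in sort(R_grid)) {
    cfg <- basis_config(M, R, loop$l)
    kset <- build_kernels(cfg, loop, rec$electrodes, sigma = sigma, ds = ds)
    for (lambda in sort(lambda_grid)) {
      cv <- loocv_error(kset, rec, lambda)
      row <- data.frame(R = R, lambda = lambda, cv_error = cv$cv_error,
                        cv_error_normalized = cv$cv_normalized)
      if (!is.null(truth_sm)) {
        est <- skcsd_estimate(kset, rec, lambda)
        row$l1_train <- l1_error(est$segment_current[, train_idx, drop = FALSE],
                                 truth_sm[, train_idx, drop = FALSE])
        row$l1_validation <- if (length(val_idx) > 0L) {
          l1_error(est$segment_current[, val_idx, drop = FALSE],
                   truth_sm[, val_idx, drop = FALSE])
        } else NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  grid <- do.call(rbind, rows)
  pick <- function(err) {
    ord <- order(err, grid$lambda, grid$R)   # tie-break: smallest lambda, then R
    grid[ord[1L], , drop = FALSE]
  }
  structure(list(grid = grid,
                 best_by_cv = pick(grid$cv_error),
                 best_by_l1 = if (!is.null(truth_sm)) pick(grid$l1_train) else NULL,
                 n_electrodes = nrow(V)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d grid cells, N = %d electrodes\n",
              nrow(x$grid), x$n_electrodes))
  cat("best by CV:  R =", x$best_by_cv$R, " lambda =", x$best_by_cv$lambda, "\n")
  if (!is.null(x$best_by_l1)) {
    cat("best by L1:  R =", x$best_by_l1$R, " lambda =", x$best_by_l1$lambda, "\n")
  }
  invisible(x)
}
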