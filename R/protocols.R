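# Reference validation protocols. These bundle the generator, forward model
# and estimator into the study designs used to characterize the method, so
# tests, scripts and vignettes run the exact same procedure.

#' Spatial-resolution protocol: cosine patterns vs electrode count
#'
#' For each spatial frequency `f`, a cosine current pattern (amplitude
#' 0.15 nA/um) is placed on the ball-and-stick cell, potentials are
#' forward-simulated at a laminar probe (600 um extent, 50 um from the
#' cable) with the requested electrode counts, and the reconstruction is
#' scored by the L1 error against the 15 um-smoothed ground truth. For
#' each `(f, n)` the error reported is the minimum over the `(R, lambda)`
#' grid -- the best reconstruction the method can produce with tuned
#' parameters, which is how spatial resolution is characterized.
#'
#' @param f_values spatial frequencies (cycles per cell length).
#' @param n_electrodes electrode counts of the laminar probe.
#' @param R_grid,lambda_grid parameter grids searched per pattern.
#' @param M number of basis functions.
#' @param sigma conductivity (S/m).
#' @param smooth_width ground-truth smoothing width (um).
#' @param tree morphology; default the 516 um / 53-segment cable.
#' @return Data frame with columns `f`, `n_electrodes`, `l1`, `R`,
#'   `lambda` (the grid cell attaining the minimum).
#' @export
protocol_cosine_resolution <- function(f_values = seq(0.5, 12.5, by = 0.5),
                                       n_electrodes = c(8, 128),
                                       R_grid = c(8, 16, 32, 64, 128),
                                       lambda_grid = 10^(-5:-1),
                                       M = 512, sigma = 0.3,
                                       smooth_width = 15,
                                       tree = make_ball_and_stick()) {
  loop <- build_loop(tree)
  out <- list()
  for (n in n_electrodes) {
    el <- electrode_layout("laminar", n = n, center_y = tree$total_length / 2)
    ksets <- lapply(R_grid, function(R) {
      build_kernels(basis_config(M, R, loop$l), loop, el, sigma = sigma)
    })
    for (f in f_values) {
      truth <- cosine_csd(tree, f = f)$current
      truth_sm <- smooth_ground_truth(truth, loop, smooth_width)
      rec <- forward_simulate(truth, loop, el, sigma = sigma)
      best <- NULL
      for (j in seq_along(R_grid)) {
        for (lambda in lambda_grid) {
          est <- skcsd_estimate(ksets[[j]], rec, lambda)
          err <- l1_error(est$segment_current, truth_sm)
          if (is.null(best) || err < best$l1) {
            best <- data.frame(f = f, n_electrodes = n, l1 = err,
                               R = R_grid[j], lambda = lambda)
          }
        }
      }
      out[[length(out) + 1L]] <- best
    }
  }
  do.call(rbind, out)
}

#' Noise-robustness protocol on the Y-shaped cell
#'
#' The two-synapse Y-shape protocol (simultaneous and separate activation
#' of synapses at segments 33 and 62 over 70 ms) recorded by a 4 x 8 grid
#' 50 um from the cell plane, corrupted with Gaussian white noise at the
#' given SNR values (`Inf` = noise-free), several seeds per level. Each
#' dataset is reconstructed with basis width `R`, with `lambda` chosen per
#' dataset as the minimizer of the L1 error over `lambda_grid`, and scored
#' against the 30 um-smoothed ground truth.
#'
#' @param snr_values signal-to-noise ratios (decreasing order typical).
#' @param seeds one reconstruction per seed and SNR.
#' @param R basis width (um).
#' @param lambda_grid candidate ridge parameters.
#' @param M,sigma as elsewhere.
#' @param dt time step of the simulated recording (ms).
#' @return Data frame with columns `snr`, `seed`, `l1`, `lambda`.
#' @export
protocol_noise_curve <- function(snr_values = c(Inf, 16, 4, 1),
                                 seeds = 1:5, R = 32,
                                 lambda_grid = 10^(-5:-1),
                                 M = 512, sigma = 0.3, dt = 0.5) {
  tree <- make_y_shape()
  loop <- build_loop(tree)
  times <- seq(dt, 70, by = dt)
  truth <- synaptic_csd(tree, y_shape_events(tree), times)
  truth_sm <- smooth_ground_truth(truth, loop, 30)
  el <- y_grid_electrodes(tree, nx = 4, ny = 8)
  clean <- forward_simulate(truth, loop, el, sigma = sigma, times = times)
  kset <- build_kernels(basis_config(M, R, loop$l), loop, el, sigma = sigma)
  out <- list()
  for (snr in snr_values) {
    for (seed in seeds) {
      rec <- if (is.finite(snr)) add_noise(clean, snr, seed = seed) else clean
      errs <- vapply(lambda_grid, function(lambda) {
        l1_error(skcsd_estimate(kset, rec, lambda)$segment_current, truth_sm)
      }, numeric(1L))
      j <- which.min(errs)
      out[[length(out) + 1L]] <- data.frame(snr = snr, seed = seed,
                                            l1 = errs[j],
                                            lambda = lambda_grid[j])
      if (!is.finite(snr)) break     # the noise-free dataset is unique
    }
  }
  do.call(rbind, out)
}

#' Cross-validation response to noise
#'
#' For each seed, the Y-shape protocol is simulated noise-free and with
#' Gaussian noise at the given SNR, and on each twin the ridge parameter
#' minimizing the leave-one-out CV error over `lambda_grid` is found.
#' Regularization should respond to noise: the noisy twin's optimal
#' `lambda` is expected to exceed the noiseless one in most repetitions.
#'
#' @inheritParams protocol_noise_curve
#' @param snr the noise level of the noisy twin.
#' @return Data frame with columns `seed`, `lambda_clean`, `lambda_noisy`.
#' @export
protocol_cv_lambda <- function(seeds = 1:10, snr = 4, R = 32,
                               lambda_grid = 10^(-5:-1),
                               M = 512, sigma = 0.3, dt = 0.5) {
  tree <- make_y_shape()
  loop <- build_loop(tree)
  times <- seq(dt, 70, by = dt)
  truth <- synaptic_csd(tree, y_shape_events(tree), times)
  el <- y_grid_electrodes(tree, nx = 4, ny = 8)
  clean <- forward_simulate(truth, loop, el, sigma = sigma, times = times)
  kset <- build_kernels(basis_config(M, R, loop$l), loop, el, sigma = sigma)
  cv_opt <- function(rec) {
    errs <- vapply(lambda_grid, function(lambda) {
      loocv_error(kset, rec, lambda)$cv_error
    }, numeric(1L))
    lambda_grid[which.min(errs)]
  }
  lam0 <- cv_opt(clean)
  out <- lapply(seeds, function(seed) {
    data.frame(seed = seed, lambda_clean = lam0,
               lambda_noisy = cv_opt(add_noise(clean, snr, seed = seed)))
  })
  do.call(rbind, out)
}

## 4 x 8 (or nx x ny) grid covering the bounding box of a cell lying in the
## z = 0 plane, 50 um above it.
y_grid_electrodes <- function(tree, nx = 4, ny = 8, offset = 50) {
  xs <- range(c(tree$segments$x0, tree$segments$x1))
  ys <- range(c(tree$segments$y0, tree$segments$y1))
  electrode_layout("grid", nx = nx, ny = ny,
                   pitch_x = max(diff(xs), 50) / max(nx - 1, 1),
                   pitch_y = max(diff(ys), 50) / max(ny - 1, 1),
                   center = c(mean(xs), mean(ys)), z_plane = offset)
}
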