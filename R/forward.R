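#' Electrode arrays
#'
#' @param positions numeric N x 3 matrix (or data frame) of electrode
#'   coordinates in micrometres.
#' @param labels unique electrode identifiers; defaults to `e1, e2, ...`.
#' @return An object of class `electrode_array`: a data frame with columns
#'   `label`, `x`, `y`, `z`.
#' @export
electrode_array <- function(positions, labels = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || nrow(positions) < 1L ||
      any(!is.finite(positions))) {
    stopf("electrode positions must be a finite N x 3 matrix",
          class = "skcsd_argument_error")
  }
  if (is.null(labels)) labels <- paste0("e", seq_len(nrow(positions)))
  if (anyDuplicated(labels)) {
    stopf("electrode labels must be unique", class = "skcsd_argument_error")
  }
  structure(data.frame(label = as.character(labels),
                       x = positions[, 1L], y = positions[, 2L],
                       z = positions[, 3L]),
            class = c("electrode_array", "data.frame"))
}

#' Read/write an electrode table (label, x, y, z in micrometres, TSV)
#' @param path file path.
#' @rdname electrode_array
#' @export
read_electrodes <- function(path) {
  if (!file.exists(path)) {
    stopf("electrode file not found: %s", path, class = "skcsd_data_error")
  }
  tab <- utils::read.table(path, header = TRUE)
  electrode_array(as.matrix(tab[, c("x", "y", "z")]), labels = tab$label)
}

#' @param electrodes an `electrode_array`.
#' @rdname electrode_array
#' @export
write_electrodes <- function(electrodes, path) {
  utils::write.table(as.data.frame(electrodes), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Unit contract, centralized. User-facing quantities: positions um,
## conductivity sigma S/m, line current density nA/um, potentials uV:
## V[uV] = (1e3 / (4 pi sigma)) * sum C(s) ds / r   with ds, r in um.
## The kernel matrices are assembled in SI units (volts per unit A/m source
## density): with ds and r both in um their ratio is dimensionless, so
## b_SI = (1 / (4 pi sigma)) * sum b~(s) ds / r. This keeps the Gram matrix
## K at order 1-100 so that the standard ridge grid lambda = 1e-5..1e-1 is
## numerically meaningful. 1 uV = 1e-6 V; 1 A/m = 1e3 nA/um.
potential_unit_scale <- function(sigma) {
  1e3 / (4 * pi * sigma)
}

kernel_unit_scale <- function(sigma) {
  1 / (4 * pi * sigma)
}

UV_PER_V <- 1e6
NA_UM_PER_A_M <- 1e3

## G x N matrix of distances from loop-grid points to electrodes, with the
## distance-floor policy applied. eps_d = 1 um: a line-source model is
## ill-posed for contacts closer than about one cable radius.
electrode_distances <- function(pts, electrodes, eps_d = 1,
                                on_close = c("error", "clamp")) {
  on_close <- match.arg(on_close)
  ex <- as.matrix(as.data.frame(electrodes)[, c("x", "y", "z")])
  D <- matrix(NA_real_, nrow(pts), nrow(ex))
  for (k in seq_len(nrow(ex))) D[, k] <- dist_to_point(pts, ex[k, ])
  if (any(D < eps_d)) {
    offending <- which(apply(D < eps_d, 2L, any))
    if (on_close == "error") {
      stopf(paste0("electrode(s) %s lie within %g um of the morphology loop; ",
                   "move them away or use on_close = \"clamp\""),
            paste(as.data.frame(electrodes)$label[offending], collapse = ", "),
            eps_d, class = "skcsd_data_error")
    }
    warning(sprintf("clamping %d electrode-curve distances to the %g um floor",
                    sum(D < eps_d), eps_d))
    D[D < eps_d] <- eps_d
  }
  D
}

#' Potential basis function at a point
#'
#' Line-integrates one Gaussian current-source basis function along the
#' morphology loop to obtain its extracellular potential at `electrode`,
#' assuming an infinite homogeneous medium of conductivity `sigma`:
#' `b_i(x) = 1/(4 pi sigma) * integral b~_i(s) / |x - f(s)| ds`,
#' evaluated by the midpoint rule with step `ds` (default
#' `min(R/10, l/4096)`). The cable is collapsed to its centre line.
#'
#' @param cfg a [basis_config()].
#' @param loop a [build_loop()] result (same loop the basis lives on).
#' @param i basis index.
#' @param electrode numeric length-3 position (micrometres).
#' @param sigma extracellular conductivity (S/m); 0.3 S/m is a standard
#'   value for cortical tissue.
#' @param ds quadrature step (micrometres).
#' @param on_close what to do when the electrode is within 1 um of the
#'   curve: `"error"` (strict) or `"clamp"` the distance to the floor.
#' @return Potential in microvolts per unit source weight (nA/um).
#' @export
potential_basis <- function(cfg, loop, i, electrode, sigma = 0.3,
                            ds = NULL, on_close = "error") {
  if (is.null(ds)) ds <- min(cfg$R / 10, loop$l / 4096)
  check_scalar_pos(ds, "ds")
  grid <- loop_grid(loop, ds)
  pts <- loop_point(loop, grid$s)
  D <- electrode_distances(pts, electrode_array(matrix(electrode, 1L)),
                           on_close = on_close)
  bt <- eval_basis(cfg, i, grid$s)
  potential_unit_scale(sigma) * sum(bt / D[, 1L]) * grid$ds
}

#' Assemble the skCSD kernel matrices
#'
#' Precomputes everything the estimator needs for a given basis, loop,
#' electrode array and conductivity: the basis evaluated on the quadrature
#' grid, the potential basis at the electrodes
#' `B[i, k] = b_i(x_k)` (midpoint rule, step `ds`), the electrode-space
#' kernel `K[j, k] = sum_i b_i(x_j) b_i(x_k)` (a symmetric PSD Gram
#' matrix), and the cross-kernel `Kt[g, k] = sum_i b~_i(s_g) b_i(x_k)`
#' sampled on the grid. The kernel matrices are held in SI units (volts
#' per unit A/m source density), which keeps `K` at order 1-100 so the
#' conventional ridge grid `lambda = 1e-5 .. 1e-1` is meaningful;
#' [skcsd_estimate()] converts measured microvolts and estimated nA/um at
#' its boundary.
#'
#' @inheritParams potential_basis
#' @param electrodes an [electrode_array()].
#' @return An object of class `kernel_set` with elements `K` (N x N),
#'   `Ktilde` (G x N), `B` (M x N), `Btilde` (M x G), `s_grid`, `ds`,
#'   `cfg`, `loop`, `sigma`, `electrodes`.
#' @export
build_kernels <- function(cfg, loop, electrodes, sigma = 0.3, ds = NULL,
                          on_close = "error") {
  stopifnot(inherits(cfg, "basis_config"), inherits(loop, "morphology_loop"))
  if (is.null(ds)) ds <- min(cfg$R / 10, loop$l / 4096)
  check_scalar_pos(ds, "ds")
  grid <- loop_grid(loop, ds)
  pts <- loop_point(loop, grid$s)
  D <- electrode_distances(pts, electrodes, on_close = on_close)
  Btilde <- basis_matrix(cfg, grid$s)                      # M x G
  W <- kernel_unit_scale(sigma) * grid$ds / D              # G x N (SI)
  B <- Btilde %*% W                                        # M x N: b_i(x_k), V per A/m
  K <- crossprod(B)                                        # N x N
  K <- (K + t(K)) / 2                                      # enforce exact symmetry
  Ktilde <- crossprod(Btilde, B)                           # G x N
  structure(list(K = K, Ktilde = Ktilde, B = B, Btilde = Btilde,
                 s_grid = grid$s, ds = grid$ds, cfg = cfg, loop = loop,
                 sigma = sigma, electrodes = electrodes),
            class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  cat(sprintf(
    "kernel_set: N = %d electrodes, M = %d, R = %g um, ds = %.3g um, sigma = %g S/m\n",
    nrow(x$K), x$cfg$M, x$cfg$R, x$ds, x$sigma))
  invisible(x)
}

#' Evaluate the cross-kernel at arbitrary arc lengths
#'
#' `Kt(s, k) = sum_i b~_i(s) b_i(x_k)` for the basis and potential basis
#' stored in a [build_kernels()] result.
#'
#' @param kset a `kernel_set`.
#' @param s arc lengths (micrometres, wrapped).
#' @param k electrode indices (default: all).
#' @return A `length(s) x length(k)` matrix.
#' @export
eval_cross_kernel <- function(kset, s, k = seq_len(nrow(kset$K))) {
  if (any(k < 1L) || any(k > nrow(kset$K))) {
    stopf("electrode index out of range", class = "skcsd_argument_error")
  }
  crossprod(basis_matrix(kset$cfg, s), kset$B[, k, drop = FALSE])
}

#' Brute-force forward potential from a sampled CSD
#'
#' Independent point-source oracle for the forward model: given a line
#' current density sampled on a fine arc-length grid, sums
#' `C(s) * ds / (4 pi sigma * |x - f(s)|)` over the grid. Used to
#' cross-check the analytic path `sum_i a_i b_i(x)` and to forward-simulate
#' arbitrary prescribed current distributions.
#'
#' @param csd numeric vector (length G) or G x T matrix of line current
#'   density (nA/um) sampled at `s_grid`.
#' @param loop a [build_loop()] result.
#' @param s_grid arc lengths of the samples; must be a uniform grid
#'   covering `[0, l)` (e.g. from the same quadrature step).
#' @param electrodes an [electrode_array()] or a single position.
#' @inheritParams potential_basis
#' @return Potentials in microvolts: an N-vector, or an N x T matrix.
#' @export
oracle_potential <- function(csd, loop, s_grid, electrodes, sigma = 0.3,
                             on_close = "error") {
  if (!inherits(electrodes, "electrode_array")) {
    electrodes <- electrode_array(matrix(electrodes, ncol = 3L))
  }
  ds <- loop$l / length(s_grid)
  pts <- loop_point(loop, s_grid)
  D <- electrode_distances(pts, electrodes, on_close = on_close)
  csd <- as.matrix(csd)
  out <- potential_unit_scale(sigma) * ds * crossprod(1 / D, csd)
  if (ncol(out) == 1L) drop(out) else out
}
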