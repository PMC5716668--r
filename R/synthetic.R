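#' Ball-and-stick test morphology
#'
#' A straight cable along the +y axis divided into equal segments; the
#' first `n_soma` segments represent the soma (default two segments of
#' 20 um diameter), the rest the dendrite (4 um diameter). The default
#' geometry is a 516 um cell of 53 segments; `length = 500, n_segments =
#' 52` gives the slightly shorter variant used in some protocols.
#'
#' @param length total cable length (micrometres).
#' @param n_segments number of segments (`>= 2`).
#' @param soma_diam,dend_diam diameters (micrometres).
#' @param n_soma number of soma segments.
#' @return A [segment_tree()].
#' @export
make_ball_and_stick <- function(length = 516, n_segments = 53,
                                soma_diam = 20, dend_diam = 4, n_soma = 2) {
  check_scalar_pos(length, "length")
  if (n_segments < 2L) {
    stopf("need at least 2 segments", class = "skcsd_argument_error")
  }
  h <- length / n_segments
  y0 <- (seq_len(n_segments) - 1) * h
  seg <- data.frame(
    id = seq_len(n_segments),
    parent = 0:(n_segments - 1L),
    x0 = 0, y0 = y0, z0 = 0,
    x1 = 0, y1 = y0 + h, z1 = 0,
    radius = ifelse(seq_len(n_segments) <= n_soma, soma_diam / 2, dend_diam / 2),
    tag = ifelse(seq_len(n_segments) <= n_soma, 1L, 3L))
  segment_tree(seg, root_pos = c(0, 0, 0), root_radius = soma_diam / 2,
               root_tag = 1L)
}

#' Y-shaped test morphology
#'
#' A bifurcating cell of 848 um total length and 86 equal segments in the
#' z = 0 plane: a 32-segment stem along +y (segments 1-32, the first two
#' soma-calibre), then two 27-segment branches at +/- `angle` from the
#' stem axis (segments 33-59 and 60-86). Segments 33 and 62 -- the
#' canonical synapse targets used in validation -- therefore sit on
#' different branches close to the branching point.
#'
#' @param length total cable length (micrometres).
#' @param n_stem,n_branch segment counts of the stem and of each branch.
#' @param angle branch half-opening angle from the stem direction (radians).
#' @param soma_diam,dend_diam diameters (micrometres).
#' @return A [segment_tree()] with `n_stem + 2 * n_branch` segments.
#' @export
make_y_shape <- function(length = 848, n_stem = 32, n_branch = 27,
                         angle = pi / 6, soma_diam = 20, dend_diam = 4) {
  n_tot <- n_stem + 2L * n_branch
  h <- length / n_tot
  mk_chain <- function(ids, parent0, start, dir, radius, tag) {
    k <- seq_along(ids)
    data.frame(id = ids,
               parent = c(parent0, ids[-length(ids)]),
               x0 = start[1L] + (k - 1) * h * dir[1L],
               y0 = start[2L] + (k - 1) * h * dir[2L],
               z0 = start[3L] + (k - 1) * h * dir[3L],
               x1 = start[1L] + k * h * dir[1L],
               y1 = start[2L] + k * h * dir[2L],
               z1 = start[3L] + k * h * dir[3L],
               radius = radius, tag = tag)
  }
  stem <- mk_chain(1:n_stem, 0L, c(0, 0, 0), c(0, 1, 0), dend_diam / 2, 3L)
  stem$radius[1:2] <- soma_diam / 2
  stem$tag[1:2] <- 1L
  fork <- c(0, n_stem * h, 0)
  a <- mk_chain(n_stem + (1:n_branch), n_stem, fork,
                c(sin(angle), cos(angle), 0), dend_diam / 2, 3L)
  b <- mk_chain(n_stem + n_branch + (1:n_branch), n_stem, fork,
                c(-sin(angle), cos(angle), 0), dend_diam / 2, 3L)
  segment_tree(rbind(stem, a, b), root_pos = c(0, 0, 0),
               root_radius = soma_diam / 2, root_tag = 1L)
}

#' Electrode layout generators
#'
#' Standard validation layouts, all returning an [electrode_array()]:
#' \describe{
#'   \item{laminar}{`n` contacts evenly spaced along a line of extent
#'     `span` (default 600 um) parallel to the y axis, offset by `offset`
#'     (default 50 um) along x and centred on `center_y`.}
#'   \item{grid}{an `nx` x `ny` rectangular grid with pitches `pitch_x`,
#'     `pitch_y` in the plane `z = z_plane`, centred on `center`.}
#'   \item{hexagonal}{`nx` x `ny` contacts on a triangular lattice with
#'     nearest-neighbour distance `pitch` (rows `pitch * sqrt(3)/2` apart,
#'     odd rows shifted by `pitch / 2`).}
#'   \item{random}{`n` contacts uniform in the rectangle `xlim` x `ylim`
#'     at `z = z_plane`, reproducible for a given `seed`.}
#' }
#'
#' @param kind one of `"laminar"`, `"grid"`, `"hexagonal"`, `"random"`.
#' @param n number of contacts (laminar, random).
#' @param span,offset,center_y laminar line extent, x offset and y centre (um).
#' @param nx,ny grid/hexagonal dimensions.
#' @param pitch,pitch_x,pitch_y inter-electrode distances (um).
#' @param center length-2 (x, y) centre of grid layouts (um).
#' @param z_plane z coordinate of planar layouts (um).
#' @param xlim,ylim sampling rectangle for the random layout (um).
#' @param seed RNG seed for the random layout.
#' @return An [electrode_array()].
#' @export
electrode_layout <- function(kind = c("laminar", "grid", "hexagonal", "random"),
                             n = 8, span = 600, offset = 50, center_y = 0,
                             nx = 4, ny = 8, pitch = 50,
                             pitch_x = pitch, pitch_y = pitch,
                             center = c(0, 0), z_plane = 50,
                             xlim = c(-100, 100), ylim = c(0, 600),
                             seed = NULL) {
  kind <- match.arg(kind)
  pos <- switch(kind,
    laminar = {
      if (n < 1L) stopf("n >= 1 required", class = "skcsd_argument_error")
      y <- if (n == 1L) center_y else
        seq(center_y - span / 2, center_y + span / 2, length.out = n)
      cbind(offset, y, 0)
    },
    grid = {
      gx <- (seq_len(nx) - (nx + 1) / 2) * pitch_x + center[1L]
      gy <- (seq_len(ny) - (ny + 1) / 2) * pitch_y + center[2L]
      g <- expand.grid(x = gx, y = gy)
      cbind(g$x, g$y, z_plane)
    },
    hexagonal = {
      check_scalar_pos(pitch, "pitch")
      rows <- lapply(seq_len(ny), function(r) {
        x <- (seq_len(nx) - (nx + 1) / 2) * pitch +
          ifelse(r %% 2 == 0, pitch / 2, 0) + center[1L]
        y <- (r - (ny + 1) / 2) * pitch * sqrt(3) / 2 + center[2L]
        cbind(x, y, z_plane)
      })
      do.call(rbind, rows)
    },
    random = with_seed(seed, {
      cbind(stats::runif(n, xlim[1L], xlim[2L]),
            stats::runif(n, ylim[1L], ylim[2L]),
            z_plane)
    }))
  electrode_array(pos)
}

#' Cosine ground-truth CSD pattern on a straight cable
#'
#' The spatial-resolution test pattern: a cosine line density
#' `CSD(x) = A cos(2 pi f x / L)` along an unbranched cable, where `x` is
#' the distance from the root, `L` the cable length, `f` the spatial
#' frequency in cycles per cell length and `A` the amplitude
#' (default 0.15 nA/um).
#'
#' @param tree an unbranched [segment_tree()].
#' @param f spatial frequency (cycles per cell length), e.g. from
#'   `seq(0.5, 12.5, by = 0.5)`.
#' @param A amplitude (nA/um).
#' @return A list with `density` (nA/um at the segment midpoints) and
#'   `current` (nA per segment, `density * length`), each an
#'   n_seg x 1 matrix.
#' @export
cosine_csd <- function(tree, f, A = 0.15) {
  seg <- tree$segments
  if (any(table(seg$parent[seg$parent != 0]) > 1L) ||
      sum(seg$parent == 0L) > 1L) {
    stopf("cosine pattern is defined along a single unbranched cable",
          class = "skcsd_argument_error")
  }
  check_scalar_pos(A, "A")
  L <- tree$total_length
  x_mid <- cumsum(seg$length) - seg$length / 2
  dens <- A * cos(2 * pi * f * x_mid / L)
  list(density = matrix(dens, ncol = 1L),
       current = matrix(dens * seg$length, ncol = 1L))
}

#' Synaptic-event ground-truth CSD
#'
#' Prescribed current dynamics emulating synaptic activation: each event
#' contributes a current sink `-A exp(-(t - t0) / tau)` on its segment for
#' `t >= t0` (a discontinuous conductance change followed by exponential
#' decay; `tau = 2` ms is the canonical synaptic time constant). Because a
#' real cell's membrane currents sum to zero at every instant (the return
#' currents flow out elsewhere), the generator balances each sink with a
#' distributed source of equal total magnitude, by default spread over all
#' other segments proportionally to membrane area (`2 pi r * length`);
#' `balance = "none"` disables closure.
#'
#' @param tree a [segment_tree()].
#' @param events data frame with columns `seg` (segment id), `onset` (ms),
#'   `amplitude` (nA, peak sink magnitude) and `tau` (ms).
#' @param times numeric vector of timepoints (ms).
#' @param balance `"area"` (default) or `"none"`.
#' @return n_seg x length(times) matrix of per-segment currents (nA);
#'   with balancing, every column sums to zero to machine precision.
#' @export
synaptic_csd <- function(tree, events, times, balance = c("area", "none")) {
  balance <- match.arg(balance)
  seg <- tree$segments
  if (!all(events$seg %in% seg$id)) {
    stopf("event segment(s) not in the tree", class = "skcsd_argument_error")
  }
  n <- nrow(seg)
  out <- matrix(0, n, length(times))
  area <- 2 * pi * seg$radius * seg$length
  for (e in seq_len(nrow(events))) {
    i <- match(events$seg[e], seg$id)
    amp <- -events$amplitude[e] *
      exp(-(times - events$onset[e]) / events$tau[e]) *
      (times >= events$onset[e])
    out[i, ] <- out[i, ] + amp
    if (balance == "area") {
      w <- area
      w[i] <- 0
      w <- w / sum(w)
      out <- out - w %o% amp              # return current: opposite sign
    }
  }
  out
}

#' Canonical Y-shape synaptic protocol
#'
#' Two synapses close to the branching point on different branches
#' (segments 33 and 62), the first active at 5, 45 and 60 ms, the second
#' at 5, 25 and 60 ms, over a 70 ms simulation.
#'
#' @param tree a [make_y_shape()] tree.
#' @param amplitude peak sink magnitude per event (nA).
#' @param tau synaptic decay time constant (ms).
#' @return The events data frame accepted by [synaptic_csd()].
#' @export
y_shape_events <- function(tree, amplitude = 1, tau = 2) {
  data.frame(seg = c(33L, 33L, 33L, 62L, 62L, 62L),
             onset = c(5, 45, 60, 5, 25, 60),
             amplitude = amplitude, tau = tau)
}

#' Forward-simulate extracellular potentials from a prescribed CSD
#'
#' Spreads each segment's current uniformly along the segment's two loop
#' traversals and applies the point-source forward sum
#' ([oracle_potential()]) per timepoint, yielding the potentials an ideal
#' electrode array would record from that current distribution. This
#' replaces biophysical membrane simulation with prescribed-CSD forward
#' modelling: any per-segment current matrix can serve as ground truth.
#'
#' @param truth n_seg x T matrix of per-segment currents (nA).
#' @param loop a [build_loop()] result for the same tree.
#' @param electrodes an [electrode_array()].
#' @param sigma conductivity (S/m).
#' @param times time axis (ms) for the resulting [recording_set()].
#' @param ds quadrature step (um), default `l / 4096`.
#' @param on_close distance-floor policy, see [potential_basis()].
#' @return A [recording_set()] with potentials in microvolts.
#' @export
forward_simulate <- function(truth, loop, electrodes, sigma = 0.3,
                             times = NULL, ds = NULL, on_close = "error") {
  if (is.null(ds)) ds <- loop$l / 4096
  grid <- loop_grid(loop, ds)
  dens <- spread_to_loop(as.matrix(truth), loop, grid$s)
  V <- oracle_potential(dens, loop, grid$s, electrodes, sigma = sigma,
                        on_close = on_close)
  recording_set(electrodes, matrix(V, nrow = nrow(as.data.frame(electrodes))),
                times)
}

#' Add calibrated Gaussian white noise to a recording
#'
#' The signal-to-noise ratio is defined as the standard deviation of the
#' clean potentials (pooled over all channels and timepoints) divided by
#' the standard deviation of the added noise; noise is i.i.d. Gaussian
#' across channels and time and reproducible for a given seed.
#'
#' @param rec a [recording_set()].
#' @param snr target signal-to-noise ratio (`> 0`); validation protocols
#'   use 16, 4 and 1.
#' @param seed RNG seed.
#' @return A [recording_set()] with noisy potentials.
#' @export
add_noise <- function(rec, snr, seed = NULL) {
  check_scalar_pos(snr, "snr")
  sd_clean <- stats::sd(as.vector(rec$potentials))
  if (sd_clean == 0) {
    stopf("clean recording has zero variance; SNR undefined",
          class = "skcsd_data_error")
  }
  noise <- with_seed(seed, matrix(
    stats::rnorm(length(rec$potentials), sd = sd_clean / snr),
    nrow(rec$potentials)))
  recording_set(rec$electrodes, rec$potentials + noise, rec$times)
}
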