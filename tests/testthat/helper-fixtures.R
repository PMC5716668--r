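# Shared fixtures, built in code. Kernel construction is the expensive part
# of most tests, so the common ones are created once per test run.

fix_bs <- make_ball_and_stick()
fix_bs_loop <- build_loop(fix_bs)
fix_y <- make_y_shape()
fix_y_loop <- build_loop(fix_y)

# single-segment "cell": 100 um straight cable
fix_single <- segment_tree(
  data.frame(id = 1L, parent = 0L, x0 = 0, y0 = 0, z0 = 0,
             x1 = 0, y1 = 100, z1 = 0, radius = 2, tag = 3L),
  root_pos = c(0, 0, 0))

# write a tiny SWC file and return its path
write_tiny_swc <- function(lines, path = tempfile(fileext = ".swc")) {
  writeLines(lines, path)
  path
}

# rigid rotation of a tree (z-axis by `theta`) plus translation, for
# isotropy checks
transform_tree <- function(tree, theta = 0, shift = c(0, 0, 0)) {
  Rm <- matrix(c(cos(theta), sin(theta), 0,
                 -sin(theta), cos(theta), 0,
                 0, 0, 1), 3L, 3L)
  seg <- tree$segments
  p0 <- as.matrix(seg[, c("x0", "y0", "z0")]) %*% Rm
  p1 <- as.matrix(seg[, c("x1", "y1", "z1")]) %*% Rm
  seg[, c("x0", "y0", "z0")] <- sweep(p0, 2L, -shift)
  seg[, c("x1", "y1", "z1")] <- sweep(p1, 2L, -shift)
  segment_tree(seg, root_pos = drop(tree$root_pos %*% Rm) + shift,
               root_radius = tree$root_radius, root_tag = tree$root_tag)
}

transform_points <- function(xyz, theta = 0, shift = c(0, 0, 0)) {
  Rm <- matrix(c(cos(theta), sin(theta), 0,
                 -sin(theta), cos(theta), 0,
                 0, 0, 1), 3L, 3L)
  sweep(as.matrix(xyz) %*% Rm, 2L, -shift)
}

# oriented endpoints of a loop traversal, recomputed independently of the
# package internals
visit_endpoints_for_test <- function(loop, i) {
  v <- loop$visits[i, ]
  s <- loop$tree$segments[match(v$seg, loop$tree$segments$id), ]
  if (v$dir > 0L) list(a = c(s$x0, s$y0, s$z0), b = c(s$x1, s$y1, s$z1))
  else list(a = c(s$x1, s$y1, s$z1), b = c(s$x0, s$y0, s$z0))
}

loop_grid_for_test <- function(loop, ds) {
  G <- ceiling(loop$l / ds)
  list(s = (seq_len(G) - 0.5) * loop$l / G, G = G)
}

# 4 x 8 grid spanning a planar cell's bounding box, 50 um above it
y_grid_for_acceptance <- function(tree) {
  xs <- range(c(tree$segments$x0, tree$segments$x1))
  ys <- range(c(tree$segments$y0, tree$segments$y1))
  electrode_layout("grid", nx = 4, ny = 8,
                   pitch_x = diff(xs) / 3, pitch_y = diff(ys) / 7,
                   center = c(mean(xs), mean(ys)), z_plane = 50)
}
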