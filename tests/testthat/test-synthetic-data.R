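test_that("test morphologies match their stated geometry", {
  expect_equal(fix_bs$total_length, 516)
  expect_equal(nrow(fix_bs$segments), 53L)
  variant <- make_ball_and_stick(length = 500, n_segments = 52)
  expect_equal(variant$total_length, 500)
  expect_equal(nrow(variant$segments), 52L)
  expect_error(make_ball_and_stick(n_segments = 1), "at least 2")

  expect_equal(fix_y$total_length, 848, tolerance = 1e-12)
  expect_equal(nrow(fix_y$segments), 86L)
  kids <- table(fix_y$segments$parent)
  expect_equal(sum(kids == 2L), 1L)            # exactly one branch point
  # synapse target segments 33 and 62 lie on different branches
  lineage <- function(id) {
    path <- integer(0)
    while (id != 0L) {
      path <- c(path, id)
      id <- fix_y$segments$parent[match(id, fix_y$segments$id)]
    }
    path
  }
  l33 <- lineage(33L); l62 <- lineage(62L)
  expect_false(33L %in% l62)
  expect_false(62L %in% l33)
  # both close to the branching point (within 3 segment lengths)
  h <- 848 / 86
  fork_y <- fix_y$segments$y1[32L]
  mid <- function(id) {
    s <- fix_y$segments[match(id, fix_y$segments$id), ]
    c((s$x0 + s$x1) / 2, (s$y0 + s$y1) / 2, (s$z0 + s$z1) / 2)
  }
  expect_lt(sqrt(sum((mid(33L) - c(0, fork_y, 0))^2)), 3 * h)
  expect_lt(sqrt(sum((mid(62L) - c(0, fork_y, 0))^2)), 3 * h)
})

test_that("electrode layouts honor their stated geometry", {
  lam <- electrode_layout("laminar", n = 8, center_y = 300)
  expect_equal(nrow(lam), 8L)
  expect_equal(unique(lam$x), 50)
  expect_equal(diff(lam$y), rep(600 / 7, 7))

  hex <- electrode_layout("hexagonal", nx = 6, ny = 6, pitch = 17.5)
  D <- as.matrix(dist(hex[, c("x", "y", "z")]))
  diag(D) <- Inf
  expect_equal(min(D), 17.5, tolerance = 1e-9)
  nn <- apply(D, 1L, min)
  expect_true(all(abs(nn - 17.5) < 1e-9))

  g <- electrode_layout("grid", nx = 4, ny = 8, pitch = 50)
  expect_equal(nrow(g), 32L)

  r1 <- electrode_layout("random", n = 20, seed = 11)
  r2 <- electrode_layout("random", n = 20, seed = 11)
  expect_identical(r1, r2)
  r3 <- electrode_layout("random", n = 20, seed = 12)
  expect_false(identical(r1, r3))
  expect_error(electrode_layout("spiral"), "arg")
})

test_that("seeded generators leave the caller's RNG stream untouched", {
  set.seed(99)
  ref <- rnorm(3)
  set.seed(99)
  invisible(electrode_layout("random", n = 5, seed = 4))
  expect_identical(rnorm(3), ref)
})

test_that("cosine pattern follows the stated profile on a straight cable", {
  cc <- cosine_csd(fix_bs, f = 1)
  seg <- fix_bs$segments
  x_mid <- cumsum(seg$length) - seg$length / 2
  expect_equal(drop(cc$density), 0.15 * cos(2 * pi * x_mid / 516))
  expect_lte(max(abs(cc$density)), 0.15)
  # whole periods integrate to zero
  for (f in c(1, 4, 12)) {
    tot <- sum(cosine_csd(fix_bs, f = f)$current)
    expect_lt(abs(tot), 1e-3 * 0.15 * 516)
  }
  expect_error(cosine_csd(fix_y, f = 1), "unbranched")
})

test_that("synaptic events decay exponentially and currents balance", {
  times <- seq(0, 20, by = 0.5)
  ev <- data.frame(seg = 10L, onset = 4, amplitude = 2, tau = 2)
  out <- synaptic_csd(fix_y, ev, times)
  expect_lt(max(abs(colSums(out))), 1e-9)
  # at t0 + tau the sink amplitude is A / e
  expect_equal(out[10L, times == 6], -2 * exp(-1))
  expect_true(all(out[10L, times < 4] == 0))
  # unbalanced mode reproduces the raw sink
  raw <- synaptic_csd(fix_y, ev, times, balance = "none")
  expect_equal(raw[10L, ], out[10L, ])
  expect_true(all(raw[-10L, ] == 0))
  # canonical Y protocol: sinks only on segments 33 and 62 at their onsets
  yd <- synaptic_csd(fix_y, y_shape_events(fix_y), seq(0.5, 70, 0.5),
                     balance = "none")
  active <- which(rowSums(abs(yd)) > 0)
  expect_setequal(active, c(33L, 62L))
  t33 <- seq(0.5, 70, 0.5)[which(yd[33L, ] < 0)]
  expect_equal(min(t33), 5)
  expect_true(all(yd[62L, seq(0.5, 70, 0.5) < 5] == 0))
  expect_error(synaptic_csd(fix_y, data.frame(seg = 999L, onset = 0,
                                              amplitude = 1, tau = 2),
                            times), "not in the tree")
})

test_that("forward simulation is linear and distinguishes dipoles", {
  el <- electrode_layout("laminar", n = 8, center_y = 258)
  truth <- matrix(0, 53, 2); truth[20, 1] <- 1; truth[20, 2] <- 2
  rec <- forward_simulate(truth, fix_bs_loop, el)
  expect_equal(rec$potentials[, 2L], 2 * rec$potentials[, 1L])
  rec0 <- forward_simulate(matrix(0, 53, 1), fix_bs_loop, el)
  expect_true(all(rec0$potentials == 0))
  # +q/-q on adjacent segments decays faster with distance than a lone +q
  mono <- matrix(0, 53, 1); mono[20, 1] <- 1
  dip <- matrix(0, 53, 1); dip[20, 1] <- 1; dip[21, 1] <- -1
  probe <- function(truth, d) {
    e <- electrode_array(rbind(c(d, 190, 0)))
    abs(forward_simulate(truth, fix_bs_loop, e)$potentials[1L, 1L])
  }
  fall_mono <- probe(mono, 100) / probe(mono, 400)
  fall_dip <- probe(dip, 100) / probe(dip, 400)
  expect_gt(fall_dip, 2 * fall_mono)
})

test_that("added noise is calibrated to the requested SNR and seeded", {
  el <- electrode_layout("laminar", n = 8, center_y = 258)
  set.seed(2)
  rec <- recording_set(el, matrix(rnorm(8 * 2000), 8))
  nz1 <- add_noise(rec, snr = 1, seed = 31)
  ratio <- sd(rec$potentials) / sd(nz1$potentials - rec$potentials)
  expect_gt(ratio, 0.95); expect_lt(ratio, 1.05)
  expect_identical(add_noise(rec, 1, seed = 31)$potentials, nz1$potentials)
  # snr = 16: essentially every sample perturbed by less than the clean sd
  nz16 <- add_noise(rec, snr = 16, seed = 31)
  pert <- abs(nz16$potentials - rec$potentials)
  expect_equal(mean(pert < sd(rec$potentials)), 1)
  expect_error(add_noise(recording_set(el, matrix(1, 8, 10)), 4), "variance")
  expect_error(add_noise(rec, 0), "positive")
})
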