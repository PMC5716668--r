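test_that("L1 error identities and scale invariance", {
  set.seed(5)
  C <- matrix(rnorm(53 * 4), 53)
  expect_equal(l1_error(C, C), 0)
  expect_equal(l1_error(0 * C, C), 1)
  expect_equal(l1_error(2 * C, C), 1)
  expect_equal(l1_error(3.7 * C, 3.7 * (C + 1)), l1_error(C, C + 1))
  expect_error(l1_error(C, 0 * C), "all-zero")
  expect_error(l1_error(C, C[1:10, ]), "truth")
})

test_that("ground-truth smoothing conserves mass and spreads as a Gaussian", {
  q <- 2.5
  impulse <- matrix(0, 86, 1); impulse[40, 1] <- q
  sm <- smooth_ground_truth(impulse, fix_y_loop, 30)
  expect_equal(sum(sm), q, tolerance = 1e-6)
  # width far below the segment length leaves the input nearly unchanged
  tiny <- smooth_ground_truth(impulse, fix_y_loop, 0.1)
  expect_equal(tiny, impulse, tolerance = 0.02)
  # half-max spread: compare the FFT path against a direct discrete
  # convolution oracle on the loop grid
  w <- 20
  ds <- 0.25
  G <- round(fix_y_loop$l / ds)
  s <- (seq_len(G) - 0.5) * (fix_y_loop$l / G)
  x <- numeric(G); x[1000] <- 1
  off <- (seq_len(G) - 1) * (fix_y_loop$l / G)
  d <- pmin(off, fix_y_loop$l - off)
  kern <- exp(-d^2 / w^2); kern <- kern / sum(kern)
  direct <- sapply(seq(900, 1100, by = 10), function(j) {
    sum(x * kern[((1000 - j) %% G) + 1L])
  })
  prof <- Re(stats::fft(stats::fft(x) * stats::fft(kern), inverse = TRUE)) / G
  expect_equal(prof[seq(900, 1100, by = 10)], direct, tolerance = 1e-12)
  half <- range(s[prof >= max(prof) / 2])
  expect_equal(diff(half), 2 * w * sqrt(log(2)), tolerance = 0.1)
})

test_that("leave-one-out CV exploits duplicate information and is symmetric", {
  # two co-located electrode pairs: leaving one of a pair out predicts it
  # from its twin exactly as lambda -> 0
  base <- electrode_layout("laminar", n = 8, center_y = 258)
  pos <- as.matrix(base[, c("x", "y", "z")])
  ea <- electrode_array(rbind(pos, pos))
  kset <- build_kernels(basis_config(64, 32, fix_bs_loop$l), fix_bs_loop, ea)
  V <- matrix(1e3 * kset$B[30, ], ncol = 1)
  errs <- vapply(c(1e-2, 1e-4, 1e-6, 1e-8), function(lam) {
    loocv_error(kset, V, lam)$cv_error
  }, numeric(1L))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4L], 1e-12 * sum((V / 1e6)^2))
  # permutation invariance
  perm <- sample(nrow(ea))
  ea_p <- electrode_array(as.matrix(ea[perm, c("x", "y", "z")]))
  kset_p <- build_kernels(basis_config(64, 32, fix_bs_loop$l), fix_bs_loop, ea_p)
  expect_equal(loocv_error(kset_p, V[perm, , drop = FALSE], 1e-3)$cv_error,
               loocv_error(kset, V, 1e-3)$cv_error, tolerance = 1e-9)
})

test_that("CV folds are independent: corrupting one channel acts locally", {
  ea <- electrode_layout("laminar", n = 12, center_y = 258)
  kset <- build_kernels(basis_config(64, 32, fix_bs_loop$l), fix_bs_loop, ea)
  V <- matrix(1e3 * kset$B[40, ], ncol = 1)
  ref <- loocv_error(kset, V, 1e-3)
  V2 <- V; V2[5, ] <- V2[5, ] + 50
  pert <- loocv_error(kset, V2, 1e-3)
  again <- loocv_error(kset, V2, 1e-3)
  expect_identical(pert$cv_error, again$cv_error)
  # fold 5 absorbs roughly the squared corruption (50 uV = 5e-5 V)
  expect_gt(pert$per_electrode[5L] - ref$per_electrode[5L], 0.5 * (5e-5)^2)
  expect_lt(pert$per_electrode[5L] - ref$per_electrode[5L], 2 * (5e-5)^2)
  expect_error(loocv_error(kset, V[1, , drop = FALSE], 1e-3), "electrodes")
})

test_that("grid search evaluates the full grid with deterministic tie-breaks", {
  ea <- electrode_layout("laminar", n = 8, center_y = 258)
  # all-zero recording: every grid cell has CV error 0, so the tie-break
  # (smallest lambda, then smallest R) decides
  rec0 <- recording_set(ea, matrix(0, 8, 2))
  sel0 <- grid_search(fix_bs_loop, rec0, R_grid = c(16, 8),
                      lambda_grid = c(1e-3, 1e-5), M = 32)
  expect_equal(nrow(sel0$grid), 4L)
  expect_equal(sel0$best_by_cv$lambda, 1e-5)
  expect_equal(sel0$best_by_cv$R, 8)
  expect_error(grid_search(fix_bs_loop, rec0, R_grid = numeric(0)),
               "nonempty")
})

test_that("grid search finds parameters that beat most of the grid", {
  loop <- fix_bs_loop
  cfg_true <- basis_config(512, 32, loop$l)
  ea <- electrode_layout("laminar", n = 16, center_y = 258)
  a <- numeric(512); a[200] <- 1
  grid <- loop_grid_for_test(loop, loop$l / 2048)
  C <- csd_from_weights(cfg_true, a, grid$s)
  truth <- fold_to_morphology(C, loop, grid$s)
  rec <- forward_simulate(truth, loop, ea)
  sel <- grid_search(loop, rec, truth = truth, M = 128, smooth_width = 15,
                     R_grid = c(16, 32, 64), lambda_grid = 10^(-5:-1))
  expect_lte(sel$best_by_l1$l1_train, min(sel$grid$l1_train))
  expect_gte(mean(sel$grid$l1_train > sel$best_by_l1$l1_train + 1e-12), 0.9)
  # best rows attain the minima of their columns
  expect_equal(sel$best_by_cv$cv_error, min(sel$grid$cv_error))
})


test_that("regularization responds to noise in most repetitions", {
  res <- protocol_cv_lambda(seeds = 1:4, dt = 2)
  expect_gte(mean(res$lambda_noisy > res$lambda_clean), 0.75)
})
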