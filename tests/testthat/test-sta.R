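# Synthetic paired recording: spikelet template on every channel at known
# spike times, plus slow sinusoidal background and white noise.
make_paired <- function(n_spikes = 150, fs = 20000, n_chan = 8,
                        dur_s = NULL, noise_sd = 20, drift_amp = 200,
                        seed = 123) {
  spacing <- 0.02 * fs                          # 20 ms apart
  margin <- 0.01 * fs
  Tn <- as.integer(if (is.null(dur_s)) (n_spikes + 2) * spacing
                   else dur_s * fs)
  spike_idx <- as.integer(margin + spacing * seq_len(n_spikes))
  w <- round(0.005 * fs)
  tt <- (-w:w) / fs * 1000                      # ms
  template <- t(sapply(seq_len(n_chan), function(ch) {
    -80 * exp(-(tt - 0.2)^2 / 0.05) * (1 + 0.1 * ch) +
      30 * exp(-(tt - 1)^2 / 0.3)
  }))
  with_seed_for_test(seed, {
    x <- matrix(rnorm(n_chan * Tn, sd = noise_sd), n_chan)
    drift <- drift_amp * sin(2 * pi * 7 * seq_len(Tn) / fs)  # 7 Hz background
    x <- sweep(x, 2L, drift, "+")
    for (i in spike_idx) {
      x[, (i - w):(i + w)] <- x[, (i - w):(i + w)] + template
    }
    ic <- rep(-60, Tn)
    ic[spike_idx] <- 30                         # suprathreshold spikelets
    list(ic = ic, ec = x, fs = fs, spike_idx = spike_idx,
         template = template, w = w)
  })
}

with_seed_for_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) .Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

test_that("spike detection counts upward crossings with a refractory merge", {
  expect_identical(detect_spikes(rep(-50, 1000), 20000), integer(0))
  # sine crossing zero upward k times
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  k <- 5
  expect_equal(length(detect_spikes(sin(2 * pi * k * t - 0.1), fs)), k)
  # 154 injected spikelets are all found, chatter within 1 ms is merged
  pr <- make_paired(n_spikes = 154)
  det <- detect_spikes(pr$ic, pr$fs)
  expect_equal(length(det), 154L)
  chatter <- rep(-10, 400)
  chatter[c(100, 103, 106, 300)] <- 10          # 3 crossings within 1 ms
  expect_equal(length(detect_spikes(chatter, 20000)), 2L)
})

test_that("the spike-triggered average recovers the template", {
  pr <- make_paired(n_spikes = 1, noise_sd = 0, drift_amp = 0)
  one <- spike_triggered_average(pr$ec, pr$fs, pr$spike_idx)
  expect_equal(one$sta, pr$template + 0 * one$sta, tolerance = 1e-12)
  expect_equal(one$n_used, 1L)
  # error shrinks roughly as 1/sqrt(n)
  pr <- make_paired(n_spikes = 100, drift_amp = 0, noise_sd = 40)
  err_n <- function(n) {
    sta <- spike_triggered_average(pr$ec, pr$fs, pr$spike_idx[seq_len(n)])
    sqrt(mean((sta$sta - pr$template)^2))
  }
  expect_gt(err_n(25) / err_n(100), 1.3)
  expect_lt(err_n(25) / err_n(100), 3.1)
  # edge windows are dropped, not wrapped
  sta <- suppressMessages(
    spike_triggered_average(pr$ec, pr$fs, c(3L, pr$spike_idx)))
  expect_equal(sta$n_dropped, 1L)
  expect_error(spike_triggered_average(pr$ec, pr$fs, 1L), "no spike window")
})

test_that("moving-average filters have the stated fixed points", {
  fs <- 20000
  expect_equal(moving_average_highpass(rep(7.5, 5000), fs), rep(0, 5000))
  expect_equal(moving_average_smooth(rep(7.5, 5000), fs), rep(7.5, 5000))
  # impulse through a 3-sample smoothing window
  x <- numeric(101); x[51] <- 1
  sm <- moving_average_smooth(x, fs = 20000, window = 0.15)
  expect_equal(sm[50:52], rep(1 / 3, 3))
  expect_equal(sum(sm), 1)
  # slow drift is removed while a fast transient survives
  t <- seq_len(20000)
  drift <- 100 * (t / 20000)
  spikelet <- numeric(20000); spikelet[10000 + (-20:20)] <- 50
  hp <- moving_average_highpass(drift + spikelet, fs)
  # away from the spikelet and the shrinking-window edges the linear drift
  # is removed exactly; near the spikelet its window average leaks a little
  clear <- setdiff(seq(2000, 18000), 10000 + (-1100:1100))
  expect_lt(max(abs(hp[clear])), 1e-9)
  near <- setdiff(10000 + (-1100:1100), 10000 + (-60:60))
  expect_lt(max(abs(hp[near])), 0.05 * 50)
  expect_gt(max(hp[10000 + (-20:20)]), 40)
  # white-noise variance drops by about the window sample count
  set.seed(8)
  n <- rnorm(2e5)
  vr <- var(moving_average_smooth(n, 20000, 0.15)) / var(n)
  expect_gt(vr, 1 / 3 * 0.9); expect_lt(vr, 1 / 3 * 1.1)
})

test_that("the full pipeline recovers the per-channel template", {
  pr <- make_paired(n_spikes = 150, n_chan = 10)
  el <- electrode_layout("laminar", n = 10, center_y = 258)
  rec <- sta_pipeline(pr$ic, pr$ec, pr$fs, el, exclude = c("e2", "e5"))
  expect_equal(attr(rec, "n_spikes"), 150L)
  expect_equal(nrow(rec$potentials), 8L)
  expect_false(any(c("e2", "e5") %in% rec$electrodes$label))
  # compare against the smoothed template (the pipeline's smoothing step
  # is part of its contract)
  templ <- moving_average_smooth(pr$template[-c(2L, 5L), ], pr$fs, 0.15)
  kept <- rec$potentials
  rel <- sqrt(sum((kept - templ)^2)) / sqrt(sum(templ^2))
  expect_lt(rel, 0.1)
  expect_equal(ncol(rec$potentials), 2L * round(5 * pr$fs / 1000) + 1L)
})
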