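#' Detect spikes on an intracellular trace
#'
#' Upward threshold crossings (sample above threshold whose predecessor is
#' at or below it), with crossings closer than `refractory` merged into the
#' first -- intracellular spikes are far more than 1 ms apart, so the merge
#' only removes threshold chatter.
#'
#' @param trace numeric intracellular voltage trace (mV).
#' @param fs sampling rate (Hz).
#' @param threshold detection threshold (mV), default 0.
#' @param refractory minimum separation between detections (ms).
#' @return Integer sample indices of the detected crossings (possibly
#'   empty).
#' @export
detect_spikes <- function(trace, fs, threshold = 0, refractory = 1) {
  if (any(!is.finite(trace))) {
    stopf("non-finite samples in the intracellular trace",
          class = "skcsd_data_error")
  }
  check_scalar_pos(fs, "fs")
  up <- which(trace[-1L] > threshold & trace[-length(trace)] <= threshold) + 1L
  if (length(up) < 2L) return(up)
  min_gap <- refractory * fs / 1000
  ## scan so each kept event starts a fresh refractory period
  out <- up[1L]
  for (i in up[-1L]) if (i - out[length(out)] >= min_gap) out <- c(out, i)
  out
}

#' Spike-triggered average of extracellular channels
#'
#' Cuts a window of `+/- half_window` ms around every spike on every
#' channel and averages across spikes. Windows that would extend past the
#' recording edges are dropped (their count is reported via a message).
#'
#' @param extracellular N x T matrix of extracellular potentials (uV).
#' @param fs sampling rate (Hz).
#' @param spike_idx integer sample indices of the spikes (from
#'   [detect_spikes()] on the paired intracellular trace).
#' @param half_window half-width of the window (ms), default 5.
#' @return A list with `sta` (N x W matrix), `times` (ms relative to the
#'   spike), `n_used` and `n_dropped`.
#' @export
spike_triggered_average <- function(extracellular, fs, spike_idx,
                                    half_window = 5) {
  x <- as.matrix(extracellular)
  w <- round(half_window * fs / 1000)
  ok <- spike_idx - w >= 1L & spike_idx + w <= ncol(x)
  if (!any(ok)) {
    stopf("no spike window fits inside the recording",
          class = "skcsd_data_error")
  }
  if (any(!ok)) {
    message(sprintf("dropping %d spike window(s) clipped at recording edges",
                    sum(!ok)))
  }
  idx <- spike_idx[ok]
  acc <- matrix(0, nrow(x), 2L * w + 1L)
  for (i in idx) acc <- acc + x[, (i - w):(i + w), drop = FALSE]
  list(sta = acc / length(idx),
       times = (-w:w) * 1000 / fs,
       n_used = length(idx), n_dropped = sum(!ok))
}

#' Moving-average high-pass filter
#'
#' Subtracts a centred moving-window average (default width 100 ms) from
#' every channel, removing slow drift and correlated background while
#' leaving fast transients; windows shrink at the trace edges, so a
#' constant input maps exactly to zero.
#'
#' @param x numeric vector or N x T matrix (channels x time).
#' @param fs sampling rate (Hz).
#' @param window full window width (ms).
#' @return Same shape as `x`.
#' @export
moving_average_highpass <- function(x, fs, window = 100) {
  half <- max(1L, floor(window * fs / 1000 / 2))
  f <- function(v) v - rolling_mean_centered(v, half)
  if (is.matrix(x)) t(apply(x, 1L, f)) else f(x)
}

#' Moving-average temporal smoothing
#'
#' Centred moving mean (default window 0.15 ms, about 3 samples at
#' 20 kHz); constants are preserved exactly and edges use shrunk windows.
#'
#' @inheritParams moving_average_highpass
#' @export
moving_average_smooth <- function(x, fs, window = 0.15) {
  half <- max(1L, floor(window * fs / 1000 / 2))
  f <- function(v) rolling_mean_centered(v, half)
  if (is.matrix(x)) t(apply(x, 1L, f)) else f(x)
}

#' Spike-triggered-average preprocessing pipeline
#'
#' The full experimental preprocessing chain: detect spikes on the
#' intracellular trace (0 mV upward crossings), drop excluded (broken)
#' channels, high-pass the extracellular matrix by subtracting a 100 ms
#' moving average, smooth with a 0.15 ms moving average, and cut and
#' average +/- 5 ms windows around the spikes. The result feeds
#' [skcsd_estimate()] unchanged.
#'
#' @param intracellular intracellular trace (mV).
#' @param extracellular N x T extracellular matrix (uV).
#' @param fs sampling rate (Hz).
#' @param electrodes an [electrode_array()] matching the extracellular rows.
#' @param exclude labels of channels to drop before processing.
#' @param threshold spike threshold (mV).
#' @param half_window STA half-window (ms).
#' @param highpass_window,smooth_window moving-average widths (ms).
#' @return A [recording_set()] whose T axis is the STA window, plus
#'   attributes `n_spikes` and `spike_idx`.
#' @export
sta_pipeline <- function(intracellular, extracellular, fs, electrodes,
                         exclude = character(0), threshold = 0,
                         half_window = 5, highpass_window = 100,
                         smooth_window = 0.15) {
  keep <- !(electrodes$label %in% exclude)
  x <- as.matrix(extracellular)[keep, , drop = FALSE]
  spikes <- detect_spikes(intracellular, fs, threshold = threshold)
  x <- moving_average_highpass(x, fs, highpass_window)
  x <- moving_average_smooth(x, fs, smooth_window)
  sta <- spike_triggered_average(x, fs, spikes, half_window)
  rec <- recording_set(
    electrode_array(as.matrix(electrodes[keep, c("x", "y", "z")]),
                    labels = electrodes$label[keep]),
    sta$sta, sta$times)
  attr(rec, "n_spikes") <- length(spikes)
  attr(rec, "spike_idx") <- spikes
  rec
}
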