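.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# smallest 5-smooth integer >= n, optionally a multiple of `mult`
# (mixed-radix FFTs are fast only for small prime factors)
next_smooth <- function(n, mult = 1) {
  n <- as.integer(ceiling(n / mult)) * mult
  repeat {
    m <- n
    for (f in c(2L, 3L, 5L)) while (m %% f == 0L) m <- m %/% f
    if (m == 1L) return(n)
    n <- n + mult
  }
}

# FFT-based linear convolution with a linear-phase FIR, delay-compensated.
# b must be (near-)symmetric so shifting by the group delay gives zero phase.
fir_apply <- function(data, b) {
  nb <- length(b)
  ns <- ncol(data)
  gd <- (nb - 1) / 2
  nfft <- next_smooth(ns + nb - 1)
  B <- stats::fft(c(b, rep(0, nfft - nb)))
  X <- stats::mvfft(rbind(t(data), matrix(0, nfft - ns, nrow(data))))
  y <- Re(stats::mvfft(X * B, inverse = TRUE)) / nfft
  t(y[(gd + 1):(gd + ns), , drop = FALSE])
}

#' Zero-phase FIR band-pass filter
#'
#' Filters every channel of a continuous recording with a windowed-sinc
#' (Hamming) linear-phase FIR band-pass, applied without phase distortion
#' by compensating the group delay. Defaults reproduce the 0.1--30 Hz
#' analysis band.
#'
#' @param rec A `sensor_recording`.
#' @param low,high Band edges in Hz; `0 < low < high < srate/2`.
#' @param order Filter order; default `round(3 * srate)` (transition width
#'   of roughly 1 Hz), capped below the signal length.
#' @return The filtered `sensor_recording` (same length, channels, events).
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 30, order = NULL) {
  fs <- rec$srate
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < Nyquist", call. = FALSE)
  }
  ns <- ncol(rec$data)
  if (is.null(order)) order <- min(round(3 * fs), 2 * floor((ns - 2) / 2))
  if (order %% 2 == 1) order <- order + 1  # even order: no zero at Nyquist
  b <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  rec$data <- fir_apply(rec$data, as.numeric(b))
  rec
}

#' Resample a recording by the Fourier method
#'
#' Downsamples every channel by truncating its discrete spectrum to the new
#' Nyquist band (the standard frequency-domain resampling used for
#' band-limited M/EEG data; the preceding band-pass guarantees
#' band-limitation). Event sample indices are remapped from their
#' (invariant) times.
#'
#' @param rec A `sensor_recording`.
#' @param target_rate New sampling rate in Hz; must be below the current
#'   rate.
#' @return The resampled `sensor_recording`.
#' @export
resample_recording <- function(rec, target_rate) {
  fs <- rec$srate
  if (target_rate >= fs) {
    stop("only downsampling is supported (`target_rate` < current rate)",
         call. = FALSE)
  }
  ns <- ncol(rec$data)
  n_new <- round(ns * target_rate / fs)
  # reflection-pad to an FFT-friendly length at which the rate ratio is
  # exact, resample, then crop; keeps the FFT fast and the edges clean
  ratio <- target_rate / fs
  mult <- as.integer(fs / .gcd(fs, target_rate))
  np <- next_smooth(ns, mult)
  if (np > ns) {
    k <- np - ns
    pad <- rec$data[, ns - seq_len(k), drop = FALSE]
    x <- cbind(rec$data, pad)
  } else {
    x <- rec$data
  }
  np_new <- as.integer(np * ratio)
  h <- ceiling((np_new + 1) / 2)          # non-negative bins incl. DC
  X <- stats::mvfft(t(x))
  Y <- matrix(0 + 0i, np_new, nrow(x))
  Y[seq_len(h), ] <- X[seq_len(h), ]
  if (np_new > h) {
    Y[(h + 1):np_new, ] <- X[(np - (np_new - h) + 1):np, ]
  }
  out <- Re(stats::mvfft(Y, inverse = TRUE)) / np
  rec$data <- t(out)[, seq_len(n_new), drop = FALSE]
  rec$srate <- target_rate
  rec$events$sample <- as.integer(round(rec$events$time * target_rate)) + 1L
  rec
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' Extracts one epoch per event over the half-open window `[tmin, tmax)`
#' (onset at t = 0; at 100 Hz the default -0.4 to 0.8 s window has 120
#' samples). Events whose window would exceed the recording bounds are
#' dropped with a message. Per-trial metadata joins the sequence fields
#' with the previous and pre-previous stimulus ids and omission flags,
#' which the decoder's trial matching needs.
#'
#' @param rec A `sensor_recording`.
#' @param seq The `stim_sequence` the recording was simulated from.
#' @param tmin,tmax Epoch window in seconds (default -0.4, 0.8).
#' @return A `sensor_epochs`: list with `data` (trials x channels x time),
#'   `times`, `srate` and `metadata`.
#' @export
epoch_recording <- function(rec, seq, tmin = -0.4, tmax = 0.8) {
  fs <- rec$srate
  offs <- as.integer(round(tmin * fs)):(as.integer(round(tmax * fs)) - 1L)
  times <- offs / fs
  ns <- ncol(rec$data)
  ok <- rec$events$sample + offs[1] >= 1 &
    rec$events$sample + offs[length(offs)] <= ns
  if (!any(ok)) stop("no events with a complete epoch window", call. = FALSE)
  if (any(!ok)) {
    message(sum(!ok), " event(s) dropped at the recording edges")
  }
  ev <- rec$events[ok, , drop = FALSE]
  nch <- nrow(rec$data)
  data <- array(NA_real_, c(nrow(ev), nch, length(offs)))
  for (i in seq_len(nrow(ev))) {
    data[i, , ] <- rec$data[, ev$sample[i] + offs, drop = FALSE]
  }
  meta <- seq[match(ev$trial, seq$trial), , drop = FALSE]
  prev_idx <- match(ev$trial - 1L, seq$trial)
  prev2_idx <- match(ev$trial - 2L, seq$trial)
  meta$prev_stimulus <- seq$stimulus[prev_idx]
  meta$prev_omitted <- seq$omitted[prev_idx]
  meta$prev2_stimulus <- seq$stimulus[prev2_idx]
  meta$prev2_omitted <- seq$omitted[prev2_idx]
  rownames(meta) <- NULL
  structure(list(data = data, times = times, srate = fs, metadata = meta),
            class = "sensor_epochs")
}
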