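#' Digital preprocessing filter chain
#'
#' Standard sEMG conditioning: a Butterworth band-pass over the
#' physiological band plus an elliptic notch at the power-line fundamental
#' and Butterworth band-stops at its harmonics. All filters are applied
#' zero-phase (forward-backward with reflective padding) so later feature
#' extraction sees no phase distortion.
#'
#' The band-pass is realized as an order `order/2` high-pass cascaded with
#' an order `order/2` low-pass (the stated total pole count), which is
#' numerically robust where a single transfer-function band-pass of the
#' same order is not.
#'
#' @param bandpass numeric `c(low_Hz, high_Hz)` pass band, default 10-450 Hz.
#' @param order total band-pass order (even, poles split between the
#'   high-pass and low-pass halves), default 16.
#' @param notch_hz power-line fundamental, default 50 Hz. `NA` disables.
#' @param harmonics how many multiples of `notch_hz` to suppress in total
#'   (1 = fundamental only), default 4 (50/100/150/200 Hz).
#' @param notch_halfwidth_hz half-width of each stop band, default 2 Hz.
#' @return a `filter_chain` object.
#' @export
filter_chain <- function(bandpass = c(10, 450), order = 16, notch_hz = 50,
                         harmonics = 4, notch_halfwidth_hz = 2) {
  if (length(bandpass) != 2 || bandpass[1] <= 0 || bandpass[1] >= bandpass[2])
    stop("bandpass must be c(low, high) with 0 < low < high")
  if (order < 2 || order %% 2 != 0) stop("order must be even and positive")
  structure(list(bandpass = bandpass, order = order, notch_hz = notch_hz,
                 harmonics = harmonics,
                 notch_halfwidth_hz = notch_halfwidth_hz),
            class = "filter_chain")
}

# zero-phase filtering with reflective (odd) end padding to suppress
# filtfilt edge transients; padlen capped at n-1
zero_phase <- function(filt, x, padlen = 1000L) {
  n <- length(x)
  p <- min(n - 1L, padlen)
  if (p < 1L) return(signal::filtfilt(filt, x))
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[(p + 1):(p + n)]
}

#' Apply a filter chain to a recording
#'
#' @param rec a [recording()].
#' @param chain a [filter_chain()].
#' @return the filtered recording (same shape, annotations preserved).
#' @export
apply_filters <- function(rec, chain = filter_chain()) {
  stopifnot(inherits(rec, "semg_recording"), inherits(chain, "filter_chain"))
  fs <- rec$fs
  nyq <- fs / 2
  if (chain$bandpass[2] >= nyq)
    stop("band edge ", chain$bandpass[2], " Hz invalid for fs = ", fs, " Hz")
  half <- chain$order / 2
  hp <- signal::butter(half, chain$bandpass[1] / nyq, type = "high")
  lp <- signal::butter(half, chain$bandpass[2] / nyq, type = "low")
  stops <- list()
  if (!is.na(chain$notch_hz) && chain$harmonics >= 1) {
    hw <- chain$notch_halfwidth_hz
    for (k in seq_len(chain$harmonics)) {
      f0 <- k * chain$notch_hz
      if (f0 + hw >= nyq) break
      band <- c(f0 - hw, f0 + hw) / nyq
      stops[[k]] <- if (k == 1)
        signal::ellip(4, 0.1, 40, band, type = "stop")
      else
        signal::butter(2, band, type = "stop")
    }
  }
  y <- rec$samples
  for (j in seq_len(ncol(y))) {
    v <- zero_phase(lp, zero_phase(hp, y[, j]))
    for (st in stops) v <- zero_phase(st, v)
    y[, j] <- v
  }
  rec$samples <- y
  rec
}

#' Signal-to-noise ratio of an sEMG channel
#'
#' Compares the maximum windowed RMS amplitude of an active (strained
#' muscle) segment against that of a rest segment:
#' `SNR_dB = 10 log10(A_m^2 / A_r^2)`.
#'
#' @param active numeric vector, signal while the muscle is active.
#' @param rest numeric vector, signal at rest.
#' @param window_s RMS window length in seconds, default 0.25.
#' @param fs sampling rate in Hz, default 1000.
#' @return list with `A_m`, `A_r`, `snr_db` (class `snr_report`).
#' @export
compute_snr <- function(active, rest, window_s = 0.25, fs = 1000) {
  win <- floor(window_s * fs)
  if (win < 1) stop("window shorter than one sample")
  if (length(active) < win || length(rest) < win)
    stop("both segments must contain at least one full window")
  max_rms <- function(x) {
    starts <- window_starts(length(x), win, win)
    max(vapply(starts, function(s) sqrt(mean(x[(s + 1):(s + win)]^2)),
               numeric(1)))
  }
  a_m <- max_rms(active)
  a_r <- max_rms(rest)
  if (a_r == 0) stop("silent rest segment (A_r = 0)")
  structure(list(A_m = a_m, A_r = a_r,
                 snr_db = 10 * log10(a_m^2 / a_r^2)),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("SNR %.2f dB (A_m = %.4g, A_r = %.4g)\n", x$snr_db, x$A_m, x$A_r))
  invisible(x)
}
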