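#' Feature-extraction specification
#'
#' Parameters of the 42-dimension per-channel sEMG feature bank. Amplitude
#' thresholds are expressed as fractions of each analysis window's RMS so
#' the count-type features are invariant to overall gain; all are
#' configurable because threshold choice is known to change which Willison
#' amplitude variants survive feature selection.
#'
#' @param wamp_fracs 5 Willison-amplitude thresholds, as fractions of the
#'   window RMS.
#' @param zc_fracs 2 zero-crossing deadband thresholds (fractions of RMS).
#' @param ssc_frac slope-sign-change threshold (fraction of RMS; the
#'   comparison is against the squared value since SSC tests a product of
#'   consecutive differences).
#' @param hemg_bins number of amplitude-histogram bins.
#' @param hemg_range_sd histogram half-range in units of the window SD.
#' @param ar_order autoregressive model order.
#' @param dwt_levels DWT decomposition depth (`dwt_levels + 1` sub-bands).
#' @param welch_seg_len,welch_overlap Welch PSD segment length (samples,
#'   capped at the window length) and overlap fraction.
#' @return a `feature_spec` object.
#' @export
feature_spec <- function(wamp_fracs = c(0.05, 0.1, 0.2, 0.3, 0.4),
                         zc_fracs = c(0, 0.05), ssc_frac = 0,
                         hemg_bins = 6, hemg_range_sd = 3, ar_order = 4,
                         dwt_levels = 6, welch_seg_len = 256,
                         welch_overlap = 0.5) {
  if (length(wamp_fracs) != 5 || is.unsorted(wamp_fracs, strictly = TRUE))
    stop("wamp_fracs must be 5 strictly increasing thresholds")
  if (length(zc_fracs) != 2 || is.unsorted(zc_fracs, strictly = TRUE))
    stop("zc_fracs must be 2 strictly increasing thresholds")
  structure(list(wamp_fracs = wamp_fracs, zc_fracs = zc_fracs,
                 ssc_frac = ssc_frac, hemg_bins = hemg_bins,
                 hemg_range_sd = hemg_range_sd, ar_order = ar_order,
                 dwt_levels = dwt_levels, welch_seg_len = welch_seg_len,
                 welch_overlap = welch_overlap),
            class = "feature_spec")
}

#' Canonical names of the per-channel feature bank
#'
#' @param spec a [feature_spec()] (bin/threshold counts fix the names).
#' @return character vector of 42 feature names in extraction order.
#' @export
semg_feature_names <- function(spec = feature_spec()) {
  lv <- spec$dwt_levels
  bands <- c(paste0("D", seq_len(lv)), paste0("A", lv))
  c("MAV", "MMAV1", "MMAV2", "RMS", "VAR", "WL",
    paste0("ZC", seq_along(spec$zc_fracs)), "SSC",
    paste0("WAMP", seq_along(spec$wamp_fracs)), "SSI",
    paste0("HEMG", seq_len(spec$hemg_bins)),
    paste0("AR", seq_len(spec$ar_order)), "MDF", "MNF", "STFT",
    paste0("APWC_", bands), paste0("SDWC_", bands))
}

#' Time-domain features of one analysis window
#'
#' Standard amplitude-based sEMG descriptors: mean absolute value (MAV) and
#' its two weighted variants (MMAV1: weight 1 on the central half of the
#' window, 0.5 elsewhere; MMAV2: piecewise-linear ramp weights), RMS,
#' unbiased variance, waveform length (sum of consecutive absolute
#' differences), zero crossings with two deadband thresholds, slope sign
#' changes, Willison amplitudes at five thresholds, simple square integral,
#' and a 6-bin amplitude histogram spanning +/- `hemg_range_sd` SD.
#'
#' @param x numeric vector (one window of one channel), length >= 3.
#' @param spec a [feature_spec()].
#' @return named numeric vector of 21 values.
#' @export
extract_time_features <- function(x, spec = feature_spec()) {
  n <- length(x)
  if (n < 3) stop("window must contain at least 3 samples")
  ax <- abs(x)
  rms <- sqrt(mean(x^2))
  i <- seq_len(n)
  w1 <- ifelse(i >= 0.25 * n & i <= 0.75 * n, 1, 0.5)
  w2 <- ifelse(i < 0.25 * n, 4 * i / n,
               ifelse(i > 0.75 * n, 4 * (i - n) / n + 4, 1))
  d <- diff(x)
  zc <- vapply(spec$zc_fracs * rms, function(th)
    sum(x[-n] * x[-1] < 0 & abs(d) >= th), numeric(1))
  prod2 <- (x[2:(n - 1)] - x[1:(n - 2)]) * (x[2:(n - 1)] - x[3:n])
  ssc <- sum(prod2 > (spec$ssc_frac * rms)^2)
  wamp <- vapply(spec$wamp_fracs * rms, function(th)
    sum(abs(d) > th), numeric(1))
  s <- stats::sd(x)
  if (s > 0) {
    edges <- seq(-spec$hemg_range_sd * s, spec$hemg_range_sd * s,
                 length.out = spec$hemg_bins + 1) + mean(x)
    bin <- findInterval(x, edges, all.inside = TRUE)
    bin <- pmin(pmax(bin, 1L), spec$hemg_bins)   # clamp outliers to edge bins
    hemg <- tabulate(bin, nbins = spec$hemg_bins)
  } else {
    hemg <- numeric(spec$hemg_bins)
    hemg[floor(spec$hemg_bins / 2) + 1] <- n     # degenerate constant window
  }
  out <- c(mean(ax), mean(w1 * ax), mean(w2 * ax), rms,
           if (n > 1) stats::var(x) else 0, sum(abs(d)), zc, ssc, wamp,
           sum(x^2), hemg)
  names(out) <- semg_feature_names(spec)[1:21]
  out
}

# Welch PSD: averaged hamming-windowed periodograms, 50% overlap default.
# Returns one-sided freq/psd (density normalized so integral ~ power).
welch_psd <- function(x, fs, seg_len = 256, overlap = 0.5) {
  n <- length(x)
  seg <- min(seg_len, n)
  stride <- max(1L, floor(seg * (1 - overlap)))
  starts <- window_starts(n, seg, stride)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, seg - 1) / (seg - 1))
  scale <- fs * sum(w^2)
  nf <- floor(seg / 2) + 1
  p <- numeric(nf)
  for (s in starts) {
    seg_x <- x[(s + 1):(s + seg)] * w
    P <- Mod(stats::fft(seg_x))^2 / scale
    p <- p + P[1:nf]
  }
  p <- p / length(starts)
  p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  list(freq = seq(0, nf - 1) * fs / seg, psd = p)
}

#' Frequency-domain features of one analysis window
#'
#' Autoregressive coefficients (Burg estimator, order 4 by default), median
#' frequency (bin at which the cumulative Welch PSD first reaches half the
#' total power) and mean frequency (PSD-weighted mean).
#'
#' @param x numeric vector, length >= `2 * ar_order`.
#' @param fs sampling rate in Hz.
#' @param spec a [feature_spec()].
#' @return named numeric vector of 6 values (`AR1..AR4`, `MDF`, `MNF`).
#' @export
extract_frequency_features <- function(x, fs, spec = feature_spec()) {
  if (length(x) < 2 * spec$ar_order)
    stop("window too short for AR order ", spec$ar_order)
  if (stats::var(x) == 0)
    stop("degenerate (constant) window: AR/MDF/MNF undefined")
  arfit <- stats::ar.burg(x, aic = FALSE, order.max = spec$ar_order,
                          demean = TRUE)
  ar <- arfit$ar
  if (length(ar) < spec$ar_order)
    ar <- c(ar, numeric(spec$ar_order - length(ar)))
  pw <- welch_psd(x, fs, spec$welch_seg_len, spec$welch_overlap)
  cum <- cumsum(pw$psd)
  mdf <- pw$freq[which(cum >= cum[length(cum)] / 2)[1]]
  mnf <- sum(pw$freq * pw$psd) / sum(pw$psd)
  out <- c(ar, mdf, mnf)
  names(out) <- c(paste0("AR", seq_len(spec$ar_order)), "MDF", "MNF")
  out
}

#' Time-frequency features of one analysis window
#'
#' A scalar short-time Fourier descriptor (mean of the Welch PSD) plus the
#' average power (mean squared coefficient, APWC) and standard deviation
#' (SDWC) of the DWT coefficients in each of the `dwt_levels + 1` DB4
#' sub-bands `D1..D6, A6`.
#'
#' @param x numeric vector, long enough for the configured DWT depth.
#' @param fs sampling rate in Hz.
#' @param spec a [feature_spec()].
#' @return named numeric vector of 15 values.
#' @export
extract_timefreq_features <- function(x, fs, spec = feature_spec()) {
  w <- dwt_db4(x, spec$dwt_levels)
  coefs <- c(w$details, list(w$approx))
  apwc <- vapply(coefs, function(cc) mean(cc^2), numeric(1))
  sdwc <- vapply(coefs, stats::sd, numeric(1))
  pw <- welch_psd(x, fs, spec$welch_seg_len, spec$welch_overlap)
  bands <- c(paste0("D", seq_len(spec$dwt_levels)), paste0("A", spec$dwt_levels))
  out <- c(mean(pw$psd), apwc, sdwc)
  names(out) <- c("STFT", paste0("APWC_", bands), paste0("SDWC_", bands))
  out
}

#' Feature matrix container
#'
#' Windows x features matrix with class labels and channel provenance.
#'
#' @param values numeric matrix (windows x named features).
#' @param labels character vector of class labels, one per window.
#' @param channels character vector naming the channels the columns came
#'   from (provenance only).
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(values, labels, channels = "ch1") {
  values <- as.matrix(values)
  if (length(labels) != nrow(values))
    stop("labels length must equal the number of windows")
  structure(list(values = values, feature_names = colnames(values),
                 labels = as.character(labels), channels = channels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " windows x ", ncol(x$values),
      " features (", paste(x$channels, collapse = ", "), ")\n", sep = "")
  tab <- table(x$labels)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset a feature matrix by windows and/or feature columns
#'
#' @param x a [feature_matrix()].
#' @param i window (row) index.
#' @param j feature (column) index or names.
#' @param ... unused.
#' @return a `feature_matrix`.
#' @export
`[.feature_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  feature_matrix(x$values[i, j, drop = FALSE], x$labels[i], x$channels)
}

#' Extract the full feature bank from segmented windows
#'
#' Runs the time, frequency and time-frequency extractors on every window
#' and channel, cascading channels in recording order. With one channel the
#' columns carry the 42 canonical names; with `C` channels the `42 * C`
#' columns are prefixed `<channel>_<feature>`.
#'
#' @param windows window list from [segment_recording()].
#' @param fs sampling rate in Hz.
#' @param spec a [feature_spec()].
#' @param channels optional subset of channel names/indices to extract.
#' @return a [feature_matrix()].
#' @export
extract_features <- function(windows, fs, spec = feature_spec(),
                             channels = NULL) {
  if (!length(windows)) stop("no windows to extract")
  ch_names <- colnames(windows[[1]]$samples)
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(ncol(windows[[1]]$samples)))
  if (is.null(channels)) channels <- ch_names
  if (is.numeric(channels)) channels <- ch_names[channels]
  base_names <- semg_feature_names(spec)
  col_names <- if (length(channels) == 1) base_names
    else as.vector(vapply(channels, function(ch) paste(ch, base_names, sep = "_"),
                          character(length(base_names))))
  vals <- matrix(NA_real_, nrow = length(windows), ncol = length(col_names),
                 dimnames = list(NULL, col_names))
  for (i in seq_along(windows)) {
    row <- unlist(lapply(channels, function(ch) {
      x <- windows[[i]]$samples[, match(ch, ch_names)]
      c(extract_time_features(x, spec),
        extract_frequency_features(x, fs, spec),
        extract_timefreq_features(x, fs, spec))
    }), use.names = FALSE)
    vals[i, ] <- row
  }
  feature_matrix(vals, vapply(windows, function(w) w$label, character(1)),
                 channels)
}
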