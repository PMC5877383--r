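#' Synthetic sEMG generator configuration
#'
#' Describes labelled multichannel surface-EMG-like recordings for testing
#' the full pipeline without real data. Each trial is 1.5 s: a 0.25 s
#' onset ramp, a 1 s execution plateau and a 0.25 s offset ramp. Every
#' movement class produces band-limited Gaussian noise in its own spectral
#' band (make-fist strongest at low frequencies, wrist flexion in the
#' 105-195 Hz band) with a class-by-channel gain matrix mimicking
#' muscle-electrode coupling (each movement strongest on one channel);
#' rest is a low-amplitude broadband floor. Power-line interference at
#' 50 Hz is added before any filtering so preprocessing is exercised.
#'
#' @param n_channels number of channels, default 4.
#' @param fs sampling rate in Hz, default 1000.
#' @param channel_names channel labels, default forearm sites
#'   `APL, ECR, ECU, FCU` (truncated/extended to `n_channels`).
#' @param classes movement classes, default `REST, MF, WE, WF`.
#' @param trials_per_class trials per class, default 40 (so a 250 ms
#'   disjoint segmentation of the 1 s execution yields 160 windows/class).
#' @param class_bands named list of `c(low, high)` Hz bands per class.
#' @param class_gains class x channel matrix of RMS amplitudes (arbitrary
#'   units); `NULL` uses the built-in coupling pattern.
#' @param onset_s,plateau_s,offset_s trial envelope segments in seconds.
#' @param mains_amp 50 Hz interference amplitude, default 0.1.
#' @param noise_floor white measurement-noise SD, default 0.05.
#' @return a `synthetic_config`.
#' @export
synthetic_config <- function(n_channels = 4, fs = 1000,
                             channel_names = c("APL", "ECR", "ECU", "FCU"),
                             classes = c("REST", "MF", "WE", "WF"),
                             trials_per_class = 40,
                             class_bands = list(REST = c(10, 450),
                                                MF = c(10, 105),
                                                WE = c(40, 250),
                                                WF = c(105, 195)),
                             class_gains = NULL,
                             onset_s = 0.25, plateau_s = 1, offset_s = 0.25,
                             mains_amp = 0.1, noise_floor = 0.05) {
  channel_names <- rep_len(channel_names, n_channels)
  for (b in class_bands)
    if (b[1] <= 0 || b[2] >= fs / 2 || b[1] >= b[2])
      stop("class band (", b[1], ", ", b[2], ") invalid for fs = ", fs)
  if (is.null(class_gains)) {
    # each movement couples strongest into one electrode site
    class_gains <- rbind(REST = rep(0.06, n_channels),
                         MF = rep_len(c(1.2, 0.6, 0.7, 0.8), n_channels),
                         WE = rep_len(c(0.5, 1.2, 1.0, 0.4), n_channels),
                         WF = rep_len(c(0.5, 0.4, 0.6, 1.2), n_channels))
    class_gains <- class_gains[classes, , drop = FALSE]
  }
  if (any(class_gains < 0)) stop("gains must be >= 0")
  colnames(class_gains) <- channel_names
  structure(list(n_channels = n_channels, fs = fs,
                 channel_names = channel_names, classes = classes,
                 trials_per_class = trials_per_class,
                 class_bands = class_bands, class_gains = class_gains,
                 onset_s = onset_s, plateau_s = plateau_s,
                 offset_s = offset_s, mains_amp = mains_amp,
                 noise_floor = noise_floor),
            class = "synthetic_config")
}

# band-limited unit-RMS Gaussian noise
band_noise <- function(n, band, fs) {
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- zero_phase(bp, stats::rnorm(n))
  x / sqrt(mean(x^2))
}

#' Generate a labelled synthetic sEMG recording
#'
#' Trials of all classes are interleaved in seeded random order and
#' concatenated; identical seeds give identical sample streams.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @return an annotated [recording()].
#' @export
generate_semg <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$fs
  trial_s <- config$onset_s + config$plateau_s + config$offset_s
  nt <- floor(trial_s * fs)
  n_on <- floor(config$onset_s * fs)
  n_off <- floor(config$offset_s * fs)
  env <- c(seq(0, 1, length.out = n_on),
           rep(1, nt - n_on - n_off),
           seq(1, 0, length.out = n_off))
  order_lab <- with_seed(seed, sample(rep(config$classes,
                                          config$trials_per_class)))
  total <- length(order_lab) * nt
  X <- matrix(0, nrow = total, ncol = config$n_channels)
  with_seed(seed + 1L, {
    for (i in seq_along(order_lab)) {
      lab <- order_lab[i]
      rows <- ((i - 1) * nt + 1):(i * nt)
      shape <- if (lab == "REST") rep(1, nt) else env
      for (j in seq_len(config$n_channels)) {
        src <- band_noise(nt, config$class_bands[[lab]], fs)
        X[rows, j] <- config$class_gains[lab, j] * shape * src
      }
    }
    X <- X + matrix(stats::rnorm(total * config$n_channels,
                                 sd = config$noise_floor),
                    nrow = total)
    if (config$mains_amp > 0) {
      t <- seq_len(total) / fs
      phases <- stats::runif(config$n_channels, 0, 2 * pi)
      for (j in seq_len(config$n_channels))
        X[, j] <- X[, j] + config$mains_amp * sin(2 * pi * 50 * t + phases[j])
    }
  })
  rec <- recording(X, fs = fs, channel_names = config$channel_names)
  set_trials(rec, trial_annotations(
    onset_s = (seq_along(order_lab) - 1) * trial_s,
    label = order_lab, task_duration_s = trial_s,
    exec_start_s = config$onset_s,
    exec_end_s = config$onset_s + config$plateau_s))
}

#' Generate a feature matrix with planted discriminative features
#'
#' Direct test harness for the separability criteria: all features are
#' i.i.d. standard normal except the planted set, whose class-conditional
#' mean and standard deviation both shift with the class index in
#' proportion to `effect_size` (so variance-based and distance-based
#' criteria can each detect them). `effect_size = 0` makes all features
#' exchangeable.
#'
#' @param n_windows total windows (split as evenly as possible over the
#'   classes).
#' @param n_features total features.
#' @param planted integer indices of the discriminative features.
#' @param effect_size nonnegative scalar effect size (in baseline SD
#'   units per class step).
#' @param seed RNG seed.
#' @param classes class labels, default the four movement classes.
#' @return a [feature_matrix()] with features named `F1..Fn`.
#' @export
generate_planted_features <- function(n_windows, n_features, planted,
                                      effect_size, seed = 1,
                                      classes = c("REST", "MF", "WE", "WF")) {
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (length(planted) && (min(planted) < 1 || max(planted) > n_features))
    stop("planted indices out of range")
  K <- length(classes)
  labels <- rep_len(classes, n_windows)
  vals <- with_seed(seed, {
    M <- matrix(stats::rnorm(n_windows * n_features), n_windows, n_features)
    for (p in planted) {
      k <- match(labels, classes) - 1        # 0-based class index
      mu <- effect_size * (k - (K - 1) / 2)
      sdv <- 1 + effect_size * k / 2
      M[, p] <- mu + sdv * M[, p]
    }
    M
  })
  colnames(vals) <- paste0("F", seq_len(n_features))
  feature_matrix(vals, labels, channels = "synthetic")
}
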