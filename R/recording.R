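#' Multichannel sEMG recording
#'
#' A `semg_recording` bundles a multichannel surface-EMG signal with its
#' sampling rate, channel labels and (optionally) a table of trial
#' annotations. Samples are stored as a numeric matrix with one column per
#' channel and one row per time sample, matching the on-disk CSV layout.
#'
#' @param samples numeric matrix, samples x channels (a vector is treated as
#'   one channel).
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names optional character vector of channel labels; defaults
#'   to `"ch1"`, `"ch2"`, ... or the matrix column names.
#' @param trials optional trial annotation `data.frame`, see
#'   [trial_annotations()].
#' @return An object of class `semg_recording` with elements `samples`,
#'   `fs`, `channel_names`, `trials`.
#' @examples
#' rec <- recording(matrix(rnorm(2000), ncol = 2), fs = 1000)
#' print(rec)
#' @export
recording <- function(samples, fs = 1000, channel_names = NULL, trials = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive finite scalar")
  nch <- ncol(samples)
  if (is.null(channel_names)) {
    channel_names <- colnames(samples)
    if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  }
  if (length(channel_names) != nch)
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", nch, ")")
  colnames(samples) <- channel_names
  rec <- structure(list(samples = samples, fs = fs,
                        channel_names = channel_names, trials = NULL),
                   class = "semg_recording")
  if (!is.null(trials)) rec <- set_trials(rec, trials)
  rec
}

#' @export
print.semg_recording <- function(x, ...) {
  cat("<semg_recording> ", ncol(x$samples), " channel(s) x ",
      nrow(x$samples), " samples @ ", x$fs, " Hz (",
      round(nrow(x$samples) / x$fs, 3), " s)\n", sep = "")
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  if (!is.null(x$trials))
    cat("  trials:", nrow(x$trials), "annotated (",
        paste(names(table(x$trials$label)), table(x$trials$label),
              sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' @export
dim.semg_recording <- function(x) dim(x$samples)

#' Trial annotation table
#'
#' Annotates movement trials within a recording. Each trial starts at
#' `onset_s` seconds, lasts `task_duration_s` seconds, and contains an
#' execution window `[exec_start_s, exec_end_s)` relative to onset during
#' which the movement is held steadily (between the onset and offset
#' transients). Defaults follow the common cue-based protocol: a 1.5 s task
#' with a 0.25 s onset transient, 1 s execution and 0.25 s offset.
#'
#' @param onset_s numeric vector of trial onsets in seconds.
#' @param label character/factor vector of movement classes (e.g. `"REST"`,
#'   `"MF"`, `"WE"`, `"WF"`).
#' @param task_duration_s trial length in seconds (recycled).
#' @param exec_start_s,exec_end_s execution window relative to onset
#'   (recycled).
#' @return `data.frame` with one row per trial.
#' @export
trial_annotations <- function(onset_s, label, task_duration_s = 1.5,
                              exec_start_s = 0.25, exec_end_s = 1.25) {
  ann <- data.frame(onset_s = as.numeric(onset_s),
                    label = as.character(label),
                    task_duration_s = as.numeric(task_duration_s),
                    exec_start_s = as.numeric(exec_start_s),
                    exec_end_s = as.numeric(exec_end_s),
                    stringsAsFactors = FALSE)
  bad <- ann$exec_start_s < 0 | ann$exec_start_s >= ann$exec_end_s |
    ann$exec_end_s > ann$task_duration_s
  if (any(bad))
    stop("execution window must satisfy 0 <= start < end <= task_duration")
  ann
}

#' Attach trial annotations to a recording
#'
#' @param rec a [recording()].
#' @param trials a [trial_annotations()] data frame.
#' @return the recording with validated `trials` attached.
#' @export
set_trials <- function(rec, trials) {
  stopifnot(inherits(rec, "semg_recording"))
  trials <- trial_annotations(trials$onset_s, trials$label,
                              trials$task_duration_s %||% 1.5,
                              trials$exec_start_s %||% 0.25,
                              trials$exec_end_s %||% 1.25)
  dur_s <- nrow(rec$samples) / rec$fs
  if (any(trials$onset_s < 0) ||
      any(trials$onset_s + trials$task_duration_s > dur_s + 1e-9))
    stop("trial intervals must lie within the signal extent (0, ",
         round(dur_s, 3), " s)")
  rec$trials <- trials
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a recording from CSV or WAV
#'
#' CSV files hold one column per channel (header row = channel names) and one
#' row per sample; the sampling rate is taken from `fs`. WAV files carry
#' their own sampling rate, which overrides `fs`.
#'
#' @param path file path.
#' @param fs sampling rate in Hz for CSV input (ignored for WAV).
#' @param format `"csv"`, `"wav"`, or `"auto"` (by file extension).
#' @param trials optional path to a trial-annotation CSV with columns
#'   `onset_s,label` (and optionally `task_duration_s,exec_start_s,exec_end_s`).
#' @return a [recording()].
#' @export
read_recording <- function(path, fs = 1000, format = c("auto", "csv", "wav"),
                           trials = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "csv"
  if (format == "wav") {
    w <- read_wav(path)
    rec <- recording(w$samples, fs = w$fs)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    num <- vapply(df, is.numeric, logical(1))
    if (!all(num))
      stop("non-numeric sample in column(s): ",
           paste(names(df)[!num], collapse = ", "))
    rec <- recording(as.matrix(df), fs = fs, channel_names = names(df))
  }
  if (!is.null(trials)) {
    tr <- utils::read.csv(trials, stringsAsFactors = FALSE)
    rec <- set_trials(rec, trial_annotations(
      tr$onset_s, tr$label, tr$task_duration_s %||% 1.5,
      tr$exec_start_s %||% 0.25, tr$exec_end_s %||% 1.25))
  }
  rec
}

#' Write a recording to CSV (full precision) or WAV (float32)
#'
#' CSV output round-trips samples bit-exactly through [read_recording()].
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @param format `"csv"`, `"wav"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "wav")) {
  stopifnot(inherits(rec, "semg_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "csv"
  if (format == "wav") {
    write_wav(rec$samples, rec$fs, path)
  } else {
    df <- as.data.frame(rec$samples)
    names(df) <- rec$channel_names
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Sliding-window specification
#'
#' Disjoint segmentation uses consecutive non-overlapping windows; overlapped
#' segmentation slides the window by `length_s * (1 - overlap_frac)`. Window
#' lengths and strides are floored to whole samples (stride at least 1) and
#' windows are half-open sample intervals `[start, end)`, 0-based.
#'
#' @param length_s window length in seconds.
#' @param overlap_frac overlap fraction in `[0, 1)`; 0 means disjoint.
#' @return a `window_spec` list.
#' @export
window_spec <- function(length_s, overlap_frac = 0) {
  if (!is.numeric(length_s) || length_s <= 0) stop("length_s must be > 0")
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)")
  structure(list(length_s = length_s, overlap_frac = overlap_frac,
                 mode = if (overlap_frac == 0) "disjoint" else "overlapped"),
            class = "window_spec")
}

# 0-based start indices for windows of win samples within n samples
window_starts <- function(n, win, stride) {
  if (win > n) return(integer(0))
  seq.int(0L, n - win, by = stride)
}

#' Segment a recording into labelled analysis windows
#'
#' With `scope = "execution_only"` each annotated trial's execution interval
#' is segmented separately (the usual training-set convention: features come
#' only from the steady one-second execution period); with `scope = "full"`
#' the whole signal is segmented as one stream and windows carry label `NA`.
#' Trailing samples that do not fill a whole window are dropped.
#'
#' @param rec a [recording()] (annotated when `scope = "execution_only"`).
#' @param spec a [window_spec()].
#' @param scope `"execution_only"` or `"full"`.
#' @return list of windows; each window is a list with `samples`
#'   (win x channels matrix), `label`, `trial` (index or `NA`) and
#'   `start` (0-based sample index into the recording).
#' @export
segment_recording <- function(rec, spec,
                              scope = c("execution_only", "full")) {
  stopifnot(inherits(rec, "semg_recording"), inherits(spec, "window_spec"))
  scope <- match.arg(scope)
  win <- floor(spec$length_s * rec$fs)
  if (win < 1) stop("window shorter than one sample at fs = ", rec$fs)
  stride <- max(1L, floor(win * (1 - spec$overlap_frac)))
  out <- list()
  if (scope == "full") {
    n <- nrow(rec$samples)
    if (win > n) stop("window (", win, " samples) exceeds signal length (", n, ")")
    for (s in window_starts(n, win, stride))
      out[[length(out) + 1L]] <- list(
        samples = rec$samples[(s + 1L):(s + win), , drop = FALSE],
        label = NA_character_, trial = NA_integer_, start = s)
    return(out)
  }
  if (is.null(rec$trials)) stop("recording has no trial annotations")
  for (i in seq_len(nrow(rec$trials))) {
    tr <- rec$trials[i, ]
    i0 <- floor((tr$onset_s + tr$exec_start_s) * rec$fs)
    i1 <- floor((tr$onset_s + tr$exec_end_s) * rec$fs)
    n <- i1 - i0
    if (win > n)
      stop("window (", win, " samples) exceeds execution interval (",
           n, " samples) of trial ", i)
    for (s in window_starts(n, win, stride))
      out[[length(out) + 1L]] <- list(
        samples = rec$samples[(i0 + s + 1L):(i0 + s + win), , drop = FALSE],
        label = tr$label, trial = i, start = i0 + s)
  }
  out
}
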