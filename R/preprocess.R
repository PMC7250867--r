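#' Resample, filter and realign sensor epochs
#'
#' Standard sensor-space preparation: anti-alias filtered decimation to the
#' analysis rate (default 100 Hz), zero-phase high-pass filtering (4th-order
#' Butterworth, default 0.5 Hz cutoff, applied forward and backward) to
#' remove slow drift, and optional realignment/cropping to an analysis window
#' relative to a within-trial event.
#'
#' @param epochs An [epoch_set()], typically segmented at the acquisition
#'   rate (e.g. 600 Hz, -200..+8000 ms around trial onset).
#' @param new_rate Target sampling rate in Hz.
#' @param highpass High-pass cutoff in Hz (`NULL` to skip filtering).
#' @param align_ms If not `NULL`, crop to the window starting at this time
#'   (ms, relative to the current alignment) and reset the time axis to start
#'   at 0 — used to realign post-decision analyses to post-decision stimulus
#'   onset.
#' @param window_ms Window length retained after realignment (default 850 ms).
#' @param alignment Label recorded for the new alignment event.
#' @return An [epoch_set()] at `new_rate`.
#' @export
preprocess <- function(epochs, new_rate = 100, highpass = 0.5,
                       align_ms = NULL, window_ms = 850,
                       alignment = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  fs <- epochs$sampling_rate
  data <- epochs$data
  times <- epochs$times_ms

  if (new_rate != fs) {
    if (new_rate > fs) abort("upsampling is not supported")
    q <- fs / new_rate
    if (abs(q - round(q)) > 1e-9) abort("`new_rate` must divide the sampling rate")
    q <- as.integer(round(q))
    n_new <- ceiling(d[3] / q)
    out <- array(0, dim = c(d[1], d[2], n_new))
    for (i in seq_len(d[1])) for (ch in seq_len(d[2])) {
      out[i, ch, ] <- signal::decimate(data[i, ch, ], q)
    }
    data <- out
    times <- times[1] + (seq_len(n_new) - 1) * 1000 / new_rate
    fs <- new_rate
  }

  if (!is.null(highpass) && highpass > 0) {
    bf <- signal::butter(4, highpass / (fs / 2), type = "high")
    for (i in seq_len(dim(data)[1])) for (ch in seq_len(dim(data)[2])) {
      data[i, ch, ] <- signal::filtfilt(bf, data[i, ch, ])
    }
  }

  out <- epoch_set(data, times, fs, epochs$trials, epochs$channels,
                   alignment = alignment %b% epochs$alignment)
  if (!is.null(align_ms)) {
    out <- crop_epochs(out, align_ms, window_ms,
                       alignment = alignment %b% "realigned")
  }
  out
}

#' Crop an epoch set to an analysis window
#'
#' Retains samples in `[onset_ms, onset_ms + window_ms]` and resets the time
#' axis so the window starts at 0 — the package's realignment primitive
#' (onsets are configurable because task timelines differ between studies).
#'
#' @param epochs An [epoch_set()].
#' @param onset_ms Window onset relative to the current alignment.
#' @param window_ms Window length in ms.
#' @param alignment Label for the new alignment event.
#' @return An [epoch_set()] covering the window.
#' @export
crop_epochs <- function(epochs, onset_ms, window_ms = 850,
                        alignment = "realigned") {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$times_ms >= onset_ms - 1e-9 &
                 epochs$times_ms <= onset_ms + window_ms + 1e-9)
  if (length(idx) < 2) abort("requested window is shorter than the segment allows")
  if (max(epochs$times_ms) < onset_ms + window_ms - 1e-9) {
    abort("segment too short for the requested window")
  }
  epoch_set(epochs$data[, , idx, drop = FALSE],
            epochs$times_ms[idx] - onset_ms, epochs$sampling_rate,
            epochs$trials, epochs$channels, alignment = alignment)
}

#' Sliding-window decoding features
#'
#' Converts an epoch set into per-timepoint feature matrices: at each
#' timepoint of the grid (step `step_ms`), features are the mean channel
#' activity over the preceding `window_ms` (windows right-aligned to the
#' nominal timepoint and clipped at the epoch edge), optionally z-scored per
#' channel across trials.
#'
#' @param epochs An [epoch_set()].
#' @param window_ms Averaging window length (default 100 ms).
#' @param step_ms Grid step (default 10 ms).
#' @param standardize Z-score each channel across trials at each timepoint.
#' @return An object of class `dv_features`: list of trials x channels
#'   matrices (one per timepoint), the timepoint grid (`times_ms`), channel
#'   names and the trial label tibble.
#' @export
sliding_features <- function(epochs, window_ms = 100, step_ms = 10,
                             standardize = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (step_ms <= 0) abort("`step_ms` must be positive")
  if (window_ms > diff(range(epochs$times_ms))) {
    abort("`window_ms` exceeds the epoch length")
  }
  grid <- seq(min(epochs$times_ms), max(epochs$times_ms), by = step_ms)
  x <- lapply(grid, function(tp) {
    idx <- which(epochs$times_ms > tp - window_ms + 1e-9 &
                   epochs$times_ms <= tp + 1e-9)
    m <- if (length(idx) == 1) epochs$data[, , idx]
         else apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
    m <- matrix(m, dim(epochs$data)[1], dim(epochs$data)[2])
    if (standardize) .zscore_cols(m) else m
  })
  structure(list(x = x, times_ms = grid, channels = epochs$channels,
                 trials = epochs$trials),
            class = "dv_features")
}

# z-score columns; constant columns become 0
.zscore_cols <- function(m, center = NULL, scale = NULL) {
  center <- center %b% colMeans(m)
  scale <- scale %b% apply(m, 2, sd)
  scale[scale < .Machine$double.eps] <- 1
  sweep(sweep(m, 2, center, "-"), 2, scale, "/")
}

#' @export
print.dv_features <- function(x, ...) {
  cat(sprintf("<dv_features> %d timepoints (%g..%g ms), %d trials x %d channels\n",
              length(x$times_ms), min(x$times_ms), max(x$times_ms),
              nrow(x$x[[1]]), ncol(x$x[[1]])))
  invisible(x)
}
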