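#' Construct a sensor-space epoch container
#'
#' Lightweight container for segmented sensor data: a trials x channels x
#' samples array plus the time axis, sampling rate, channel names, the
#' alignment event, and a tibble of per-trial labels.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param times_ms Numeric vector of sample times in ms relative to the
#'   alignment event; must be strictly increasing and uniform.
#' @param sampling_rate Sampling rate in Hz.
#' @param trials Tibble of per-trial labels (one row per trial).
#' @param channels Channel names; defaults to `MEG001`...
#' @param alignment Name of the alignment event (e.g. `"trial_onset"`).
#' @return A list of class `epoch_set`.
#' @export
epoch_set <- function(data, times_ms, sampling_rate, trials,
                      channels = NULL, alignment = "trial_onset") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(times_ms) != dim(data)[3]) {
    abort("`times_ms` must match the sample dimension")
  }
  dt <- diff(times_ms)
  if (any(dt <= 0) || max(abs(dt - 1000 / sampling_rate)) > 1e-6) {
    abort("`times_ms` must be strictly increasing at 1/sampling_rate")
  }
  if (nrow(trials) != dim(data)[1]) {
    abort("`trials` must have one row per epoch")
  }
  channels <- channels %b% sprintf("MEG%03d", seq_len(dim(data)[2]))
  structure(list(data = data, times_ms = as.numeric(times_ms),
                 sampling_rate = sampling_rate,
                 channels = channels, trials = as_tibble(trials),
                 alignment = alignment),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, %g..%g ms (aligned: %s)\n",
              d[1], d[2], d[3], x$sampling_rate, min(x$times_ms),
              max(x$times_ms), x$alignment))
  invisible(x)
}

#' Ground truth for synthetic sensor epochs
#'
#' Describes the decodable signal injected into synthetic epochs: a unit-norm
#' spatial pattern over channels, amplitude-trajectory coefficients for the
#' pre- and post-decision phases, and the noise model (Gaussian with
#' exponential spatial correlation across channels).
#'
#' The post-decision amplitude of trial i is
#' `choice_sign * intercept_i + direction_sign * slope_i * t`, with
#' `slope_i = slope_intercept + slope_decision * d + slope_confidence * c +
#' slope_interaction * c * d + N(0, slope_trial_sd)` (d = +1 confirmatory /
#' -1 disconfirmatory, c = +1 high / -1 low confidence) and an analogous
#' model for the intercept. These per-trial values are what the decoding
#' pipeline must recover.
#'
#' @param n_channels Number of sensors (default 273).
#' @param noise_scale Noise standard deviation per channel per sample.
#' @param spatial_corr_length Exponential correlation length of the noise
#'   across the channel index (channels; 0 = white).
#' @param pattern Optional spatial pattern vector; drawn smoothly at random
#'   and normalized to unit norm if `NULL`.
#' @param pre_intercept,pre_slope Pre-decision amplitude trajectory
#'   (choice-locked; slope per second).
#' @param slope_intercept,slope_decision,slope_confidence,slope_interaction
#'   Post-decision slope coefficients (DV units per second).
#' @param icpt_intercept,icpt_decision,icpt_confidence,icpt_interaction
#'   Post-decision intercept coefficients.
#' @param slope_trial_sd,icpt_trial_sd Trial-level variability.
#' @return A list of class `epoch_ground_truth`.
#' @export
epoch_ground_truth <- function(n_channels = 273, noise_scale = 0.5,
                               spatial_corr_length = 5, pattern = NULL,
                               pre_intercept = 0.2, pre_slope = 1.5,
                               slope_intercept = 1.0, slope_decision = 0.3,
                               slope_confidence = 0.1, slope_interaction = 0.4,
                               icpt_intercept = 0.05, icpt_decision = 0.05,
                               icpt_confidence = 0.05, icpt_interaction = 0.05,
                               slope_trial_sd = 0.4, icpt_trial_sd = 0.15) {
  if (noise_scale < 0) abort("`noise_scale` must be >= 0")
  if (!is.null(pattern)) {
    if (length(pattern) != n_channels) abort("`pattern` length must equal `n_channels`")
    pattern <- pattern / sqrt(sum(pattern^2))
  }
  structure(list(
    n_channels = n_channels, noise_scale = noise_scale,
    spatial_corr_length = spatial_corr_length, pattern = pattern,
    pre_intercept = pre_intercept, pre_slope = pre_slope,
    slope = c(intercept = slope_intercept, decision = slope_decision,
              confidence = slope_confidence, interaction = slope_interaction),
    icpt = c(intercept = icpt_intercept, decision = icpt_decision,
             confidence = icpt_confidence, interaction = icpt_interaction),
    slope_trial_sd = slope_trial_sd, icpt_trial_sd = icpt_trial_sd
  ), class = "epoch_ground_truth")
}

#' Simulate sensor-space epochs carrying a decodable decision signal
#'
#' Generates trials x channels x samples epochs as spatially correlated
#' Gaussian noise plus a rank-one signal: the ground-truth spatial pattern
#' times a side-signed amplitude trajectory. In the pre-decision window the
#' amplitude is locked to the initial choice (so a choice decoder can be
#' trained); in the post-decision window the intercept is locked to the
#' initial choice while the slope follows the presented motion direction with
#' a magnitude set by the condition-dependent ground truth.
#'
#' @param trials Trial table (binary-confidence variant of
#'   [simulate_session()]); must carry `initial_choice`, `direction`,
#'   `initial_confidence`, `initial_correct`, `change_of_mind`.
#' @param truth An [epoch_ground_truth()].
#' @param seed Integer seed.
#' @param times_ms Sample times in ms relative to trial onset; the default
#'   spans -200..8000 ms at 100 Hz (821 samples).
#' @param sampling_rate Sampling rate in Hz.
#' @param pre_onset_ms,post_onset_ms Onsets of the pre- and post-decision
#'   evidence windows (configurable task delays).
#' @param window_ms Length of each analysis window (default 850 ms).
#' @return A list with elements `epochs` (an [epoch_set()]) and `truth` (the
#'   input ground truth augmented with a `per_trial` tibble of the injected
#'   intercepts and slopes).
#' @export
simulate_epochs <- function(trials, truth = epoch_ground_truth(), seed = 1L,
                            times_ms = seq(-200, 8000, by = 10),
                            sampling_rate = 100,
                            pre_onset_ms = 0, post_onset_ms = 4000,
                            window_ms = 850) {
  stopifnot(inherits(truth, "epoch_ground_truth"), is.data.frame(trials))
  need <- c("initial_choice", "direction", "initial_confidence",
            "initial_correct", "change_of_mind")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    abort(paste0("`trials` lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(trials); C <- truth$n_channels; Tn <- length(times_ms)
  set.seed(seed)
  pattern <- truth$pattern
  if (is.null(pattern)) {
    raw <- as.numeric(stats::filter(rnorm(C + 20), rep(1, 7), sides = 2))
    pattern <- raw[11:(10 + C)]
    pattern[is.na(pattern)] <- 0
    pattern <- pattern / sqrt(sum(pattern^2))
  }

  conf <- trials$initial_confidence
  if (!all(conf %in% c(0, 1))) conf <- as.numeric(conf > median(conf))
  c_s <- 2 * conf - 1
  d_s <- ifelse(trials$initial_correct == 1, 1, -1)
  choice_sign <- ifelse(trials$initial_choice == "right", 1, -1)
  dir_sign <- ifelse(trials$direction == "right", 1, -1)

  slope_i <- truth$slope[["intercept"]] + truth$slope[["decision"]] * d_s +
    truth$slope[["confidence"]] * c_s + truth$slope[["interaction"]] * c_s * d_s +
    rnorm(n, 0, truth$slope_trial_sd)
  icpt_i <- truth$icpt[["intercept"]] + truth$icpt[["decision"]] * d_s +
    truth$icpt[["confidence"]] * c_s + truth$icpt[["interaction"]] * c_s * d_s +
    rnorm(n, 0, truth$icpt_trial_sd)

  pre_idx <- which(times_ms >= pre_onset_ms & times_ms <= pre_onset_ms + window_ms)
  post_idx <- which(times_ms >= post_onset_ms & times_ms <= post_onset_ms + window_ms)
  if (!length(pre_idx) || !length(post_idx)) {
    abort("analysis windows fall outside `times_ms`")
  }
  t_pre <- (times_ms[pre_idx] - pre_onset_ms) / 1000
  t_post <- (times_ms[post_idx] - post_onset_ms) / 1000

  # amplitude matrix trials x samples
  amp <- matrix(0, n, Tn)
  amp[, pre_idx] <- outer(choice_sign * truth$pre_intercept, rep(1, length(pre_idx))) +
    outer(choice_sign * truth$pre_slope, t_pre)
  amp[, post_idx] <- outer(choice_sign * icpt_i, rep(1, length(post_idx))) +
    outer(dir_sign * slope_i, t_post)

  L <- NULL
  if (truth$noise_scale > 0 && truth$spatial_corr_length > 0) {
    Sig <- exp(-abs(outer(seq_len(C), seq_len(C), "-")) / truth$spatial_corr_length)
    L <- chol(Sig)
  }
  data <- array(0, dim = c(n, C, Tn))
  for (i in seq_len(n)) {
    sig <- outer(pattern, amp[i, ])
    if (truth$noise_scale > 0) {
      noise <- matrix(rnorm(C * Tn, 0, truth$noise_scale), C, Tn)
      if (!is.null(L)) noise <- crossprod(L, noise)
      sig <- sig + noise
    }
    data[i, , ] <- sig
  }

  truth$pattern <- pattern
  truth$per_trial <- tibble(trial = seq_len(n), intercept = icpt_i,
                            slope = slope_i, direction = trials$direction,
                            choice_sign = choice_sign)
  truth$windows <- list(pre_onset_ms = pre_onset_ms,
                        post_onset_ms = post_onset_ms, window_ms = window_ms)
  list(
    epochs = epoch_set(data, times_ms, sampling_rate, trials,
                       alignment = "trial_onset"),
    truth = truth
  )
}
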