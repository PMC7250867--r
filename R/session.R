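#' Simulate a two-stage decision session
#'
#' Generates a balanced 2 (positive-evidence level: LPE/HPE) x 2
#' (post-decision evidence strength: weak/strong) factorial session for one or
#' more synthetic observers. Per trial: a motion direction is drawn; the
#' initial choice and RT come from a pre-decision diffusion whose drift is set
#' by the condition's calibrated coherence difference; confidence is generated
#' from decision time plus a positive-evidence offset (so HPE raises
#' confidence at matched accuracy); the final choice and RT come from a
#' post-decision diffusion whose drift rate and starting point depend on
#' confidence, the initial decision and their interaction according to the
#' observer's ground-truth coefficients.
#'
#' @param observer An [observer_spec()]; its `post` coefficients are the
#'   ground truth that recovery analyses target.
#' @param n_subjects Number of subjects to simulate.
#' @param trials_per_cell Trials in each of the 4 design cells (default 90).
#' @param stimuli A [make_stimulus_set()] result, or `NULL` to calibrate the
#'   coherences by running the staircase on the observer.
#' @param target_accuracy Staircase target used when `stimuli` is `NULL`.
#' @param confidence_format `"continuous"` for a rating in `[0.5, 1]`
#'   (behavioural studies) or `"binary"` for a high/low rating obtained by
#'   median split (the MEG variant).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param dt Diffusion integration step (seconds).
#'
#' @return A tibble (one row per trial) with columns `subject_id`,
#'   `pe_condition`, `post_strength`, `direction`, `initial_choice`,
#'   `initial_correct`, `initial_confidence`, `initial_rt`, `final_choice`,
#'   `final_correct`, `final_confidence`, `final_rt`, `change_of_mind`.
#' @export
simulate_session <- function(observer = observer_spec(), n_subjects = 1,
                             trials_per_cell = 90, stimuli = NULL,
                             target_accuracy = 0.71,
                             confidence_format = c("continuous", "binary"),
                             seed = 1L, dt = 0.002) {
  confidence_format <- match.arg(confidence_format)
  stopifnot(inherits(observer, "observer_spec"))
  if (trials_per_cell < 1 || n_subjects < 1) {
    abort("`n_subjects` and `trials_per_cell` must be positive")
  }
  if (is.null(stimuli)) {
    lpe <- run_staircase(observer, target_accuracy, n_trials = 600,
                         seed = seed + 7L, incorrect_coherence = 0.05)
    hpe <- run_staircase(observer, target_accuracy, n_trials = 600,
                         seed = seed + 11L, incorrect_coherence = 0.15)
    stimuli <- make_stimulus_set(lpe_correct = lpe$coherence,
                                 hpe_correct = hpe$coherence)
  }
  stopifnot(inherits(stimuli, "stimulus_coherences"))
  set.seed(seed)
  out <- purrr::map(seq_len(n_subjects), function(s) {
    .simulate_subject(observer, s, trials_per_cell, stimuli, dt)
  }) |> bind_rows()
  if (confidence_format == "binary") {
    out <- out |>
      group_by(.data$subject_id) |>
      mutate(
        initial_confidence = as.numeric(.data$initial_confidence >
                                          median(.data$initial_confidence)),
        final_confidence = as.numeric(.data$final_confidence >
                                        median(.data$final_confidence))
      ) |>
      ungroup()
  }
  out
}

.simulate_subject <- function(observer, subject_id, trials_per_cell,
                              stimuli, dt) {
  cells <- tidyr::expand_grid(pe_condition = c("LPE", "HPE"),
                              post_strength = c("weak", "strong"))
  design <- cells[rep(seq_len(nrow(cells)), each = trials_per_cell), ]
  n <- nrow(design)
  direction <- sample(c("left", "right"), n, replace = TRUE)

  dc_pre <- ifelse(design$pe_condition == "HPE",
                   stimuli$hpe_correct - stimuli$hpe_incorrect,
                   stimuli$lpe_correct - stimuli$lpe_incorrect)
  total_coh <- ifelse(design$pe_condition == "HPE",
                      stimuli$hpe_correct + stimuli$hpe_incorrect,
                      stimuli$lpe_correct + stimuli$lpe_incorrect)

  # initial stage: accuracy-coded diffusion, drift tied to the psychometric
  # slope so diffusion accuracy matches the staircase calibration
  v_pre <- observer$psycho_slope / observer$pre_a * dc_pre
  pre <- .sim_wiener_trials_cpp(rep(observer$pre_a, n), v_pre, rep(0.5, n),
                                rep(observer$pre_t0, n), dt)
  initial_correct <- pre$upper
  initial_rt <- pre$rt
  initial_choice <- ifelse(initial_correct == 1, direction,
                           ifelse(direction == "left", "right", "left"))

  # confidence: decision time + positive-evidence offset, on [0.5, 1]
  conf_logit <- observer$conf_intercept -
    observer$conf_rt_gain * (initial_rt - observer$pre_t0) +
    observer$conf_pe_gain * total_coh +
    rnorm(n, 0, observer$conf_noise)
  initial_confidence <- 0.5 + 0.5 * plogis(conf_logit)

  # post-decision stage, ground-truth regression structure
  cf <- observer$post
  c_s <- scale_confidence(initial_confidence)
  d_s <- ifelse(initial_correct == 1, 1, -1)
  w_s <- ifelse(design$post_strength == "strong", 1, -1)
  v_post <- cf[["v0"]] + cf[["v_w"]] * w_s + cf[["v_c"]] * c_s +
    cf[["v_d"]] * d_s + cf[["v_cd"]] * c_s * d_s
  z_post <- plogis(cf[["z0"]] + cf[["z_c"]] * c_s + cf[["z_d"]] * d_s +
                     cf[["z_cd"]] * c_s * d_s)
  a_post <- exp(cf[["log_a0"]] + cf[["a_c"]] * c_s)
  post <- .sim_wiener_trials_cpp(a_post, v_post, z_post,
                                 rep(cf[["t0"]], n), dt)
  final_correct <- post$upper
  final_rt <- post$rt
  final_choice <- ifelse(final_correct == 1, direction,
                         ifelse(direction == "left", "right", "left"))

  final_conf_logit <- conf_logit +
    0.8 * (2 * final_correct - 1) + rnorm(n, 0, observer$conf_noise)
  tibble(
    subject_id = sprintf("S%02d", subject_id),
    pe_condition = design$pe_condition,
    post_strength = design$post_strength,
    direction = direction,
    initial_choice = initial_choice,
    initial_correct = initial_correct,
    initial_confidence = initial_confidence,
    initial_rt = initial_rt,
    final_choice = final_choice,
    final_correct = final_correct,
    final_confidence = 0.5 + 0.5 * plogis(final_conf_logit),
    final_rt = final_rt,
    change_of_mind = as.integer(final_choice != initial_choice)
  )
}

#' Discard implausibly fast final responses
#'
#' Removes trials whose final RT falls below the minimum plausible decision
#' latency (default 200 ms) before diffusion fitting, and reports how many
#' rows were dropped.
#'
#' @param trials A trial table.
#' @param min_rt Threshold in seconds (default 0.2).
#' @return The filtered tibble; errors if nothing survives.
#' @export
filter_rts <- function(trials, min_rt = 0.2) {
  stopifnot(is.data.frame(trials), "final_rt" %in% names(trials))
  keep <- trials$final_rt >= min_rt
  dropped <- sum(!keep)
  if (dropped > 0) {
    inform(sprintf("filter_rts: discarded %d of %d trials with final RT < %g s",
                   dropped, nrow(trials), min_rt))
  }
  out <- trials[keep, , drop = FALSE]
  if (nrow(out) == 0) abort("all trials removed by the RT filter; fit impossible")
  as_tibble(out)
}
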