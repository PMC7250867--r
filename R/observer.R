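#' Specify a synthetic observer
#'
#' Bundles the generative parameters of a simulated participant: a logistic
#' psychometric function over the correct-minus-incorrect coherence difference,
#' pre-decision diffusion parameters for the initial choice and its RT, a
#' confidence model, and the ground-truth post-decision regression coefficients
#' that couple drift rate and starting point to initial confidence, initial
#' decision and their interaction (the quantities the hierarchical diffusion
#' fit is meant to recover).
#'
#' The psychometric function is `P(correct) = plogis(psycho_slope * dc)` where
#' `dc` is the coherence difference; with the default pre-decision boundary the
#' diffusion-based initial stage reproduces the same accuracy at the calibrated
#' coherence because the pre-decision drift is `psycho_slope / pre_a * dc`.
#'
#' Confidence is generated on the half-probability scale `[0.5, 1]` as
#' `0.5 + 0.5 * plogis(conf_intercept - conf_rt_gain * decision_time +
#' conf_pe_gain * total_coherence + noise)`: decision time carries the coupling
#' between confidence and accuracy, while the positive-evidence term (total
#' coherent motion, correct + incorrect) raises confidence without touching
#' accuracy — the dissociation the task design is built around.
#'
#' Post-decision accumulation is accuracy-coded. With confidence `c` scaled to
#' `[-1, 1]`, initial decision `d` coded +1 (correct, hence confirmatory
#' post-decision evidence) / -1, and post-decision strength `w` coded
#' -1 (weak) / +1 (strong):
#' \deqn{v = v0 + v_w w + v_c c + v_d d + v_{cd} c d}
#' \deqn{z = plogis(z0 + z_c c + z_d d + z_{cd} c d)}
#' \deqn{a = exp(log_a0 + a_c c)}
#'
#' @param psycho_slope Slope of the logistic psychometric function (per unit
#'   coherence difference).
#' @param pre_a,pre_t0 Pre-decision boundary separation and non-decision time.
#' @param conf_intercept,conf_rt_gain,conf_pe_gain,conf_noise Confidence model
#'   parameters (logit scale).
#' @param post Named numeric vector of post-decision generative coefficients;
#'   any subset of the defaults may be overridden.
#' @return A list of class `observer_spec`.
#' @examples
#' obs <- observer_spec()
#' obs$post[["v_cd"]]
#' @export
observer_spec <- function(psycho_slope = 6,
                          pre_a = 1.6, pre_t0 = 0.35,
                          conf_intercept = 0.5, conf_rt_gain = 1.2,
                          conf_pe_gain = 2.0, conf_noise = 0.8,
                          post = NULL) {
  if (!is.numeric(psycho_slope) || psycho_slope <= 0) {
    abort("`psycho_slope` must be positive")
  }
  post_default <- c(v0 = 1.0, v_w = 0.3, v_c = 0, v_d = 0.3, v_cd = 0.4,
                    z0 = 0, z_c = 0, z_d = 0.3, z_cd = 0.15,
                    log_a0 = log(1.5), a_c = -0.1, t0 = 0.35)
  if (!is.null(post)) {
    bad <- setdiff(names(post), names(post_default))
    if (length(bad)) abort(paste0("unknown post-decision coefficients: ",
                                  paste(bad, collapse = ", ")))
    post_default[names(post)] <- post
  }
  if (any(!is.finite(post_default))) abort("post-decision coefficients must be finite")
  structure(list(
    psycho_slope = psycho_slope,
    pre_a = pre_a, pre_t0 = pre_t0,
    conf_intercept = conf_intercept, conf_rt_gain = conf_rt_gain,
    conf_pe_gain = conf_pe_gain, conf_noise = conf_noise,
    post = post_default
  ), class = "observer_spec")
}

#' Calibrate the correct-direction coherence with a weighted up/down staircase
#'
#' Runs a transformed weighted up/down staircase (Kaernbach-type) on a
#' simulated observer to find the correct-direction coherence that yields a
#' target proportion correct. After an error the coherence is raised by
#' `step_up`; after a correct response it is lowered by
#' `step_up * (1 - target) / target`, so the procedure equilibrates at the
#' target accuracy.
#'
#' @param observer An [observer_spec()], or a function
#'   `f(correct_coherence, incorrect_coherence)` returning `TRUE`/`FALSE`
#'   (correct/incorrect) for deterministic test observers.
#' @param target_accuracy Target proportion correct, strictly between 0.5 and 1.
#' @param n_trials Number of staircase trials.
#' @param seed Integer seed; the run is fully reproducible.
#' @param incorrect_coherence Fixed incorrect-direction coherence of the
#'   condition being calibrated.
#' @param start_coherence Initial correct-direction coherence.
#' @param step_up Upward step after an error, in coherence units.
#' @param tail_fraction Fraction of trials (from the end) used to assess
#'   convergence and compute the converged coherence.
#' @param tolerance Maximum absolute deviation of tail accuracy from the
#'   target before the run is flagged as non-converged.
#'
#' @return A list of class `staircase_state`: `coherence` (mean over the
#'   tail), `tail_accuracy`, `converged` (logical), `target_accuracy`, and a
#'   `history` tibble with one row per trial (`trial`, `coherence`, `correct`).
#' @export
run_staircase <- function(observer, target_accuracy, n_trials = 180,
                          seed = 1L, incorrect_coherence = 0.05,
                          start_coherence = 0.5, step_up = 0.02,
                          tail_fraction = 0.2, tolerance = 0.05) {
  if (!(target_accuracy > 0.5 && target_accuracy < 1)) {
    abort("`target_accuracy` must be strictly between 0.5 and 1")
  }
  if (n_trials < 1) abort("`n_trials` must be positive")
  respond <- if (is.function(observer)) {
    function(cc) isTRUE(observer(cc, incorrect_coherence))
  } else if (inherits(observer, "observer_spec")) {
    slope <- observer$psycho_slope
    function(cc) runif(1) < plogis(slope * (cc - incorrect_coherence))
  } else {
    abort("`observer` must be an observer_spec or a function")
  }
  step_down <- step_up * (1 - target_accuracy) / target_accuracy
  set.seed(seed)
  coherence <- numeric(n_trials)
  correct <- logical(n_trials)
  cc <- start_coherence
  for (i in seq_len(n_trials)) {
    coherence[i] <- cc
    correct[i] <- respond(cc)
    cc <- if (correct[i]) cc - step_down else cc + step_up
    cc <- min(max(cc, 0), 1)
  }
  tail_n <- max(1L, floor(n_trials * tail_fraction))
  tail_idx <- seq.int(n_trials - tail_n + 1L, n_trials)
  tail_acc <- mean(correct[tail_idx])
  pinned <- mean(coherence[tail_idx] %in% c(0, 1))
  converged <- abs(tail_acc - target_accuracy) <= tolerance && pinned < 0.5
  structure(list(
    coherence = mean(coherence[tail_idx]),
    tail_accuracy = tail_acc,
    converged = converged,
    target_accuracy = target_accuracy,
    incorrect_coherence = incorrect_coherence,
    history = tibble(trial = seq_len(n_trials), coherence = coherence,
                     correct = as.integer(correct))
  ), class = "staircase_state")
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf(
    "<staircase_state> %d trials, target %.2f, tail accuracy %.3f, coherence %.3f%s\n",
    nrow(x$history), x$target_accuracy, x$tail_accuracy, x$coherence,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}
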