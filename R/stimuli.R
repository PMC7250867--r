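#' Construct the factorial stimulus coherence set
#'
#' Builds the full set of random-dot-motion coherence levels for a two-stage
#' session with a positive-evidence manipulation. Dots move coherently in both
#' the correct and the incorrect direction; the incorrect-direction coherence is
#' fixed at 5% in the low positive-evidence (LPE) condition and 15% in the high
#' positive-evidence (HPE) condition, while the correct-direction coherences are
#' staircase-calibrated inputs. Post-decision stimuli are derived from the
#' calibrated pre-decision values: the incorrect-direction coherence is the
#' average of the two fixed incorrect values, the weak correct-direction
#' coherence is the average of the two calibrated correct values, and the strong
#' one multiplies the weak value by 1.3.
#'
#' @param lpe_correct Correct-direction coherence for the LPE condition, in
#'   `[0, 1]` (typically the output of [run_staircase()]).
#' @param hpe_correct Correct-direction coherence for the HPE condition.
#' @param lpe_incorrect,hpe_incorrect Fixed incorrect-direction coherences;
#'   defaults are the design constants 0.05 and 0.15.
#' @param strong_multiplier Multiplier turning weak into strong post-decision
#'   evidence; default 1.3.
#'
#' @return A one-row tibble of class `stimulus_coherences` with columns
#'   `lpe_correct`, `lpe_incorrect`, `hpe_correct`, `hpe_incorrect`,
#'   `post_incorrect`, `post_weak_correct`, `post_strong_correct`.
#' @examples
#' make_stimulus_set(lpe_correct = 0.25, hpe_correct = 0.35)
#' @export
make_stimulus_set <- function(lpe_correct, hpe_correct,
                              lpe_incorrect = 0.05, hpe_incorrect = 0.15,
                              strong_multiplier = 1.3) {
  vals <- c(lpe_correct = lpe_correct, hpe_correct = hpe_correct,
            lpe_incorrect = lpe_incorrect, hpe_incorrect = hpe_incorrect)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    abort("coherences must be finite proportions in [0, 1]")
  }
  post_incorrect <- (lpe_incorrect + hpe_incorrect) / 2
  post_weak_correct <- (lpe_correct + hpe_correct) / 2
  post_strong_correct <- post_weak_correct * strong_multiplier
  out <- tibble(
    lpe_correct = lpe_correct, lpe_incorrect = lpe_incorrect,
    hpe_correct = hpe_correct, hpe_incorrect = hpe_incorrect,
    post_incorrect = post_incorrect,
    post_weak_correct = post_weak_correct,
    post_strong_correct = post_strong_correct
  )
  if (any(unlist(out) > 1)) {
    abort("derived coherence exceeds 1; lower the correct-direction inputs")
  }
  # total coherent motion cannot exceed the dot budget
  sums <- c(lpe_correct + lpe_incorrect, hpe_correct + hpe_incorrect,
            post_weak_correct + post_incorrect,
            post_strong_correct + post_incorrect)
  if (any(sums > 1)) {
    abort("correct + incorrect coherence exceeds 1 for at least one stimulus")
  }
  class(out) <- c("stimulus_coherences", class(out))
  out
}

#' Quadratic scoring rule for confidence reports
#'
#' Points awarded for a single decision under the incentive-compatible
#' quadratic scoring rule: `100 * (1 - (correct - confidence)^2)`. The rule is
#' proper: expected points are maximized by reporting confidence equal to the
#' subjective probability of being correct.
#'
#' @param correct 0/1 indicator (vectorized) of whether the choice was correct.
#' @param confidence Confidence report in `[0, 1]`, interpreted as the
#'   subjective probability of being correct.
#' @return Numeric vector of points in `[0, 100]`.
#' @examples
#' score_qsr(correct = 1, confidence = 1)    # 100
#' score_qsr(correct = 1, confidence = 0.5)  # 75
#' score_qsr(correct = 0, confidence = 1)    # 0
#' @export
score_qsr <- function(correct, confidence) {
  if (any(!correct %in% c(0, 1))) abort("`correct` must be 0 or 1")
  if (any(!is.finite(confidence)) || any(confidence < 0) || any(confidence > 1)) {
    abort("`confidence` must lie in [0, 1]")
  }
  100 * (1 - (correct - confidence)^2)
}
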