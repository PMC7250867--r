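#' The ten-model regression family over diffusion parameters
#'
#' Builds the covariate-dependency specification for one of the ten
#' hierarchical diffusion regression models. Every model includes intercepts
#' for all parameters, a dependency of drift rate on post-decision evidence
#' strength, and a dependency of boundary separation on confidence. The
#' baseline model (1) adds nothing else. Three families then add dependencies
#' of starting point and/or drift rate on (i) initial confidence (models 2-4),
#' (ii) the initial decision (models 5-7), or (iii) confidence, decision and
#' their interaction together (models 8-10, the interaction family keeping its
#' lower-order terms). Within each family the three variants place the
#' dependency on the starting point only, the drift rate only, or both — so
#' model 10 is the full model with confidence, initial decision and their
#' interaction on both starting point and drift rate.
#'
#' @param model_id Integer in 1..10.
#' @return A list of class `ddm_model_spec` with character vectors `z_terms`,
#'   `v_terms`, `a_terms` (intercepts implicit).
#' @examples
#' build_model(1)$v_terms   # post_evidence_strength only
#' build_model(10)$z_terms  # confidence, initial_decision, interaction
#' @export
build_model <- function(model_id) {
  if (length(model_id) != 1 || !model_id %in% 1:10) {
    abort("`model_id` must be a single integer in 1..10")
  }
  model_id <- as.integer(model_id)
  fam_terms <- list(
    character(0),                                      # baseline
    "confidence",                                      # family i
    "initial_decision",                                # family ii
    c("confidence", "initial_decision", "interaction") # family iii
  )
  if (model_id == 1L) {
    z_extra <- character(0); v_extra <- character(0)
  } else {
    fam <- (model_id - 2L) %/% 3L + 2L      # 2..4
    variant <- (model_id - 2L) %% 3L        # 0 = z-only, 1 = v-only, 2 = both
    terms <- fam_terms[[fam]]
    z_extra <- if (variant %in% c(0L, 2L)) terms else character(0)
    v_extra <- if (variant %in% c(1L, 2L)) terms else character(0)
  }
  structure(list(
    model_id = model_id,
    z_terms = z_extra,
    v_terms = c("post_evidence_strength", v_extra),
    a_terms = "confidence"
  ), class = "ddm_model_spec")
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  fmt <- function(t) paste(c("1", t), collapse = " + ")
  cat(sprintf("<ddm_model_spec> model %d\n", x$model_id))
  cat("  starting point      ~ ", fmt(x$z_terms), "\n", sep = "")
  cat("  drift rate          ~ ", fmt(x$v_terms), "\n", sep = "")
  cat("  boundary separation ~ ", fmt(x$a_terms), "\n", sep = "")
  invisible(x)
}

#' Rescale confidence ratings to the model's parametric range
#'
#' Behavioural confidence lives on `[0.5, 1]` (probability of being correct);
#' the regression models use a symmetric `[-1, 1]` coding. The map is affine:
#' `(confidence - 0.75) / 0.25`.
#'
#' @param confidence Numeric vector in `[0.5, 1]`.
#' @return Numeric vector in `[-1, 1]`.
#' @export
scale_confidence <- function(confidence) {
  if (any(confidence < 0.5 - 1e-9 | confidence > 1 + 1e-9, na.rm = TRUE)) {
    abort("behavioural confidence must lie in [0.5, 1]")
  }
  (confidence - 0.75) / 0.25
}

#' Add model covariate codings to a trial table
#'
#' Derives the covariates the diffusion regressions use from a trial table:
#' `confidence` scaled to `[-1, 1]` (from `initial_confidence`),
#' `initial_decision` coded +1 when the initial choice was correct (so the
#' post-decision evidence is confirmatory) and -1 otherwise, their
#' `interaction`, and `post_evidence_strength` coded -1 (weak) / +1 (strong).
#'
#' @param trials A trial table (see [simulate_session()]).
#' @return The table with columns `confidence`, `initial_decision`,
#'   `interaction`, `post_evidence_strength` appended.
#' @export
code_covariates <- function(trials) {
  stopifnot(is.data.frame(trials))
  conf <- trials$initial_confidence
  conf_c <- if (all(conf %in% c(0, 1))) 2 * conf - 1 else scale_confidence(conf)
  trials |>
    mutate(
      confidence = conf_c,
      initial_decision = ifelse(.data$initial_correct == 1, 1, -1),
      interaction = .data$confidence * .data$initial_decision,
      post_evidence_strength = ifelse(.data$post_strength == "strong", 1, -1)
    )
}
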