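.trial_cols <- c("subject_id", "pe_condition", "post_strength", "direction",
                 "initial_choice", "initial_correct", "initial_confidence",
                 "initial_rt", "final_choice", "final_correct",
                 "final_confidence", "final_rt", "change_of_mind")

#' Read and write trial tables
#'
#' Trial tables are stored as plain CSV with the fixed column set documented
#' in [simulate_session()]; missing values are forbidden in both directions.
#'
#' @param trials A trial table tibble.
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   the tibble.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(.trial_cols, names(trials))
  if (length(miss)) abort(paste0("trial table lacks columns: ",
                                 paste(miss, collapse = ", ")))
  if (anyNA(trials[, .trial_cols])) abort("trial table contains missing values")
  readr::write_csv(trials[, c(.trial_cols,
                              setdiff(names(trials), .trial_cols))], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(.trial_cols, names(out))
  if (length(miss)) abort(paste0("file is not a trial table; lacks: ",
                                 paste(miss, collapse = ", ")))
  if (anyNA(out[, .trial_cols])) abort("trial table contains missing values")
  out
}

#' Read and write epoch sets
#'
#' Epoch sets are serialized as a single RDS container holding the
#' trials x channels x samples array together with `times_ms`, `channels`,
#' the trial-label tibble, the sampling rate and the alignment event — a
#' lossless round trip including all metadata.
#'
#' @param epochs An [epoch_set()].
#' @param path File path (conventionally `.rds`).
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` the
#'   epoch set.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  out <- tryCatch(readRDS(path), error = function(e)
    abort(paste0("not a readable epoch container: ", conditionMessage(e))))
  if (!inherits(out, "epoch_set")) abort("file does not contain an epoch_set")
  out
}

#' Read and write fitted diffusion models
#'
#' Fit bundles preserve the posterior draws at full precision (RDS) and can
#' additionally export the tidy fixed-effect summary as CSV alongside.
#'
#' @param fit A [fit_hierarchical()] result.
#' @param path File path for the bundle (`.rds`).
#' @param summary_csv Optional path for a CSV of the tidy summary.
#' @return `write_fit()` returns `path` invisibly; `read_fit()` the fit.
#' @export
write_fit <- function(fit, path, summary_csv = NULL) {
  stopifnot(inherits(fit, "ddm_fit"))
  saveRDS(fit, path)
  if (!is.null(summary_csv)) readr::write_csv(tidy(fit), summary_csv)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  out <- tryCatch(readRDS(path), error = function(e)
    abort(paste0("not a readable fit bundle: ", conditionMessage(e))))
  if (!inherits(out, "ddm_fit")) abort("file does not contain a ddm_fit")
  out
}
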