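#' Sensor contributions to decoding accuracy
#'
#' Estimates how much each sensor contributes to choice decodability at a
#' single timepoint (typically the timepoint of peak decodability): linear
#' classifiers are trained on random subsets of `subset_size` sensors, the
#' procedure is repeated `reps` times, and each sensor's contribution is the
#' mean cross-validated prediction accuracy over all subsets that included
#' it.
#'
#' @param features Trials x channels feature matrix at the chosen timepoint,
#'   or a [sliding_features()] object together with `timepoint` (index into
#'   its grid).
#' @param labels Initial choice labels (`"left"`/`"right"`).
#' @param subset_size Sensors per subset (default 30).
#' @param reps Number of random subsets (default 2500).
#' @param folds Cross-validation folds for the per-subset accuracy.
#' @param cost SVM regularization constant.
#' @param seed Integer seed; the map is reproducible.
#' @param timepoint Timepoint index when `features` is a `dv_features`.
#' @return A tibble (`channel`, `contribution`, `n_subsets`); a warning
#'   reports coverage if some channel appears in no subset.
#' @export
sensor_contributions <- function(features, labels, subset_size = 30,
                                 reps = 2500, folds = 4, cost = 1, seed = 1L,
                                 timepoint = NULL) {
  if (inherits(features, "dv_features")) {
    if (is.null(timepoint)) abort("supply `timepoint` with dv_features input")
    channels <- features$channels
    features <- features$x[[timepoint]]
  } else {
    channels <- colnames(features) %b% sprintf("MEG%03d", seq_len(ncol(features)))
  }
  y <- factor(as.character(labels), levels = c("left", "right"))
  n <- nrow(features); C <- ncol(features)
  if (C < subset_size) abort("`subset_size` exceeds the channel count")

  set.seed(seed)
  sums <- numeric(C); counts <- integer(C)
  for (r in seq_len(reps)) {
    ch <- sample.int(C, subset_size)
    X <- features[, ch, drop = FALSE]
    fold_of <- .stratified_folds(as.integer(y), folds)
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_of != f; te <- fold_of == f
      rule <- .svm_linear_rule(X[tr, , drop = FALSE], y[tr], cost)
      pred <- drop(X[te, , drop = FALSE] %*% rule$w) + rule$b
      correct <- correct + sum((pred > 0) == (y[te] == "right"))
    }
    acc <- correct / n
    sums[ch] <- sums[ch] + acc
    counts[ch] <- counts[ch] + 1L
  }
  uncovered <- sum(counts == 0)
  if (uncovered > 0) {
    warn(sprintf("sensor_contributions: %d of %d channels appear in no subset (reps too small)",
                 uncovered, C))
  }
  tibble(channel = channels,
         contribution = ifelse(counts > 0, sums / counts, NA_real_),
         n_subsets = counts)
}
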