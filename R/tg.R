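# rank-based AUC (equivalent to the Wilcoxon statistic); labels logical,
# TRUE = positive class, scores higher-is-positive
.auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment: deal shuffled indices round-robin per stratum
.stratified_folds <- function(strata, folds) {
  assign <- integer(length(strata))
  for (g in unique(strata)) {
    idx <- sample(which(strata == g))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Temporal generalization of the choice decoder across decision phases
#'
#' Trains the linear choice decoder at every pre-decision timepoint and tests
#' it at every post-decision timepoint, producing a train-time x test-time
#' matrix of decoding accuracy (AUC of predicting the initial decision from
#' the continuous decision-variable output). Cross-validation is stratified
#' fourfold — folds balanced over initial choice, confidence class and
#' change of mind — and repeated to average out fold-assignment noise.
#' Accuracy is reported separately for the four confidence x change-of-mind
#' cells.
#'
#' @param pre_features,post_features [sliding_features()] objects for the two
#'   phases (same trials).
#' @param labels Tibble with per-trial `initial_choice` (`"left"`/`"right"`),
#'   `confidence_class` (or binary `initial_confidence`) and `change_of_mind`.
#'   Defaults to the features' trial table.
#' @param folds Number of cross-validation folds (default 4).
#' @param reps Number of repetitions with fresh fold assignments
#'   (default 100).
#' @param cost SVM regularization constant.
#' @param seed Integer seed.
#' @return An object of class `tg_matrix`: `auc` is a 3-D array
#'   (pre-timepoints x post-timepoints x condition cell) with cells
#'   `low_no`, `high_no`, `low_change`, `high_change`; plus the timepoint
#'   grids and scheme metadata.
#' @export
temporal_generalization <- function(pre_features, post_features,
                                    labels = NULL, folds = 4, reps = 100,
                                    cost = 1, seed = 1L) {
  stopifnot(inherits(pre_features, "dv_features"),
            inherits(post_features, "dv_features"))
  labels <- labels %b% pre_features$trials
  y <- factor(as.character(labels$initial_choice), levels = c("left", "right"))
  conf <- labels[["confidence_class"]] %b% labels[["initial_confidence"]]
  if (!all(conf %in% c(0, 1))) conf <- as.numeric(conf > median(conf))
  com <- labels$change_of_mind
  n <- length(y)
  cells <- dplyr::case_when(
    conf == 0 & com == 0 ~ "low_no",
    conf == 1 & com == 0 ~ "high_no",
    conf == 0 & com == 1 ~ "low_change",
    conf == 1 & com == 1 ~ "high_change"
  )
  cell_names <- c("low_no", "high_no", "low_change", "high_change")
  counts <- table(factor(cells, levels = cell_names))
  small <- names(counts)[counts < folds]
  if (length(small)) {
    abort(paste0("condition cell(s) too small to stratify into ", folds,
                 " folds: ", paste(small, collapse = ", ")))
  }
  strata <- interaction(y, conf, com, drop = TRUE)
  Tp <- length(pre_features$x); Tq <- length(post_features$x)
  acc <- array(0, dim = c(Tp, Tq, 4), dimnames = list(NULL, NULL, cell_names))
  acc_all <- matrix(0, Tp, Tq)
  pos <- y == "right"

  set.seed(seed)
  for (rep_i in seq_len(reps)) {
    fold_of <- .stratified_folds(strata, folds)
    scores <- array(NA_real_, dim = c(n, Tp, Tq))
    for (f in seq_len(folds)) {
      train <- which(fold_of != f); test <- which(fold_of == f)
      # training-fold standardization statistics per timepoint, both phases
      post_std <- lapply(seq_len(Tq), function(tq) {
        X <- post_features$x[[tq]]
        ctr <- colMeans(X[train, , drop = FALSE])
        scl <- apply(X[train, , drop = FALSE], 2, sd)
        scl[scl < .Machine$double.eps] <- 1
        sweep(sweep(X[test, , drop = FALSE], 2, ctr, "-"), 2, scl, "/")
      })
      for (tp in seq_len(Tp)) {
        X <- pre_features$x[[tp]]
        ctr <- colMeans(X[train, , drop = FALSE])
        scl <- apply(X[train, , drop = FALSE], 2, sd)
        scl[scl < .Machine$double.eps] <- 1
        Xtr <- sweep(sweep(X[train, , drop = FALSE], 2, ctr, "-"), 2, scl, "/")
        r <- .svm_linear_rule(Xtr, y[train], cost)
        for (tq in seq_len(Tq)) {
          scores[test, tp, tq] <- drop(post_std[[tq]] %*% r$w) + r$b
        }
      }
    }
    for (ci in seq_along(cell_names)) {
      idx <- which(cells == cell_names[ci])
      sc <- scores[idx, , , drop = FALSE]
      p <- pos[idx]
      for (tp in seq_len(Tp)) for (tq in seq_len(Tq)) {
        acc[tp, tq, ci] <- acc[tp, tq, ci] + .auc(sc[, tp, tq], p)
      }
    }
    for (tp in seq_len(Tp)) for (tq in seq_len(Tq)) {
      acc_all[tp, tq] <- acc_all[tp, tq] + .auc(scores[, tp, tq], pos)
    }
  }
  acc <- acc / reps
  acc_all <- acc_all / reps
  structure(list(auc = acc, auc_overall = acc_all,
                 times_pre = pre_features$times_ms,
                 times_post = post_features$times_ms,
                 folds = folds, reps = reps, n_trials = n,
                 cell_counts = as.integer(counts)),
            class = "tg_matrix")
}

#' @export
print.tg_matrix <- function(x, ...) {
  cat(sprintf("<tg_matrix> %d x %d timepoints, %d trials, %d-fold x %d reps; mean diagonal AUC %.3f\n",
              dim(x$auc)[1], dim(x$auc)[2], x$n_trials, x$folds, x$reps,
              mean(diag(apply(x$auc, c(1, 2), mean, na.rm = TRUE)), na.rm = TRUE)))
  invisible(x)
}

#' @export
autoplot.tg_matrix <- function(object, cell = NULL, ...) {
  m <- if (is.null(cell)) apply(object$auc, c(1, 2), mean, na.rm = TRUE)
       else object$auc[, , cell]
  df <- tidyr::expand_grid(train_ms = object$times_pre,
                           test_ms = object$times_post)
  df$auc <- as.vector(t(m))
  ggplot(df, aes(x = .data$test_ms, y = .data$train_ms, fill = .data$auc)) +
    geom_tile() +
    scale_fill_gradient2(midpoint = 0.5, low = "navy", high = "firebrick") +
    labs(x = "test time, post-decision (ms)",
         y = "train time, pre-decision (ms)", fill = "AUC",
         title = if (is.null(cell)) "Temporal generalization (all cells)"
                 else paste("Temporal generalization:", cell)) +
    theme_minimal()
}
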