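# linear SVM rule with sign fixed so positive scores mean "right"
.svm_linear_rule <- function(X, y, cost = 1) {
  m <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE,
                  type = "C-classification")
  w <- drop(crossprod(m$coefs, m$SV))
  b <- -m$rho
  # libsvm's positive decision value corresponds to the first training label
  pos_class <- as.character(m$levels[m$labels[1]])
  if (pos_class != "right") { w <- -w; b <- -b }
  # normalize so scores are geometric distances to the hyperplane; keeps the
  # DV scale comparable across timepoints
  nw <- sqrt(sum(w^2))
  if (nw > .Machine$double.eps) { w <- w / nw; b <- b / nw }
  list(w = w, b = b)
}

#' Train per-timepoint linear choice decoders
#'
#' Trains a linear support-vector classifier (cost parameter `C = 1`) on each
#' timepoint's feature matrix to predict the initial choice (left vs right).
#' With `scheme = "loo"` a leave-one-out protocol is used: the rules later
#' applied to a trial are trained with that trial held out, and the
#' standardization statistics are likewise estimated on the training trials
#' only (no leakage). With `scheme = "full"` a single rule per timepoint is
#' trained on all trials.
#'
#' @param features A [sliding_features()] object (pre-decision phase).
#' @param labels Character/factor vector of initial choices (`"left"` /
#'   `"right"`), one per trial.
#' @param scheme `"loo"` (default, as used for decision-variable extraction)
#'   or `"full"`.
#' @param cost SVM regularization constant (default 1).
#' @return An object of class `decoder_ensemble`.
#' @export
train_decoders <- function(features, labels, scheme = c("loo", "full"),
                           cost = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(features, "dv_features"))
  y <- factor(as.character(labels), levels = c("left", "right"))
  if (any(is.na(y))) abort("labels must be 'left' or 'right'")
  if (nlevels(droplevels(y)) < 2) abort("both classes must be present")
  n <- nrow(features$x[[1]])
  if (length(y) != n) abort("label length must equal trial count")

  tps <- seq_along(features$x)
  rules <- lapply(tps, function(tp) {
    X <- features$x[[tp]]
    if (scheme == "full") {
      ctr <- colMeans(X); scl <- apply(X, 2, sd)
      r <- .svm_linear_rule(.zscore_cols(X, ctr, scl), y, cost)
      list(w = r$w, b = r$b, center = ctr, scale = scl)
    } else {
      W <- matrix(0, n, ncol(X)); bvec <- numeric(n)
      ctrs <- matrix(0, n, ncol(X)); scls <- matrix(0, n, ncol(X))
      for (i in seq_len(n)) {
        Xi <- X[-i, , drop = FALSE]
        ctr <- colMeans(Xi); scl <- apply(Xi, 2, sd)
        r <- .svm_linear_rule(.zscore_cols(Xi, ctr, scl), y[-i], cost)
        W[i, ] <- r$w; bvec[i] <- r$b; ctrs[i, ] <- ctr; scls[i, ] <- scl
      }
      list(w = W, b = bvec, center = ctrs, scale = scls)
    }
  })
  structure(list(rules = rules, times_ms = features$times_ms,
                 channels = features$channels, scheme = scheme, cost = cost,
                 n_trials = n, labels = y),
            class = "decoder_ensemble")
}

#' Decode the neural decision variable from the post-decision phase
#'
#' Reapplies each pre-decision decoder to the corresponding timepoint of the
#' post-decision phase: the decision variable at timepoint t is the signed
#' distance of the trial's post-decision features to the hyperplane trained
#' at pre-decision timepoint t (positive = evidence for a rightward
#' decision). Post-decision features are standardized with the matching
#' training statistics.
#'
#' @param ensemble A [train_decoders()] result.
#' @param post_features A [sliding_features()] object from the post-decision
#'   phase, with the same timepoint count as the ensemble.
#' @return An object of class `dv_series`: matrix `dv` (trials x timepoints),
#'   `times_ms`, and the trial label tibble.
#' @export
decode_dv <- function(ensemble, post_features) {
  stopifnot(inherits(ensemble, "decoder_ensemble"),
            inherits(post_features, "dv_features"))
  if (length(post_features$x) != length(ensemble$rules)) {
    abort("timepoint counts of ensemble and post-decision features differ")
  }
  n <- nrow(post_features$x[[1]])
  if (ensemble$scheme == "loo" && n != ensemble$n_trials) {
    abort("leave-one-out ensemble requires the same trials as training")
  }
  dv <- matrix(0, n, length(ensemble$rules))
  for (tp in seq_along(ensemble$rules)) {
    r <- ensemble$rules[[tp]]
    X <- post_features$x[[tp]]
    if (ensemble$scheme == "full") {
      scl <- r$scale; scl[scl < .Machine$double.eps] <- 1
      Xs <- sweep(sweep(X, 2, r$center, "-"), 2, scl, "/")
      dv[, tp] <- drop(Xs %*% r$w) + r$b
    } else {
      scl <- r$scale; scl[scl < .Machine$double.eps] <- 1
      Xs <- (X - r$center) / scl
      dv[, tp] <- rowSums(Xs * r$w) + r$b
    }
  }
  structure(list(dv = dv, times_ms = post_features$times_ms,
                 trials = post_features$trials),
            class = "dv_series")
}

#' @export
print.dv_series <- function(x, ...) {
  cat(sprintf("<dv_series> %d trials x %d timepoints (%g..%g ms)\n",
              nrow(x$dv), ncol(x$dv), min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Trial-wise slope and intercept of the decision-variable timecourse
#'
#' Fits an ordinary least-squares line to each trial's decision-variable
#' timeseries over the stated window (typically post-decision stimulus onset
#' to the timepoint of peak decodability). The slope is the neural analogue
#' of the drift rate and the intercept the analogue of the starting point.
#'
#' @param series A [decode_dv()] result.
#' @param window_ms Length-2 numeric, window bounds in ms (inclusive);
#'   defaults to the full series. Time is centered at the window start and
#'   expressed in seconds, so the intercept is the fitted DV at window onset.
#' @return A tibble with one row per trial: the trial labels plus `intercept`
#'   and `slope` (signed; positive = toward rightward).
#' @export
dv_trend <- function(series, window_ms = NULL) {
  stopifnot(inherits(series, "dv_series"))
  window_ms <- window_ms %b% range(series$times_ms)
  keep <- which(series$times_ms >= window_ms[1] - 1e-9 &
                  series$times_ms <= window_ms[2] + 1e-9)
  if (length(keep) < 3) abort("trend window must contain at least 3 timepoints")
  tt <- (series$times_ms[keep] - series$times_ms[keep[1]]) / 1000
  X <- cbind(1, tt)
  # closed-form OLS for all trials at once
  B <- series$dv[, keep, drop = FALSE] %*% X %*% solve(crossprod(X))
  bind_cols(series$trials,
            tibble(intercept = unname(B[, 1]), slope = unname(B[, 2])))
}

#' Convert signed DV summaries to motion-sensitivity units
#'
#' Reverses the sign of slope and intercept on trials where leftward motion
#' was presented, turning the signed (rightward-positive) summaries into a
#' general index of how strongly the neural DV tracked the presented motion.
#' Applying the flip twice restores the input.
#'
#' @param summary A [dv_trend()] tibble containing a `direction` column.
#' @param direction Optional explicit direction vector overriding the column.
#' @return The tibble with `slope` and `intercept` sign-flipped on leftward
#'   trials.
#' @export
unsign <- function(summary, direction = NULL) {
  direction <- direction %b% summary$direction
  if (is.null(direction)) abort("`direction` not found")
  if (!all(direction %in% c("left", "right"))) {
    abort("direction labels must be 'left' or 'right'")
  }
  s <- ifelse(direction == "left", -1, 1)
  summary |>
    mutate(slope = .data$slope * s, intercept = .data$intercept * s)
}

#' Timepoint of peak decodability
#'
#' Finds the timepoint at which the pre-decision classifier best generalizes
#' to the corresponding post-decision timepoint: the maximum of the temporal
#' generalization matrix's diagonal, computed on the overall (all-trials)
#' decoding accuracy and averaged across subjects when several matrices are
#' supplied. Ties break toward the earlier timepoint; an all-equal diagonal
#' returns the earliest timepoint with a warning.
#'
#' @param tg A `tg_matrix` object (see [temporal_generalization()]) or a list
#'   of them.
#' @return Timepoint in ms, with the index as attribute `index`.
#' @export
peak_decodability <- function(tg) {
  if (inherits(tg, "tg_matrix")) tg <- list(tg)
  stopifnot(all(vapply(tg, inherits, TRUE, "tg_matrix")))
  diags <- sapply(tg, function(x) diag(x$auc_overall))
  d <- rowMeans(diags, na.rm = TRUE)
  if (max(d) - min(d) < .Machine$double.eps) {
    warn("diagonal decodability is flat; returning the earliest timepoint")
  }
  k <- which.max(d)   # which.max takes the earliest maximum
  structure(tg[[1]]$times_pre[k], index = k)
}
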