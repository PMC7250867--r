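#' Hierarchical regression of trial-level outcomes
#'
#' Mixed-effects regression with subject-level random intercepts: linear for
#' continuous outcomes, logistic for binary ones (chosen automatically unless
#' forced). Fixed-effect t statistics use residual degrees of freedom
#' (observations minus fixed-effect count), matching the field's reporting
#' convention for large trial-level models; logistic fits report Wald z.
#'
#' @param data Trial-level data frame.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor columns.
#' @param subject Name of the subject identifier column.
#' @param family `"auto"` (default), `"gaussian"` or `"binomial"`.
#' @return An object of class `hier_reg`; `tidy()` gives the fixed-effect
#'   table (term, estimate, std.error, statistic, df, p.value).
#' @export
hier_regress <- function(data, outcome, predictors,
                         subject = "subject_id",
                         family = c("auto", "gaussian", "binomial")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(outcome, predictors, subject), names(data))
  if (length(miss)) abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  if (length(unique(data[[subject]])) < 2) abort("at least 2 subjects required")

  X <- as.matrix(cbind(1, data[, predictors, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("collinear design; offending columns: ",
                 paste(bad, collapse = ", ")))
  }
  yv <- data[[outcome]]
  if (family == "auto") {
    family <- if (all(yv %in% c(0, 1))) "binomial" else "gaussian"
  }
  fml <- stats::as.formula(paste0(
    "`", outcome, "` ~ ", paste(predictors, collapse = " + "),
    " + (1 | `", subject, "`)"))
  fit <- if (family == "gaussian") {
    lme4::lmer(fml, data = data, REML = TRUE)
  } else {
    suppressWarnings(lme4::glmer(fml, data = data, family = binomial()))
  }
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  stat <- cf / se
  n <- nrow(data); p <- length(cf)
  if (family == "gaussian") {
    df <- n - p
    pval <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  } else {
    df <- Inf
    pval <- 2 * pnorm(abs(stat), lower.tail = FALSE)
  }
  structure(list(
    table = tibble(term = names(cf), estimate = unname(cf),
                   std.error = unname(se), statistic = unname(stat),
                   df = df, p.value = unname(pval)),
    model = fit, family = family, outcome = outcome, n = n
  ), class = "hier_reg")
}

#' @export
tidy.hier_reg <- function(x, ...) x$table

#' @export
glance.hier_reg <- function(x, ...) {
  tibble(outcome = x$outcome, family = x$family, nobs = x$n,
         n_terms = nrow(x$table))
}

#' @export
print.hier_reg <- function(x, ...) {
  cat(sprintf("<hier_reg> %s outcome '%s', %d observations\n",
              x$family, x$outcome, x$n))
  print(x$table)
  invisible(x)
}

#' Effects of decision and confidence on neural accumulation summaries
#'
#' Hierarchical regressions of the unsigned neural slope and intercept on the
#' initial decision (+1 confirmatory / -1 disconfirmatory), confidence
#' (+1 high / -1 low) and their interaction — the neural analogue of the
#' diffusion model's regression structure.
#'
#' @param summaries Unsigned [dv_trend()] output (after [unsign()]) with
#'   `subject_id`, `slope`, `intercept`, plus either the coded columns
#'   `initial_decision`/`confidence` or the raw `initial_correct` and
#'   `initial_confidence` columns to derive them from.
#' @return A tibble of fixed effects with an `outcome` column distinguishing
#'   the slope and intercept models.
#' @export
slope_effects <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  if (!all(c("initial_decision", "confidence") %in% names(summaries))) {
    conf <- summaries$initial_confidence
    if (!all(conf %in% c(0, 1))) conf <- as.numeric(conf > median(conf))
    summaries <- summaries |>
      mutate(initial_decision = ifelse(.data$initial_correct == 1, 1, -1),
             confidence = 2 * conf - 1)
  }
  summaries <- summaries |>
    mutate(decision_x_confidence = .data$initial_decision * .data$confidence)
  cells <- with(summaries, table(initial_decision, confidence))
  if (length(cells) < 4 || any(cells == 0)) {
    abort("all four decision x confidence cells must be present")
  }
  preds <- c("initial_decision", "confidence", "decision_x_confidence")
  purrr::map(c("slope", "intercept"), function(out) {
    tidy(hier_regress(summaries, out, preds, family = "gaussian")) |>
      mutate(outcome = out, .before = 1)
  }) |> bind_rows()
}

# shared family object; glm.fit is called tens of thousands of times in the
# bootstrap, so construct it once
.binomial_family <- stats::binomial()

# per-subject path coefficients for the mediation model; returns c(a, b, c, c')
.mediation_paths <- function(Xa, Xb, Xc, M, Y) {
  # path a: mediator ~ predictor + covariates (linear)
  a <- .lm.fit(Xa, M)$coefficients[2]
  # paths b, c': outcome ~ predictor + mediator + covariates (logistic)
  fb <- suppressWarnings(glm.fit(Xb, Y, family = .binomial_family,
                                 control = list(epsilon = 1e-6, maxit = 15,
                                                trace = FALSE)))
  b <- fb$coefficients[3]
  cprime <- fb$coefficients[2]
  # path c: outcome ~ predictor + covariates (logistic)
  fc <- suppressWarnings(glm.fit(Xc, Y, family = .binomial_family,
                                 control = list(epsilon = 1e-6, maxit = 15,
                                                trace = FALSE)))
  cc <- fc$coefficients[2]
  c(a = unname(a), b = unname(b), c = unname(cc), cprime = unname(cprime))
}

#' Multilevel bootstrap mediation
#'
#' Tests whether the effect of a trial-level predictor on a binary outcome is
#' mediated by a continuous mediator, with subjects as the upper level. Path
#' a is the predictor's effect on the mediator (linear), path b the
#' mediator's effect on the outcome controlling for the predictor (logistic),
#' c and c' the total and direct predictor effects, and a x b the mediated
#' effect (product of coefficients on the latent scale). Paths are estimated
#' per subject and averaged; uncertainty comes from a two-stage bootstrap
#' that resamples subjects with replacement and then trials within each
#' sampled subject, giving percentile confidence intervals and two-tailed
#' bootstrap p values.
#'
#' @param data Trial-level data frame.
#' @param predictor,mediator,outcome Column names; the outcome must be
#'   binary 0/1.
#' @param covariates Character vector of covariate columns entered in every
#'   path model (default none).
#' @param subject Subject identifier column.
#' @param n_boot Bootstrap draws (default 5000; values below 1000 warn).
#' @param seed Integer seed.
#' @param conf_level Confidence level for the percentile intervals.
#' @return An object of class `mediation_result`; `tidy()` gives one row per
#'   path (a, b, c, cprime, ab) with estimate, CI and p value.
#' @export
mediation <- function(data, predictor, mediator, outcome,
                      covariates = character(0), subject = "subject_id",
                      n_boot = 5000, seed = 1L, conf_level = 0.95) {
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(predictor, mediator, outcome, covariates, subject),
                  names(data))
  if (length(miss)) abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  Y_all <- data[[outcome]]
  if (!all(Y_all %in% c(0, 1))) abort("`outcome` must be binary 0/1")
  subj <- as.character(data[[subject]])
  subjects <- unique(subj)
  if (length(subjects) < 2) abort("at least 2 subjects required")
  if (sd(data[[mediator]]) < .Machine$double.eps) {
    abort("mediator has (near-)zero variance")
  }
  if (n_boot < 1000) warn("n_boot < 1000: bootstrap intervals will be unstable")

  Xcov <- if (length(covariates)) as.matrix(data[, covariates, drop = FALSE])
          else NULL
  xp_all <- data[[predictor]]; m_all <- data[[mediator]]
  idx_s <- split(seq_len(nrow(data)), subj)
  # per-subject design matrices, built once; the bootstrap only row-indexes
  prep <- lapply(idx_s, function(idx) {
    cv <- if (is.null(Xcov)) NULL else Xcov[idx, , drop = FALSE]
    list(Xb = cbind(1, xp_all[idx], m_all[idx], cv),
         Y = Y_all[idx], n = length(idx))
  })

  paths_for <- function(subj_sample, resample_trials) {
    ps <- vapply(subj_sample, function(s) {
      P <- prep[[s]]
      if (resample_trials) {
        ii <- sample.int(P$n, P$n, replace = TRUE)
        Xb <- P$Xb[ii, , drop = FALSE]; Y <- P$Y[ii]
      } else {
        Xb <- P$Xb; Y <- P$Y
      }
      M <- Xb[, 3]
      Xa <- Xb[, -3, drop = FALSE]
      if (sd(M) < .Machine$double.eps || length(unique(Y)) < 2 ||
          sd(Xb[, 2]) < .Machine$double.eps) {
        return(c(a = NA_real_, b = NA_real_, c = NA_real_, cprime = NA_real_))
      }
      .mediation_paths(Xa, Xb, Xa, M, Y)
    }, numeric(4))
    est <- rowMeans(ps, na.rm = TRUE)
    c(est, ab = est[["a"]] * est[["b"]])
  }

  set.seed(seed)
  point <- paths_for(subjects, resample_trials = FALSE)
  boot <- matrix(NA_real_, n_boot, 5,
                 dimnames = list(NULL, c("a", "b", "c", "cprime", "ab")))
  for (i in seq_len(n_boot)) {
    bs <- sample(subjects, length(subjects), replace = TRUE)
    boot[i, ] <- paths_for(bs, resample_trials = TRUE)
  }
  alpha <- 1 - conf_level
  ci <- apply(boot, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              na.rm = TRUE)
  pvals <- apply(boot, 2, function(x) {
    x <- x[is.finite(x)]
    p <- 2 * min(mean(x <= 0), mean(x >= 0)) + 1 / length(x)
    min(p, 1)
  })
  structure(list(
    table = tibble(path = colnames(boot), estimate = unname(point),
                   conf.low = ci[1, ], conf.high = ci[2, ],
                   p.value = unname(pvals)),
    n_boot = n_boot, seed = seed, conf_level = conf_level,
    covariates = covariates, boot = boot
  ), class = "mediation_result")
}

#' @export
tidy.mediation_result <- function(x, ...) x$table

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %d bootstrap draws, %d%% percentile CIs\n",
              x$n_boot, round(100 * x$conf_level)))
  print(x$table)
  invisible(x)
}
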