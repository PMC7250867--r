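#' Fit a hierarchical Bayesian diffusion regression model
#'
#' Fits one of the ten diffusion regression models to a multi-subject trial
#' table by adaptive Markov chain Monte Carlo. Subject-level base parameters
#' (starting-point intercept on the logit scale, drift intercept, log boundary
#' separation, log non-decision time) are drawn from group normal
#' distributions, while covariate coefficients on starting point, drift rate
#' and boundary separation are estimated as fixed group-level effects — the
#' standard hierarchical-diffusion regression structure. The trial likelihood
#' is the Wiener first-passage density mixed with a uniform contaminant
#' (weight `outlier_probability`), and RTs below `min_rt` are discarded first.
#'
#' The sampler is Metropolis-within-Gibbs: a jointly-proposed random-walk
#' block per subject, random-walk blocks for each parameter's coefficient
#' vector, conjugate Gibbs updates for the group means and random-walk updates
#' for the group spreads, with Robbins-Monro scale adaptation during warm-up.
#' Links keep parameters in range: logistic for the starting point,
#' exponential for boundary separation and non-decision time, identity for
#' drift.
#'
#' @param trials Trial table with `subject_id`, `final_rt`, `final_correct`
#'   and either the covariate codings from [code_covariates()] or the raw
#'   columns they are derived from.
#' @param spec A [build_model()] specification.
#' @param config A [fit_config()].
#' @return An object of class `ddm_fit` with posterior draws per chain,
#'   per-parameter Gelman-Rubin statistics, a convergence flag and the
#'   retained draw count. Use [tidy()], [glance()], [dic()] and [autoplot()].
#' @export
fit_hierarchical <- function(trials, spec, config = fit_config()) {
  stopifnot(inherits(spec, "ddm_model_spec"), inherits(config, "fit_config"))
  need <- c("confidence", "initial_decision", "interaction",
            "post_evidence_strength")
  if (!all(need %in% names(trials))) trials <- code_covariates(trials)
  trials <- filter_rts(trials, config$min_rt)
  covs <- as.matrix(trials[, need])
  if (any(!is.finite(covs))) abort("covariates must be finite")
  dat <- .ddm_prepare_data(trials, spec)
  if (dat$n_subj < 2) abort("at least 2 subjects are required")

  chains <- lapply(seq_len(config$chains), function(ch) {
    .ddm_run_chain(dat, config, config$seed + ch - 1L)
  })
  draws <- lapply(chains, `[[`, "draws")
  rhat <- if (config$chains >= 2) gelman_rubin(draws) else
    setNames(rep(NA_real_, ncol(draws[[1]])), colnames(draws[[1]]))
  mon <- !grepl("^deviance$", names(rhat))
  converged <- config$chains >= 2 &&
    all(rhat[mon] < config$rhat_threshold, na.rm = TRUE)
  if (config$chains >= 2 && !converged) {
    warn(sprintf("fit_hierarchical: max Gelman-Rubin statistic %.3f exceeds %.2f",
                 max(rhat[mon], na.rm = TRUE), config$rhat_threshold))
  }
  structure(list(
    draws = draws, spec = spec, config = config, data = dat,
    subjects = dat$subj_levels, rhat = rhat, converged = converged,
    n_retained = nrow(draws[[1]]) * length(draws)
  ), class = "ddm_fit")
}

.ddm_prepare_data <- function(trials, spec) {
  subj_levels <- sort(unique(trials$subject_id))
  subj <- match(trials$subject_id, subj_levels)
  mkX <- function(terms) {
    if (!length(terms)) return(matrix(0, nrow(trials), 0))
    as.matrix(trials[, terms, drop = FALSE])
  }
  Xz <- mkX(spec$z_terms); Xv <- mkX(spec$v_terms); Xa <- mkX(spec$a_terms)
  pz <- ncol(Xz); pv <- ncol(Xv); pa <- ncol(Xa)
  beta_names <- c(if (pz) paste0("z_", spec$z_terms),
                  paste0("v_", spec$v_terms),
                  if (pa) paste0("a_", spec$a_terms))
  rt <- trials$final_rt
  dat <- list(
    rt = rt, upper = as.integer(trials$final_correct),
    subj = subj, subj0 = subj - 1L, n_subj = length(subj_levels),
    subj_levels = subj_levels,
    Xz = Xz, Xv = Xv, Xa = Xa,
    bz_idx = seq_len(pz), bv_idx = pz + seq_len(pv),
    ba_idx = pz + pv + seq_len(pa),
    n_beta = pz + pv + pa, beta_names = beta_names,
    rt_range = max(diff(range(rt)), 1e-3),
    idx_s = split(seq_along(rt), subj),
    min_rt_s = tapply(rt, subj, min)
  )
  dat
}

# subject-slice log-likelihood for one subject's parameter row
.ddm_subject_ll <- function(theta_row, beta, dat, s, p_out) {
  i <- dat$idx_s[[s]]
  bz <- beta[dat$bz_idx]; bv <- beta[dat$bv_idx]; ba <- beta[dat$ba_idx]
  z_lin <- theta_row[1] + if (length(bz)) drop(dat$Xz[i, , drop = FALSE] %*% bz) else 0
  v <- theta_row[2] + drop(dat$Xv[i, , drop = FALSE] %*% bv)
  a_lin <- theta_row[3] + if (length(ba)) drop(dat$Xa[i, , drop = FALSE] %*% ba) else 0
  n <- length(i)
  .wiener_loglik_cpp(dat$rt[i], dat$upper[i], exp(rep_len(a_lin, n)),
                     rep_len(v, n), plogis(rep_len(z_lin, n)),
                     rep(exp(theta_row[4]), n), p_out, dat$rt_range)
}

.ddm_run_chain <- function(dat, config, chain_seed) {
  set.seed(chain_seed)
  S <- dat$n_subj
  p_out <- config$outlier_probability
  # priors
  mu0 <- c(0, 0, 0.4, -1.2); s0 <- c(2, 5, 1.5, 1.5)
  beta_sd <- 2; sig_prior_sd <- 1

  # initial state
  acc_s <- tapply(dat$upper, dat$subj, mean)
  theta <- cbind(
    rnorm(S, 0, 0.1),
    qlogis(pmin(pmax(acc_s, 0.55), 0.95)) / 1.5 + rnorm(S, 0, 0.1),
    log(1.5) + rnorm(S, 0, 0.05),
    log(pmax(0.5 * dat$min_rt_s, 0.05)) + rnorm(S, 0, 0.05)
  )
  beta <- rep(0, dat$n_beta)
  mu <- colMeans(theta); sig <- rep(0.3, 4)

  ll_subj <- vapply(seq_len(S), function(s)
    .ddm_subject_ll(theta[s, ], beta, dat, s, p_out), numeric(1))

  beta_blocks <- Filter(length, list(dat$bz_idx, dat$bv_idx, dat$ba_idx))
  ls_subj <- rep(log(0.08), S)
  ls_beta <- rep(log(0.04), length(beta_blocks))
  ls_sig <- rep(log(0.3), 4)
  prop_scale <- c(1, 1, 0.5, 0.5)   # relative step sizes per base parameter

  n_keep <- (config$n_samples - config$n_burn) %/% config$thin
  cn <- c(paste0(rep(c("z0", "v0", "log_a", "log_t0"), each = S),
                 "[", rep(dat$subj_levels, 4), "]"),
          dat$beta_names,
          paste0("mu_", c("z0", "v0", "log_a", "log_t0")),
          paste0("sigma_", c("z0", "v0", "log_a", "log_t0")),
          "deviance")
  out <- matrix(NA_real_, n_keep, length(cn), dimnames = list(NULL, cn))
  keep_i <- 0L

  for (it in seq_len(config$n_samples)) {
    adapting <- it <= config$n_burn
    gam <- 1 / it^0.6

    # subject blocks
    for (s in seq_len(S)) {
      prop <- theta[s, ] + rnorm(4) * exp(ls_subj[s]) * prop_scale
      ll_new <- .ddm_subject_ll(prop, beta, dat, s, p_out)
      lr <- ll_new - ll_subj[s] +
        sum(dnorm(prop, mu, sig, log = TRUE)) -
        sum(dnorm(theta[s, ], mu, sig, log = TRUE))
      acc <- is.finite(lr) && log(runif(1)) < lr
      if (acc) { theta[s, ] <- prop; ll_subj[s] <- ll_new }
      if (adapting) ls_subj[s] <- ls_subj[s] + gam * ((acc * 1) - 0.3)
    }

    # fixed-effect blocks
    for (g in seq_along(beta_blocks)) {
      idx <- beta_blocks[[g]]
      prop <- beta
      prop[idx] <- prop[idx] + rnorm(length(idx)) * exp(ls_beta[g])
      ll_new <- .ddm_loglik_by_subject(theta, prop, dat, p_out)
      lr <- sum(ll_new) - sum(ll_subj) +
        sum(dnorm(prop[idx], 0, beta_sd, log = TRUE)) -
        sum(dnorm(beta[idx], 0, beta_sd, log = TRUE))
      acc <- is.finite(lr) && log(runif(1)) < lr
      if (acc) { beta <- prop; ll_subj <- ll_new }
      if (adapting) ls_beta[g] <- ls_beta[g] + gam * ((acc * 1) - 0.3)
    }

    # group means: conjugate normal
    for (k in 1:4) {
      prec <- S / sig[k]^2 + 1 / s0[k]^2
      m <- (sum(theta[, k]) / sig[k]^2 + mu0[k] / s0[k]^2) / prec
      mu[k] <- rnorm(1, m, sqrt(1 / prec))
    }

    # group spreads: random walk on log sigma, half-normal prior
    for (k in 1:4) {
      lsig_new <- log(sig[k]) + rnorm(1, 0, exp(ls_sig[k]))
      sn <- exp(lsig_new)
      lr <- sum(dnorm(theta[, k], mu[k], sn, log = TRUE)) -
        sum(dnorm(theta[, k], mu[k], sig[k], log = TRUE)) +
        dnorm(sn, 0, sig_prior_sd, log = TRUE) -
        dnorm(sig[k], 0, sig_prior_sd, log = TRUE) +
        lsig_new - log(sig[k])
      acc <- is.finite(lr) && log(runif(1)) < lr
      if (acc) sig[k] <- sn
      if (adapting) ls_sig[k] <- ls_sig[k] + gam * ((acc * 1) - 0.44)
    }

    if (!adapting && (it - config$n_burn) %% config$thin == 0L) {
      keep_i <- keep_i + 1L
      out[keep_i, ] <- c(theta[, 1], theta[, 2], theta[, 3], theta[, 4],
                         beta, mu, sig, -2 * sum(ll_subj))
    }
  }
  list(draws = out[seq_len(keep_i), , drop = FALSE])
}

#' Deviance Information Criterion of a fitted diffusion model
#'
#' `DIC = Dbar + pD` where `Dbar` is the posterior mean deviance and the
#' effective number of parameters `pD = Dbar - D(posterior mean)`
#' (Spiegelhalter's construction). Lower is better.
#'
#' @param fit A [fit_hierarchical()] result.
#' @return The DIC score (scalar) with attributes `pd`, `dbar`, `dhat`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  all_draws <- do.call(rbind, fit$draws)
  dbar <- mean(all_draws[, "deviance"])
  if (!is.finite(dbar)) abort("deviance is not finite; DIC undefined")
  post_mean <- colMeans(all_draws)
  S <- fit$data$n_subj
  theta_hat <- matrix(post_mean[seq_len(4 * S)], S, 4)
  beta_hat <- if (fit$data$n_beta)
    post_mean[4 * S + seq_len(fit$data$n_beta)] else numeric(0)
  dhat <- -2 * sum(.ddm_loglik_by_subject(theta_hat, beta_hat, fit$data,
                                          fit$config$outlier_probability))
  pd <- dbar - dhat
  structure(dbar + pd, pd = pd, dbar = dbar, dhat = dhat)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the classic Gelman-Rubin statistic per parameter from two or more
#' chains of equal length: with within-chain variance `W` and between-chain
#' variance `B`, `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`.
#'
#' @param chains A list of draw matrices (iterations x parameters) with
#'   identical dimensions and column names.
#' @return Named numeric vector of Rhat values.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2) {
    abort("at least 2 chains are required")
  }
  n <- nrow(chains[[1]])
  if (any(vapply(chains, nrow, 1L) != n)) abort("chains must have equal length")
  p <- ncol(chains[[1]])
  means <- matrix(vapply(chains, colMeans, numeric(p)), nrow = p)
  vars <- matrix(vapply(chains, function(x) apply(x, 2, var), numeric(p)),
                 nrow = p)
  W <- rowMeans(vars)
  B <- n * apply(means, 1, var)
  vhat <- (n - 1) / n * W + B / n
  # the scale-reduction factor is >= 1 in expectation; sampling noise can push
  # the plug-in estimate just below, so floor at 1
  r <- pmax(sqrt(vhat / W), 1)
  r[W < .Machine$double.eps] <- 1
  setNames(r, colnames(chains[[1]]))
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("<ddm_fit> model %d, %d subjects, %d retained draws (%d chains)%s\n",
              x$spec$model_id, x$data$n_subj, x$n_retained,
              length(x$draws),
              if (isTRUE(x$converged)) "" else " [convergence not established]"))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.ddm_fit <- function(x, effects = c("fixed", "group", "all"), ...) {
  effects <- match.arg(effects)
  all_draws <- do.call(rbind, x$draws)
  keep <- switch(effects,
    fixed = x$data$beta_names,
    group = grep("^(mu_|sigma_)", colnames(all_draws), value = TRUE),
    all = setdiff(colnames(all_draws), "deviance"))
  qs <- apply(all_draws[, keep, drop = FALSE], 2, quantile,
              probs = c(0.025, 0.975))
  tibble(
    term = keep,
    estimate = colMeans(all_draws[, keep, drop = FALSE]),
    std.error = apply(all_draws[, keep, drop = FALSE], 2, sd),
    conf.low = qs[1, ], conf.high = qs[2, ],
    rhat = unname(x$rhat[keep])
  )
}

#' @export
glance.ddm_fit <- function(x, ...) {
  d <- dic(x)
  tibble(model_id = x$spec$model_id, dic = as.numeric(d),
         pd = attr(d, "pd"), n_draws = x$n_retained,
         max_rhat = max(x$rhat[names(x$rhat) != "deviance"], na.rm = TRUE),
         converged = x$converged)
}

#' @export
autoplot.ddm_fit <- function(object, ...) {
  all_draws <- do.call(rbind, object$draws)
  df <- tidyr::pivot_longer(
    as_tibble(all_draws[, object$data$beta_names, drop = FALSE]),
    cols = dplyr::everything(), names_to = "term", values_to = "draw")
  ggplot(df, aes(x = .data$draw)) +
    geom_density(fill = "grey80") +
    geom_vline(xintercept = 0, linetype = "dashed") +
    facet_wrap(~term, scales = "free") +
    labs(x = "posterior draw", y = "density",
         title = sprintf("Fixed-effect posteriors (model %d)",
                         object$spec$model_id)) +
    theme_minimal()
}
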