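#' Fitting configuration for the hierarchical diffusion models
#'
#' Chain settings, RT filtering and the contaminant mixture for
#' [fit_hierarchical()]. Defaults are desk-scale (4 chains of 2,000 draws
#' after 1,000 warm-up each); larger runs are reached by raising `n_samples`
#' and `n_burn`. The retained draw count is always reported as
#' `(n_samples - n_burn) / thin` per chain rather than assumed.
#'
#' @param n_samples Total MCMC iterations per chain (including warm-up).
#' @param n_burn Warm-up iterations discarded (and used for adaptation).
#' @param thin Thinning factor (keep every `thin`-th draw).
#' @param chains Number of chains.
#' @param seed Integer seed; chain `k` uses `seed + k - 1`.
#' @param outlier_probability Mixture weight of the uniform contaminant in the
#'   trial likelihood (default 0.05).
#' @param min_rt RT filter threshold in seconds (default 0.2).
#' @param rhat_threshold Convergence flag threshold for the Gelman-Rubin
#'   statistic.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_samples = 3000, n_burn = 1000, thin = 1, chains = 4,
                       seed = 1L, outlier_probability = 0.05, min_rt = 0.2,
                       rhat_threshold = 1.1) {
  if (!(n_burn < n_samples)) abort("`n_burn` must be smaller than `n_samples`")
  if (thin < 1) abort("`thin` must be >= 1")
  if (!(outlier_probability >= 0 && outlier_probability < 1)) {
    abort("`outlier_probability` must lie in [0, 1)")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 chains = as.integer(chains), seed = as.integer(seed),
                 outlier_probability = outlier_probability,
                 min_rt = min_rt, rhat_threshold = rhat_threshold),
            class = "fit_config")
}

# per-trial diffusion parameters from subject params + fixed effects
.ddm_param_vectors <- function(theta, beta, dat) {
  bz <- beta[dat$bz_idx]; bv <- beta[dat$bv_idx]; ba <- beta[dat$ba_idx]
  z_lin <- theta[dat$subj, 1] +
    if (length(bz)) drop(dat$Xz %*% bz) else 0
  v <- theta[dat$subj, 2] + drop(dat$Xv %*% bv)
  a_lin <- theta[dat$subj, 3] +
    if (length(ba)) drop(dat$Xa %*% ba) else 0
  list(a = exp(a_lin), v = v, w = plogis(z_lin),
       t0 = exp(theta[dat$subj, 4]))
}

.ddm_loglik_by_subject <- function(theta, beta, dat, p_out) {
  p <- .ddm_param_vectors(theta, beta, dat)
  .wiener_loglik_by_subject_cpp(dat$rt, dat$upper, p$a, p$v, p$w, p$t0,
                                dat$subj0, dat$n_subj, p_out, dat$rt_range)
}

#' Trial log-likelihood under the outlier mixture
#'
#' Log-likelihood of one or more (choice, RT) observations under the
#' diffusion model with a uniform contaminant: the density is
#' `(1 - p_out) * wfpt(rt) + p_out * unif(rt_range) / 2`, the uniform spanning
#' the observed RT range and both response options. With `p_out = 0` this
#' reduces to the pure first-passage density; with `p_out = 1` it is constant
#' in the diffusion parameters.
#'
#' @param rt Vector of RTs (seconds).
#' @param upper Vector of 0/1 indicators (1 = correct/upper bound).
#' @param params A [wiener_params()] object (shared across the trials).
#' @param outlier_probability Mixture weight of the contaminant.
#' @param rt_range Width of the contaminant's uniform support (defaults to the
#'   observed range of `rt`, with a floor to stay proper for single trials).
#' @return Total log-likelihood (scalar).
#' @export
trial_loglik <- function(rt, upper, params, outlier_probability = 0.05,
                         rt_range = NULL) {
  stopifnot(inherits(params, "wiener_params"))
  if (any(!is.finite(rt)) || any(!is.finite(upper))) {
    abort("`rt` and `upper` must be finite")
  }
  rt_range <- rt_range %b% max(diff(range(rt)), 1)
  n <- length(rt)
  .wiener_loglik_cpp(rt, as.integer(upper),
                     rep(params$a / params$s, n), rep(params$v / params$s, n),
                     rep(params$z, n), rep(params$t0, n),
                     outlier_probability, rt_range)
}
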