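#' Wiener diffusion parameters
#'
#' Parameter container for a two-boundary Wiener diffusion process under
#' accuracy coding: the upper bound is the correct response. The diffusion
#' scale is fixed at `s = 1` (the modern convention; all drift/boundary values
#' are relative to it).
#'
#' @param v Drift rate (evidence units per second; positive drives the process
#'   toward the correct bound).
#' @param a Boundary separation (> 0).
#' @param z Relative starting point in (0, 1); 0.5 is unbiased.
#' @param t0 Non-decision time in seconds (>= 0).
#' @param s Diffusion scale (fixed convention, default 1).
#' @return A list of class `wiener_params`.
#' @examples
#' wiener_params(v = 1, a = 2, z = 0.5, t0 = 0.3)
#' @export
wiener_params <- function(v, a, z = 0.5, t0 = 0.3, s = 1) {
  if (!is.finite(v)) abort("`v` must be finite")
  if (!(a > 0)) abort("`a` must be positive")
  if (!(z > 0 && z < 1)) abort("`z` must lie strictly in (0, 1)")
  if (!(t0 >= 0)) abort("`t0` must be non-negative")
  if (!(s > 0)) abort("`s` must be positive")
  structure(list(v = v, a = a, z = z, t0 = t0, s = s),
            class = "wiener_params")
}

#' Defective first-passage-time density
#'
#' Density of absorption at the named bound at time `t`, for a Wiener process
#' with parameters `params`. The density is defective: integrated over all `t`
#' it equals the probability of absorbing at that bound. Evaluation uses the
#' standard small-time / large-time series split with truncation chosen by the
#' error-bound rule (tolerance 1e-7). Times at or below `t0` return density 0.
#'
#' @param t Vector of times (seconds).
#' @param params A [wiener_params()] object.
#' @param bound `"upper"` (correct) or `"lower"` (error).
#' @return Numeric vector of non-negative densities.
#' @export
wiener_fpt_density <- function(t, params, bound = c("upper", "lower")) {
  bound <- match.arg(bound)
  stopifnot(inherits(params, "wiener_params"))
  # rescale to s = 1
  .dwiener_cpp(t, params$a / params$s, params$v / params$s, params$z,
               params$t0, bound == "upper")
}

#' Probability of absorbing at the correct (upper) bound
#'
#' Closed-form absorption probability for the two-boundary Wiener process:
#' with start `x0 = z * a`, `P(upper) = (1 - exp(-2 v x0 / s^2)) /
#' (1 - exp(-2 v a / s^2))`, reducing to `z` when `v = 0`.
#'
#' @inheritParams wiener_fpt_density
#' @return Scalar probability.
#' @examples
#' choice_probability(wiener_params(v = 1, a = 2, z = 0.5))  # 0.8808
#' @export
choice_probability <- function(params) {
  stopifnot(inherits(params, "wiener_params"))
  v <- params$v / params$s
  a <- params$a / params$s
  z <- params$z
  if (abs(v) < 1e-12) return(z)
  num <- -expm1(-2 * v * z * a)
  den <- -expm1(-2 * v * a)
  num / den
}

#' Simulate first passages of the Wiener process
#'
#' Euler-Maruyama simulation of the two-boundary diffusion; each walk runs
#' until absorption (or until `max_t` of accumulation, in which case the
#' nearer bound is assigned). RTs are `t0` plus the accumulation time.
#'
#' @inheritParams wiener_fpt_density
#' @param n Number of walks.
#' @param dt Integration step in seconds; must be small relative to typical
#'   first-passage times.
#' @param seed Integer seed.
#' @param max_t Accumulation-time cap in seconds.
#' @return A tibble with columns `upper` (1 = absorbed at the correct bound)
#'   and `rt` (seconds).
#' @export
simulate_wiener <- function(params, n, dt = 0.001, seed = 1L, max_t = 30) {
  stopifnot(inherits(params, "wiener_params"))
  if (n < 1) abort("`n` must be positive")
  set.seed(seed)
  res <- .sim_wiener_cpp(as.integer(n), params$a, params$v, params$z,
                         params$t0, dt, params$s, max_t)
  tibble(upper = res$upper, rt = res$rt)
}
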