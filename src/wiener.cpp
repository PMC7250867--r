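#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density of a Wiener process between absorbing bounds
// {0, a}, start a*w, drift v, diffusion s = 1, at the LOWER bound.
// Series-split evaluation: the standardized density f(t/a^2; w) is computed
// with the small-time or large-time expansion, whichever needs fewer terms
// for truncation error < eps.

static double fpt_lower_std(double tau, double w, double eps) {
  // terms needed by the small-time expansion (error bound rule)
  double ks;
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * std::sqrt(2.0 * M_PI * tau) * eps));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }
  // terms needed by the large-time expansion
  double kl;
  if (M_PI * tau * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * eps) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }

  double p = 0.0;
  if (ks < kl) {  // small-time expansion
    int K = (int)std::ceil(ks);
    for (int k = -(K - 1) / 2; k <= K / 2; k++) {
      double x = w + 2.0 * k;
      p += x * std::exp(-x * x / (2.0 * tau));
    }
    p /= std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {        // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; k++) {
      p += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) * std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p > 0.0 ? p : 0.0;
}

static double dwiener_one(double t, double a, double v, double w, double t0,
                          bool upper, double eps) {
  double tt = t - t0;
  if (!(tt > 0.0) || a <= 0.0 || w <= 0.0 || w >= 1.0) return 0.0;
  double vv = v, ww = w;
  if (upper) { vv = -v; ww = 1.0 - w; }   // reflection: upper bound via lower-bound form
  double tau = tt / (a * a);
  double f = fpt_lower_std(tau, ww, eps) / (a * a);
  f *= std::exp(-vv * a * ww - vv * vv * tt / 2.0);
  return f > 0.0 ? f : 0.0;
}

// [[Rcpp::export(name = ".dwiener_cpp")]]
NumericVector dwiener_cpp(NumericVector t, double a, double v, double w,
                          double t0, bool upper, double eps = 1e-7) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = dwiener_one(t[i], a, v, w, t0, upper, eps);
  return out;
}

// Mixture log-likelihood over trials with per-trial parameters:
// (1 - p_out) * wfpt(rt | a, v, w, t0, bound) + p_out * unif(rt_range) / 2
// The contaminant is uniform over the observed RT range and over the two
// response options (hence the 1/2).
// [[Rcpp::export(name = ".wiener_loglik_cpp")]]
double wiener_loglik_cpp(NumericVector rt, IntegerVector upper,
                         NumericVector a, NumericVector v, NumericVector w,
                         NumericVector t0, double p_out, double rt_range,
                         double eps = 1e-7) {
  int n = rt.size();
  double ll = 0.0;
  double u = (p_out > 0.0 && rt_range > 0.0) ? p_out / (2.0 * rt_range) : 0.0;
  for (int i = 0; i < n; i++) {
    double f = dwiener_one(rt[i], a[i], v[i], w[i], t0[i], upper[i] == 1, eps);
    double lik = (1.0 - p_out) * f + u;
    if (!(lik > 0.0)) return -INFINITY;
    ll += std::log(lik);
  }
  return ll;
}

// Same mixture likelihood, accumulated per subject (0-based subject index).
// [[Rcpp::export(name = ".wiener_loglik_by_subject_cpp")]]
NumericVector wiener_loglik_by_subject_cpp(NumericVector rt, IntegerVector upper,
                                           NumericVector a, NumericVector v,
                                           NumericVector w, NumericVector t0,
                                           IntegerVector subj, int n_subj,
                                           double p_out, double rt_range,
                                           double eps = 1e-7) {
  int n = rt.size();
  NumericVector ll(n_subj);
  double u = (p_out > 0.0 && rt_range > 0.0) ? p_out / (2.0 * rt_range) : 0.0;
  for (int i = 0; i < n; i++) {
    double f = dwiener_one(rt[i], a[i], v[i], w[i], t0[i], upper[i] == 1, eps);
    double lik = (1.0 - p_out) * f + u;
    ll[subj[i]] += (lik > 0.0) ? std::log(lik) : -INFINITY;
  }
  return ll;
}

// One Euler-Maruyama walk with a Brownian-bridge correction for bound
// crossings inside a step (removes the leading-order discretization bias).
// Returns +1 / 0 for upper / lower absorption via `up`, steps via `step`.
static void walk_one(double a, double v, double w, double dt, double s,
                     int max_steps, int &up, int &step) {
  double x = w * a;
  double sdt = s * std::sqrt(dt);
  double s2dt = s * s * dt;
  step = 0;
  while (step < max_steps) {
    double xn = x + v * dt + sdt * norm_rand();
    step++;
    if (xn >= a) { up = 1; return; }
    if (xn <= 0.0) { up = 0; return; }
    // within-step crossing probabilities (Brownian bridge)
    double p_up = std::exp(-2.0 * (a - x) * (a - xn) / s2dt);
    if (unif_rand() < p_up) { up = 1; return; }
    double p_lo = std::exp(-2.0 * x * xn / s2dt);
    if (unif_rand() < p_lo) { up = 0; return; }
    x = xn;
  }
  up = (x >= a * 0.5) ? 1 : 0;  // censored at max_t: nearest bound
}

// Simulation of the two-bound Wiener process; uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export(name = ".sim_wiener_cpp")]]
List sim_wiener_cpp(int n, double a, double v, double w, double t0,
                    double dt, double s = 1.0, double max_t = 30.0) {
  NumericVector rt(n);
  IntegerVector up(n);
  int max_steps = (int)(max_t / dt);
  for (int i = 0; i < n; i++) {
    int u = 0, step = 0;
    walk_one(a, v, w, dt, s, max_steps, u, step);
    up[i] = u;
    rt[i] = t0 + step * dt;
  }
  return List::create(_["upper"] = up, _["rt"] = rt);
}

// Per-trial variant: vectors of parameters (one walk per trial).
// [[Rcpp::export(name = ".sim_wiener_trials_cpp")]]
List sim_wiener_trials_cpp(NumericVector a, NumericVector v, NumericVector w,
                           NumericVector t0, double dt, double s = 1.0,
                           double max_t = 30.0) {
  int n = a.size();
  NumericVector rt(n);
  IntegerVector up(n);
  int max_steps = (int)(max_t / dt);
  for (int i = 0; i < n; i++) {
    int u = 0, step = 0;
    walk_one(a[i], v[i], w[i], dt, s, max_steps, u, step);
    up[i] = u;
    rt[i] = t0[i] + step * dt;
  }
  return List::create(_["upper"] = up, _["rt"] = rt);
}

// Connected-component labeling of a logical matrix under 4-connectivity.
// Returns an integer matrix of labels (0 = background), labels start at 1.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next_label = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      if (mask(i, j) && lab(i, j) == 0) {
        next_label++;
        stack.push_back(i + j * nr);
        lab(i, j) = next_label;
        while (!stack.empty()) {
          int idx = stack.back(); stack.pop_back();
          int ci = idx % nr, cj = idx / nr;
          const int di[4] = {-1, 1, 0, 0};
          const int dj[4] = {0, 0, -1, 1};
          for (int k = 0; k < 4; k++) {
            int ni = ci + di[k], nj = cj + dj[k];
            if (ni >= 0 && ni < nr && nj >= 0 && nj < nc &&
                mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next_label;
              stack.push_back(ni + nj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
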