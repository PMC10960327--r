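#include <Rcpp.h>
using namespace Rcpp;

// Wiener first-passage-time machinery for the simple two-boundary DDM
// (no inter-trial variability). All internal computation assumes unit
// diffusion; callers rescale (v, a) by s before entry.

static const double ERR_TOL = 1e-9; // series truncation tolerance

// Density of absorption at the LOWER boundary at normalised time
// tt = t / a^2 for a zero-drift, unit-diffusion, unit-separation process
// started at relative position z. Adaptive choice between the small-time
// and large-time series expansions, each truncated at the number of terms
// guaranteeing error < ERR_TOL.
static double fpt_lower_std(double tt, double z) {
  if (tt <= 0.0) return 0.0;

  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * ERR_TOL < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt *
                         std::log(2.0 * ERR_TOL * std::sqrt(2.0 * M_PI * tt)));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tt * ERR_TOL < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * ERR_TOL) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }

  double p;
  if (ks < kl) { // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = (int)(-std::floor((K - 1) / 2.0));
    int hi = (int)(std::ceil((K - 1) / 2.0));
    double sum = 0.0;
    for (int k = lo; k <= hi; ++k) {
      double w = z + 2.0 * k;
      sum += w * std::exp(-w * w / (2.0 * tt));
    }
    p = sum / std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else { // large-time expansion
    int K = (int)std::ceil(kl);
    double sum = 0.0;
    for (int k = 1; k <= K; ++k) {
      sum += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
             std::sin(k * M_PI * z);
    }
    p = M_PI * sum;
  }
  return p > 0.0 ? p : 0.0;
}

// Defective density of absorption at the lower boundary at decision time
// td (> 0), drift v, separation a, relative start z, unit diffusion.
static double fpt_lower(double td, double v, double a, double z) {
  if (td <= 0.0) return 0.0;
  double d = fpt_lower_std(td / (a * a), z);
  if (d <= 0.0) return 0.0;
  return d * std::exp(-v * a * z - v * v * td / 2.0) / (a * a);
}

// upper-boundary density via the reflection (v, z) -> (-v, 1 - z)
static inline double fpt_boundary(double td, int upper, double v, double a,
                                  double z) {
  return upper ? fpt_lower(td, -v, a, 1.0 - z) : fpt_lower(td, v, a, z);
}

// [[Rcpp::export]]
NumericVector wfpt_density_cpp(NumericVector t, int upper, double v, double a,
                               double z, double t0, double s) {
  int n = t.size();
  NumericVector out(n);
  double vs = v / s, as = a / s;
  for (int i = 0; i < n; ++i) {
    double td = t[i] - t0;
    out[i] = (td > 0.0) ? fpt_boundary(td, upper, vs, as, z) : 0.0;
  }
  return out;
}

// lower-boundary density with the series branch forced (1 = small-time,
// 2 = large-time), truncated at enough terms for ERR_TOL either way;
// exposed so branch agreement at the adaptive switch can be tested
// [[Rcpp::export]]
double wfpt_density_forced_cpp(double t, double v, double a, double z,
                               double t0, double s, int branch) {
  double td = t - t0;
  if (td <= 0.0) return 0.0;
  double vs = v / s, as = a / s;
  double tt = td / (as * as);
  double p;
  if (branch == 1) {
    int K = 12; // generous fixed truncation
    double sum = 0.0;
    for (int k = -K; k <= K; ++k) {
      double w = z + 2.0 * k;
      sum += w * std::exp(-w * w / (2.0 * tt));
    }
    p = sum / std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {
    int K = 200;
    double sum = 0.0;
    for (int k = 1; k <= K; ++k)
      sum += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
             std::sin(k * M_PI * z);
    p = M_PI * sum;
  }
  if (p < 0.0) p = 0.0;
  return p * std::exp(-vs * as * z - vs * vs * td / 2.0) / (as * as);
}

// which small/large series branch would be picked at normalised time tt
// (exposed only so the branch switch point can be tested)
// [[Rcpp::export]]
IntegerVector wfpt_branch_cpp(NumericVector tt) {
  int n = tt.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double t = tt[i];
    double ks, kl;
    if (2.0 * std::sqrt(2.0 * M_PI * t) * ERR_TOL < 1.0) {
      ks = 2.0 + std::sqrt(-2.0 * t *
                           std::log(2.0 * ERR_TOL * std::sqrt(2.0 * M_PI * t)));
      ks = std::max(ks, std::sqrt(t) + 1.0);
    } else ks = 2.0;
    if (M_PI * t * ERR_TOL < 1.0) {
      kl = std::sqrt(-2.0 * std::log(M_PI * t * ERR_TOL) / (M_PI * M_PI * t));
      kl = std::max(kl, 1.0 / (M_PI * std::sqrt(t)));
    } else kl = 1.0 / (M_PI * std::sqrt(t));
    out[i] = ks < kl ? 1 : 2; // 1 = small-time, 2 = large-time
  }
  return out;
}

// Summed log-likelihood of one participant's trials for each row of a
// parameter matrix. Columns of `par`: v_c, v_m, a, z_c, z_m, t0_c, t0_m.
// `correct[i]` = 1 maps to the upper (correct-response) boundary,
// `cued[i]` = 1 selects the cued-condition parameters. Per-trial log
// densities are clamped below at `floor_log`.
// [[Rcpp::export]]
NumericVector ddm_loglik_cpp(NumericVector rt, IntegerVector correct,
                             IntegerVector cued, NumericMatrix par, double s,
                             double floor_log) {
  int ntr = rt.size(), np = par.nrow();
  NumericVector out(np);
  for (int r = 0; r < np; ++r) {
    double vc = par(r, 0) / s, vm = par(r, 1) / s, a = par(r, 2) / s;
    double zc = par(r, 3), zm = par(r, 4), t0c = par(r, 5), t0m = par(r, 6);
    double ll = 0.0;
    for (int i = 0; i < ntr; ++i) {
      double v, z, t0;
      if (cued[i]) { v = vc; z = zc; t0 = t0c; }
      else         { v = vm; z = zm; t0 = t0m; }
      double td = rt[i] - t0;
      double dens = (td > 0.0) ? fpt_boundary(td, correct[i], v, a, z) : 0.0;
      double ld = (dens > 0.0) ? std::log(dens) : floor_log;
      ll += (ld > floor_log) ? ld : floor_log;
    }
    out[r] = ll;
  }
  return out;
}

// Euler-Maruyama simulator with a Brownian-bridge crossing correction:
// after each step the probability that the within-step bridge touched a
// boundary (exp(-2 d_old d_new / (s^2 dt))) is applied, removing the
// O(sqrt(dt)) absorption bias of naive discrete boundary checking. Uses
// R's RNG so results are reproducible under set.seed(). Walks that have
// not been absorbed by `t_max` seconds of decision time are assigned the
// nearer boundary at t_max (never reached with sane parameters;
// documented guard).
// [[Rcpp::export]]
List simulate_ddm_cpp(int n, double v, double a, double z, double t0, double s,
                      double dt, double t_max = 100.0) {
  NumericVector rt(n);
  IntegerVector upper(n);
  double sq = s * std::sqrt(dt);
  double inv2 = 2.0 / (s * s * dt);
  int max_steps = (int)(t_max / dt);
  for (int i = 0; i < n; ++i) {
    double x = z * a;
    int step = 0;
    bool done = false;
    while (step < max_steps && !done) {
      double x_old = x;
      x += v * dt + sq * norm_rand();
      ++step;
      if (x >= a) { upper[i] = 1; done = true; }
      else if (x <= 0.0) { upper[i] = 0; done = true; }
      else {
        // bridge crossing probabilities for the step [x_old, x]
        double p_up = std::exp(-inv2 * (a - x_old) * (a - x));
        double p_lo = std::exp(-inv2 * x_old * x);
        double u = unif_rand();
        if (u < p_up) { upper[i] = 1; done = true; }
        else if (u > 1.0 - p_lo) { upper[i] = 0; done = true; }
      }
    }
    if (!done) upper[i] = (x >= a / 2.0) ? 1 : 0;
    rt[i] = t0 + step * dt;
  }
  return List::create(_["rt"] = rt, _["upper"] = upper);
}
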