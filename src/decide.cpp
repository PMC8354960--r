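#include <Rcpp.h>
using namespace Rcpp;

// Two-population rectified-rate attractor with self-excitation, mutual
// inhibition and additive background noise.  Euler-Maruyama integration:
//
//   dx_i = [-leak*x_i + w_self*g(x_i) - w_inh*g(x_j) + I_i] dt
//          + noise_sd*sqrt(dt)*eta_i,      g(x) = max(x, 0)
//
// The first population whose g(x) reaches `threshold` wins.  Inputs I_i
// already contain value drive and polarization offset.  Uses R's RNG so
// all randomness flows from set.seed() on the R side.

static inline double g(double x) { return x > 0.0 ? x : 0.0; }

// one decision; returns (choice, steps, x_sn, x_lf, timeout)
static void decide_one(double I_sn, double I_lf,
                       double &x_sn, double &x_lf,
                       double leak, double w_self, double w_inh,
                       double noise_sd, double threshold,
                       double dt, int max_steps,
                       int &choice, int &steps, int &timeout) {
  const double sq = noise_sd * std::sqrt(dt);
  timeout = 0;
  for (steps = 1; steps <= max_steps; ++steps) {
    const double gs = g(x_sn), gl = g(x_lf);
    const double dxs = (-leak * x_sn + w_self * gs - w_inh * gl + I_sn) * dt
      + sq * R::norm_rand();
    const double dxl = (-leak * x_lf + w_self * gl - w_inh * gs + I_lf) * dt
      + sq * R::norm_rand();
    x_sn += dxs;
    x_lf += dxl;
    const bool cs = g(x_sn) >= threshold, cl = g(x_lf) >= threshold;
    if (cs || cl) {
      if (cs && cl) {                      // same-step tie
        if (x_sn > x_lf)      choice = 0;
        else if (x_lf > x_sn) choice = 1;
        else                  choice = (R::unif_rand() < 0.5) ? 0 : 1;
      } else {
        choice = cl ? 1 : 0;
      }
      return;
    }
  }
  // timeout: resolve by currently larger activity, coin flip on exact tie
  steps = max_steps;
  timeout = 1;
  if (x_sn > x_lf)      choice = 0;
  else if (x_lf > x_sn) choice = 1;
  else                  choice = (R::unif_rand() < 0.5) ? 0 : 1;
}

// [[Rcpp::export]]
NumericVector decide_cpp(double I_sn, double I_lf,
                         double x_sn, double x_lf,
                         double leak, double w_self, double w_inh,
                         double noise_sd, double threshold,
                         double dt, int max_steps) {
  int choice, steps, timeout;
  decide_one(I_sn, I_lf, x_sn, x_lf, leak, w_self, w_inh,
             noise_sd, threshold, dt, max_steps, choice, steps, timeout);
  return NumericVector::create(
    _["choice"] = choice, _["steps"] = steps,
    _["x_sn"] = x_sn, _["x_lf"] = x_lf, _["timeout"] = timeout);
}

// A whole block of trials with residual-activity decay between trials.
// iti_ms[i] is the interval before trial i (ignored for i == 0; the state
// is reset to rest at block start).  tau_ms is the (polarization-scaled)
// decay time constant for this block.
// [[Rcpp::export]]
List simulate_block_cpp(NumericVector I_sn, NumericVector I_lf,
                        NumericVector iti_ms, double tau_ms,
                        double leak, double w_self, double w_inh,
                        double noise_sd, double threshold,
                        double dt, int max_steps) {
  const int n = I_sn.size();
  IntegerVector choice(n), timeout(n);
  NumericVector steps(n), x_sn_pre(n), x_lf_pre(n);
  double xs = 0.0, xl = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && R_finite(iti_ms[i])) {
      const double f = std::exp(-iti_ms[i] / tau_ms);
      xs *= f;
      xl *= f;
    }
    x_sn_pre[i] = xs;
    x_lf_pre[i] = xl;
    int ch, st, to;
    decide_one(I_sn[i], I_lf[i], xs, xl, leak, w_self, w_inh,
               noise_sd, threshold, dt, max_steps, ch, st, to);
    choice[i] = ch;
    steps[i] = st;
    timeout[i] = to;
  }
  return List::create(
    _["choice"] = choice, _["steps"] = steps, _["timeout"] = timeout,
    _["x_sn_pre"] = x_sn_pre, _["x_lf_pre"] = x_lf_pre);
}
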