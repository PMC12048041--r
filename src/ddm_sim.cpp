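#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama first-passage simulation of a Wiener process with drift
// between symmetric absorbing barriers at +/- `barrier`, starting from 0.
// One trial per element of `drift`; `sigma`, `dt` shared.
//
// Discrete-time monitoring misses barrier crossings that occur inside a
// step, which biases first-passage times upward by O(sqrt(dt)). Each step
// therefore also performs a Brownian-bridge crossing check: conditional on
// the endpoints (x0, x1) of a step, the probability that the continuous
// path touched a barrier within the step is exp(-2*d0*d1/(sigma^2*dt)),
// with d0, d1 the endpoint distances to that barrier. Trials are absorbed
// at the step in which the (corrected) crossing occurs.
//
// Uses R's RNG so results are reproducible under set.seed(). Returns the
// signed barrier hit (+1 upper, -1 lower) and the decision time in seconds.
// [[Rcpp::export]]
List simulate_fp_cpp(NumericVector drift, double sigma, double barrier,
                     double dt, int max_steps) {
  int n = drift.size();
  NumericVector t_d(n);
  IntegerVector hit(n);
  double sdt = sigma * std::sqrt(dt);
  double inv_var = 1.0 / (sigma * sigma * dt);
  for (int i = 0; i < n; ++i) {
    double rdt = drift[i] * dt;
    double x = 0.0;
    int steps = 0;
    int b = 0;
    while (b == 0) {
      double x0 = x;
      x += rdt + sdt * norm_rand();
      ++steps;
      if (x >= barrier) {
        b = 1;
      } else if (x <= -barrier) {
        b = -1;
      } else {
        // bridge correction: crossing inside the step without ending outside
        double p_up = std::exp(-2.0 * (barrier - x0) * (barrier - x) *
                               inv_var);
        double p_dn = std::exp(-2.0 * (barrier + x0) * (barrier + x) *
                               inv_var);
        double u = unif_rand();
        if (u < p_up) {
          b = 1;
        } else if (u < p_up + p_dn) {
          b = -1;
        } else if (steps >= max_steps) {
          stop("first-passage simulation exceeded %d steps without absorption",
               max_steps);
        }
      }
      if (b != 0) {
        t_d[i] = steps * dt;
        hit[i] = b;
      }
    }
  }
  return List::create(_["barrier"] = hit, _["decision_time"] = t_d);
}
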