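#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// gain codes: 0 = zero, 1 = identity, 2 = tanh_plus
static inline double gain_eval(int code, double u) {
  switch (code) {
  case 0: return 0.0;
  case 1: return u;
  case 2: return u > 0 ? std::tanh(u) : 0.0;
  default: stop("unsupported gain code in compiled kernel");
  }
  return 0.0;
}

// Direct-method stochastic simulation of the coarse LMN.
// Uses R's RNG (set.seed on the R side makes runs reproducible).
// [[Rcpp::export(name = ".ssa_direct_cpp")]]
List ssa_direct_cpp(IntegerVector sizes,
                    NumericVector leak_on, NumericVector leak_off,
                    IntegerVector gain_on, IntegerVector gain_off,
                    NumericMatrix W, NumericVector h,
                    IntegerVector init, double t_end,
                    double max_events) {
  const int M = sizes.size();
  std::vector<int> n(init.begin(), init.end());
  std::vector<double> beta(M), delta(M), u(M);

  R_xlen_t cap = 1024;
  std::vector<double> ev_t; ev_t.reserve(cap);
  std::vector<int> ev_k; ev_k.reserve(cap);
  std::vector<int> ev_d; ev_d.reserve(cap);

  RNGScope scope;
  double t = 0.0;
  bool absorbing = false;

  while (true) {
    // propensities at the current state
    double total = 0.0;
    for (int k = 0; k < M; ++k) {
      double uk = h[k];
      for (int l = 0; l < M; ++l) uk += W(k, l) * (double)n[l] / (double)sizes[l];
      u[k] = uk;
      double phi = gain_eval(gain_on[k], uk);
      double psi = gain_eval(gain_off[k], uk);
      beta[k]  = (double)(sizes[k] - n[k]) * (leak_on[k] + phi);
      delta[k] = (double)n[k] * (leak_off[k] + psi);
      if (beta[k] < 0 || delta[k] < 0)
        stop("negative propensity during simulation");
      total += beta[k] + delta[k];
    }
    if (total <= 0.0) { absorbing = true; break; }

    double dt = R::exp_rand() / total;
    t += dt;
    if (t > t_end) break;

    double r = unif_rand() * total;
    int k = 0, dir = +1;
    for (k = 0; k < M; ++k) {
      if (r < beta[k]) { dir = +1; break; }
      r -= beta[k];
      if (r < delta[k]) { dir = -1; break; }
      r -= delta[k];
    }
    if (k == M) { k = M - 1; dir = delta[M - 1] > 0 ? -1 : +1; } // fp guard

    n[k] += dir;
    ev_t.push_back(t);
    ev_k.push_back(k + 1);
    ev_d.push_back(dir);
    if ((double)ev_t.size() > max_events)
      stop("event count exceeded 'max_events' (%g); shorten t_end or raise the cap",
           max_events);
  }

  return List::create(
    _["time"] = NumericVector(ev_t.begin(), ev_t.end()),
    _["block"] = IntegerVector(ev_k.begin(), ev_k.end()),
    _["direction"] = IntegerVector(ev_d.begin(), ev_d.end()),
    _["absorbing"] = absorbing,
    _["final"] = IntegerVector(n.begin(), n.end()));
}
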