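#include <Rcpp.h>
using namespace Rcpp;

// Daily-step recursion of the complete cancer-development model:
//   F(x,t) = x + [nu*r*x - nu*mu*x^((nu+1)/nu) - s(t)] + m(t)
//   x(t+1) = max(F(x,t), 0)
// with per-day immune response s, mutation counts m and moving threshold
// abar all precomputed in R. Detects the first confirmed transition:
// an upward crossing of abar that reaches conf_mult * max(abar, 1) cells
// before dipping back below the threshold. Returns the trajectory
// (truncated at the stopping day) and the transition bookkeeping.
//
// [[Rcpp::export(name = ".lifetime_loop")]]
List lifetime_loop(double x0, double nu, double r, double mu,
                   NumericVector s, NumericVector m, NumericVector abar,
                   double conf_mult, bool record, double overflow_guard) {
  int H = s.size();
  if (m.size() != H || abar.size() != H)
    stop("s, m and abar must have equal length");
  NumericVector x(record ? H + 1 : 1);
  double xc = x0;
  if (record) x[0] = x0;
  double expo = (nu + 1.0) / nu;
  int cross_day = -1;      // day of current above-threshold excursion
  double conf = R_PosInf;  // confirmation size for that excursion
  int transition_day = -1;
  int stop_day = H;
  bool above_prev = x0 > abar[0];
  for (int t = 0; t < H; ++t) {
    // R_pow matches R's `^` semantics bit-for-bit, and the bracketed
    // evaluation order follows F(x,t) = x + [drift - s] + m, so the
    // p = 0 reduction is exactly the plain-R Euler recursion
    double drift = nu * r * xc - nu * mu * ::R_pow(xc, expo) - s[t];
    double xn = xc + drift + m[t];
    if (xn < 0.0) xn = 0.0;
    if (xn > overflow_guard)
      stop("overflow guard: x exceeded %g cells at day %d", overflow_guard, t);
    xc = xn;
    if (record) x[t + 1] = xc;
    double thr = abar[t];
    bool above = xc > thr;
    if (above && !above_prev) {           // upward crossing
      cross_day = t + 1;
      conf = conf_mult * std::max(thr, 1.0);
    } else if (!above && above_prev) {    // back below: excursion over
      cross_day = -1;
      conf = R_PosInf;
    }
    if (above && cross_day >= 0 && xc >= conf) {
      transition_day = cross_day;
      stop_day = t + 1;
      break;
    }
    above_prev = above;
  }
  NumericVector xout;
  if (record) {
    xout = NumericVector(x.begin(), x.begin() + std::min(stop_day + 1, H + 1));
  }
  return List::create(_["x"] = xout,
                      _["transition_day"] = transition_day,
                      _["stop_day"] = stop_day,
                      _["final_x"] = xc);
}
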