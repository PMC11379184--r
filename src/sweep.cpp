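#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Poisson-Gamma segment score: terms that depend on the segment
// composition only through (Y, sumE). The sum_t [y log E - log y!] part is
// identical for merged vs split configurations of the same years, so it
// cancels from the Gibbs ratio and is omitted here.
static inline double seg_score(double Y, double sumE, double a, double b) {
  return a * std::log(b) - R::lgammafn(a) + R::lgammafn(a + Y) -
         (a + Y) * std::log(b + sumE);
}

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// One collapsed single-site Gibbs sweep over the changepoint indicators of
// all states for one drug. z is S x (T-1), with z(s, t) = 1 meaning year
// t+2 (1-based) opens a new regime. Regime rates are integrated out under
// their Gamma(a, b) prior; the autologistic prior contributes the Bernoulli
// mass of z_t itself and of its successor (whose conditional probability
// depends on z_t through the centered autoregressive term).
// [[Rcpp::export]]
IntegerMatrix cpp_sweep_indicators(IntegerMatrix z, NumericMatrix y,
                                   NumericMatrix E, double a, double b,
                                   NumericVector lin, double eta) {
  const int S = y.nrow(), T = y.ncol(), Tm1 = T - 1;
  std::vector<double> cy(T + 1), cE(T + 1);
  for (int s = 0; s < S; ++s) {
    cy[0] = 0.0; cE[0] = 0.0;
    for (int t = 0; t < T; ++t) {
      cy[t + 1] = cy[t] + y(s, t);
      cE[t + 1] = cE[t] + E(s, t);
    }
    const double mu = logistic(lin[s]);
    for (int t = 0; t < Tm1; ++t) {
      // boundary year (1-based year index t+2; 0-based year index t+1)
      int yb = t + 1;
      // segment start: first year after the nearest earlier boundary
      int L = 0;
      for (int u = t - 1; u >= 0; --u) {
        if (z(s, u) == 1) { L = u + 1; break; }
      }
      // segment end (inclusive, 0-based): year before the next boundary
      int Rend = T - 1;
      for (int u = t + 1; u < Tm1; ++u) {
        if (z(s, u) == 1) { Rend = u; break; }
      }
      double Yl = cy[yb] - cy[L],      El = cE[yb] - cE[L];
      double Yr = cy[Rend + 1] - cy[yb], Er = cE[Rend + 1] - cE[yb];
      double lw1 = seg_score(Yl, El, a, b) + seg_score(Yr, Er, a, b);
      double lw0 = seg_score(Yl + Yr, El + Er, a, b);
      // prior mass of z_t given its predecessor
      double p_t = (t == 0) ? mu
                 : logistic(lin[s] + eta * (z(s, t - 1) - mu));
      lw1 += std::log(p_t);
      lw0 += std::log1p(-p_t);
      // prior mass of the successor, whose probability depends on z_t
      if (t + 1 < Tm1) {
        double znext = z(s, t + 1);
        double p1 = logistic(lin[s] + eta * (1.0 - mu));
        double p0 = logistic(lin[s] + eta * (0.0 - mu));
        lw1 += znext ? std::log(p1) : std::log1p(-p1);
        lw0 += znext ? std::log(p0) : std::log1p(-p0);
      }
      double pr1 = 1.0 / (1.0 + std::exp(lw0 - lw1));
      z(s, t) = (R::unif_rand() < pr1) ? 1 : 0;
    }
  }
  return z;
}

// Gamma draws of regime rates for all states of one drug, given indicators.
// Returns an S x T matrix with the drawn rate replicated across each
// regime's years. theta[k] ~ Gamma(a + Y_seg, b + E_seg).
// [[Rcpp::export]]
NumericMatrix cpp_draw_rates(IntegerMatrix z, NumericMatrix y,
                             NumericMatrix E, double a, double b) {
  const int S = y.nrow(), T = y.ncol(), Tm1 = T - 1;
  NumericMatrix rate(S, T);
  for (int s = 0; s < S; ++s) {
    int start = 0;
    while (start < T) {
      int end = T - 1;
      for (int u = start; u < Tm1; ++u) {
        if (z(s, u) == 1) { end = u; break; }
      }
      double Y = 0.0, sumE = 0.0;
      for (int t = start; t <= end; ++t) { Y += y(s, t); sumE += E(s, t); }
      double th = R::rgamma(a + Y, 1.0 / (b + sumE));
      for (int t = start; t <= end; ++t) rate(s, t) = th;
      start = end + 1;
    }
  }
  return rate;
}

// Autologistic log prior of one drug's indicator matrix (S x T-1) given the
// per-state linear predictor and the autoregressive coefficient. Used by
// the Metropolis updates of beta0, eta and phi, where it is the only part
// of the target that moves.
// [[Rcpp::export]]
double cpp_autologistic_logpdf(IntegerMatrix z, NumericVector lin,
                               double eta) {
  const int S = z.nrow(), Tm1 = z.ncol();
  double lp = 0.0;
  for (int s = 0; s < S; ++s) {
    const double mu = logistic(lin[s]);
    for (int t = 0; t < Tm1; ++t) {
      double p = (t == 0) ? mu
               : logistic(lin[s] + eta * (z(s, t - 1) - mu));
      lp += z(s, t) ? std::log(p) : std::log1p(-p);
    }
  }
  return lp;
}
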