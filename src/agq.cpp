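#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(x)), overflow-safe
static inline double log1pexp_c(double x) {
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

static inline double plogis_c(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// Adaptive Gauss-Hermite evaluation of the dyad marginal log-likelihood.
// eta2, y2: n x 2 (mother, child). nodes/logwz2: GH abscissae and
// log(weights) + nodes^2. Returns total loglik, per-dyad posterior modes,
// and (optionally) posterior-weighted residuals per member.
// [[Rcpp::export]]
List agq_core_cpp(NumericMatrix eta2, NumericMatrix y2, double sigma,
                  NumericVector nodes, NumericVector logwz2,
                  bool want_resid) {
  const int n = eta2.nrow(), K = nodes.size();
  NumericVector bhat(n);
  NumericMatrix resid2(want_resid ? n : 0, 2);
  double ll = 0.0;

  if (sigma < 1e-8) {
    for (int i = 0; i < n; ++i) {
      for (int m = 0; m < 2; ++m) {
        double e = eta2(i, m), y = y2(i, m);
        ll += y * e - log1pexp_c(e);
        if (want_resid) resid2(i, m) = y - plogis_c(e);
      }
    }
    return List::create(_["ll"] = ll, _["bhat"] = bhat,
                        _["resid2"] = resid2);
  }

  const double isig2 = 1.0 / (sigma * sigma);
  const double lconst = 0.5 * std::log(2.0) - std::log(sigma) -
    0.5 * std::log(2.0 * M_PI);
  std::vector<double> lw(K), p1(K), p2(K);

  for (int i = 0; i < n; ++i) {
    const double e1 = eta2(i, 0), e2 = eta2(i, 1);
    const double y1 = y2(i, 0), yy2 = y2(i, 1);
    // Newton for the integrand mode
    double b = 0.0, h = isig2;
    for (int it = 0; it < 25; ++it) {
      double m1 = plogis_c(e1 + b), m2 = plogis_c(e2 + b);
      double g = (y1 - m1) + (yy2 - m2) - b * isig2;
      h = m1 * (1.0 - m1) + m2 * (1.0 - m2) + isig2;
      double step = g / h;
      b += step;
      if (std::fabs(step) < 1e-10) break;
    }
    {
      double m1 = plogis_c(e1 + b), m2 = plogis_c(e2 + b);
      h = m1 * (1.0 - m1) + m2 * (1.0 - m2) + isig2;
    }
    const double shat = 1.0 / std::sqrt(h);
    double mmax = -INFINITY;
    for (int k = 0; k < K; ++k) {
      const double bk = b + shat * M_SQRT2 * nodes[k];
      const double a1 = e1 + bk, a2 = e2 + bk;
      double v = y1 * a1 - log1pexp_c(a1) + yy2 * a2 - log1pexp_c(a2) -
        0.5 * bk * bk * isig2 + logwz2[k];
      lw[k] = v;
      if (want_resid) { p1[k] = plogis_c(a1); p2[k] = plogis_c(a2); }
      if (v > mmax) mmax = v;
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(lw[k] - mmax);
    ll += mmax + std::log(s) + std::log(shat) + lconst;
    bhat[i] = b;
    if (want_resid) {
      double r1 = 0.0, r2 = 0.0;
      for (int k = 0; k < K; ++k) {
        const double w = std::exp(lw[k] - mmax) / s;
        r1 += w * p1[k];
        r2 += w * p2[k];
      }
      resid2(i, 0) = y1 - r1;
      resid2(i, 1) = yy2 - r2;
    }
  }
  return List::create(_["ll"] = ll, _["bhat"] = bhat, _["resid2"] = resid2);
}
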