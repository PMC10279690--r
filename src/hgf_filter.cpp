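#include <Rcpp.h>
using namespace Rcpp;

// Forward filter of a binary input sequence through the three-level HGF.
//
// u holds 0/1 contingency-congruence inputs; NA marks trials without an
// objective outcome (ambiguous probes), on which the belief state is frozen.
// Hatted (prediction) quantities are computed before the trial's input is
// seen, posteriors after. If a posterior precision becomes non-positive the
// filter stops updating and reports the offending trial, so that callers can
// reject the parameter proposal cleanly instead of propagating NaN.
// [[Rcpp::export]]
List hgf_filter_cpp(NumericVector u, double omega2, double omega3,
                    double kappa, double mu2_0, double sigma2_0,
                    double mu3_0, double sigma3_0) {
  const int n = u.size();
  NumericVector muhat1(n), muhat2(n), muhat3(n), pihat2(n), pihat3(n),
      delta1(n), eps2(n), eps3(n), mu2(n), mu3(n), sigma2(n), sigma3(n);
  double m2 = mu2_0, s2 = sigma2_0, m3 = mu3_0, s3 = sigma3_0;
  const double pclamp = 1e-8;  // probability clamp and precision floor
  bool stable = true;
  int bad_trial = NA_INTEGER;

  for (int t = 0; t < n; ++t) {
    // predictions from the previous posterior (no drift)
    const double mh2 = m2, mh3 = m3;
    double mh1 = 1.0 / (1.0 + std::exp(-mh2));
    if (mh1 < pclamp) mh1 = pclamp;
    if (mh1 > 1.0 - pclamp) mh1 = 1.0 - pclamp;
    const double v2 = std::exp(kappa * m3 + omega2);  // level-2 step variance
    const double v3 = std::exp(omega3);               // level-3 step variance
    const double ph2 = 1.0 / (s2 + v2);
    const double ph3 = 1.0 / (s3 + v3);

    muhat1[t] = mh1; muhat2[t] = mh2; muhat3[t] = mh3;
    pihat2[t] = ph2; pihat3[t] = ph3;

    if (stable && (!std::isfinite(ph2) || !std::isfinite(ph3) ||
                   ph2 <= 0.0 || ph3 <= 0.0)) {
      stable = false;
      bad_trial = t + 1;
    }

    if (NumericVector::is_na(u[t]) || !stable) {
      // no objective input (or filter halted): freeze the belief state
      delta1[t] = NA_REAL; eps2[t] = 0.0; eps3[t] = 0.0;
      mu2[t] = m2; mu3[t] = m3; sigma2[t] = s2; sigma3[t] = s3;
      continue;
    }

    // level-1 prediction error and level-2 update
    const double d1 = u[t] - mh1;
    const double w1 = mh1 * (1.0 - mh1);  // 1 / pihat1
    const double p2 = ph2 + w1;
    const double m2new = mh2 + d1 / p2;
    const double s2new = 1.0 / p2;

    // level-3 (volatility) update
    const double w2 = v2 * ph2;  // volatility weight, in (0,1)
    const double d2 = (s2new + (m2new - mh2) * (m2new - mh2)) * ph2 - 1.0;
    double p3 = ph3 + 0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * d2);
    if (!std::isfinite(p3) || p3 <= 0.0) {
      stable = false;
      bad_trial = t + 1;
      delta1[t] = NA_REAL; eps2[t] = 0.0; eps3[t] = 0.0;
      mu2[t] = m2; mu3[t] = m3; sigma2[t] = s2; sigma3[t] = s3;
      continue;
    }
    if (p3 < pclamp) p3 = pclamp;
    const double m3new = mh3 + 0.5 * kappa * w2 * d2 / p3;

    delta1[t] = d1;
    eps2[t] = m2new - mh2;
    eps3[t] = m3new - mh3;
    m2 = m2new; s2 = s2new;
    m3 = m3new; s3 = 1.0 / p3;
    mu2[t] = m2; mu3[t] = m3; sigma2[t] = s2; sigma3[t] = s3;
  }

  return List::create(
      _["muhat1"] = muhat1, _["muhat2"] = muhat2, _["muhat3"] = muhat3,
      _["pihat2"] = pihat2, _["pihat3"] = pihat3, _["delta1"] = delta1,
      _["eps2"] = eps2, _["eps3"] = eps3, _["mu2"] = mu2, _["mu3"] = mu3,
      _["sigma2"] = sigma2, _["sigma3"] = sigma3,
      _["stable"] = stable, _["bad_trial"] = bad_trial);
}
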