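#include <Rcpp.h>
using namespace Rcpp;

// Grouped sequential filters. `grp` holds a 1-based stream index per trial
// (all ones for the state source, item indices for the item source). Each
// stream is filtered independently in trial order, so the within-stream time
// index is the repetition count of that item. Outputs stay aligned with the
// chronological trial order of the input.

// [[Rcpp::export]]
NumericMatrix rw_filter_cpp(IntegerVector y, IntegerVector grp, int ngrp,
                            double alpha, double v0) {
  int n = y.size();
  NumericMatrix out(n, 2);
  colnames(out) = CharacterVector::create("muhat", "v");
  std::vector<double> v(ngrp, v0);
  for (int t = 0; t < n; ++t) {
    int g = grp[t] - 1;
    out(t, 0) = v[g];                 // prediction before outcome t
    v[g] += alpha * ((double)y[t] - v[g]);
    out(t, 1) = v[g];                 // posterior after outcome t
  }
  return out;
}

// Kalman gain recursion K = (K + pi*omega) / (K + pi*omega + 1); the belief
// is moved by the gain-weighted prediction error of the previous trial, so
// the stored value is always the prediction for the current trial.

// [[Rcpp::export]]
NumericMatrix kf_filter_cpp(IntegerVector y, IntegerVector grp, int ngrp,
                            double pi, double omega, double k0, double mu0) {
  int n = y.size();
  double a = pi * omega;
  NumericMatrix out(n, 2);
  colnames(out) = CharacterVector::create("muhat", "gain");
  std::vector<double> mu(ngrp, mu0), K(ngrp, k0), yprev(ngrp, 0.0);
  std::vector<int> seen(ngrp, 0);
  for (int t = 0; t < n; ++t) {
    int g = grp[t] - 1;
    if (seen[g]) {
      K[g] = (K[g] + a) / (K[g] + a + 1.0);
      mu[g] += K[g] * (yprev[g] - mu[g]);
    }
    out(t, 0) = mu[g];
    out(t, 1) = K[g];
    yprev[g] = (double)y[t];
    seen[g] = 1;
  }
  return out;
}

// Two-level binary hierarchical Gaussian filter. Level 1 is Bernoulli with
// muhat1 = sigmoid(mu2); level 2 is a Gaussian random walk with step
// variance exp(omega). The level-2 update weight psi is the inverse of the
// level-2 posterior precision, so more uncertain beliefs move further per
// unit prediction error. mu2 is clamped to +/-36 inside the sigmoid to keep
// first-level precisions finite.

// [[Rcpp::export]]
NumericMatrix hgf2_filter_cpp(IntegerVector y, IntegerVector grp, int ngrp,
                              double omega, double mu2_0, double sigma2_0) {
  int n = y.size();
  double eo = std::exp(omega);
  NumericMatrix out(n, 6);
  colnames(out) = CharacterVector::create("muhat1", "mu2", "sigma2",
                                          "pihat1", "psi", "delta");
  std::vector<double> mu2(ngrp, mu2_0), s2(ngrp, sigma2_0);
  for (int t = 0; t < n; ++t) {
    int g = grp[t] - 1;
    double m2 = mu2[g];
    if (m2 > 36.0) m2 = 36.0;
    if (m2 < -36.0) m2 = -36.0;
    double mh = 1.0 / (1.0 + std::exp(-m2));
    double w = mh * (1.0 - mh);          // 1 / pihat1
    double d = (double)y[t] - mh;        // first-level prediction error
    double pihat2 = 1.0 / (s2[g] + eo);
    double pi2 = pihat2 + w;             // level-2 posterior precision
    double psi = 1.0 / pi2;
    mu2[g] += psi * d;
    s2[g] = psi;
    if (!(s2[g] > 0.0))
      stop("second-level variance left the positive domain");
    out(t, 0) = mh;
    out(t, 1) = mu2[g];
    out(t, 2) = s2[g];
    out(t, 3) = 1.0 / w;
    out(t, 4) = psi;
    out(t, 5) = d;
  }
  return out;
}
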