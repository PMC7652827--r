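#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Partial log-likelihood, score and observed information for a Cox model
// with an optional shared per-plot random intercept in the linear predictor
// and optional left truncation (counting-process data). Rows must be sorted
// by stop time in DECREASING order so the risk set can be accumulated
// incrementally; rem_ord gives row indices sorted by start time decreasing
// (empty when there is no truncation). The risk set at an event time t is
// {i : start_i < t <= stop_i}. Tied events use Efron or Breslow weights.
//
// The frailty block of the design is an indicator per cluster; its sums are
// kept sparse (per-cluster scalars) and only the information matrix is
// assembled dense, dimension (p + q) with the fixed effects first.
// [[Rcpp::export]]
List cox_engine_eval(NumericVector time, IntegerVector status,
                     NumericMatrix X, IntegerVector clust, int nclust,
                     NumericVector beta, NumericVector b,
                     NumericVector offset, bool efron, bool want_info,
                     NumericVector start, IntegerVector rem_ord) {
  const int n = time.size();
  const int p = X.ncol();
  const int q = nclust;
  const int P = p + q;
  const bool frail = q > 0;
  const bool trunc = rem_ord.size() > 0;

  std::vector<double> eta(n);
  for (int i = 0; i < n; ++i) {
    double e = offset[i];
    for (int a = 0; a < p; ++a) e += X(i, a) * beta[a];
    if (frail) e += b[clust[i]];
    eta[i] = e;
  }

  // persistent risk-set sums
  double s0 = 0.0;
  std::vector<double> s1x(p, 0.0), s1b(q, 0.0);
  std::vector<double> Sxx(p * p, 0.0);
  std::vector<double> Sxb(p * q, 0.0);
  std::vector<double> Sbb(q, 0.0);

  // per-tied-time event sums
  std::vector<double> d1x(p), d1b(q), Dxx(p * p), Dxb(p * q), Dbb(q);
  std::vector<double> xbx(p), xbb(q);

  double loglik = 0.0;
  NumericVector grad(P);
  NumericMatrix info(want_info ? P : 1, want_info ? P : 1);
  int nevent = 0;

  // add (sign +1) or remove (sign -1) one row from the risk-set sums
  auto update = [&](int k, double sign) {
    double w = sign * std::exp(eta[k]);
    s0 += w;
    int c = frail ? clust[k] : 0;
    for (int a = 0; a < p; ++a) {
      double wx = w * X(k, a);
      s1x[a] += wx;
      for (int a2 = a; a2 < p; ++a2) Sxx[a * p + a2] += wx * X(k, a2);
      if (frail) Sxb[a * q + c] += wx;
    }
    if (frail) { s1b[c] += w; Sbb[c] += w; }
  };

  int i = 0, ir = 0;
  while (i < n) {
    int j = i;
    while (j < n && time[j] == time[i]) ++j;
    double t = time[i];

    // enter subjects [i, j) into the risk set, then drop those whose entry
    // time is at or after t (they are not at risk at t)
    for (int k = i; k < j; ++k) update(k, 1.0);
    if (trunc) {
      while (ir < n && start[rem_ord[ir]] >= t) { update(rem_ord[ir], -1.0); ++ir; }
    }

    // events at this time
    int d = 0;
    double d0 = 0.0;
    std::fill(d1x.begin(), d1x.end(), 0.0);
    if (frail) { std::fill(d1b.begin(), d1b.end(), 0.0);
                 std::fill(Dbb.begin(), Dbb.end(), 0.0);
                 std::fill(Dxb.begin(), Dxb.end(), 0.0); }
    std::fill(Dxx.begin(), Dxx.end(), 0.0);
    for (int k = i; k < j; ++k) {
      if (status[k] != 1) continue;
      ++d;
      double w = std::exp(eta[k]);
      d0 += w;
      loglik += eta[k];
      int c = frail ? clust[k] : 0;
      for (int a = 0; a < p; ++a) {
        grad[a] += X(k, a);
        double wx = w * X(k, a);
        d1x[a] += wx;
        for (int a2 = a; a2 < p; ++a2) Dxx[a * p + a2] += wx * X(k, a2);
        if (frail) Dxb[a * q + c] += wx;
      }
      if (frail) { grad[p + c] += 1.0; d1b[c] += w; Dbb[c] += w; }
    }
    nevent += d;

    for (int k = 0; k < d; ++k) {
      double f = efron ? (double)k / d : 0.0;
      double den = s0 - f * d0;
      loglik -= std::log(den);
      for (int a = 0; a < p; ++a) xbx[a] = (s1x[a] - f * d1x[a]) / den;
      if (frail) for (int c = 0; c < q; ++c) xbb[c] = (s1b[c] - f * d1b[c]) / den;
      for (int a = 0; a < p; ++a) grad[a] -= xbx[a];
      if (frail) for (int c = 0; c < q; ++c) grad[p + c] -= xbb[c];
      if (want_info) {
        for (int a = 0; a < p; ++a)
          for (int a2 = a; a2 < p; ++a2) {
            double v = (Sxx[a * p + a2] - f * Dxx[a * p + a2]) / den -
                       xbx[a] * xbx[a2];
            info(a, a2) += v;
            if (a2 != a) info(a2, a) += v;
          }
        if (frail) {
          for (int a = 0; a < p; ++a)
            for (int c = 0; c < q; ++c) {
              double v = (Sxb[a * q + c] - f * Dxb[a * q + c]) / den -
                         xbx[a] * xbb[c];
              info(a, p + c) += v;
              info(p + c, a) += v;
            }
          for (int c = 0; c < q; ++c) {
            info(p + c, p + c) += (Sbb[c] - f * Dbb[c]) / den;
            for (int c2 = 0; c2 < q; ++c2)
              info(p + c, p + c2) -= xbb[c] * xbb[c2];
          }
        }
      }
    }
    i = j;
  }

  return List::create(_["loglik"] = loglik, _["grad"] = grad,
                      _["info"] = info, _["nevent"] = nevent);
}
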