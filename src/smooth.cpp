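#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Tricube-weighted local polynomial smoother applied independently within
// clusters of adjacent CpGs. For each probe the neighbourhood is the k
// nearest probes of its cluster by genomic distance (k = ceil(span * n),
// floored at 4 so a local quadratic stays identifiable after the zero
// tricube weight at the window edge). Clusters with fewer than 4 probes
// fall back to a centred 3-point running mean, which reduces to the
// identity for a single probe. Degenerate weighted designs fall back to
// local linear, then to the weighted mean.

static double fit_local_poly(const double *x, const double *y, int l, int r,
                             double x0) {
  // distances and tricube weights relative to the farthest point in window
  int m = r - l + 1;
  double dmax = 0.0;
  for (int j = l; j <= r; ++j) {
    double d = std::fabs(x[j] - x0);
    if (d > dmax) dmax = d;
  }
  if (dmax <= 0.0) { // all positions identical (cannot happen for sorted
    double s = 0.0;  // strictly increasing positions, kept for safety)
    for (int j = l; j <= r; ++j) s += y[j];
    return s / m;
  }
  // weighted power sums for quadratic normal equations in z = (x - x0)/dmax
  double S0 = 0, S1 = 0, S2 = 0, S3 = 0, S4 = 0;
  double T0 = 0, T1 = 0, T2 = 0;
  for (int j = l; j <= r; ++j) {
    double z = (x[j] - x0) / dmax;
    double az = std::fabs(z);
    double w1 = 1.0 - az * az * az;
    double w = w1 * w1 * w1;
    if (w <= 0.0) continue;
    double z2 = z * z;
    S0 += w; S1 += w * z; S2 += w * z2; S3 += w * z2 * z; S4 += w * z2 * z2;
    T0 += w * y[j]; T1 += w * z * y[j]; T2 += w * z2 * y[j];
  }
  if (S0 <= 0.0) {
    double s = 0.0;
    for (int j = l; j <= r; ++j) s += y[j];
    return s / m;
  }
  // solve the 3x3 system [S0 S1 S2; S1 S2 S3; S2 S3 S4] b = [T0 T1 T2]
  double a11 = S0, a12 = S1, a13 = S2;
  double a22 = S2, a23 = S3, a33 = S4;
  double det = a11 * (a22 * a33 - a23 * a23) - a12 * (a12 * a33 - a23 * a13) +
               a13 * (a12 * a23 - a22 * a13);
  double scale = a11 * a22 * a33;
  if (scale < 1.0) scale = 1.0;
  if (std::fabs(det) > 1e-12 * scale) {
    // Cramer for b0 only (value at z = 0)
    double det0 = T0 * (a22 * a33 - a23 * a23) - a12 * (T1 * a33 - a23 * T2) +
                  a13 * (T1 * a23 - a22 * T2);
    return det0 / det;
  }
  // local linear fallback
  double detl = S0 * S2 - S1 * S1;
  if (std::fabs(detl) > 1e-12 * std::max(1.0, S0 * S2))
    return (T0 * S2 - S1 * T1) / detl;
  return T0 / S0; // weighted mean
}

// [[Rcpp::export]]
NumericVector smooth_clusters_cpp(NumericVector x, NumericVector y,
                                  IntegerVector starts, IntegerVector ends,
                                  double span) {
  int n = x.size();
  NumericVector out(n);
  const double *px = REAL(x);
  const double *py = REAL(y);
  for (int c = 0; c < starts.size(); ++c) {
    int s = starts[c], e = ends[c];
    int nc = e - s + 1;
    if (nc < 4) {
      // centred 3-point running mean, truncated at cluster edges
      for (int i = s; i <= e; ++i) {
        int l = std::max(s, i - 1), r = std::min(e, i + 1);
        double acc = 0.0;
        for (int j = l; j <= r; ++j) acc += py[j];
        out[i] = acc / (r - l + 1);
      }
      continue;
    }
    int k = (int)std::ceil(span * nc);
    if (k < 4) k = 4;
    if (k > nc) k = nc;
    for (int i = s; i <= e; ++i) {
      // contiguous window of k probes containing i with minimal max distance
      int lmin = std::max(s, i - k + 1);
      int lmax = std::min(i, e - k + 1);
      int bestl = lmin;
      double bestd = R_PosInf;
      for (int l = lmin; l <= lmax; ++l) {
        double d1 = px[i] - px[l];
        double d2 = px[l + k - 1] - px[i];
        double d = d1 > d2 ? d1 : d2;
        if (d < bestd) { bestd = d; bestl = l; }
      }
      out[i] = fit_local_poly(px, py, bestl, bestl + k - 1, px[i]);
    }
  }
  return out;
}
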