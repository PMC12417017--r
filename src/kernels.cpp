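#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Rolling summary statistics over index windows of an activity-count series.
// starts/ends are 1-based inclusive epoch indices (already clipped to the
// grid).  Returns a 10-column matrix: mean, median, sd, min, max, iqr,
// skewness, kurtosis (excess), rms, zero fraction.  Degenerate windows
// (length < 2 for sd, zero variance for skew/kurt) emit 0, keeping feature
// matrices model-ready.
// [[Rcpp::export]]
NumericMatrix roll_stats_cpp(NumericVector x, IntegerVector starts,
                             IntegerVector ends) {
  int n = starts.size();
  NumericMatrix out(n, 10);
  std::vector<double> w;
  for (int i = 0; i < n; ++i) {
    int a = starts[i] - 1, b = ends[i] - 1;
    int len = b - a + 1;
    w.assign(x.begin() + a, x.begin() + b + 1);
    double s = 0.0, s2 = 0.0, nz = 0.0;
    double mn = w[0], mx = w[0];
    for (int j = 0; j < len; ++j) {
      s += w[j]; s2 += w[j] * w[j];
      if (w[j] < mn) mn = w[j];
      if (w[j] > mx) mx = w[j];
      if (w[j] == 0.0) nz += 1.0;
    }
    double mean = s / len;
    double var = len > 1 ? (s2 - len * mean * mean) / (len - 1) : 0.0;
    if (var < 0) var = 0;
    double sd = std::sqrt(var);
    std::sort(w.begin(), w.end());
    double med = (len % 2 == 1) ? w[len / 2]
                                : 0.5 * (w[len / 2 - 1] + w[len / 2]);
    // quantile type 7 for the quartiles
    auto q7 = [&](double p) {
      double h = (len - 1) * p;
      int lo = (int)std::floor(h);
      int hi = lo + 1 < len ? lo + 1 : lo;
      return w[lo] + (h - lo) * (w[hi] - w[lo]);
    };
    double iqr = q7(0.75) - q7(0.25);
    double skew = 0.0, kurt = 0.0;
    if (sd > 0 && len > 2) {
      double m3 = 0.0, m4 = 0.0;
      for (int j = 0; j < len; ++j) {
        double d = (w[j] - mean);
        m3 += d * d * d; m4 += d * d * d * d;
      }
      double mv = (s2 - len * mean * mean) / len;  // population variance
      if (mv > 0) {
        skew = (m3 / len) / std::pow(mv, 1.5);
        kurt = (m4 / len) / (mv * mv) - 3.0;
      }
    }
    double rms = std::sqrt(s2 / len);
    out(i, 0) = mean;  out(i, 1) = med;  out(i, 2) = sd;
    out(i, 3) = mn;    out(i, 4) = mx;   out(i, 5) = iqr;
    out(i, 6) = skew;  out(i, 7) = kurt; out(i, 8) = rms;
    out(i, 9) = nz / len;
  }
  return out;
}

static double phi_apen(const std::vector<double>& x, int m, double r) {
  int n = x.size();
  int nm = n - m + 1;
  if (nm <= 0) return NA_REAL;
  double acc = 0.0;
  for (int i = 0; i < nm; ++i) {
    int cnt = 0;
    for (int j = 0; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
      }
      if (d <= r) ++cnt;
    }
    acc += std::log((double)cnt / nm);
  }
  return acc / nm;
}

// Approximate entropy, ApEn(m, r) with self-matches included (standard
// Pincus definition).  Returns 0 for degenerate input (r <= 0 or too short).
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2 || r <= 0) return 0.0;
  std::vector<double> v(x.begin(), x.end());
  double p1 = phi_apen(v, m, r), p2 = phi_apen(v, m + 1, r);
  if (!std::isfinite(p1) || !std::isfinite(p2)) return 0.0;
  return p1 - p2;
}

// Sample entropy, SampEn(m, r), self-matches excluded.  Degenerate or
// matchless input returns 0.
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2 || r <= 0) return 0.0;
  long A = 0, B = 0;
  for (int i = 0; i < n - m; ++i) {
    for (int j = i + 1; j < n - m; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
      }
      if (d <= r) {
        ++B;
        double dd = std::fabs(x[i + m] - x[j + m]);
        if (std::max(d, dd) <= r) ++A;
      }
    }
  }
  if (A == 0 || B == 0) return 0.0;
  return -std::log((double)A / (double)B);
}
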