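#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Trailing time-window descriptive statistics.
//
// For each observation i the window holds every sample j with
// t[i] - window < t[j] <= t[i] (j <= i, series time-sorted), so the current
// sample is always in-window and no future sample ever is. Windows are
// duration-based, not row-count based: gaps left by cleaning shrink the
// sample count, never stretch the horizon.
//
// Returns mean, sample std (0 for a single-sample window), median, min, max
// and the in-window sample count per row.
// [[Rcpp::export(name = ".roll_stats_cpp")]]
List roll_stats_cpp(NumericVector t, NumericVector x, double window) {
  const int n = t.size();
  if (x.size() != n) stop("t and x must have equal length");
  NumericVector mean_(n), sd_(n), med_(n), min_(n), max_(n);
  IntegerVector cnt(n);
  std::vector<double> buf;
  int lo = 0;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && t[i] <= t[i - 1]) stop("timestamps must be strictly increasing");
    while (t[lo] <= t[i] - window) ++lo;
    const int m = i - lo + 1;
    double s = 0.0, mn = x[lo], mx = x[lo];
    buf.assign(x.begin() + lo, x.begin() + i + 1);
    for (int j = 0; j < m; ++j) {
      s += buf[j];
      if (buf[j] < mn) mn = buf[j];
      if (buf[j] > mx) mx = buf[j];
    }
    const double mu = s / m;
    double ss = 0.0;
    for (int j = 0; j < m; ++j) ss += (buf[j] - mu) * (buf[j] - mu);
    mean_[i] = mu;
    sd_[i] = (m > 1) ? std::sqrt(ss / (m - 1)) : 0.0;
    min_[i] = mn;
    max_[i] = mx;
    std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
    if (m % 2 == 1) {
      med_[i] = buf[m / 2];
    } else {
      double hi = buf[m / 2];
      double lo2 = *std::max_element(buf.begin(), buf.begin() + m / 2);
      med_[i] = (lo2 + hi) / 2.0;
    }
    cnt[i] = m;
  }
  return List::create(_["mean"] = mean_, _["std"] = sd_, _["median"] = med_,
                      _["min"] = min_, _["max"] = max_, _["n_in_window"] = cnt);
}
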