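// Adaptive-partitioning mutual information on rank-transformed data.
//
// Points live on the unit square after mapping each value to rank/n
// (average ranks for ties). A cell is split into four quadrants at its
// midpoint while a chi-square test (3 df, alpha 0.05) rejects uniformity
// of the quadrant counts; leaves contribute p * log(p / area). The sum is
// a discrete KL divergence against the product measure, hence >= 0.

#include <Rcpp.h>
#include <cmath>
#include <numeric>
#include <vector>

using namespace Rcpp;

namespace {

const double kChi2Crit = 7.814728;  // qchisq(0.95, df = 3)
const int kMinSplit = 8;            // do not split cells smaller than this

struct Workspace {
  const double* x;
  const double* y;
  int n;
  double mi;
};

void recurse(Workspace& w, const std::vector<int>& idx, double xlo,
             double xhi, double ylo, double yhi, bool root) {
  const int k = static_cast<int>(idx.size());
  if (k == 0) return;

  const double xm = 0.5 * (xlo + xhi);
  const double ym = 0.5 * (ylo + yhi);

  std::vector<int> q0, q1, q2, q3;
  q0.reserve(k); q1.reserve(k); q2.reserve(k); q3.reserve(k);
  for (int i : idx) {
    const bool right = w.x[i] > xm;
    const bool top = w.y[i] > ym;
    if (right) {
      if (top) q3.push_back(i); else q1.push_back(i);
    } else {
      if (top) q2.push_back(i); else q0.push_back(i);
    }
  }

  const double e = k / 4.0;
  double chi2 = 0.0;
  const double c0 = q0.size() - e, c1 = q1.size() - e;
  const double c2 = q2.size() - e, c3 = q3.size() - e;
  chi2 = (c0 * c0 + c1 * c1 + c2 * c2 + c3 * c3) / e;

  // fully coincident points (tied in both coordinates, e.g. a sample
  // drawn many times in a bootstrap replicate) can never be separated:
  // treat the cell as a leaf instead of recursing forever
  bool separable = false;
  for (int i = 1; i < k; ++i) {
    if (w.x[idx[i]] != w.x[idx[0]] || w.y[idx[i]] != w.y[idx[0]]) {
      separable = true;
      break;
    }
  }

  if (k >= kMinSplit && separable && (root || chi2 > kChi2Crit)) {
    recurse(w, q0, xlo, xm, ylo, ym, false);
    recurse(w, q1, xm, xhi, ylo, ym, false);
    recurse(w, q2, xlo, xm, ym, yhi, false);
    recurse(w, q3, xm, xhi, ym, yhi, false);
  } else {
    const double p = static_cast<double>(k) / w.n;
    const double area = (xhi - xlo) * (yhi - ylo);
    w.mi += p * std::log(p / area);
  }
}

double mi_one(const double* x, const double* y, int n) {
  Workspace w;
  w.x = x;
  w.y = y;
  w.n = n;
  w.mi = 0.0;
  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  recurse(w, idx, 0.0, 1.0, 0.0, 1.0, true);
  return w.mi > 0.0 ? w.mi : 0.0;
}

}  // namespace

// [[Rcpp::export]]
double mi_ap_pair_cpp(NumericVector xr, NumericVector yr) {
  const int n = xr.size();
  if (yr.size() != n) stop("rank vectors differ in length");
  return mi_one(REAL(xr), REAL(yr), n);
}

// Cross MI between every column of `xr` and every column of `yr`
// (both n x p rank-coordinate matrices). Returns ncol(xr) x ncol(yr).
// [[Rcpp::export]]
NumericMatrix mi_ap_cross_cpp(NumericMatrix xr, NumericMatrix yr) {
  const int n = xr.nrow();
  if (yr.nrow() != n) stop("rank matrices differ in sample count");
  const int p = xr.ncol(), q = yr.ncol();
  NumericMatrix out(p, q);
  for (int i = 0; i < p; ++i) {
    const double* xi = &xr(0, i);
    for (int j = 0; j < q; ++j) {
      out(i, j) = mi_one(xi, &yr(0, j), n);
    }
  }
  return out;
}

// MI for selected column pairs of a single rank matrix; `ii`/`jj` are
// 1-based column indices of equal length.
// [[Rcpp::export]]
NumericVector mi_ap_pairs_cpp(NumericMatrix xr, IntegerVector ii,
                              IntegerVector jj) {
  const int n = xr.nrow();
  const int m = ii.size();
  if (jj.size() != m) stop("index vectors differ in length");
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    out[k] = mi_one(&xr(0, ii[k] - 1), &xr(0, jj[k] - 1), n);
  }
  return out;
}
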