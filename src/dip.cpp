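#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Dip statistic of unimodality.
//
// dip(F_n) = min over unimodal G of sup_x |F_n(x) - G(x)|, where G ranges
// over distribution functions that are convex to the left of some mode m
// and concave to its right (an atom at the mode is allowed).
//
// Computation: a unimodal G stays within sup-distance d of the ecdf iff at
// every data value x_i the constraints |i/n - G(x_i)| <= d (value) and
// |(i-1)/n - G(x_i^-)| <= d (left limit) hold, which collapse to the band
//   L_i = i/n - d  <=  G(x_i)  <=  U_i = (i-1)/n + d
// at each knot (tied knots pool their bands).  A convex function fits a set
// of bands iff the greatest convex minorant of the upper bounds clears every
// lower bound; concave is the mirror image.  G exists for a given d iff the
// knots split into a convex-feasible prefix and a concave-feasible suffix.
// The dip is the smallest feasible d, found by bisection; it is bounded
// below by 1/(2n) (band width is 2d - 1/n).

// Largest prefix (in number of knots) of strictly increasing knots x that
// admits a convex interpolant v with L[i] <= v(x[i]) <= U[i].
static int convex_prefix(const std::vector<double>& x,
                         const std::vector<double>& L,
                         const std::vector<double>& U) {
  const int m = (int) x.size();
  const double eps = 1e-12;
  std::vector<int> hull;
  hull.reserve(m);
  for (int j = 0; j < m; ++j) {
    if (L[j] > U[j] + eps) return j;
    // maintain the lower convex hull of (x, U)
    while ((int) hull.size() >= 2) {
      int b = hull[hull.size() - 1], a = hull[hull.size() - 2];
      double cross = (x[b] - x[a]) * (U[j] - U[a]) -
                     (U[b] - U[a]) * (x[j] - x[a]);
      if (cross > 0) break; // b strictly below chord a->j: keep
      hull.pop_back();
    }
    int lo = hull.empty() ? j : hull.back();
    hull.push_back(j);
    // the minorant changed only on (lo, j]; recheck lower bounds there
    if (lo < j) {
      double slope = (U[j] - U[lo]) / (x[j] - x[lo]);
      for (int i = lo + 1; i <= j; ++i) {
        double g = U[lo] + slope * (x[i] - x[lo]);
        if (g < L[i] - eps) return j;
      }
    }
  }
  return m;
}

struct Bands {
  std::vector<double> x, L, U; // per unique knot, pooled over ties
  int n;                       // sample size
};

static Bands make_bands(const NumericVector& xs) {
  Bands b;
  b.n = (int) xs.size();
  int i = 0;
  while (i < b.n) {
    int j = i;
    while (j + 1 < b.n && xs[j + 1] == xs[i]) ++j;
    b.x.push_back(xs[i]);
    // lower bound from the last tied index, upper from the first
    b.L.push_back((double) (j + 1) / b.n); // minus d later
    b.U.push_back((double) i / b.n);       // plus d later
    i = j + 1;
  }
  return b;
}

static bool feasible(const Bands& b, double d) {
  const int m = (int) b.x.size();
  std::vector<double> L(m), U(m);
  for (int i = 0; i < m; ++i) {
    L[i] = std::max(b.L[i] - d, 0.0);
    U[i] = std::min(b.U[i] + d, 1.0);
  }
  int pre = convex_prefix(b.x, L, U);
  if (pre == m) return true;
  // concave suffix via the mirror transform x -> -x, v -> -v
  std::vector<double> xr(m), Lr(m), Ur(m);
  for (int i = 0; i < m; ++i) {
    xr[i] = -b.x[m - 1 - i];
    Lr[i] = -U[m - 1 - i];
    Ur[i] = -L[m - 1 - i];
  }
  int suf = convex_prefix(xr, Lr, Ur);
  return pre + suf >= m;
}

// [[Rcpp::export(name = ".dipStatC")]]
double dip_stat(NumericVector x) {
  const int n = (int) x.size();
  if (n < 4) stop("dip statistic needs at least 4 observations");
  NumericVector xs = clone(x).sort();
  Bands b = make_bands(xs);
  double lo = 0.5 / n, hi = 0.5;
  if (feasible(b, lo)) return lo;
  for (int it = 0; it < 48; ++it) {
    double mid = 0.5 * (lo + hi);
    if (feasible(b, mid)) hi = mid; else lo = mid;
  }
  return hi;
}

// Dip statistics for nBoot uniform(0,1) samples of size n (null reference
// distribution); uses R's RNG so results honour set.seed().
// [[Rcpp::export(name = ".dipNullC")]]
NumericVector dip_null(int n, int nBoot) {
  NumericVector out(nBoot);
  for (int bIdx = 0; bIdx < nBoot; ++bIdx) {
    NumericVector u = runif(n);
    out[bIdx] = dip_stat(u);
  }
  return out;
}
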