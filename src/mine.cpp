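// Maximal information coefficient via the MINE approximation:
// equipartition one axis into q rows, optimize the other axis' column
// partition by dynamic programming over clump boundaries, for every q with
// 2*q <= B(n); both orientations; MIC = max normalized mutual information.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double plogp(double p) { return p > 0.0 ? p * std::log(p) : 0.0; }

// Assign q near-equal rows over values sorted ascending, keeping ties
// together; returns 0-based row ids in sorted order (rows actually used may
// be fewer than q when ties are heavy).
static std::vector<int> equipartition(const std::vector<double>& v, int q) {
  int n = (int)v.size();
  std::vector<int> row(n);
  int i = 0, curr = 0, currsize = 0;
  double desired = (double)n / q;
  while (i < n) {
    int s = 1;
    while (i + s < n && v[i + s] == v[i]) ++s;
    if (currsize != 0 && curr < q - 1 &&
        std::fabs(currsize + s - desired) >= std::fabs(currsize - desired)) {
      ++curr;
      currsize = 0;
      desired = (double)(n - i) / (q - curr);
    }
    for (int k = 0; k < s; ++k) row[i + k] = curr;
    currsize += s;
    i += s;
  }
  return row;
}

// Clump ids (0-based, increasing) for points sorted by x: x-ties stay
// together; a tie-group spanning several rows forms its own clump; adjacent
// groups in the same single row merge.
static std::vector<int> get_clumps(const std::vector<double>& xs,
                                   const std::vector<int>& rowOfPoint) {
  int n = (int)xs.size();
  std::vector<int> clump(n);
  int cid = -1;
  int prevLabel = -2;  // -2: nothing; -1: previous group was mixed
  int i = 0;
  while (i < n) {
    int s = 1;
    bool uniform = true;
    while (i + s < n && xs[i + s] == xs[i]) {
      if (rowOfPoint[i + s] != rowOfPoint[i]) uniform = false;
      ++s;
    }
    int label = uniform ? rowOfPoint[i] : -1;
    if (label < 0 || label != prevLabel) ++cid;
    prevLabel = (label < 0) ? -2 : label;  // mixed groups never merge
    for (int k = 0; k < s; ++k) clump[i + k] = cid;
    i += s;
  }
  return clump;
}

// Merge clumps into at most khat superclumps (equipartition over clump ids,
// which keeps clump members together).
static std::vector<int> superclumps(const std::vector<int>& clump, int khat) {
  int k = clump.empty() ? 0 : clump.back() + 1;
  if (k <= khat) return clump;
  std::vector<double> asval(clump.begin(), clump.end());
  return equipartition(asval, khat);
}

// Best I(P;Q) for each number of columns 2..L over points grouped in k
// clumps with row labels Q (q rows), all probabilities normalized by n.
// Returns vector I[l] for l = 2..L (index l-2).
static std::vector<double> optimize_axis(const std::vector<int>& clump,
                                         const std::vector<int>& rowOfPoint,
                                         int q, int L) {
  int n = (int)clump.size();
  int k = clump.back() + 1;
  if (L > k) L = k;
  if (L < 2) return std::vector<double>();

  // cumulative per-row counts by clump prefix: cum[t*q + r], t = 0..k
  std::vector<int> cum((size_t)(k + 1) * q, 0);
  std::vector<int> np(k + 1, 0);
  {
    std::vector<int> acc(q, 0);
    int t = 0, i = 0;
    for (t = 1; t <= k; ++t) {
      while (i < n && clump[i] == t - 1) { ++acc[rowOfPoint[i]]; ++i; }
      for (int r = 0; r < q; ++r) cum[(size_t)t * q + r] = acc[r];
      np[t] = i;
    }
  }
  double H_Q = 0.0;
  for (int r = 0; r < q; ++r)
    H_Q -= plogp((double)cum[(size_t)k * q + r] / n);

  // column score of clumps (s, t]:  -p log p + sum_r p_r log p_r
  // stored transposed (t-major) so the DP's inner s loop is contiguous
  std::vector<double> score((size_t)(k + 1) * (k + 1));
  for (int t = 1; t <= k; ++t) {
    const int* ct = &cum[(size_t)t * q];
    double* st = &score[(size_t)t * (k + 1)];
    for (int s = 0; s < t; ++s) {
      const int* cs = &cum[(size_t)s * q];
      double tot = (double)(np[t] - np[s]) / n;
      double sc = -plogp(tot);
      for (int r = 0; r < q; ++r)
        sc += plogp((double)(ct[r] - cs[r]) / n);
      st[s] = sc;
    }
  }

  // DP over (clumps used, columns): G[t] for current l
  std::vector<double> Gprev(k + 1, -1e300), Gcur(k + 1, -1e300);
  for (int t = 1; t <= k; ++t) Gprev[t] = score[(size_t)t * (k + 1)];
  std::vector<double> best(L - 1, -1e300);
  for (int l = 2; l <= L; ++l) {
    for (int t = l; t <= k; ++t) {
      const double* st = &score[(size_t)t * (k + 1)];
      double bestv = -1e300;
      for (int s = l - 1; s < t; ++s) {
        double v = Gprev[s] + st[s];
        if (v > bestv) bestv = v;
      }
      Gcur[t] = bestv;
    }
    best[l - 2] = H_Q + Gcur[k];
    std::swap(Gprev, Gcur);
    std::fill(Gcur.begin(), Gcur.end(), -1e300);
  }
  // allow fewer columns than the budget (monotone envelope)
  for (int l = 1; l < (int)best.size(); ++l)
    if (best[l] < best[l - 1]) best[l] = best[l - 1];
  return best;
}

// One orientation: rows on `yv`, optimized columns on `xv`.
static double mic_one_orientation(const std::vector<double>& xv,
                                  const std::vector<double>& yv,
                                  int B, int cfac) {
  int n = (int)xv.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  // sort by y for the equipartition
  std::vector<int> ordy(ord);
  std::sort(ordy.begin(), ordy.end(),
            [&](int a, int b) { return yv[a] < yv[b]; });
  std::vector<double> ys(n);
  for (int i = 0; i < n; ++i) ys[i] = yv[ordy[i]];

  // sort by x once for the clump pass
  std::vector<int> ordx(ord);
  std::sort(ordx.begin(), ordx.end(),
            [&](int a, int b) { return xv[a] < xv[b]; });
  std::vector<double> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = xv[ordx[i]];

  double best = 0.0;
  for (int q = 2; 2 * q <= B; ++q) {
    int L = B / q;
    if (L < 2) break;
    std::vector<int> rowSorted = equipartition(ys, q);
    int qeff = rowSorted.back() + 1;   // rows actually produced
    if (qeff < 2) continue;
    std::vector<int> rowOfPoint(n);
    for (int i = 0; i < n; ++i) rowOfPoint[ordy[i]] = rowSorted[i];
    std::vector<int> rowByX(n);
    for (int i = 0; i < n; ++i) rowByX[i] = rowOfPoint[ordx[i]];
    std::vector<int> cl = get_clumps(xs, rowByX);
    cl = superclumps(cl, std::max(1, cfac * L));
    std::vector<double> I = optimize_axis(cl, rowByX, qeff, L);
    for (int l = 2; l - 2 < (int)I.size(); ++l) {
      double denom = std::log((double)std::min(l, qeff));
      if (denom <= 0.0) continue;
      double v = I[l - 2] / denom;
      if (v > best) best = v;
    }
  }
  return best;
}

// [[Rcpp::export]]
double mine_mic(NumericVector x, NumericVector y, double alpha, int cfac) {
  int n = x.size();
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> yv(y.begin(), y.end());
  int B = (int)std::floor(std::pow((double)n, alpha));
  if (B < 4) B = 4;
  double m1 = mic_one_orientation(xv, yv, B, cfac);
  double m2 = mic_one_orientation(yv, xv, B, cfac);
  double v = std::max(m1, m2);
  return v > 1.0 ? 1.0 : v;
}
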