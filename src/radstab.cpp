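#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance from each pixel to the nearest zero pixel.
// Pixels that are zero get distance 0; if no zero pixel exists, Inf.
// [[Rcpp::export(name = ".cppEdtSq")]]
NumericMatrix cppEdtSq(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix out(nr, nc);
  // column pass
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) == 0 ? 0.0 : INF;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
  }
  // row pass
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = out(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j];
  }
  return out;
}

// ---- connected-component labelling (stack flood fill), 4 or 8 ----

static void floodLabel(const int* mask, int* lab, int nr, int nc,
                       int connectivity, std::vector<int>& stack,
                       int start, int label) {
  const int n = nr * nc;
  stack.clear();
  lab[start] = label;
  stack.push_back(start);
  while (!stack.empty()) {
    int p = stack.back();
    stack.pop_back();
    int i = p % nr, j = p / nr;
    int cand[8];
    int ncand = 0;
    if (i > 0) cand[ncand++] = p - 1;
    if (i < nr - 1) cand[ncand++] = p + 1;
    if (j > 0) cand[ncand++] = p - nr;
    if (j < nc - 1) cand[ncand++] = p + nr;
    if (connectivity == 8) {
      if (i > 0 && j > 0) cand[ncand++] = p - 1 - nr;
      if (i > 0 && j < nc - 1) cand[ncand++] = p - 1 + nr;
      if (i < nr - 1 && j > 0) cand[ncand++] = p + 1 - nr;
      if (i < nr - 1 && j < nc - 1) cand[ncand++] = p + 1 + nr;
    }
    for (int t = 0; t < ncand; ++t) {
      int q = cand[t];
      if (q >= 0 && q < n && mask[q] != 0 && lab[q] == 0) {
        lab[q] = label;
        stack.push_back(q);
      }
    }
  }
}

// [[Rcpp::export(name = ".cppLabel")]]
IntegerMatrix cppLabel(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<int> stack;
  stack.reserve(n);
  int next = 0;
  const int* m = mask.begin();
  int* l = lab.begin();
  for (int p = 0; p < n; ++p)
    if (m[p] != 0 && l[p] == 0)
      floodLabel(m, l, nr, nc, connectivity, stack, p, ++next);
  return lab;
}

// Keep the largest 4-connected foreground component and fill interior
// holes (background components not touching the border). Returns a logical
// matrix.
// [[Rcpp::export(name = ".cppCleanMask")]]
LogicalMatrix cppCleanMask(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  std::vector<int> lab(n, 0), stack;
  stack.reserve(n);
  const int* m = mask.begin();
  int next = 0;
  for (int p = 0; p < n; ++p)
    if (m[p] != 0 && lab[p] == 0)
      floodLabel(m, lab.data(), nr, nc, 4, stack, p, ++next);
  LogicalMatrix out(nr, nc);
  if (next == 0) return out;
  std::vector<int> sizes(next + 1, 0);
  for (int p = 0; p < n; ++p) if (lab[p]) ++sizes[lab[p]];
  int best = 1;
  for (int k = 2; k <= next; ++k) if (sizes[k] > sizes[best]) best = k;
  // invert: label background reachable from the border of the kept mask
  std::vector<int> inv(n), bg(n, 0);
  for (int p = 0; p < n; ++p) inv[p] = lab[p] == best ? 0 : 1;
  int bnext = 0;
  for (int i = 0; i < nr; ++i) {
    int edges[2] = {i, i + (nc - 1) * nr};
    for (int e = 0; e < 2; ++e)
      if (inv[edges[e]] && bg[edges[e]] == 0)
        floodLabel(inv.data(), bg.data(), nr, nc, 4, stack, edges[e],
                   ++bnext);
  }
  for (int j = 0; j < nc; ++j) {
    int edges[2] = {j * nr, nr - 1 + j * nr};
    for (int e = 0; e < 2; ++e)
      if (inv[edges[e]] && bg[edges[e]] == 0)
        floodLabel(inv.data(), bg.data(), nr, nc, 4, stack, edges[e],
                   ++bnext);
  }
  for (int p = 0; p < n; ++p)
    out[p] = (lab[p] == best) || (inv[p] && bg[p] == 0);
  return out;
}

// ---- gray-level co-occurrence counts ----
// levels: integer matrix, 0 = outside mask, 1..ngray inside.
// Symmetric accumulation for offset (dr, dc).

// [[Rcpp::export(name = ".cppGlcm")]]
NumericMatrix cppGlcm(const IntegerMatrix& levels, int ngray, int dr, int dc) {
  const int nr = levels.nrow(), nc = levels.ncol();
  NumericMatrix P(ngray, ngray);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int a = levels(i, j);
      if (a == 0) continue;
      int ii = i + dr, jj = j + dc;
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      int b = levels(ii, jj);
      if (b == 0) continue;
      P(a - 1, b - 1) += 1.0;
      P(b - 1, a - 1) += 1.0;
    }
  }
  return P;
}

// Direction-level GLCM summary: normalized symmetric matrix features.
// Order: JointEnergy, JointEntropy, Contrast, Dissimilarity,
// InverseDifferenceMoment, InverseDifference, Correlation, ClusterShade,
// ClusterProminence. Constant regions get correlation 1 by convention.
// [[Rcpp::export(name = ".cppGlcmFeatures")]]
NumericVector cppGlcmFeatures(const NumericMatrix& P) {
  const int ng = P.nrow();
  double s = 0;
  for (int i = 0; i < ng * ng; ++i) s += P[i];
  std::vector<double> px(ng, 0.0);
  for (int i = 0; i < ng; ++i)
    for (int j = 0; j < ng; ++j) px[i] += P(i, j) / s;
  double mu = 0;
  for (int i = 0; i < ng; ++i) mu += (i + 1) * px[i];
  double sig2 = 0;
  for (int i = 0; i < ng; ++i) sig2 += (i + 1 - mu) * (i + 1 - mu) * px[i];
  double je = 0, jent = 0, con = 0, dis = 0, idm = 0, idf = 0, sij = 0,
         cs = 0, cp = 0;
  for (int i = 0; i < ng; ++i) {
    for (int j = 0; j < ng; ++j) {
      double v = P(i, j) / s;
      if (v == 0) continue;
      double d = i - j;
      double ad = d < 0 ? -d : d;
      double e = (i + 1) + (j + 1) - 2 * mu;
      je += v * v;
      jent -= v * std::log2(v);
      con += d * d * v;
      dis += ad * v;
      idm += v / (1 + d * d);
      idf += v / (1 + ad);
      sij += (i + 1) * (double)(j + 1) * v;
      cs += e * e * e * v;
      cp += e * e * e * e * v;
    }
  }
  double corr = sig2 > 0 ? (sij - mu * mu) / sig2 : 1.0;
  return NumericVector::create(je, jent, con, dis, idm, idf, corr, cs, cp);
}

// ---- gray-level run-length counts for one direction ----

// [[Rcpp::export(name = ".cppGlrlm")]]
NumericMatrix cppGlrlm(const IntegerMatrix& levels, int ngray, int dr, int dc) {
  const int nr = levels.nrow(), nc = levels.ncol();
  const int maxrun = std::max(nr, nc);
  NumericMatrix R(ngray, maxrun);
  // a pixel starts a run if its backward neighbour (i-dr, j-dc) is not the
  // same in-mask gray level
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int g = levels(i, j);
      if (g == 0) continue;
      int pi = i - dr, pj = j - dc;
      bool starts = true;
      if (pi >= 0 && pi < nr && pj >= 0 && pj < nc && levels(pi, pj) == g)
        starts = false;
      if (!starts) continue;
      int len = 1, ii = i + dr, jj = j + dc;
      while (ii >= 0 && ii < nr && jj >= 0 && jj < nc && levels(ii, jj) == g) {
        ++len;
        ii += dr;
        jj += dc;
      }
      R(g - 1, len - 1) += 1.0;
    }
  }
  return R;
}

// ---- gray-level size-zone counts (8-connected zones) ----

// [[Rcpp::export(name = ".cppGlszm")]]
NumericMatrix cppGlszm(const IntegerMatrix& levels, int ngray) {
  const int nr = levels.nrow(), nc = levels.ncol();
  const int n = nr * nc;
  std::vector<char> seen(n, 0);
  std::vector<int> stack;
  stack.reserve(n);
  const int* lv = levels.begin();
  std::vector<std::pair<int, int> > zones; // (gray, size)
  int maxsize = 1;
  for (int p0 = 0; p0 < n; ++p0) {
    int g = lv[p0];
    if (g == 0 || seen[p0]) continue;
    int size = 0;
    seen[p0] = 1;
    stack.clear();
    stack.push_back(p0);
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      ++size;
      int i = p % nr, j = p / nr;
      for (int di = -1; di <= 1; ++di) {
        for (int dj = -1; dj <= 1; ++dj) {
          if (di == 0 && dj == 0) continue;
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          int q = ii + jj * nr;
          if (!seen[q] && lv[q] == g) {
            seen[q] = 1;
            stack.push_back(q);
          }
        }
      }
    }
    zones.push_back(std::make_pair(g, size));
    if (size > maxsize) maxsize = size;
  }
  NumericMatrix Z(ngray, maxsize);
  for (size_t z = 0; z < zones.size(); ++z)
    Z(zones[z].first - 1, zones[z].second - 1) += 1.0;
  return Z;
}

// ---- gray-level dependence counts ----
// Chebyshev distance-1 neighbourhood (8 neighbours); a neighbour is dependent
// if in-mask and |g_center - g_neighbour| <= alpha. Column d+1 holds
// dependence d (d in 0..8).

// [[Rcpp::export(name = ".cppGldm")]]
NumericMatrix cppGldm(const IntegerMatrix& levels, int ngray, int alpha) {
  const int nr = levels.nrow(), nc = levels.ncol();
  const int dx[] = {1, -1, 0, 0, 1, 1, -1, -1},
            dy[] = {0, 0, 1, -1, 1, -1, 1, -1};
  NumericMatrix D(ngray, 9);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int g = levels(i, j);
      if (g == 0) continue;
      int dep = 0;
      for (int t = 0; t < 8; ++t) {
        int ii = i + dx[t], jj = j + dy[t];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) {
          int h = levels(ii, jj);
          if (h != 0 && std::abs(h - g) <= alpha) ++dep;
        }
      }
      D(g - 1, dep) += 1.0;
    }
  }
  return D;
}
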