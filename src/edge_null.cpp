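#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// measure codes: 1 pearson, 2 spearman, 3 bray, 4 kld

static void rank_vector(const std::vector<double>& v, std::vector<double>& r) {
  int n = v.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[idx[j + 1]] == v[idx[i]]) ++j;
    double avg = 0.5 * (i + j) + 1.0;  // mid-rank for ties
    for (int k = i; k <= j; ++k) r[idx[k]] = avg;
    i = j + 1;
  }
}

static double pearson(const std::vector<double>& x,
                      const std::vector<double>& y) {
  int n = x.size();
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    sx += x[i]; sy += y[i];
    sxx += x[i] * x[i]; syy += y[i] * y[i]; sxy += x[i] * y[i];
  }
  double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
  if (vx <= 0 || vy <= 0) return NA_REAL;
  return (sxy - sx * sy / n) / std::sqrt(vx * vy);
}

static double score_pair(const std::vector<double>& x,
                         const std::vector<double>& y, int measure,
                         std::vector<double>& rx, std::vector<double>& ry) {
  int n = x.size();
  switch (measure) {
  case 1:
    return pearson(x, y);
  case 2:
    rank_vector(x, rx);
    rank_vector(y, ry);
    return pearson(rx, ry);
  case 3: {  // Bray-Curtis on sum-1 profiles
    double tx = 0, ty = 0;
    for (int i = 0; i < n; ++i) { tx += x[i]; ty += y[i]; }
    if (tx <= 0 || ty <= 0) return NA_REAL;
    double s = 0;
    for (int i = 0; i < n; ++i) s += std::min(x[i] / tx, y[i] / ty);
    return 1.0 - s;
  }
  case 4: {  // symmetrised KL with 1e-6 pseudocount on sum-1 profiles
    double tx = 0, ty = 0;
    for (int i = 0; i < n; ++i) { tx += x[i]; ty += y[i]; }
    if (tx <= 0 || ty <= 0) return NA_REAL;
    // renormalise after pseudocount
    double zx = 1.0 + 1e-6 * n, zy = 1.0 + 1e-6 * n;
    double kl = 0;
    for (int i = 0; i < n; ++i) {
      double px = (x[i] / tx + 1e-6) / zx;
      double py = (y[i] / ty + 1e-6) / zy;
      kl += 0.5 * (px * std::log(px / py) + py * std::log(py / px));
    }
    return kl;
  }
  }
  return NA_REAL;
}

// Permutation null scores for one edge.  x, y are the two features'
// per-sample (closed) relative abundances; perm holds 1-based sample
// permutations (n x iterations).  With renormalize, after shuffling x the
// sample totals change by (x_perm - x) and both features are re-closed.
// [[Rcpp::export]]
NumericVector cpp_perm_null(NumericVector x, NumericVector y,
                            IntegerMatrix perm, int measure,
                            bool renormalize) {
  int n = x.size(), iters = perm.ncol();
  NumericVector out(iters);
  std::vector<double> xi(n), yi(n), rx(n), ry(n);
  for (int it = 0; it < iters; ++it) {
    for (int s = 0; s < n; ++s) {
      double xp = x[perm(s, it) - 1];
      if (renormalize) {
        double denom = 1.0 - x[s] + xp;  // rows were closed to sum 1
        xi[s] = xp / denom;
        yi[s] = y[s] / denom;
      } else {
        xi[s] = xp;
        yi[s] = y[s];
      }
    }
    out[it] = score_pair(xi, yi, measure, rx, ry);
  }
  return out;
}

// Bootstrap scores for one edge: samples resampled with replacement
// (boot: n x iterations, 1-based).
// [[Rcpp::export]]
NumericVector cpp_boot_scores(NumericVector x, NumericVector y,
                              IntegerMatrix boot, int measure) {
  int n = x.size(), iters = boot.ncol();
  NumericVector out(iters);
  std::vector<double> xi(n), yi(n), rx(n), ry(n);
  for (int it = 0; it < iters; ++it) {
    for (int s = 0; s < n; ++s) {
      int idx = boot(s, it) - 1;
      xi[s] = x[idx];
      yi[s] = y[idx];
    }
    out[it] = score_pair(xi, yi, measure, rx, ry);
  }
  return out;
}

// R's default (type-7) quantile on a copy of v.
static double quantile7(std::vector<double> v, double prob) {
  std::sort(v.begin(), v.end());
  int n = v.size();
  double h = (n - 1) * prob;
  int lo = (int)std::floor(h);
  int hi = lo + 1 < n ? lo + 1 : lo;
  return v[lo] + (h - lo) * (v[hi] - v[lo]);
}

// Batch permutation-p / bootstrap-interval computation for a candidate
// edge list.  data: samples x features, rows closed to sum 1; src/tgt:
// 1-based column indices; measure: codes per edge; obs: observed scores.
// Returns a matrix with columns p, boot_lo, boot_hi, unstable.
// [[Rcpp::export]]
NumericMatrix cpp_edge_significance(NumericMatrix data, IntegerVector src,
                                    IntegerVector tgt, IntegerVector measure,
                                    NumericVector obs, IntegerMatrix perm,
                                    IntegerMatrix boot, bool renormalize) {
  int n = data.nrow(), iters = perm.ncol(), n_edge = src.size();
  NumericMatrix out(n_edge, 4);
  std::vector<double> x(n), y(n), xi(n), yi(n), rx(n), ry(n);
  std::vector<double> null_sc(iters), boot_sc(iters);
  for (int e = 0; e < n_edge; ++e) {
    int cx = src[e] - 1, cy = tgt[e] - 1, code = measure[e];
    for (int s = 0; s < n; ++s) { x[s] = data(s, cx); y[s] = data(s, cy); }
    for (int it = 0; it < iters; ++it) {
      for (int s = 0; s < n; ++s) {
        double xp = x[perm(s, it) - 1];
        if (renormalize) {
          double denom = 1.0 - x[s] + xp;
          xi[s] = xp / denom;
          yi[s] = y[s] / denom;
        } else {
          xi[s] = xp;
          yi[s] = y[s];
        }
      }
      null_sc[it] = score_pair(xi, yi, code, rx, ry);
    }
    for (int it = 0; it < iters; ++it) {
      for (int s = 0; s < n; ++s) {
        int idx = boot(s, it) - 1;
        xi[s] = x[idx];
        yi[s] = y[idx];
      }
      boot_sc[it] = score_pair(xi, yi, code, rx, ry);
    }
    double center = 0.0;
    if (code >= 3) {  // dissimilarities: center at the null mean
      double m = 0; int k = 0;
      for (double v : null_sc) if (R_finite(v)) { m += v; ++k; }
      center = k > 0 ? m / k : 0.0;
    }
    int extreme = 0, used = 0;
    double o = std::fabs(obs[e] - center);
    for (double v : null_sc) {
      if (!R_finite(v)) continue;
      ++used;
      if (std::fabs(v - center) >= o) ++extreme;
    }
    out(e, 0) = (1.0 + extreme) / (used + 1.0);
    std::vector<double> bs;
    bs.reserve(iters);
    for (double v : boot_sc) if (R_finite(v)) bs.push_back(v);
    if (bs.size() > 1) {
      out(e, 1) = quantile7(bs, 0.025);
      out(e, 2) = quantile7(bs, 0.975);
      out(e, 3) = (out(e, 1) <= center && center <= out(e, 2)) ? 1.0 : 0.0;
    } else {
      out(e, 1) = NA_REAL; out(e, 2) = NA_REAL; out(e, 3) = NA_REAL;
    }
  }
  return out;
}
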