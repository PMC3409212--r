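// Compiled cores for the permutation-heavy stages: circular binary
// segmentation (max arc statistic + recursive splitting), the STAC-style
// re-placement null, and the GISTIC-style circular-shift null. All
// randomness goes through R's RNG so set.seed() in R controls everything.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Average ranks (ties averaged), 1..n.
static std::vector<double> avg_rank(const std::vector<double>& x) {
  int n = x.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&x](int a, int b) { return x[a] < x[b]; });
  std::vector<double> r(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
    double avg = (i + j) / 2.0 + 1.0;
    for (int k = i; k <= j; ++k) r[ord[k]] = avg;
    i = j + 1;
  }
  return r;
}

struct ArcStat {
  double t;
  int i, j;  // arc is [i, j) within the segment, 0-based
};

// Max over all arcs [i, j) of the two-sample statistic
// |mean_in - mean_out| / (s * sqrt(1/k + 1/(n-k))), s^2 the segment variance.
// Both the arc and its complement must hold >= min_seg probes. For a fixed
// arc length k the statistic is |c_k * S_arc - d_k| * scale_k / s, linear in
// the windowed sum S_arc, so only the windows with the extreme sums need
// evaluating: the scan is O(n^2) with a two-comparison inner loop.
static ArcStat max_arc(const std::vector<double>& y, int min_seg) {
  int n = y.size();
  ArcStat best = {0.0, -1, -1};
  if (n < 2 * min_seg) return best;
  std::vector<double> S(n + 1, 0.0);
  double ss = 0.0;
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + y[i];
    ss += y[i] * y[i];
  }
  double mean = S[n] / n;
  double s2 = (ss - n * mean * mean) / (n - 1);
  if (s2 <= 1e-12) return best;
  double s = std::sqrt(s2);
  double tot = S[n];
  for (int k = min_seg; k <= n - min_seg; ++k) {
    int nk = n - k;
    double ck = 1.0 / k + 1.0 / nk;
    double dk = tot / nk;
    double scale = 1.0 / (s * std::sqrt(ck));
    double lo = S[k] - S[0], hi = lo;
    int ilo = 0, ihi = 0;
    for (int i = 1; i <= n - k; ++i) {
      double w = S[i + k] - S[i];
      if (w < lo) { lo = w; ilo = i; }
      if (w > hi) { hi = w; ihi = i; }
    }
    double t_hi = std::fabs(ck * hi - dk) * scale;
    double t_lo = std::fabs(ck * lo - dk) * scale;
    if (t_hi > best.t) { best.t = t_hi; best.i = ihi; best.j = ihi + k; }
    if (t_lo > best.t) { best.t = t_lo; best.i = ilo; best.j = ilo + k; }
  }
  return best;
}

// Conservative chromosome-wide bound on the max-arc p-value: number of
// arcs x two-sided normal tail.
static double arc_bound(double tmax, int n) {
  double tail = R::pnorm(-tmax, 0.0, 1.0, 1, 0);
  double b = (double)n * (n - 1) * tail;
  return b > 1.0 ? 1.0 : b;
}

// Significance of the best split of segment y: hybrid rule. Accept
// immediately when the conservative bound is <= alpha; otherwise fall back
// to a label-permutation p with early stopping in both directions.
static bool split_significant(const std::vector<double>& y, const ArcStat& best,
                              double alpha, int n_perm, int min_seg) {
  int n = y.size();
  if (best.i < 0) return false;
  if (arc_bound(best.t, n) <= alpha) return true;
  if (n_perm <= 0) return false;
  double pmin = 1.0 / (n_perm + 1.0);
  if (pmin > alpha) return false;  // unreachable even with 0 exceedances
  std::vector<double> z = y;
  int exceed = 0;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates with R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(z[i], z[j]);
    }
    ArcStat st = max_arc(z, min_seg);
    if (st.t >= best.t) ++exceed;
    double p_low = (1.0 + exceed) / (n_perm + 1.0);
    if (p_low > alpha) return false;                       // can't pass
    if ((1.0 + exceed + (n_perm - 1 - p)) / (n_perm + 1.0) <= alpha)
      return true;                                         // can't fail
  }
  return (1.0 + exceed) / (n_perm + 1.0) <= alpha;
}

static void cbs_recurse(const std::vector<double>& x, int lo, int hi,
                        double alpha, int n_perm, int min_seg, bool use_ranks,
                        std::vector<int>& breaks) {
  int n = hi - lo;
  if (n < 2 * min_seg) return;
  std::vector<double> y(x.begin() + lo, x.begin() + hi);
  if (use_ranks) y = avg_rank(y);
  ArcStat best = max_arc(y, min_seg);
  if (!split_significant(y, best, alpha, n_perm, min_seg)) return;
  int a = lo + best.i, b = lo + best.j;
  if (best.i > 0) breaks.push_back(a);
  if (best.j < n) breaks.push_back(b);
  cbs_recurse(x, lo, a, alpha, n_perm, min_seg, use_ranks, breaks);
  cbs_recurse(x, a, b, alpha, n_perm, min_seg, use_ranks, breaks);
  cbs_recurse(x, b, hi, alpha, n_perm, min_seg, use_ranks, breaks);
}

// [[Rcpp::export(name = ".cbs_breakpoints")]]
IntegerVector cbs_breakpoints_cpp(NumericVector x, double alpha, int n_perm,
                                  int min_seg, bool use_ranks) {
  std::vector<double> v(x.begin(), x.end());
  std::vector<int> breaks;
  cbs_recurse(v, 0, v.size(), alpha, n_perm, min_seg, use_ranks, breaks);
  std::sort(breaks.begin(), breaks.end());
  return wrap(breaks);  // 0-based indices of segment starts (interior)
}

// Batched form: one chromosome's probe matrix (probes x samples), one
// breakpoint vector per sample. Avoids per-sample call overhead.
// [[Rcpp::export(name = ".cbs_breakpoints_matrix")]]
List cbs_breakpoints_matrix_cpp(NumericMatrix mat, double alpha, int n_perm,
                                int min_seg, bool use_ranks) {
  int n = mat.nrow(), ns = mat.ncol();
  List out(ns);
  std::vector<double> v(n);
  for (int s = 0; s < ns; ++s) {
    for (int i = 0; i < n; ++i) v[i] = mat(i, s);
    std::vector<int> breaks;
    cbs_recurse(v, 0, n, alpha, n_perm, min_seg, use_ranks, breaks);
    std::sort(breaks.begin(), breaks.end());
    out[s] = wrap(breaks);
  }
  return out;
}

// [[Rcpp::export(name = ".max_arc_stat")]]
List max_arc_stat_cpp(NumericVector x, int min_seg, bool use_ranks) {
  std::vector<double> v(x.begin(), x.end());
  if (use_ranks) v = avg_rank(v);
  ArcStat best = max_arc(v, min_seg);
  return List::create(_["t"] = best.t, _["i"] = best.i, _["j"] = best.j,
                      _["p_bound"] = best.i < 0
                          ? 1.0
                          : arc_bound(best.t, (int)v.size()));
}

// Rejection-sampling placement of background events on chromosome arms,
// avoiding blocked intervals (planted loci and previously placed events,
// each padded by `gap`). Lengths are log-uniform between min_len and the
// containing arm length. Returns a matrix with columns arm-index (1-based),
// start, end; rows only for successfully placed events.
// [[Rcpp::export(name = ".place_background")]]
NumericMatrix place_background_cpp(int n_bg, NumericVector arm_start,
                                   NumericVector arm_end, IntegerVector arm_chrom,
                                   NumericVector blk_start, NumericVector blk_end,
                                   IntegerVector blk_chrom, double min_len,
                                   double gap, int max_tries) {
  int na = arm_start.size();
  std::vector<double> wt(na), cum(na);
  double tot = 0.0;
  for (int a = 0; a < na; ++a) {
    wt[a] = arm_end[a] - arm_start[a];
    tot += wt[a];
    cum[a] = tot;
  }
  std::vector<double> occ_s(blk_start.begin(), blk_start.end());
  std::vector<double> occ_e(blk_end.begin(), blk_end.end());
  std::vector<int> occ_c(blk_chrom.begin(), blk_chrom.end());
  for (size_t b = 0; b < occ_s.size(); ++b) {
    occ_s[b] -= gap;
    occ_e[b] += gap;
  }
  NumericMatrix out(n_bg, 3);
  int placed = 0;
  for (int i = 0; i < n_bg; ++i) {
    for (int t = 0; t < max_tries; ++t) {
      double u = unif_rand() * tot;
      int a = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
      if (a >= na) a = na - 1;
      double arm_len = wt[a];
      double len = std::exp(std::log(min_len) +
                            unif_rand() * (std::log(arm_len) - std::log(min_len)));
      if (len >= arm_len) len = arm_len;
      double start = arm_start[a] + unif_rand() * (arm_len - len);
      double end = start + len;
      bool hit = false;
      for (size_t b = 0; b < occ_s.size(); ++b) {
        if (occ_c[b] == arm_chrom[a] && occ_s[b] < end && occ_e[b] > start) {
          hit = true;
          break;
        }
      }
      if (!hit) {
        out(placed, 0) = a + 1;
        out(placed, 1) = start;
        out(placed, 2) = end;
        ++placed;
        occ_s.push_back(start - gap);
        occ_e.push_back(end + gap);
        occ_c.push_back(arm_chrom[a]);
        break;
      }
    }
  }
  if (placed == 0) return NumericMatrix(0, 3);
  return out(Range(0, placed - 1), _);
}

// STAC-style null: for each permutation, every sample's aberration runs
// (lengths preserved) are re-placed uniformly among non-wrapping positions on
// an m-marker chromosome; a marker covered by any of a sample's runs counts
// once. Returns the max marker count over the chromosome per permutation.
// [[Rcpp::export(name = ".stac_null_max")]]
IntegerVector stac_null_max_cpp(int m, List run_lengths, int n_perm) {
  int ns = run_lengths.size();
  IntegerVector out(n_perm);
  std::vector<int> counts(m);
  std::vector<char> covered(m);
  for (int p = 0; p < n_perm; ++p) {
    std::fill(counts.begin(), counts.end(), 0);
    for (int s = 0; s < ns; ++s) {
      IntegerVector runs = run_lengths[s];
      if (runs.size() == 0) continue;
      std::fill(covered.begin(), covered.end(), 0);
      for (int r = 0; r < runs.size(); ++r) {
        int L = runs[r];
        if (L > m) L = m;
        int start = (int)(unif_rand() * (m - L + 1));
        if (start > m - L) start = m - L;
        for (int k = start; k < start + L; ++k) covered[k] = 1;
      }
      for (int k = 0; k < m; ++k) counts[k] += covered[k];
    }
    out[p] = *std::max_element(counts.begin(), counts.end());
  }
  return out;
}

// GISTIC-style null: per permutation and sample, circularly shift the
// sample's focal-amplitude vector within each chromosome by a uniform
// offset; return the pooled permuted G scores (one vector of length m per
// permutation, concatenated).
// [[Rcpp::export(name = ".gistic_null_scores")]]
NumericVector gistic_null_scores_cpp(NumericMatrix amp, IntegerVector chrom_start,
                                     IntegerVector chrom_len, int n_perm) {
  int m = amp.nrow(), ns = amp.ncol(), nc = chrom_start.size();
  NumericVector out((R_xlen_t)n_perm * m);
  std::vector<double> g(m);
  for (int p = 0; p < n_perm; ++p) {
    std::fill(g.begin(), g.end(), 0.0);
    for (int s = 0; s < ns; ++s) {
      for (int c = 0; c < nc; ++c) {
        int off = chrom_start[c], nk = chrom_len[c];
        int shift = (int)(unif_rand() * nk);
        if (shift >= nk) shift = nk - 1;
        for (int k = 0; k < nk; ++k) {
          g[off + (k + shift) % nk] += amp(off + k, s);
        }
      }
    }
    for (int k = 0; k < m; ++k) out[(R_xlen_t)p * m + k] = g[k];
  }
  return out;
}
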