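#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Projected cyclic coordinate descent for
//   min_x 0.5 * x' H x - f' x   subject to  x >= 0,
// with H symmetric positive definite. Exact per-coordinate minimisation with
// clamping at zero converges for convex problems; the gradient is maintained
// incrementally so each sweep costs O(n^2) on the dense Hessian.
// [[Rcpp::export]]
NumericVector qp_nnls_cd(NumericMatrix H, NumericVector f, NumericVector x0,
                         int max_sweeps = 5000, double tol = 1e-12) {
  const int n = f.size();
  NumericVector x = clone(x0);
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += H(i, j) * x[j];
    g[i] = s - f[i];
  }
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (int i = 0; i < n; ++i) {
      const double hii = H(i, i);
      if (hii <= 0.0) continue;
      double xi = x[i] - g[i] / hii;
      if (xi < 0.0) xi = 0.0;
      const double d = xi - x[i];
      if (d != 0.0) {
        // H is symmetric: walk column i (contiguous in memory)
        const double* col = &H(0, i);
        for (int j = 0; j < n; ++j) g[j] += col[j] * d;
        x[i] = xi;
        const double rel = std::fabs(d) / std::max(1.0, std::fabs(xi));
        if (rel > max_delta) max_delta = rel;
      }
    }
    if (max_delta < tol) break;
  }
  return x;
}

// Fasano-Franceschini two-sample statistic: for every data point of either
// sample taken as origin, compare the fractions of each sample falling in the
// four open quadrants; D is the largest absolute difference encountered.
// Points lying on a quadrant boundary (equal coordinate) are excluded from the
// counts for that origin, in both samples symmetrically.
static double ks2d_D(const double* px, const double* py, const int* lab,
                     int n_total, int na, int nb) {
  double D = 0.0;
  for (int o = 0; o < n_total; ++o) {
    const double ox = px[o], oy = py[o];
    int ca[4] = {0, 0, 0, 0};
    int cb[4] = {0, 0, 0, 0};
    for (int i = 0; i < n_total; ++i) {
      const double dx = px[i] - ox, dy = py[i] - oy;
      if (dx == 0.0 || dy == 0.0) continue;
      const int q = (dx > 0.0 ? 1 : 0) + (dy > 0.0 ? 2 : 0);
      if (lab[i] == 0) ++ca[q]; else ++cb[q];
    }
    for (int q = 0; q < 4; ++q) {
      const double diff = std::fabs((double)ca[q] / na - (double)cb[q] / nb);
      if (diff > D) D = diff;
    }
  }
  return D;
}

// [[Rcpp::export]]
double ks2d_stat_cpp(NumericVector ax, NumericVector ay,
                     NumericVector bx, NumericVector by) {
  const int na = ax.size(), nb = bx.size(), n = na + nb;
  std::vector<double> px(n), py(n);
  std::vector<int> lab(n);
  for (int i = 0; i < na; ++i) { px[i] = ax[i]; py[i] = ay[i]; lab[i] = 0; }
  for (int i = 0; i < nb; ++i) { px[na + i] = bx[i]; py[na + i] = by[i]; lab[na + i] = 1; }
  return ks2d_D(px.data(), py.data(), lab.data(), n, na, nb);
}

// Label-permutation null for the quadrant statistic. Uses R's RNG so that
// set.seed() on the R side fixes the permutation stream.
// [[Rcpp::export]]
List ks2d_perm_cpp(NumericVector ax, NumericVector ay,
                   NumericVector bx, NumericVector by, int n_perm) {
  const int na = ax.size(), nb = bx.size(), n = na + nb;
  std::vector<double> px(n), py(n);
  std::vector<int> lab(n);
  for (int i = 0; i < na; ++i) { px[i] = ax[i]; py[i] = ay[i]; lab[i] = 0; }
  for (int i = 0; i < nb; ++i) { px[na + i] = bx[i]; py[na + i] = by[i]; lab[na + i] = 1; }
  const double D_obs = ks2d_D(px.data(), py.data(), lab.data(), n, na, nb);

  std::vector<int> base(n);
  for (int i = 0; i < n; ++i) base[i] = (i < na) ? 0 : 1;
  std::vector<int> perm(n);
  int count_ge = 0;
  for (int p = 0; p < n_perm; ++p) {
    perm = base;
    // Fisher-Yates shuffle of the labels
    for (int i = n - 1; i > 0; --i) {
      const int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(perm[i], perm[j]);
    }
    const double Dp = ks2d_D(px.data(), py.data(), perm.data(), n, na, nb);
    if (Dp >= D_obs - 1e-12) ++count_ge;
  }
  return List::create(_["D"] = D_obs, _["count_ge"] = count_ge,
                      _["n_perm"] = n_perm);
}

// Fenwick tree over y-ranks holding signed sample weights.
struct Fenwick {
  std::vector<double> t;
  int n;
  void init(int n_) { n = n_; t.assign(n + 1, 0.0); }
  void clear() { std::fill(t.begin(), t.end(), 0.0); }
  void add(int i, double v) { for (; i <= n; i += i & (-i)) t[i] += v; }
  double pref(int i) const {
    double s = 0.0;
    for (; i > 0; i -= i & (-i)) s += t[i];
    return s;
  }
};

// O(N log N) evaluation of the quadrant statistic for tie-free data:
// two x-sweeps (descending and ascending) with a Fenwick tree over y-ranks
// give, for every origin, the signed weight sums of the four strict
// quadrants; D is the largest |sum|. z[i] = +1/na for sample a, -1/nb for b.
static double ks2d_D_sweep(const std::vector<int>& ord_desc,
                           const std::vector<int>& ry,
                           const std::vector<double>& px,
                           const std::vector<double>& z,
                           Fenwick& bit) {
  const int n = (int)ord_desc.size();
  double D = 0.0;
  for (int pass = 0; pass < 2; ++pass) {
    bit.clear();
    double total = 0.0;
    int ptr = 0;
    for (int i = 0; i < n; ++i) {
      // pass 0: descending order (inserted points have x > origin x);
      // pass 1: ascending (x < origin x)
      const int oi = pass == 0 ? ord_desc[i] : ord_desc[n - 1 - i];
      const double ox = px[oi];
      while (ptr < n) {
        const int pi = pass == 0 ? ord_desc[ptr] : ord_desc[n - 1 - ptr];
        const bool ins = pass == 0 ? (px[pi] > ox) : (px[pi] < ox);
        if (!ins) break;
        bit.add(ry[pi], z[pi]);
        total += z[pi];
        ++ptr;
      }
      const double below = bit.pref(ry[oi] - 1);
      const double above = total - bit.pref(ry[oi]);
      if (std::fabs(below) > D) D = std::fabs(below);
      if (std::fabs(above) > D) D = std::fabs(above);
    }
  }
  return D;
}

// [[Rcpp::export]]
List ks2d_perm_fast_cpp(NumericVector ax, NumericVector ay,
                        NumericVector bx, NumericVector by, int n_perm) {
  const int na = ax.size(), nb = bx.size(), n = na + nb;
  std::vector<double> px(n), py(n);
  for (int i = 0; i < na; ++i) { px[i] = ax[i]; py[i] = ay[i]; }
  for (int i = 0; i < nb; ++i) { px[na + i] = bx[i]; py[na + i] = by[i]; }

  std::vector<int> ord_desc(n), ord_y(n);
  for (int i = 0; i < n; ++i) ord_desc[i] = ord_y[i] = i;
  std::sort(ord_desc.begin(), ord_desc.end(),
            [&](int a, int b) { return px[a] > px[b]; });
  std::sort(ord_y.begin(), ord_y.end(),
            [&](int a, int b) { return py[a] < py[b]; });
  bool ties = false;
  for (int i = 1; i < n; ++i) {
    if (px[ord_desc[i]] == px[ord_desc[i - 1]] ||
        py[ord_y[i]] == py[ord_y[i - 1]]) { ties = true; break; }
  }
  if (ties) return ks2d_perm_cpp(ax, ay, bx, by, n_perm);

  std::vector<int> ry(n);
  for (int i = 0; i < n; ++i) ry[ord_y[i]] = i + 1;
  Fenwick bit;
  bit.init(n);

  const double wa = 1.0 / na, wb = -1.0 / nb;
  std::vector<double> z(n);
  for (int i = 0; i < n; ++i) z[i] = i < na ? wa : wb;
  const double D_obs = ks2d_D_sweep(ord_desc, ry, px, z, bit);

  std::vector<int> lab(n);
  for (int i = 0; i < n; ++i) lab[i] = i < na ? 0 : 1;
  int count_ge = 0;
  for (int p = 0; p < n_perm; ++p) {
    for (int i = n - 1; i > 0; --i) {
      const int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(lab[i], lab[j]);
    }
    for (int i = 0; i < n; ++i) z[i] = lab[i] == 0 ? wa : wb;
    const double Dp = ks2d_D_sweep(ord_desc, ry, px, z, bit);
    if (Dp >= D_obs - 1e-12) ++count_ge;
  }
  return List::create(_["D"] = D_obs, _["count_ge"] = count_ge,
                      _["n_perm"] = n_perm);
}

// Rolling-window Pearson correlation over consecutive blocks. Windows with
// any invalid pair or zero variance yield NA. Inputs are the block series,
// the window length in blocks and the step in blocks.
// [[Rcpp::export]]
NumericVector rolling_corr_cpp(NumericVector x, NumericVector y,
                               int n_samples, int step_blocks) {
  const int nb = x.size();
  const int n_win = (nb < n_samples) ? 0 : (nb - n_samples) / step_blocks + 1;
  NumericVector out(n_win, NA_REAL);
  for (int w = 0; w < n_win; ++w) {
    const int s = w * step_blocks;
    // two-pass centred accumulation: immune to cancellation when the
    // signal mean dwarfs its variance (e.g. ABP around 90 mmHg)
    double sx = 0, sy = 0;
    bool ok = true;
    for (int i = s; i < s + n_samples; ++i) {
      const double xi = x[i], yi = y[i];
      if (ISNAN(xi) || ISNAN(yi)) { ok = false; break; }
      sx += xi; sy += yi;
    }
    if (!ok) continue;
    const double mx_ = sx / n_samples, my_ = sy / n_samples;
    double vx = 0, vy = 0, vxy = 0;
    for (int i = s; i < s + n_samples; ++i) {
      const double dx = x[i] - mx_, dy = y[i] - my_;
      vx += dx * dx; vy += dy * dy; vxy += dx * dy;
    }
    if (vx <= 0.0 || vy <= 0.0) continue;
    out[w] = vxy / std::sqrt(vx * vy);
  }
  return out;
}
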