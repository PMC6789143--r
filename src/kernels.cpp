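#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exhaustive SAD block matching between two frames.
// Grid is floor(nrow/block) x floor(ncol/block); each block of `prev` is
// searched in `next` within +/- radius (clipped to the frame). Ties broken by
// smaller displacement magnitude, then by scan order (dy then dx, ascending).
// [[Rcpp::export]]
List cpp_block_match(NumericMatrix prev, NumericMatrix next_,
                     int block, int radius) {
  const int nr = prev.nrow(), nc = prev.ncol();
  const int gr = nr / block, gc = nc / block;
  IntegerMatrix dy(gr, gc), dx(gr, gc);
  for (int bi = 0; bi < gr; ++bi) {
    for (int bj = 0; bj < gc; ++bj) {
      const int r0 = bi * block, c0 = bj * block;
      double best = std::numeric_limits<double>::infinity();
      int best_dy = 0, best_dx = 0;
      double best_mag = std::numeric_limits<double>::infinity();
      for (int sy = -radius; sy <= radius; ++sy) {
        if (r0 + sy < 0 || r0 + sy + block > nr) continue;
        for (int sx = -radius; sx <= radius; ++sx) {
          if (c0 + sx < 0 || c0 + sx + block > nc) continue;
          double sad = 0.0;
          for (int j = 0; j < block; ++j) {
            const double *pa = &prev(r0, c0 + j);
            const double *pb = &next_(r0 + sy, c0 + sx + j);
            for (int i = 0; i < block; ++i)
              sad += std::fabs(pa[i] - pb[i]);
            if (sad >= best) break; // partial early exit; SAD only grows
          }
          const double mag = (double)(sy * sy + sx * sx);
          if (sad < best || (sad == best && mag < best_mag)) {
            best = sad; best_dy = sy; best_dx = sx; best_mag = mag;
          }
        }
      }
      dy(bi, bj) = best_dy;
      dx(bi, bj) = best_dx;
    }
  }
  return List::create(_["dy"] = dy, _["dx"] = dx);
}

// Smallest nonzero and largest pairwise Euclidean distance of the rows of X.
// [[Rcpp::export]]
NumericVector cpp_pair_minmax(NumericMatrix X) {
  const int n = X.nrow(), m = X.ncol();
  double mn = std::numeric_limits<double>::infinity(), mx = 0.0;
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < i; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double d = X(i, k) - X(j, k);
        d2 += d * d;
      }
      if (d2 > mx) mx = d2;
      if (d2 > 0.0 && d2 < mn) mn = d2;
    }
  }
  if (!std::isfinite(mn)) mn = 0.0; // all points identical
  return NumericVector::create(std::sqrt(mn), std::sqrt(mx));
}

// Count pairs with distance <= each edge (edges ascending). A pair below the
// first edge counts into bin 0. Returns cumulative counts per edge.
// [[Rcpp::export]]
NumericVector cpp_pair_counts(NumericMatrix X, NumericVector edges) {
  const int n = X.nrow(), m = X.ncol(), nb = edges.size();
  std::vector<double> hist(nb, 0.0);
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < i; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double d = X(i, k) - X(j, k);
        d2 += d * d;
      }
      // compare on the distance itself, not its square: the bin edges are
      // sqrt()s of accumulated squares, and squaring them back loses the
      // last bit, misplacing pairs that sit exactly on r_min/r_max
      const double dd = std::sqrt(d2);
      // first edge with edge >= dd
      int lo = 0, hi = nb;
      while (lo < hi) {
        const int mid = (lo + hi) / 2;
        if (edges[mid] >= dd) hi = mid; else lo = mid + 1;
      }
      if (lo < nb) hist[lo] += 1.0;
      // d2 beyond the last edge (possible only through rounding): dropped
    }
  }
  NumericVector out(nb);
  double acc = 0.0;
  for (int b = 0; b < nb; ++b) { acc += hist[b]; out[b] = acc; }
  return out;
}

// Kennel false-nearest-neighbour fractions for m = 1..m_max.
// S is the scalar series, tau the delay. For each m the points
// x_i = (S_i, S_{i+tau}, ..., S_{i+(m-1)tau}), i = 1..N-m*tau, are lifted to
// m+1 dimensions; a nearest neighbour is false when the extra-coordinate
// ratio exceeds rtol or the lifted distance exceeds atol * sd(S).
// [[Rcpp::export]]
NumericVector cpp_fnn_fractions(NumericVector S, int tau, int m_max,
                                double rtol, double atol) {
  const int N = S.size();
  double mu = 0.0;
  for (int i = 0; i < N; ++i) mu += S[i];
  mu /= N;
  double v = 0.0;
  for (int i = 0; i < N; ++i) v += (S[i] - mu) * (S[i] - mu);
  const double sigma = std::sqrt(v / (N - 1));
  NumericVector frac(m_max, NA_REAL);
  for (int m = 1; m <= m_max; ++m) {
    const int n = N - m * tau; // points that also exist in m+1 dims
    if (n < 2) break;
    long false_n = 0, total = 0;
    for (int i = 0; i < n; ++i) {
      double best = std::numeric_limits<double>::infinity();
      int nn = -1;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double d2 = 0.0;
        for (int k = 0; k < m; ++k) {
          const double d = S[i + k * tau] - S[j + k * tau];
          d2 += d * d;
          if (d2 >= best) break;
        }
        if (d2 < best) { best = d2; nn = j; }
      }
      if (nn < 0) continue;
      const double Rm = std::sqrt(best);
      const double extra = std::fabs(S[i + m * tau] - S[nn + m * tau]);
      bool is_false;
      if (Rm == 0.0) {
        is_false = extra > 0.0;
      } else {
        const double R1 = std::sqrt(best + extra * extra);
        is_false = (extra / Rm > rtol) || (sigma > 0.0 && R1 / sigma > atol);
      }
      ++total;
      if (is_false) ++false_n;
    }
    frac[m - 1] = total > 0 ? (double)false_n / total : NA_REAL;
  }
  return frac;
}
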