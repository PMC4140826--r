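// Base-pair probability matrix by a McCaskill-style inside-outside
// partition function over a simple energy model: every canonical or wobble
// pair (AU, UA, GC, CG, GU, UG) contributes the same Boltzmann factor
// `pair_weight`, hairpin loops have at least `min_loop` unpaired bases,
// there are no dangles or loop-type terms. Structures are counted through
// the unambiguous decomposition that conditions on the pairing partner of
// the segment's last base, so every structure is generated exactly once.
//
// Partition-function values are rescaled per nucleotide (Z(i,j)/scale^len)
// to keep doubles in range; the scale is adjusted and the computation
// retried on overflow or underflow.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// bases coded 0=A, 1=C, 2=G, 3=U
static inline bool can_pair(int a, int b) {
  switch (a * 4 + b) {
  case 0 * 4 + 3: case 3 * 4 + 0:  // AU, UA
  case 1 * 4 + 2: case 2 * 4 + 1:  // CG, GC
  case 2 * 4 + 3: case 3 * 4 + 2:  // GU, UG
    return true;
  default:
    return false;
  }
}

// [[Rcpp::export]]
NumericMatrix bpp_matrix_cpp(IntegerVector seq_codes, double pair_weight,
                             int min_loop) {
  const int n = seq_codes.size();
  NumericMatrix P(n, n);
  if (n == 0) return P;
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = seq_codes[i];
    if (s[i] < 0 || s[i] > 3) stop("sequence codes must be in 0..3");
  }

  double scale = std::pow(std::max(pair_weight, 1.0), 1.0 / 3.0) + 0.5;
  const int max_try = 16;
  for (int attempt = 0; attempt < max_try; ++attempt) {
    std::vector<double> Z((size_t)n * n, 0.0), Zb((size_t)n * n, 0.0);
    std::vector<double> O((size_t)n * n, 0.0), Ob((size_t)n * n, 0.0);
    auto idx = [n](int i, int j) { return (size_t)i * n + j; };
    auto getZ = [&](int i, int j) -> double {
      return (i > j) ? 1.0 : Z[idx(i, j)];
    };
    const double wss = pair_weight / (scale * scale);
    bool ok = true;

    // inside pass, increasing span
    for (int len = 1; len <= n && ok; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        if (j - i > min_loop && can_pair(s[i], s[j]))
          Zb[idx(i, j)] = wss * getZ(i + 1, j - 1);
        double z = getZ(i, j - 1) / scale;  // last base unpaired
        for (int k = i; k <= j - min_loop - 1; ++k) {
          double zb = Zb[idx(k, j)];
          if (zb != 0.0) z += getZ(i, k - 1) * zb;  // last base pairs k
        }
        Z[idx(i, j)] = z;
        if (!std::isfinite(z)) { ok = false; break; }
      }
    }
    double Ztot = getZ(0, n - 1);
    if (!ok || !std::isfinite(Ztot)) { scale *= 1.5; continue; }
    if (Ztot <= 0.0) { scale /= 1.5; continue; }

    // outside pass, decreasing span
    O[idx(0, n - 1)] = 1.0;
    for (int len = n; len >= 1; --len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        double o = O[idx(i, j)];
        if (o == 0.0) continue;
        if (j - 1 >= i) O[idx(i, j - 1)] += o / scale;
        for (int k = i; k <= j - min_loop - 1; ++k) {
          double zb = Zb[idx(k, j)];
          if (zb == 0.0) continue;
          Ob[idx(k, j)] += o * getZ(i, k - 1);
          if (k - 1 >= i) O[idx(i, k - 1)] += o * zb;
        }
      }
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        double ob = Ob[idx(i, j)];
        if (ob != 0.0 && Zb[idx(i, j)] != 0.0)
          O[idx(i + 1, j - 1)] += ob * wss;  // interior nonempty (min_loop)
      }
    }

    bool fin = true;
    for (int i = 0; i < n && fin; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double zb = Zb[idx(i, j)];
        double p = (zb == 0.0) ? 0.0 : zb * Ob[idx(i, j)] / Ztot;
        if (!std::isfinite(p)) { fin = false; break; }
        P(i, j) = p;
        P(j, i) = p;
      }
    }
    if (!fin) { scale *= 1.5; continue; }
    return P;
  }
  stop("partition function over/underflowed repeatedly; "
       "sequence too long for the folding engine");
  return P;  // not reached
}
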