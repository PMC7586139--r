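#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Simplified-ESOM training core.
//
// Cell order is row-major: cell k (0-based) sits at line k / C, column k % C
// (0-based), matching the R-side cell_index(). The BMU search uses a strict
// "<" over ascending k, which realises the smallest-(line, column)
// lexicographic tie-break. metric: 0 = Euclidean, 1 = Manhattan.
//
// [[Rcpp::export]]
NumericMatrix sesom_train_cpp(const NumericMatrix& data,
                              NumericMatrix weights,
                              const int L, const int C,
                              const NumericVector& radii,
                              const IntegerMatrix& orders,
                              const IntegerVector& reset_cells,
                              const NumericMatrix& reset_means,
                              const int metric) {
  const int n = data.nrow(), d = data.ncol(), nc = L * C;
  NumericMatrix W = clone(weights);

  for (int step = 0; step < radii.size(); ++step) {
    const double R = radii[step];
    const double cutoff = M_PI * (R * R);  // h > 0 iff grid d^2 < cutoff

    for (int t = 0; t < n; ++t) {
      const int j = orders(t, step);

      // global BMU search over all prototypes
      int bmu = 0;
      double best = R_PosInf;
      for (int k = 0; k < nc; ++k) {
        double acc = 0.0;
        for (int c = 0; c < d; ++c) {
          const double diff = data(j, c) - W(k, c);
          acc += (metric == 0) ? diff * diff : std::fabs(diff);
          if (acc >= best) break;
        }
        if (acc < best) { best = acc; bmu = k; }
      }
      const int bl = bmu / C, bc = bmu % C;

      // neighbourhood pull: w <- w + h * (x - w)
      for (int k = 0; k < nc; ++k) {
        int dl = std::abs(k / C - bl); dl = std::min(dl, L - dl);
        int dc = std::abs(k % C - bc); dc = std::min(dc, C - dc);
        const double d2 = (double)dl * dl + (double)dc * dc;
        if (d2 < cutoff) {
          const double h = 1.0 - d2 / cutoff;
          for (int c = 0; c < d; ++c)
            W(k, c) += h * (data(j, c) - W(k, c));
        }
      }
    }

    // reset predefined prototypes to their data (means) after the sweep
    for (int r = 0; r < reset_cells.size(); ++r)
      for (int c = 0; c < d; ++c)
        W(reset_cells[r], c) = reset_means(r, c);
  }
  return W;
}

// Brute-force U-heights on the torus: mean input-space distance between each
// prototype and its eight Moore neighbours.
//
// [[Rcpp::export]]
NumericMatrix uheights_cpp(const NumericMatrix& W, const int L, const int C,
                           const int metric) {
  const int d = W.ncol();
  NumericMatrix U(L, C);
  for (int l = 0; l < L; ++l) {
    for (int c = 0; c < C; ++c) {
      const int k = l * C + c;
      double acc = 0.0;
      for (int dl = -1; dl <= 1; ++dl) {
        for (int dc = -1; dc <= 1; ++dc) {
          if (dl == 0 && dc == 0) continue;
          const int nl = (l + dl + L) % L, ncol = (c + dc + C) % C;
          const int kn = nl * C + ncol;
          double dist = 0.0;
          for (int cc = 0; cc < d; ++cc) {
            const double diff = W(k, cc) - W(kn, cc);
            dist += (metric == 0) ? diff * diff : std::fabs(diff);
          }
          acc += (metric == 0) ? std::sqrt(dist) : dist;
        }
      }
      U(l, c) = acc / 8.0;
    }
  }
  return U;
}
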