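#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Capacity-adjusted power-diagram tessellation with Lloyd relaxation on a
// pixel raster. Pixels are assigned to the seed minimising the power distance
// |p - s_i|^2 - w_i; seed positions move to cell centroids for the first
// `lloydIters` iterations and weights adapt throughout so realised pixel
// areas approach the requested target areas. `group` restricts assignment:
// a pixel of group g may only be claimed by seeds of group g (used to keep
// the placode boundary exactly on the placode disk when a surrounding
// epithelium is tessellated in the same pass).
//
// After the first full scan each pixel only competes among the previously
// assigned seed and its nearest neighbouring seeds (power-diagram boundaries
// only move between spatial neighbours), which keeps the per-iteration cost
// near-linear in pixel count. The final iteration re-runs a full scan.
// All loops are deterministic; identical inputs give identical output.
// [[Rcpp::export(name = ".powerDiagram")]]
List powerDiagram(NumericVector px, NumericVector py, IntegerVector pgroup,
                  NumericMatrix seeds, IntegerVector sgroup,
                  NumericVector target, double pixArea,
                  int nIter, int lloydIters, double eta, int nNeighbors = 24) {
  const int m = px.size();
  const int n = seeds.nrow();
  NumericVector sx(n), sy(n), w(n, 0.0);
  for (int i = 0; i < n; ++i) { sx[i] = seeds(i, 0); sy[i] = seeds(i, 1); }
  IntegerVector assign(m, -1);
  NumericVector area(n), cx(n), cy(n);
  std::vector<int> cnt(n);
  const int k = std::min(nNeighbors, n);
  std::vector<int> nbr((size_t)n * k);
  std::vector<std::pair<double, int> > ord(n);

  for (int it = 0; it < nIter; ++it) {
    const bool full = (it == 0) || (it == nIter - 1);
    if (!full) {
      // k nearest seeds (same group first by distance; self included)
      for (int i = 0; i < n; ++i) {
        for (int j = 0; j < n; ++j) {
          const double dx = sx[i] - sx[j], dy = sy[i] - sy[j];
          double d = dx * dx + dy * dy;
          if (sgroup[j] != sgroup[i]) d += 1e18; // other group: never useful
          ord[j] = std::make_pair(d, j);
        }
        std::partial_sort(ord.begin(), ord.begin() + k, ord.end());
        for (int j = 0; j < k; ++j) nbr[(size_t)i * k + j] = ord[j].second;
      }
    }
    std::fill(cnt.begin(), cnt.end(), 0);
    std::fill(cx.begin(), cx.end(), 0.0);
    std::fill(cy.begin(), cy.end(), 0.0);
    for (int j = 0; j < m; ++j) {
      double best = R_PosInf;
      int bi = -1;
      const int g = pgroup[j];
      if (full || assign[j] < 0) {
        for (int i = 0; i < n; ++i) {
          if (sgroup[i] != g) continue;
          const double dx = px[j] - sx[i], dy = py[j] - sy[i];
          const double d = dx * dx + dy * dy - w[i];
          if (d < best) { best = d; bi = i; }
        }
      } else {
        const int a = assign[j];
        const int *cand = &nbr[(size_t)a * k];
        for (int c = 0; c < k; ++c) {
          const int i = cand[c];
          if (sgroup[i] != g) continue;
          const double dx = px[j] - sx[i], dy = py[j] - sy[i];
          const double d = dx * dx + dy * dy - w[i];
          if (d < best) { best = d; bi = i; }
        }
      }
      assign[j] = bi;
      cnt[bi]++;
      cx[bi] += px[j];
      cy[bi] += py[j];
    }
    for (int i = 0; i < n; ++i) {
      area[i] = cnt[i] * pixArea;
      if (cnt[i] > 0) { cx[i] /= cnt[i]; cy[i] /= cnt[i]; }
      else { cx[i] = sx[i]; cy[i] = sy[i]; }
    }
    if (it == nIter - 1) break;
    if (it < lloydIters) {
      for (int i = 0; i < n; ++i) { sx[i] = cx[i]; sy[i] = cy[i]; }
    }
    // capacity step: grow under-sized cells, shrink over-sized ones; an
    // empty cell gets a full-target boost so it re-acquires territory
    for (int i = 0; i < n; ++i) {
      double adj = eta * (target[i] - area[i]);
      if (cnt[i] == 0) adj = eta * target[i];
      w[i] += adj;
    }
  }

  NumericMatrix outSeeds(n, 2), centroids(n, 2);
  for (int i = 0; i < n; ++i) {
    outSeeds(i, 0) = sx[i]; outSeeds(i, 1) = sy[i];
    centroids(i, 0) = cx[i]; centroids(i, 1) = cy[i];
  }
  return List::create(_["assign"] = assign, _["area"] = area,
                      _["seeds"] = outSeeds, _["centroids"] = centroids,
                      _["weights"] = w);
}

// Mean pairwise Euclidean distance over the rows of a coordinate matrix.
// [[Rcpp::export(name = ".meanPairwiseDist")]]
double meanPairwiseDist(NumericMatrix xy) {
  const int n = xy.nrow();
  if (n < 2) return NA_REAL;
  double s = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = xy(i, 0) - xy(j, 0);
      const double dy = xy(i, 1) - xy(j, 1);
      s += std::sqrt(dx * dx + dy * dy);
    }
  return s / (n * (n - 1) / 2.0);
}
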