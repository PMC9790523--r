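#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  double mag;
  int idx;
};

// max-heap by magnitude; ties broken towards the lower linear index so the
// growth order (and hence the result) is fully deterministic
struct NodeCmp {
  bool operator()(const Node &a, const Node &b) const {
    if (a.mag != b.mag) return a.mag < b.mag;
    return a.idx > b.idx;
  }
};

} // namespace

// Magnitude-guided region growing over per-voxel field-map candidates.
// Each voxel offers two candidate off-resonance values (Hz), defined up to
// the aliasing period 1/dTE; the grower visits voxels in decreasing
// magnitude order starting from seedIdx and assigns the candidate (over
// both roots and aliases k in {-1,0,1}) closest to the mean of already
// resolved 6-neighbours. The seed uses reference 0 Hz. Voxels below
// magThreshold, or with undefined candidates, inherit the neighbour mean.
// [[Rcpp::export]]
NumericVector regionGrowSelect(NumericVector cand1, NumericVector cand2,
                               NumericVector mag, IntegerVector dims,
                               double magThreshold, double aliasPeriod,
                               int seedIdx) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (cand1.size() != n || cand2.size() != n || mag.size() != n)
    stop("candidate/magnitude arrays do not match the grid");
  if (seedIdx < 0 || seedIdx >= n) stop("seed index out of range");

  NumericVector psi(n, NA_REAL);
  std::vector<char> resolved(n, 0), queued(n, 0);
  std::priority_queue<Node, std::vector<Node>, NodeCmp> pq;
  pq.push({mag[seedIdx], seedIdx});
  queued[seedIdx] = 1;

  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};

  while (!pq.empty()) {
    const Node nd = pq.top();
    pq.pop();
    const int idx = nd.idx;
    if (resolved[idx]) continue;
    const int k = idx / (nx * ny);
    const int rem = idx % (nx * ny);
    const int j = rem / nx;
    const int i = rem % nx;

    double sum = 0.0;
    int cnt = 0;
    int nbrs[6];
    int nnb = 0;
    for (int t = 0; t < 6; ++t) {
      const int ii = i + dxs[t], jj = j + dys[t], kk = k + dzs[t];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      const int nb = ii + nx * (jj + ny * kk);
      nbrs[nnb++] = nb;
      if (resolved[nb]) {
        sum += psi[nb];
        ++cnt;
      }
    }
    const double ref = (cnt > 0) ? sum / cnt : 0.0;

    double best = ref;
    const double c1 = cand1[idx], c2 = cand2[idx];
    const bool usable = (mag[idx] >= magThreshold) &&
                        !NumericVector::is_na(c1) &&
                        !NumericVector::is_na(c2);
    if (usable) {
      double bd = R_PosInf;
      const double cs[2] = {c1, c2};
      for (int ci = 0; ci < 2; ++ci) {
        for (int a = -1; a <= 1; ++a) {
          const double v = cs[ci] + a * aliasPeriod;
          const double d = std::fabs(v - ref);
          if (d < bd) {
            bd = d;
            best = v;
          }
        }
      }
    }
    psi[idx] = best;
    resolved[idx] = 1;
    for (int t = 0; t < nnb; ++t) {
      const int nb = nbrs[t];
      if (!queued[nb]) {
        queued[nb] = 1;
        pq.push({mag[nb], nb});
      }
    }
  }
  return psi;
}
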