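#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Priority-flood depression filling. Cells are flooded inward from the
// grid edge (and from cells bordering nodata, which drain off-analysis)
// in order of increasing elevation; a cell lower than the flood level is
// raised to level + eps, which leaves a defined descent direction across
// filled flats when eps > 0.
// [[Rcpp::export]]
NumericMatrix cpp_fill_sinks(NumericMatrix dem, double eps) {
  const int nr = dem.nrow(), nc = dem.ncol();
  NumericMatrix out(nr, nc);
  std::vector<bool> done(static_cast<size_t>(nr) * nc, false);
  typedef std::pair<double, int> Cell; // (elevation, flat index r + c*nr)
  std::priority_queue<Cell, std::vector<Cell>, std::greater<Cell> > pq;

  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = dem(r, c);

  // seed: edge cells and cells adjacent to nodata
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (NumericMatrix::is_na(dem(r, c))) { done[r + c * nr] = true; continue; }
      bool seed = (r == 0 || r == nr - 1 || c == 0 || c == nc - 1);
      if (!seed) {
        for (int dr = -1; dr <= 1 && !seed; ++dr)
          for (int dc = -1; dc <= 1 && !seed; ++dc)
            if (NumericMatrix::is_na(dem(r + dr, c + dc))) seed = true;
      }
      if (seed) {
        pq.push(Cell(dem(r, c), r + c * nr));
        done[r + c * nr] = true;
      }
    }
  }
  if (pq.empty()) stop("fill_sinks: no non-nodata cells to drain");

  while (!pq.empty()) {
    Cell top = pq.top(); pq.pop();
    int idx = top.second;
    int r = idx % nr, c = idx / nr;
    double level = out(r, c);
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int nidx = rr + cc * nr;
        if (done[nidx]) continue;
        done[nidx] = true;
        double z = dem(rr, cc);
        if (z < level + eps) z = level + eps;
        out(rr, cc) = z;
        pq.push(Cell(z, nidx));
      }
    }
  }
  return out;
}

// Sequential chamfer distance transform with the 5x5 mask (axial, diagonal
// and knight moves at exact Euclidean step lengths 1, sqrt2, sqrt5 cell
// units). `acc` arrives initialised to the sentinel everywhere except the
// destination cells (0). Cost is per-cell traversal seconds; moving between
// two cells costs step_length * (t_a + t_b) / 2. Cells with cost >= sentinel
// or NA are hard barriers and are never entered or left; knight moves are
// additionally disallowed when either cell flanking their midpoint is a
// barrier, so a one-cell-thick barrier line cannot be jumped.
//
// One call performs `scan_pairs` quartets of scans: row-major forward and
// backward, then column-major forward and backward (the four scans of the
// transform). With converge = true, quartets repeat until no cell changes.
// [[Rcpp::export]]
List cpp_chamfer(NumericMatrix cost, NumericMatrix acc, double sentinel,
                 int scan_pairs, bool converge) {
  const int nr = cost.nrow(), nc = cost.ncol();
  static const int DR[16] = {-1, 1, 0, 0, -1, -1, 1, 1, -2, -2, -1, -1, 1, 1, 2, 2};
  static const int DC[16] = {0, 0, -1, 1, -1, 1, -1, 1, -1, 1, -2, 2, -2, 2, -1, 1};
  // midpoint-flanking cells of each knight move (first 8 moves have none)
  static const int M1R[16] = {0,0,0,0,0,0,0,0, -1,-1, 0, 0, 0, 0, 1, 1};
  static const int M1C[16] = {0,0,0,0,0,0,0,0,  0, 0,-1, 1,-1, 1, 0, 0};
  static const int M2R[16] = {0,0,0,0,0,0,0,0, -1,-1,-1,-1, 1, 1, 1, 1};
  static const int M2C[16] = {0,0,0,0,0,0,0,0, -1, 1,-1, 1,-1, 1,-1, 1};
  static const double DD[16] = {1, 1, 1, 1, M_SQRT2, M_SQRT2, M_SQRT2, M_SQRT2,
                                2.2360679774997896, 2.2360679774997896,
                                2.2360679774997896, 2.2360679774997896,
                                2.2360679774997896, 2.2360679774997896,
                                2.2360679774997896, 2.2360679774997896};
  NumericMatrix out = clone(acc);

  std::vector<bool> passable(static_cast<size_t>(nr) * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      passable[r + c * nr] = !NumericMatrix::is_na(cost(r, c)) &&
                             cost(r, c) < sentinel;

  long changed_total = 0;
  int quartets = 0;
  bool any_change = true;
  while (any_change && (converge || quartets < scan_pairs)) {
    any_change = false;
    for (int scan = 0; scan < 4; ++scan) {
      // scan 0: rows top->bottom, cols left->right (row-major forward)
      // scan 1: row-major backward; scans 2/3: column-major fwd/back
      const bool colmajor = scan >= 2;
      const bool backward = (scan % 2) == 1;
      const int outerN = colmajor ? nc : nr;
      const int innerN = colmajor ? nr : nc;
      for (int oi = 0; oi < outerN; ++oi) {
        const int o = backward ? outerN - 1 - oi : oi;
        for (int ii = 0; ii < innerN; ++ii) {
          const int i = backward ? innerN - 1 - ii : ii;
          const int r = colmajor ? i : o;
          const int c = colmajor ? o : i;
          if (!passable[r + c * nr]) continue;
          double best = out(r, c);
          const double tc = cost(r, c);
          for (int k = 0; k < 16; ++k) {
            const int rr = r + DR[k], cc = c + DC[k];
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (!passable[rr + cc * nr]) continue;
            if (k >= 8) {
              const int m1r = r + M1R[k], m1c = c + M1C[k];
              const int m2r = r + M2R[k], m2c = c + M2C[k];
              if (!passable[m1r + m1c * nr] || !passable[m2r + m2c * nr])
                continue;
            }
            const double nv = out(rr, cc);
            if (nv >= sentinel) continue;
            const double cand = nv + DD[k] * (tc + cost(rr, cc)) / 2.0;
            if (cand < best) best = cand;
          }
          if (best < out(r, c)) {
            out(r, c) = best;
            any_change = true;
            ++changed_total;
          }
        }
      }
    }
    ++quartets;
    if (!converge && quartets >= scan_pairs) break;
  }
  return List::create(_["acc"] = out, _["quartets"] = quartets,
                      _["changed"] = changed_total);
}
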