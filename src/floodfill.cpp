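#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Wrap a phase difference into (-pi, pi].
static inline double wrapd(double x) {
  double w = x - 2.0 * M_PI * std::round(x / (2.0 * M_PI));
  if (w <= -M_PI) w += 2.0 * M_PI;
  return w;
}

// Goldstein flood-fill unwrapping over an arbitrary (sub)frame.
//
// Breadth-first propagation with 4-connectivity from the first non-cut pixel
// in row-major order (seeded at its wrapped value); each pixel is unwrapped
// from the neighbour that reached it via phi = phi_nb + wrap(psi - psi_nb).
// Pixels on branch cuts are never used as references: they are assigned last
// from any unwrapped non-cut neighbour (then, if still unreached, from
// assigned cut neighbours) but do not propagate. Disconnected non-cut
// components are each seeded independently at their own wrapped value.
//
// psi:  wrapped phase matrix (radians)
// cuts: logical matrix, TRUE where a pixel lies on a branch cut
// [[Rcpp::export]]
NumericMatrix cpp_floodfill(NumericMatrix psi, LogicalMatrix cuts) {
  const int nr = psi.nrow(), nc = psi.ncol(), n = nr * nc;
  if (cuts.nrow() != nr || cuts.ncol() != nc)
    stop("psi and cuts must have the same shape");
  NumericMatrix phi(nr, nc);
  std::vector<char> done(n, 0);
  // neighbour visit order: up, down, left, right (row-major storage)
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  bool any_noncut = false;
  std::queue<int> q;
  // row-major scan for seeds; each unvisited non-cut component gets one
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int idx = c * nr + r;
      if (cuts(r, c) || done[idx]) continue;
      any_noncut = true;
      phi(r, c) = psi(r, c);
      done[idx] = 1;
      q.push(idx);
      while (!q.empty()) {
        int cur = q.front(); q.pop();
        int cr = cur % nr, cc = cur / nr;
        for (int k = 0; k < 4; ++k) {
          int r2 = cr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int i2 = c2 * nr + r2;
          if (done[i2] || cuts(r2, c2)) continue;
          phi(r2, c2) = phi(cr, cc) + wrapd(psi(r2, c2) - psi(cr, cc));
          done[i2] = 1;
          q.push(i2);
        }
      }
    }
  }
  if (!any_noncut) stop("no seed available: all pixels lie on branch cuts");

  // assign cut pixels from any already-assigned neighbour; iterate so that
  // chains of cut pixels resolve (they still never serve as references for
  // non-cut pixels, which are all done by now)
  bool progress = true;
  while (progress) {
    progress = false;
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        int idx = c * nr + r;
        if (done[idx]) continue;
        for (int k = 0; k < 4; ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (!done[c2 * nr + r2]) continue;
          phi(r, c) = phi(r2, c2) + wrapd(psi(r, c) - psi(r2, c2));
          done[idx] = 1;
          progress = true;
          break;
        }
      }
    }
  }
  return phi;
}
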