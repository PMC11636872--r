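#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <deque>
using namespace Rcpp;

// SLIC superpixel segmentation on a CIE-Lab image.
//
// Grid-seeded k-means in the joint [L, a, b, x/S*m, y/S*m] space, restricted
// to a 2S x 2S search window around each cluster center, followed by a
// connectivity-enforcement pass that floods connected components and merges
// fragments smaller than S^2/4 into an adjacent component. Deterministic:
// seeding is a regular grid and ties are resolved by scan order.
//
// L, a, b: H x W matrices; n_segments: requested superpixel count;
// compactness: spatial regularization weight m; n_iter: k-means sweeps.
// Returns an IntegerMatrix of labels in 0..k-1.
// [[Rcpp::export(name = ".slic_cpp")]]
IntegerMatrix slic_cpp(NumericMatrix L, NumericMatrix a, NumericMatrix b,
                       int n_segments, double compactness, int n_iter) {
  const int H = L.nrow(), W = L.ncol();
  const int npix = H * W;
  const double S = std::sqrt((double)npix / (double)n_segments);

  // grid seeding at spacing ~S, offset S/2
  std::vector<double> cL, ca, cb, cx, cy;
  int gy = std::max(1, (int)std::lround((double)H / S));
  int gx = std::max(1, (int)std::lround((double)W / S));
  for (int iy = 0; iy < gy; ++iy) {
    for (int ix = 0; ix < gx; ++ix) {
      double y = (iy + 0.5) * (double)H / gy;
      double x = (ix + 0.5) * (double)W / gx;
      int yi = std::min(H - 1, (int)y), xi = std::min(W - 1, (int)x);
      cy.push_back(y); cx.push_back(x);
      cL.push_back(L(yi, xi)); ca.push_back(a(yi, xi)); cb.push_back(b(yi, xi));
    }
  }
  const int k = (int)cx.size();
  std::vector<int> lab(npix, -1);
  std::vector<double> dist(npix);
  const double invS2m2 = (compactness * compactness) / (S * S);

  for (int it = 0; it < n_iter; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int c = 0; c < k; ++c) {
      int y0 = std::max(0, (int)std::floor(cy[c] - S)),
          y1 = std::min(H - 1, (int)std::ceil(cy[c] + S)),
          x0 = std::max(0, (int)std::floor(cx[c] - S)),
          x1 = std::min(W - 1, (int)std::ceil(cx[c] + S));
      for (int x = x0; x <= x1; ++x) {
        for (int y = y0; y <= y1; ++y) {
          int p = x * H + y; // column-major
          double px = x + 0.5, py = y + 0.5;
          double dc = (L[p] - cL[c]) * (L[p] - cL[c]) +
                      (a[p] - ca[c]) * (a[p] - ca[c]) +
                      (b[p] - cb[c]) * (b[p] - cb[c]);
          double ds = (px - cx[c]) * (px - cx[c]) + (py - cy[c]) * (py - cy[c]);
          double D = dc + ds * invS2m2;
          if (D < dist[p]) { dist[p] = D; lab[p] = c; }
        }
      }
    }
    // update centers
    std::vector<double> sL(k, 0), sa(k, 0), sb(k, 0), sx(k, 0), sy(k, 0);
    std::vector<int> cnt(k, 0);
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        int p = x * H + y, c = lab[p];
        if (c < 0) continue;
        sL[c] += L[p]; sa[c] += a[p]; sb[c] += b[p];
        sx[c] += x + 0.5; sy[c] += y + 0.5; cnt[c]++;
      }
    }
    for (int c = 0; c < k; ++c) {
      if (cnt[c] == 0) continue; // orphan center keeps its position
      cL[c] = sL[c] / cnt[c]; ca[c] = sa[c] / cnt[c]; cb[c] = sb[c] / cnt[c];
      cx[c] = sx[c] / cnt[c]; cy[c] = sy[c] / cnt[c];
    }
  }
  // any pixel missed by every window (possible for extreme aspect ratios):
  // assign to nearest seeded grid cell spatially
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int p = x * H + y;
      if (lab[p] >= 0) continue;
      double best = R_PosInf; int bc = 0;
      for (int c = 0; c < k; ++c) {
        double ds = (x + 0.5 - cx[c]) * (x + 0.5 - cx[c]) +
                    (y + 0.5 - cy[c]) * (y + 0.5 - cy[c]);
        if (ds < best) { best = ds; bc = c; }
      }
      lab[p] = bc;
    }

  // connectivity enforcement: flood 4-connected components in scan order,
  // merge components smaller than min_size into the previously labelled
  // neighbour component
  const int min_size = std::max(1, (int)(S * S / 4.0));
  std::vector<int> newlab(npix, -1);
  int nlab = 0;
  const int dx[4] = {1, -1, 0, 0}, dy[4] = {0, 0, 1, -1};
  std::vector<int> comp;
  comp.reserve(npix);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int p = x * H + y;
      if (newlab[p] >= 0) continue;
      int adj = -1; // an adjacent, already-relabelled component
      comp.clear();
      comp.push_back(p);
      newlab[p] = nlab;
      for (size_t qi = 0; qi < comp.size(); ++qi) {
        int q = comp[qi];
        int qx = q / H, qy = q % H;
        for (int d = 0; d < 4; ++d) {
          int nx = qx + dx[d], ny = qy + dy[d];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          int np = nx * H + ny;
          if (newlab[np] >= 0 && newlab[np] != nlab) {
            adj = newlab[np];
          } else if (newlab[np] < 0 && lab[np] == lab[p]) {
            newlab[np] = nlab;
            comp.push_back(np);
          }
        }
      }
      if ((int)comp.size() < min_size && adj >= 0) {
        for (int q : comp) newlab[q] = adj;
      } else {
        nlab++;
      }
    }
  }
  // compact to 0..k-1 (merging can leave gaps)
  std::vector<int> remap(nlab, -1);
  int kk = 0;
  IntegerMatrix out(H, W);
  for (int p = 0; p < npix; ++p) {
    int c = newlab[p];
    if (remap[c] < 0) remap[c] = kk++;
  }
  for (int p = 0; p < npix; ++p) out[p] = remap[newlab[p]];
  return out;
}

// Label connected components of a binary matrix.
// connectivity: 4 or 8. Background (0) pixels get label 0; components 1..n.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix out(H, W);
  std::fill(out.begin(), out.end(), 0);
  int nlab = 0;
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int nd = (connectivity == 8) ? 8 : 4;
  std::deque<int> queue;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int p = x * H + y;
      if (mask[p] == 0 || out[p] != 0) continue;
      ++nlab;
      out[p] = nlab;
      queue.push_back(p);
      while (!queue.empty()) {
        int q = queue.front(); queue.pop_front();
        int qx = q / H, qy = q % H;
        for (int d = 0; d < nd; ++d) {
          int nx = qx + dx8[d], ny = qy + dy8[d];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          int np = nx * H + ny;
          if (mask[np] != 0 && out[np] == 0) { out[np] = nlab; queue.push_back(np); }
        }
      }
    }
  }
  return out;
}
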