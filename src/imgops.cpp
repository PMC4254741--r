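#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 2-D convolution with reflected (mirror) border handling.
// Kernel dimensions must be odd. Output has the same size as the image.
// [[Rcpp::export]]
NumericMatrix conv2_reflect_cpp(NumericMatrix img, NumericMatrix kernel) {
  int nr = img.nrow(), nc = img.ncol();
  int kr = kernel.nrow(), kc = kernel.ncol();
  if (kr % 2 == 0 || kc % 2 == 0)
    stop("kernel dimensions must be odd");
  int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int kj = -hc; kj <= hc; ++kj) {
        int cj = j + kj;
        // reflect without repeating the border pixel (scipy 'mirror' / R convention)
        if (cj < 0) cj = -cj;
        if (cj >= nc) cj = 2 * nc - 2 - cj;
        for (int ki = -hr; ki <= hr; ++ki) {
          int ci = i + ki;
          if (ci < 0) ci = -ci;
          if (ci >= nr) ci = 2 * nr - 2 - ci;
          // convolution (kernel flipped); LoG kernels are symmetric so this
          // coincides with correlation, but keep the flip for correctness
          acc += img(ci, cj) * kernel(hr - ki, hc - kj);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Connected-component labelling of a binary mask (4- or 8-connectivity),
// two-pass with union-find. Returns an integer matrix of labels (0 = background),
// labels renumbered 1..n in scan order of first appearance.
static int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // label 0 unused
  int next = 1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      // previously scanned neighbours (column-major scan): N, W, NW, SW
      int neigh[4];
      int nn = 0;
      if (i > 0 && mask(i - 1, j)) neigh[nn++] = lab(i - 1, j);
      if (j > 0 && mask(i, j - 1)) neigh[nn++] = lab(i, j - 1);
      if (connectivity == 8 && j > 0) {
        if (i > 0 && mask(i - 1, j - 1)) neigh[nn++] = lab(i - 1, j - 1);
        if (i < nr - 1 && mask(i + 1, j - 1)) neigh[nn++] = lab(i + 1, j - 1);
      }
      if (nn == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        int m = neigh[0];
        for (int k = 1; k < nn; ++k) if (neigh[k] < m) m = neigh[k];
        lab(i, j) = m;
        for (int k = 0; k < nn; ++k) {
          int ra = find_root(parent, m), rb = find_root(parent, neigh[k]);
          if (ra != rb) parent[rb < ra ? ra : rb] = (rb < ra ? rb : ra);
        }
      }
    }
  }
  // resolve + renumber consecutively
  std::vector<int> newlab(parent.size(), 0);
  int cnt = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = find_root(parent, l);
      if (newlab[r] == 0) newlab[r] = ++cnt;
      lab(i, j) = newlab[r];
    }
  }
  return lab;
}

// Minimum distance from each query point to a polyline, plus the arclength
// position of the closest point. verts is an n x 2 matrix of (x, y) vertices.
// Returns a list with 'dist' and 'arclength' vectors.
// [[Rcpp::export]]
List polyline_dist_cpp(NumericVector px, NumericVector py, NumericMatrix verts) {
  int np = px.size();
  int nv = verts.nrow();
  if (nv < 1) stop("polyline needs at least one vertex");
  NumericVector dist(np), arc(np);
  // cumulative arclength at each vertex
  std::vector<double> cum(nv, 0.0);
  for (int k = 1; k < nv; ++k) {
    double dx = verts(k, 0) - verts(k - 1, 0);
    double dy = verts(k, 1) - verts(k - 1, 1);
    cum[k] = cum[k - 1] + std::sqrt(dx * dx + dy * dy);
  }
  for (int p = 0; p < np; ++p) {
    double best = R_PosInf, besta = 0.0;
    if (nv == 1) {
      double dx = px[p] - verts(0, 0), dy = py[p] - verts(0, 1);
      best = std::sqrt(dx * dx + dy * dy);
    }
    for (int k = 0; k + 1 < nv; ++k) {
      double ax = verts(k, 0), ay = verts(k, 1);
      double bx = verts(k + 1, 0), by = verts(k + 1, 1);
      double vx = bx - ax, vy = by - ay;
      double L2 = vx * vx + vy * vy;
      double t = 0.0;
      if (L2 > 0) {
        t = ((px[p] - ax) * vx + (py[p] - ay) * vy) / L2;
        if (t < 0) t = 0; else if (t > 1) t = 1;
      }
      double dx = px[p] - (ax + t * vx), dy = py[p] - (ay + t * vy);
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < best) {
        best = d;
        besta = cum[k] + t * std::sqrt(L2);
      }
    }
    dist[p] = best;
    arc[p] = besta;
  }
  return List::create(_["dist"] = dist, _["arclength"] = arc);
}
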