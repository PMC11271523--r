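// Pixel-level primitives for nucleus / duct segmentation: connected-component
// labeling, exact Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope algorithm applied separably), and a priority-flood marker
// watershed. All operate on R matrices (column-major, nrow = image height).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cpp_label(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int dx8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dy8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dx4[] = {-1, 1, 0, 0};
  const int dy4[] = {0, 0, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dx = (connectivity == 8) ? dx8 : dx4;
  const int* dy = (connectivity == 8) ? dy8 : dy4;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (mask(y, x) == 0 || lab(y, x) != 0) continue;
      ++next;
      lab(y, x) = next;
      stack.push_back(x * H + y);
      while (!stack.empty()) {
        const int idx = stack.back(); stack.pop_back();
        const int cy = idx % H, cx = idx / H;
        for (int j = 0; j < nn; ++j) {
          const int ny = cy + dy[j], nx = cx + dx[j];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (mask(ny, nx) != 0 && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            stack.push_back(nx * H + ny);
          }
        }
      }
    }
  }
  return lab;
}

static void edt_1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int kk = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * q) - (f[v[kk]] + v[kk] * v[kk])) / (2.0 * q - 2.0 * v[kk]);
    while (s <= z[kk]) {
      --kk;
      s = ((f[q] + q * q) - (f[v[kk]] + v[kk] * v[kk])) / (2.0 * q - 2.0 * v[kk]);
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    d[q] = (q - v[kk]) * (q - v[kk]) + f[v[kk]];
  }
}

// Euclidean distance of each foreground pixel to the nearest background pixel.
// [[Rcpp::export]]
NumericMatrix cpp_edt(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double INF = 1e20;
  NumericMatrix g(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) f[y] = (mask(y, x) != 0) ? INF : 0.0;
    edt_1d(f, d, H);
    for (int y = 0; y < H; ++y) g(y, x) = d[y];
  }
  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) f[x] = g(y, x);
    edt_1d(f, d, W);
    for (int x = 0; x < W; ++x) out(y, x) = std::sqrt(d[x]);
  }
  return out;
}

struct WsNode {
  double elev;
  long order;
  int idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;   // min-heap on elevation
    return a.order > b.order;                        // FIFO tie-break
  }
};

// Priority-flood watershed restricted to mask, growing from labeled markers.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& elev, const IntegerMatrix& markers,
                            const IntegerMatrix& mask) {
  const int H = elev.nrow(), W = elev.ncol();
  IntegerMatrix lab(H, W);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      if (markers(y, x) > 0 && mask(y, x) != 0) {
        lab(y, x) = markers(y, x);
        pq.push({elev(y, x), order++, x * H + y});
      }
  const int dx[] = {-1, 1, 0, 0};
  const int dy[] = {0, 0, -1, 1};
  while (!pq.empty()) {
    const WsNode nd = pq.top(); pq.pop();
    const int cy = nd.idx % H, cx = nd.idx / H;
    for (int j = 0; j < 4; ++j) {
      const int ny = cy + dy[j], nx = cx + dx[j];
      if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
      if (mask(ny, nx) == 0 || lab(ny, nx) != 0) continue;
      lab(ny, nx) = lab(cy, cx);
      pq.push({elev(ny, nx), order++, nx * H + ny});
    }
  }
  return lab;
}
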