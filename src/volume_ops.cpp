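// Low-level 3D grid operations shared by the segmentation modules.
// Arrays are R arrays with dim = c(nz, ny, nx), i.e. z is the
// fastest-varying index; all distances are in physical units (micrometres)
// derived from the per-axis voxel spacing.
#include <Rcpp.h>
#include <functional>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher) on a
// uniformly spaced grid with step d. f holds squared distances on input.
static void dt1d(std::vector<double> &f, std::vector<double> &out,
                 std::vector<int> &v, std::vector<double> &zi,
                 int n, double d) {
  const double s = d * d;
  int k = 0;
  v[0] = 0;
  zi[0] = -INF;
  zi[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double sint;
    while (true) {
      int r = v[k];
      sint = ((f[q] + s * q * q) - (f[r] + s * r * r)) / (2.0 * s * (q - r));
      if (sint <= zi[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zi[k] = sint;
    zi[k + 1] = INF;
  }
  if (f[v[0]] == INF) { // no sites along this line
    for (int q = 0; q < n; ++q) out[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zi[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    out[q] = s * dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance to the nearest foreground (fg TRUE) voxel,
// anisotropic spacing (dz, dy, dx). Voxels with no foreground anywhere
// get Inf.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector fg, IntegerVector dims,
                         NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = fg[i] ? 0.0 : INF;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), out(nmax), zi(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z (stride 1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) f[z] = D[base + z];
      dt1d(f, out, v, zi, nz, spacing[0]);
      for (int z = 0; z < nz; ++z) D[base + z] = out[z];
    }
  // pass along y (stride nz)
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * ny * x;
      for (int y = 0; y < ny; ++y) f[y] = D[base + (R_xlen_t)nz * y];
      dt1d(f, out, v, zi, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) D[base + (R_xlen_t)nz * y] = out[y];
    }
  // pass along x (stride nz*ny)
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * y;
      for (int x = 0; x < nx; ++x) f[x] = D[base + sx * x];
      dt1d(f, out, v, zi, nx, spacing[2]);
      for (int x = 0; x < nx; ++x) D[base + sx * x] = out[x];
    }
  return D;
}

struct WsNode {
  double d;      // flooding priority: distance-to-membrane of the voxel
  int lab;       // basin label offering the voxel
  long long cnt; // FIFO tie-break
  R_xlen_t idx;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.d != b.d) return a.d < b.d;        // deeper first
    if (a.lab != b.lab) return a.lab > b.lab; // smaller label first
    return a.cnt > b.cnt;                     // earlier push first
  }
};

// Marker-controlled watershed by ordered flooding of the distance field,
// restricted to `allowed` voxels, 6-connectivity. Deterministic: voxels are
// flooded deepest-first; at exact priority ties the smaller seed label wins.
// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerVector watershed_cpp(NumericVector dist, LogicalVector allowed,
                            IntegerVector seed_idx0, IntegerVector seed_lab,
                            IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n); // zero-initialised
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long cnt = 0;

  for (int s = 0; s < seed_idx0.size(); ++s) {
    R_xlen_t i = seed_idx0[s];
    pq.push(WsNode{dist[i], seed_lab[s], cnt++, i});
  }
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    if (lab[nd.idx] != 0) continue;
    lab[nd.idx] = nd.lab;
    int z = (int)(nd.idx % nz);
    int y = (int)((nd.idx / nz) % ny);
    int x = (int)(nd.idx / sx);
    const int dz[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dx[6] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < 6; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = zz + sy * yy + sx * xx;
      if (!allowed[j] || lab[j] != 0) continue;
      pq.push(WsNode{dist[j], nd.lab, cnt++, j});
    }
  }
  return lab;
}

// Regional maxima of `values` within `mask`, suppressing maxima whose
// topographic prominence is <= h (persistence-based, equivalent to
// h-maxima suppression). Plateaus yield a single representative voxel:
// the lexicographically smallest (z, y, x) of the plateau. Returns 1-based
// linear indices of the kept peak voxels, ordered by value descending then
// (z, y, x).
// [[Rcpp::export(name = ".prominent_maxima_cpp")]]
IntegerVector prominent_maxima_cpp(NumericVector values, LogicalVector mask,
                                   IntegerVector dims, double h) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<R_xlen_t> ord;
  ord.reserve(n / 4);
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) ord.push_back(i);
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  // sort by value desc, then lexicographic (z, y, x) asc
  std::stable_sort(ord.begin(), ord.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (values[a] != values[b]) return values[a] > values[b];
    int za = (int)(a % nz), zb = (int)(b % nz);
    if (za != zb) return za < zb;
    int ya = (int)((a / nz) % ny), yb = (int)((b / nz) % ny);
    if (ya != yb) return ya < yb;
    return (a / sx) < (b / sx);
  });

  std::vector<int> rank(n, -1); // processing order; -1 = not yet seen
  std::vector<int> parent(ord.size());
  std::vector<R_xlen_t> peak(ord.size()); // peak voxel of each component root
  std::vector<char> kept(ord.size(), 0);

  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) {
      parent[a] = parent[parent[a]];
      a = parent[a];
    }
    return a;
  };
  // returns true if peak a outranks peak b (higher value, or lex smaller)
  auto peak_before = [&](R_xlen_t a, R_xlen_t b) {
    if (values[a] != values[b]) return values[a] > values[b];
    int za = (int)(a % nz), zb = (int)(b % nz);
    if (za != zb) return za < zb;
    int ya = (int)((a / nz) % ny), yb = (int)((b / nz) % ny);
    if (ya != yb) return ya < yb;
    return (a / sx) < (b / sx);
  };

  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};
  for (size_t o = 0; o < ord.size(); ++o) {
    R_xlen_t i = ord[o];
    rank[i] = (int)o;
    parent[o] = (int)o;
    peak[o] = i;
    int z = (int)(i % nz);
    int y = (int)((i / nz) % ny);
    int x = (int)(i / sx);
    for (int k = 0; k < 6; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = zz + (R_xlen_t)nz * yy + sx * xx;
      if (rank[j] < 0) continue; // not yet flooded
      int ra = find((int)o), rb = find(rank[j]);
      if (ra == rb) continue;
      int win = peak_before(peak[ra], peak[rb]) ? ra : rb;
      int lose = (win == ra) ? rb : ra;
      double prominence = values[peak[lose]] - values[i];
      if (prominence > h) kept[lose] = 1; // dies, but is a genuine maximum
      parent[lose] = win;
    }
  }
  // components never absorbed are global maxima of their basin: always kept
  for (size_t o = 0; o < ord.size(); ++o)
    if (find((int)o) == (int)o) kept[o] = 1;

  std::vector<R_xlen_t> res;
  for (size_t o = 0; o < ord.size(); ++o)
    if (kept[o]) res.push_back(peak[o]);
  std::sort(res.begin(), res.end(), [&](R_xlen_t a, R_xlen_t b) {
    return peak_before(a, b);
  });
  IntegerVector out(res.size());
  for (size_t k = 0; k < res.size(); ++k) out[k] = (int)(res[k] + 1);
  return out;
}
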