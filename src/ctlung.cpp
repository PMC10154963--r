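#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Flat index helpers: R arrays are column-major, x fastest.
static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// 3D connected-component labeling by breadth-first search.
// Labels are assigned in raster-scan (column-major) order of each
// component's first voxel; relabeling by component size happens in R.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  int next_label = 0;
  std::queue<int> q;

  // neighbor offsets as (dx,dy,dz)
  std::vector<std::array<int,3>> nbr;
  if (connectivity == 6) {
    nbr = {{{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dx || dy || dz) nbr.push_back({{dx,dy,dz}});
  }

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = idx3(x, y, z, nx, ny);
        if (!mask[i] || labels[i]) continue;
        labels[i] = ++next_label;
        q.push(i);
        while (!q.empty()) {
          const int j = q.front(); q.pop();
          const int jz = j / (nx * ny);
          const int jy = (j - jz * nx * ny) / nx;
          const int jx = j - nx * (jy + ny * jz);
          for (const auto &d : nbr) {
            const int ax = jx + d[0], ay = jy + d[1], az = jz + d[2];
            if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz)
              continue;
            const int k = idx3(ax, ay, az, nx, ny);
            if (mask[k] && !labels[k]) { labels[k] = next_label; q.push(k); }
          }
        }
      }
  labels.attr("n_components") = next_label;
  return labels;
}

// Binary erosion/dilation with the 6-neighborhood (face) structuring
// element, iterated `iter` times. Outside the grid counts as background.
// use_z = false restricts to the in-plane 4-neighborhood (2D, per slice).
static LogicalVector morph_once(const LogicalVector &mask, int nx, int ny, int nz,
                                bool erode, bool use_z) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = idx3(x, y, z, nx, ny);
        bool center = mask[i];
        bool v = center;
        if (erode) {
          if (v) {
            // all face neighbors must be foreground (out-of-bounds = background)
            v = x > 0 && mask[i-1] && x < nx-1 && mask[i+1] &&
                y > 0 && mask[i-nx] && y < ny-1 && mask[i+nx];
            if (v && use_z)
              v = z > 0 && mask[i - nx*ny] && z < nz-1 && mask[i + nx*ny];
          }
        } else {
          if (!v) {
            v = (x > 0 && mask[i-1]) || (x < nx-1 && mask[i+1]) ||
                (y > 0 && mask[i-nx]) || (y < ny-1 && mask[i+nx]);
            if (!v && use_z)
              v = (z > 0 && mask[i - nx*ny]) || (z < nz-1 && mask[i + nx*ny]);
          }
        }
        out[i] = v;
      }
  return out;
}

// [[Rcpp::export(name = ".morph3d")]]
LogicalVector morph3d(LogicalVector mask, IntegerVector dims, int iter,
                      bool erode, bool use_z) {
  LogicalVector cur = mask;
  for (int k = 0; k < iter; ++k)
    cur = morph_once(cur, dims[0], dims[1], dims[2], erode, use_z);
  return cur;
}

// Slice-wise 2D hole filling: background connected (4-neighborhood) to the
// slice border stays background; enclosed background becomes foreground.
// [[Rcpp::export(name = ".fill_holes2d")]]
LogicalVector fill_holes2d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out = clone(mask);
  std::vector<char> reach((size_t)nx * ny);
  std::queue<int> q;
  for (int z = 0; z < nz; ++z) {
    std::fill(reach.begin(), reach.end(), 0);
    const int off = nx * ny * z;
    auto push_if = [&](int x, int y) {
      const int p = x + nx * y;
      if (!reach[p] && !mask[off + p]) { reach[p] = 1; q.push(p); }
    };
    for (int x = 0; x < nx; ++x) { push_if(x, 0); push_if(x, ny - 1); }
    for (int y = 0; y < ny; ++y) { push_if(0, y); push_if(nx - 1, y); }
    while (!q.empty()) {
      const int p = q.front(); q.pop();
      const int x = p % nx, y = p / nx;
      if (x > 0) push_if(x - 1, y);
      if (x < nx - 1) push_if(x + 1, y);
      if (y > 0) push_if(x, y - 1);
      if (y < ny - 1) push_if(x, y + 1);
    }
    for (int p = 0; p < nx * ny; ++p)
      if (!mask[off + p] && !reach[p]) out[off + p] = true;
  }
  return out;
}

// Separable 3D Gaussian blur, reflected boundaries; kernel truncated at
// ceil(3*sigma). Used by the phantom's partial-volume model.
// [[Rcpp::export(name = ".gauss_blur3d")]]
NumericVector gauss_blur3d(NumericVector vol, IntegerVector dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (auto &v : k) v /= s;

  NumericVector a = clone(vol), b(n);
  const int nd[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    const int len = nd[axis], st = stride[axis];
    for (R_xlen_t i = 0; i < n; ++i) {
      // coordinate along axis and base index of that line
      int coord;
      if (axis == 0) coord = i % nx;
      else if (axis == 1) coord = (i / nx) % ny;
      else coord = i / (nx * ny);
      double acc = 0;
      for (int d = -r; d <= r; ++d) {
        int c = coord + d;
        if (c < 0) c = -c - 1;               // reflect
        else if (c >= len) c = 2 * len - c - 1;
        acc += k[d + r] * a[i + (R_xlen_t)(c - coord) * st];
      }
      b[i] = acc;
    }
    std::swap(a, b);
  }
  return a;
}
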