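#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of a slice (nx x ny matrix) at continuous index (fx, fy),
// 0-based voxel-centre convention; zero outside the grid.
static inline double sample_bilinear(const NumericMatrix& img, double fx, double fy) {
  const int nx = img.nrow(), ny = img.ncol();
  if (fx < -1.0 || fx > nx || fy < -1.0 || fy > ny) return 0.0;
  int ix = (int)std::floor(fx), iy = (int)std::floor(fy);
  double ax = fx - ix, ay = fy - iy;
  double v = 0.0;
  for (int dj = 0; dj <= 1; ++dj) {
    int j = iy + dj;
    if (j < 0 || j >= ny) continue;
    double wy = dj ? ay : 1.0 - ay;
    for (int di = 0; di <= 1; ++di) {
      int i = ix + di;
      if (i < 0 || i >= nx) continue;
      double wx = di ? ax : 1.0 - ax;
      v += wx * wy * img(i, j);
    }
  }
  return v;
}

// Parallel-beam line integrals of one slice.
// Detector bin centres t_k = (k - (nbins-1)/2) * bin_width (mm), k 0-based.
// Returns an (n_angles x nbins) matrix of integrals in value*mm.
// [[Rcpp::export]]
NumericMatrix radon_slice_cpp(NumericMatrix img, double dx, double dy,
                              NumericVector angles_rad, int nbins,
                              double bin_width, double step) {
  const int nx = img.nrow(), ny = img.ncol(), na = angles_rad.size();
  NumericMatrix out(na, nbins);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double half_diag = 0.5 * std::sqrt((double)nx * nx * dx * dx +
                                           (double)ny * ny * dy * dy);
  const int ns = (int)std::ceil(2.0 * half_diag / step);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles_rad[a]), st = std::sin(angles_rad[a]);
    for (int k = 0; k < nbins; ++k) {
      const double t = (k - (nbins - 1) / 2.0) * bin_width;
      double acc = 0.0;
      for (int s = 0; s <= ns; ++s) {
        const double sm = -half_diag + s * step;
        const double x = t * ct - sm * st;
        const double y = t * st + sm * ct;
        acc += sample_bilinear(img, x / dx + cx, y / dy + cy);
      }
      out(a, k) = acc * step;
    }
  }
  return out;
}

// Pixel-driven backprojection of a filtered sinogram (n_angles x nbins),
// linear interpolation between detector bins; result scaled by pi/n_angles.
// [[Rcpp::export]]
NumericMatrix backproject_slice_cpp(NumericMatrix fsino, double dx, double dy,
                                    NumericVector angles_rad, double bin_width,
                                    int nx, int ny) {
  const int na = angles_rad.size(), nbins = fsino.ncol();
  NumericMatrix out(nx, ny);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double t0 = -(nbins - 1) / 2.0 * bin_width;
  std::vector<double> cs(na), sn(na);
  for (int a = 0; a < na; ++a) { cs[a] = std::cos(angles_rad[a]); sn[a] = std::sin(angles_rad[a]); }
  for (int j = 0; j < ny; ++j) {
    const double y = (j - cy) * dy;
    for (int i = 0; i < nx; ++i) {
      const double x = (i - cx) * dx;
      double acc = 0.0;
      for (int a = 0; a < na; ++a) {
        const double t = x * cs[a] + y * sn[a];
        const double fk = (t - t0) / bin_width;
        if (fk < 0 || fk > nbins - 1) continue;
        const int k = (int)std::floor(fk);
        const double w = fk - k;
        const double v = (k == nbins - 1) ? fsino(a, k)
                                          : (1.0 - w) * fsino(a, k) + w * fsino(a, k + 1);
        acc += v;
      }
      out(i, j) = acc * M_PI / na;
    }
  }
  return out;
}

// Connected-component labelling of a 3-D logical array (BFS), connectivity
// 6 (faces) or 26 (faces+edges+corners). Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start]) continue;
    labels[start] = ++cur;
    q.push(start);
    while (!q.empty()) {
      R_xlen_t idx = q.front(); q.pop();
      int z = idx / ((R_xlen_t)nx * ny);
      int rem = idx % ((R_xlen_t)nx * ny);
      int y = rem / nx, x = rem % nx;
      for (auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t nb = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[nb] && !labels[nb]) { labels[nb] = cur; q.push(nb); }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Dilate a 3-D mask by an explicit list of integer voxel offsets (n x 3).
// [[Rcpp::export]]
LogicalVector dilate_offsets_cpp(LogicalVector mask, IntegerVector dims,
                                 IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  const int no = offsets.nrow();
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!mask[idx]) continue;
    int z = idx / ((R_xlen_t)nx * ny);
    int rem = idx % ((R_xlen_t)nx * ny);
    int y = rem / nx, x = rem % nx;
    for (int o = 0; o < no; ++o) {
      int xx = x + offsets(o, 0), yy = y + offsets(o, 1), zz = z + offsets(o, 2);
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      out[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx] = true;
    }
  }
  out.attr("dim") = dims;
  return out;
}

// For each point in `from` (n x 3, mm), the euclidean distance to the nearest
// point in `to` (m x 3, mm). Brute force; surfaces are small.
// [[Rcpp::export]]
NumericVector nearest_distances_cpp(NumericMatrix from, NumericMatrix to) {
  const int n = from.nrow(), m = to.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double x = from(i, 0), y = from(i, 1), z = from(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = x - to(j, 0), dy = y - to(j, 1), dz = z - to(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Trilinear resampling of a 3-D volume at continuous 0-based indices
// (n x 3 matrix); `fill` outside the grid.
// [[Rcpp::export]]
NumericVector trilinear_sample_cpp(NumericVector vol, IntegerVector dims,
                                   NumericMatrix at, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = at.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    const double fx = at(p, 0), fy = at(p, 1), fz = at(p, 2);
    if (fx < 0 || fx > nx - 1 || fy < 0 || fy > ny - 1 || fz < 0 || fz > nz - 1) {
      out[p] = fill;
      continue;
    }
    int ix = (int)std::floor(fx), iy = (int)std::floor(fy), iz = (int)std::floor(fz);
    if (ix == nx - 1) --ix;
    if (iy == ny - 1) --iy;
    if (iz == nz - 1) --iz;
    if (nx == 1) ix = 0;
    if (ny == 1) iy = 0;
    if (nz == 1) iz = 0;
    const double ax = nx == 1 ? 0 : fx - ix, ay = ny == 1 ? 0 : fy - iy,
                 az = nz == 1 ? 0 : fz - iz;
    double v = 0.0;
    for (int dk = 0; dk <= (nz == 1 ? 0 : 1); ++dk)
      for (int dj = 0; dj <= (ny == 1 ? 0 : 1); ++dj)
        for (int di = 0; di <= (nx == 1 ? 0 : 1); ++di) {
          const double w = (di ? ax : 1 - ax) * (dj ? ay : 1 - ay) * (dk ? az : 1 - az);
          v += w * vol[(R_xlen_t)(iz + dk) * nx * ny + (R_xlen_t)(iy + dj) * nx + (ix + di)];
        }
    out[p] = v;
  }
  return out;
}
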