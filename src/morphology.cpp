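#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// 3D connected-component labeling by flood fill.
// mask: logical 3D array; connectivity 6 or 26. Labels start at 1 in scan
// order of the first voxel of each component.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;

  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1)
          continue;
        off.push_back(dx);
        off.push_back(dy);
        off.push_back(dz);
      }

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t j = q.front(); q.pop();
      int x = (int)(j % nx);
      int y = (int)((j / nx) % ny);
      int z = (int)(j / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < off.size(); k += 3) {
        int xx = x + off[k], yy = y + off[k + 1], zz = z + off[k + 2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t jj = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[jj] && !lab[jj]) {
          lab[jj] = next;
          q.push(jj);
        }
      }
    }
  }
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with sample
// pitch d; f holds squared distances on input.
static void dt1d(std::vector<double>& f, double d) {
  const int n = (int)f.size();
  if (n == 0) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), out(n);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double d2 = d * d;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + d2 * q * q) - (f[p] + d2 * p * p)) / (2.0 * d2 * (q - p));
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = d * (q - v[k]);
    out[q] = dq * dq + f[v[k]];
  }
  f = out;
}

// Euclidean distance transform on an anisotropic grid: for every voxel,
// squared distance (mm^2) to the nearest TRUE voxel of `mask`.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, NumericVector spacing) {
  IntegerVector dims = mask.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  d.attr("dim") = dims;
  // large finite sentinel: true infinity yields inf-inf = NaN inside the
  // lower-envelope recursion
  const double inf = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : inf;

  std::vector<double> line;
  // x pass
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) line[x] = d[base + x];
      dt1d(line, spacing[0]);
      for (int x = 0; x < nx; ++x) d[base + x] = line[x];
    }
  // y pass
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) line[y] = d[base + (R_xlen_t)y * nx];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)y * nx] = line[y];
    }
  // z pass
  line.resize(nz);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) line[z] = d[base + (R_xlen_t)z * nxy];
      dt1d(line, spacing[2]);
      for (int z = 0; z < nz; ++z) d[base + (R_xlen_t)z * nxy] = line[z];
    }
  return d;
}

// Mask-restricted local mean and sample SD over the in-plane square
// kernel of half-width `radius` voxels. Voxels with fewer than
// `min_count` in-mask contributors get NA.
// [[Rcpp::export(name = ".local_stats")]]
List local_stats_cpp(NumericVector vol, LogicalVector mask, int radius,
                     int min_count) {
  IntegerVector dims = vol.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector mean_out(n, NA_REAL), sd_out(n, NA_REAL);
  mean_out.attr("dim") = dims;
  sd_out.attr("dim") = dims;

  for (int z = 0; z < nz; ++z) {
    const R_xlen_t zoff = (R_xlen_t)z * nx * ny;
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = zoff + (R_xlen_t)y * nx + x;
        if (!mask[i]) continue;
        double s = 0.0, s2 = 0.0;
        int cnt = 0;
        int y0 = std::max(0, y - radius), y1 = std::min(ny - 1, y + radius);
        int x0 = std::max(0, x - radius), x1 = std::min(nx - 1, x + radius);
        for (int yy = y0; yy <= y1; ++yy) {
          R_xlen_t row = zoff + (R_xlen_t)yy * nx;
          for (int xx = x0; xx <= x1; ++xx) {
            R_xlen_t j = row + xx;
            if (!mask[j]) continue;
            double v = vol[j];
            s += v;
            s2 += v * v;
            ++cnt;
          }
        }
        if (cnt < min_count) continue;
        double m = s / cnt;
        double var = (s2 - cnt * m * m) / (cnt - 1);
        if (var < 0) var = 0;
        mean_out[i] = m;
        sd_out[i] = std::sqrt(var);
      }
    }
  }
  return List::create(_["mean"] = mean_out, _["sd"] = sd_out);
}
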