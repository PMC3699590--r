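#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Column-major voxel indexing helpers for 3-D grids stored as R arrays.
static inline R_xlen_t vox(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

static inline double sample_trilinear(const double* v, int nx, int ny, int nz,
                                      double sx, double sy, double sz, double fill) {
  if (sx < 0 || sy < 0 || sz < 0 || sx > nx - 1 || sy > ny - 1 || sz > nz - 1)
    return fill;
  int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
  int x1 = x0 + 1 < nx ? x0 + 1 : x0;
  int y1 = y0 + 1 < ny ? y0 + 1 : y0;
  int z1 = z0 + 1 < nz ? z0 + 1 : z0;
  double fx = sx - x0, fy = sy - y0, fz = sz - z0;
  double c000 = v[vox(x0, y0, z0, nx, ny)], c100 = v[vox(x1, y0, z0, nx, ny)];
  double c010 = v[vox(x0, y1, z0, nx, ny)], c110 = v[vox(x1, y1, z0, nx, ny)];
  double c001 = v[vox(x0, y0, z1, nx, ny)], c101 = v[vox(x1, y0, z1, nx, ny)];
  double c011 = v[vox(x0, y1, z1, nx, ny)], c111 = v[vox(x1, y1, z1, nx, ny)];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double sample_nearest(const double* v, int nx, int ny, int nz,
                                    double sx, double sy, double sz, double fill) {
  int x = (int)std::lround(sx), y = (int)std::lround(sy), z = (int)std::lround(sz);
  if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return fill;
  return v[vox(x, y, z, nx, ny)];
}

// Pull-back warp: out(x) = vol(x + d(x)), d given as three component grids.
// [[Rcpp::export(name = ".cpp_warp_field")]]
NumericVector cpp_warp_field(NumericVector vol, IntegerVector dim,
                             NumericVector dx, NumericVector dy, NumericVector dz,
                             int interp, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* v = vol.begin();
  R_xlen_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        double sx = x + dx[i], sy = y + dy[i], sz = z + dz[i];
        out[i] = interp == 0 ? sample_trilinear(v, nx, ny, nz, sx, sy, sz, fill)
                             : sample_nearest(v, nx, ny, nz, sx, sy, sz, fill);
      }
  return out;
}

// Affine resample onto an output grid: out(x) = vol(M x + t), x in output
// voxel coordinates, M row-major 3x3, all in voxel units of the input grid.
// [[Rcpp::export(name = ".cpp_warp_affine")]]
NumericVector cpp_warp_affine(NumericVector vol, IntegerVector dim,
                              IntegerVector outdim, NumericVector M,
                              NumericVector t, int interp, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* v = vol.begin();
  R_xlen_t i = 0;
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x, ++i) {
        double sx = M[0] * x + M[1] * y + M[2] * z + t[0];
        double sy = M[3] * x + M[4] * y + M[5] * z + t[1];
        double sz = M[6] * x + M[7] * y + M[8] * z + t[2];
        out[i] = interp == 0 ? sample_trilinear(v, nx, ny, nz, sx, sy, sz, fill)
                             : sample_nearest(v, nx, ny, nz, sx, sy, sz, fill);
      }
  return out;
}

// Separable Gaussian smoothing, kernel truncated at 3 sigma and renormalized
// at the borders so constants are preserved.
static void smooth_axis(std::vector<double>& buf, std::vector<double>& tmp,
                        int nx, int ny, int nz, int axis, double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) return;
  std::vector<double> k(2 * r + 1);
  for (int j = -r; j <= r; ++j) k[j + r] = std::exp(-0.5 * j * j / (sigma * sigma));
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  int len = n[axis];
  R_xlen_t st = stride[axis];
  int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  for (int i2 = 0; i2 < n[a2]; ++i2)
    for (int i1 = 0; i1 < n[a1]; ++i1) {
      R_xlen_t base = (R_xlen_t)i1 * stride[a1] + (R_xlen_t)i2 * stride[a2];
      for (int p = 0; p < len; ++p) {
        double acc = 0, wsum = 0;
        int lo = p - r < 0 ? -p : -r;
        int hi = p + r >= len ? len - 1 - p : r;
        for (int j = lo; j <= hi; ++j) {
          double w = k[j + r];
          acc += w * buf[base + (R_xlen_t)(p + j) * st];
          wsum += w;
        }
        tmp[p] = acc / wsum;
      }
      for (int p = 0; p < len; ++p) buf[base + (R_xlen_t)p * st] = tmp[p];
    }
}

// [[Rcpp::export(name = ".cpp_gauss_smooth")]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dim, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> tmp((size_t)std::max(nx, std::max(ny, nz)));
  if (sigma > 0) {
    smooth_axis(buf, tmp, nx, ny, nz, 0, sigma);
    smooth_axis(buf, tmp, nx, ny, nz, 1, sigma);
    smooth_axis(buf, tmp, nx, ny, nz, 2, sigma);
  }
  return NumericVector(buf.begin(), buf.end());
}

// Block matching: for each block of `bs`^3 voxels placed every `spacing`
// voxels on the fixed grid, exhaustively search integer offsets within
// `radius` maximizing the Pearson correlation with the moving image.
// Ties broken toward the smaller squared offset norm, then search order.
// Returns a (nblocks x 7) matrix: cx, cy, cz, ox, oy, oz, valid.
// [[Rcpp::export(name = ".cpp_block_match")]]
NumericMatrix cpp_block_match(NumericVector fixed, NumericVector moving,
                              IntegerVector dim, int bs, int spacing,
                              int radius, double min_var) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* F = fixed.begin();
  const double* M = moving.begin();
  int nb = bs * bs * bs;
  std::vector<int> cx, cy, cz;
  for (int z = 0; z + bs <= nz; z += spacing)
    for (int y = 0; y + bs <= ny; y += spacing)
      for (int x = 0; x + bs <= nx; x += spacing) {
        cx.push_back(x); cy.push_back(y); cz.push_back(z);
      }
  int nblocks = (int)cx.size();
  NumericMatrix out(nblocks, 7);
  std::vector<double> fb((size_t)nb);
  for (int b = 0; b < nblocks; ++b) {
    int x0 = cx[b], y0 = cy[b], z0 = cz[b];
    double fsum = 0, fsum2 = 0;
    int q = 0;
    for (int dz0 = 0; dz0 < bs; ++dz0)
      for (int dy0 = 0; dy0 < bs; ++dy0)
        for (int dx0 = 0; dx0 < bs; ++dx0, ++q) {
          double fv = F[vox(x0 + dx0, y0 + dy0, z0 + dz0, nx, ny)];
          fb[q] = fv; fsum += fv; fsum2 += fv * fv;
        }
    double fmean = fsum / nb;
    double fvar = fsum2 / nb - fmean * fmean;
    out(b, 0) = x0 + (bs - 1) / 2.0;
    out(b, 1) = y0 + (bs - 1) / 2.0;
    out(b, 2) = z0 + (bs - 1) / 2.0;
    if (fvar <= min_var) { out(b, 6) = 0; continue; }
    double best = -2.0, bestn2 = 1e30;
    int bx = 0, by = 0, bz = 0;
    bool found = false;
    for (int oz = -radius; oz <= radius; ++oz)
      for (int oy = -radius; oy <= radius; ++oy)
        for (int ox = -radius; ox <= radius; ++ox) {
          int mx = x0 + ox, my = y0 + oy, mz = z0 + oz;
          if (mx < 0 || my < 0 || mz < 0 ||
              mx + bs > nx || my + bs > ny || mz + bs > nz) continue;
          double msum = 0, msum2 = 0, cross = 0;
          q = 0;
          for (int dz0 = 0; dz0 < bs; ++dz0)
            for (int dy0 = 0; dy0 < bs; ++dy0)
              for (int dx0 = 0; dx0 < bs; ++dx0, ++q) {
                double mv = M[vox(mx + dx0, my + dy0, mz + dz0, nx, ny)];
                msum += mv; msum2 += mv * mv; cross += mv * fb[q];
              }
          double mmean = msum / nb;
          double mvar = msum2 / nb - mmean * mmean;
          if (mvar <= 0) continue;
          double corr = (cross / nb - fmean * mmean) / std::sqrt(fvar * mvar);
          double n2 = (double)ox * ox + (double)oy * oy + (double)oz * oz;
          if (!found || corr > best + 1e-12 ||
              (corr > best - 1e-12 && n2 < bestn2)) {
            best = corr; bestn2 = n2; bx = ox; by = oy; bz = oz; found = true;
          }
        }
    if (!found) { out(b, 6) = 0; continue; }
    out(b, 3) = bx; out(b, 4) = by; out(b, 5) = bz; out(b, 6) = 1;
  }
  return out;
}

// Joint histogram over bins x bins uniform bins spanning [amin,amax]x[bmin,bmax].
// [[Rcpp::export(name = ".cpp_joint_hist")]]
NumericMatrix cpp_joint_hist(NumericVector a, NumericVector b, int bins,
                             double amin, double amax, double bmin, double bmax) {
  NumericMatrix H(bins, bins);
  double ra = amax - amin, rb = bmax - bmin;
  if (ra <= 0) ra = 1;
  if (rb <= 0) rb = 1;
  R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int ia = (int)((a[i] - amin) / ra * bins);
    int ib = (int)((b[i] - bmin) / rb * bins);
    if (ia < 0) ia = 0; if (ia >= bins) ia = bins - 1;
    if (ib < 0) ib = 0; if (ib >= bins) ib = bins - 1;
    H(ia, ib) += 1.0;
  }
  return H;
}
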