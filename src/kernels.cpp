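#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Trilinear sample of a 3D column-major volume at continuous voxel
// coordinates (0-based). Outside [0, n-1] on any axis -> fill.
static inline double sample_lin(const double* v, int nx, int ny, int nz,
                                double x, double y, double z, double fill) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) return fill;
  int i = (int)std::floor(x); if (i > nx - 2) i = nx - 2; if (i < 0) i = 0;
  int j = (int)std::floor(y); if (j > ny - 2) j = ny - 2; if (j < 0) j = 0;
  int k = (int)std::floor(z); if (k > nz - 2) k = nz - 2; if (k < 0) k = 0;
  double fx = x - i, fy = y - j, fz = z - k;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double* p = v + i * sx + j * sy + k * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sx + sy] * fx;
  double c01 = p[sz] * (1 - fx) + p[sx + sz] * fx;
  double c11 = p[sy + sz] * (1 - fx) + p[sx + sy + sz] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Edge-clamped trilinear sample: coordinates are clamped to the domain, so
// the sampled function is continuous everywhere (used by the similarity
// metric, where an out-of-domain jump to a fill value would create
// spurious discontinuities at the grid faces).
static inline double sample_lin_clamp(const double* v, int nx, int ny, int nz,
                                      double x, double y, double z) {
  if (x < 0.0) x = 0.0; else if (x > nx - 1.0) x = nx - 1.0;
  if (y < 0.0) y = 0.0; else if (y > ny - 1.0) y = ny - 1.0;
  if (z < 0.0) z = 0.0; else if (z > nz - 1.0) z = nz - 1.0;
  return sample_lin(v, nx, ny, nz, x, y, z, 0.0);
}

static inline void keys_w(double t, double* w) {
  // Keys cubic convolution kernel, a = -0.5 (Catmull-Rom)
  double t2 = t * t, t3 = t2 * t;
  w[0] = -0.5 * t3 + t2 - 0.5 * t;
  w[1] =  1.5 * t3 - 2.5 * t2 + 1.0;
  w[2] = -1.5 * t3 + 2.0 * t2 + 0.5 * t;
  w[3] =  0.5 * t3 - 0.5 * t2;
}

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

static inline double sample_cub(const double* v, int nx, int ny, int nz,
                                double x, double y, double z, double fill) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) return fill;
  int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
  double wxv[4], wyv[4], wzv[4];
  keys_w(x - i, wxv); keys_w(y - j, wyv); keys_w(z - k, wzv);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  double acc = 0.0;
  for (int c = 0; c < 4; ++c) {
    int kk = clampi(k + c - 1, 0, nz - 1);
    double az = wzv[c];
    for (int b = 0; b < 4; ++b) {
      int jj = clampi(j + b - 1, 0, ny - 1);
      double ayz = az * wyv[b];
      const double* row = v + jj * sy + kk * sz;
      for (int a = 0; a < 4; ++a) {
        int ii = clampi(i + a - 1, 0, nx - 1);
        acc += ayz * wxv[a] * row[ii];
      }
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_sample3(NumericVector data, IntegerVector dim,
                          NumericVector spacing, NumericVector origin,
                          NumericMatrix pts, int method, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double* v = data.begin();
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double* px = &pts(0, 0);
  const double* py = &pts(0, 1);
  const double* pz = &pts(0, 2);
  for (R_xlen_t t = 0; t < n; ++t) {
    double x = (px[t] - ox) / hx, y = (py[t] - oy) / hy, z = (pz[t] - oz) / hz;
    out[t] = (method == 1) ? sample_cub(v, nx, ny, nz, x, y, z, fill)
                           : sample_lin(v, nx, ny, nz, x, y, z, fill);
  }
  return out;
}

// Dense displacement from cubic B-spline control coefficients.
// coef: (ncx, ncy, ncz, 3) column-major; i0*/w* precomputed per voxel:
// i0 is the 0-based index of the first of 4 supporting control points.
// [[Rcpp::export]]
NumericVector cpp_ffd_dense(NumericVector coef, IntegerVector ncp,
                            IntegerVector i0x, NumericMatrix wx,
                            IntegerVector i0y, NumericMatrix wy,
                            IntegerVector i0z, NumericMatrix wz) {
  const int nx = i0x.size(), ny = i0y.size(), nz = i0z.size();
  const int ncx = ncp[0], ncy = ncp[1], ncz = ncp[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t cstride = (R_xlen_t)ncx * ncy * ncz;
  NumericVector out(nvox * 3);
  const double* C = coef.begin();
  double* U = out.begin();
  for (int k = 0; k < nz; ++k) {
    const double* wzk = &wz(k, 0);
    int k0 = i0z[k];
    for (int j = 0; j < ny; ++j) {
      const double* wyj = &wy(j, 0);
      int j0 = i0y[j];
      for (int i = 0; i < nx; ++i) {
        const double* wxi = &wx(i, 0);
        int i0 = i0x[i];
        double ux = 0, uy = 0, uz = 0;
        for (int c = 0; c < 4; ++c) {
          double az = wzk[c * (R_xlen_t)nz];
          R_xlen_t zoff = (R_xlen_t)(k0 + c) * ncx * ncy;
          for (int b = 0; b < 4; ++b) {
            double ayz = az * wyj[b * (R_xlen_t)ny];
            R_xlen_t yzoff = zoff + (R_xlen_t)(j0 + b) * ncx + i0;
            const double* c0 = C + yzoff;
            const double* c1 = c0 + cstride;
            const double* c2 = c1 + cstride;
            for (int a = 0; a < 4; ++a) {
              double w = ayz * wxi[a * (R_xlen_t)nx];
              ux += w * c0[a];
              uy += w * c1[a];
              uz += w * c2[a];
            }
          }
        }
        R_xlen_t v = i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
        U[v] = ux; U[v + nvox] = uy; U[v + 2 * nvox] = uz;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

static inline void keys_dw(double t, double* w) {
  // derivative of the Keys a = -0.5 kernel weights with respect to t
  double t2 = t * t;
  w[0] = -1.5 * t2 + 2.0 * t - 0.5;
  w[1] =  4.5 * t2 - 5.0 * t;
  w[2] = -4.5 * t2 + 4.0 * t + 0.5;
  w[3] =  1.5 * t2 - 1.0 * t;
}

// Cubic (Keys) sample of a volume together with the analytic gradient of the
// interpolant, at clamped continuous voxel coordinates. Consistency between
// the sampled value and its gradient keeps the similarity landscape smooth,
// which a mismatched finite-difference gradient does not.
static inline double sample_cub_grad(const double* v, int nx, int ny, int nz,
                                     double x, double y, double z,
                                     double* g) {
  bool inx = true, iny = true, inz = true;
  if (x < 0.0) { x = 0.0; inx = false; }
  else if (x > nx - 1.0) { x = nx - 1.0; inx = false; }
  if (y < 0.0) { y = 0.0; iny = false; }
  else if (y > ny - 1.0) { y = ny - 1.0; iny = false; }
  if (z < 0.0) { z = 0.0; inz = false; }
  else if (z > nz - 1.0) { z = nz - 1.0; inz = false; }
  int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
  if (i > nx - 2) i = nx - 2;
  if (j > ny - 2) j = ny - 2;
  if (k > nz - 2) k = nz - 2;
  double wxv[4], wyv[4], wzv[4], dxv[4], dyv[4], dzv[4];
  keys_w(x - i, wxv); keys_w(y - j, wyv); keys_w(z - k, wzv);
  keys_dw(x - i, dxv); keys_dw(y - j, dyv); keys_dw(z - k, dzv);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  double val = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
  for (int c = 0; c < 4; ++c) {
    int kk = clampi(k + c - 1, 0, nz - 1);
    for (int b = 0; b < 4; ++b) {
      int jj = clampi(j + b - 1, 0, ny - 1);
      const double* row = v + jj * sy + kk * sz;
      double wyz = wyv[b] * wzv[c];
      double dyz = dyv[b] * wzv[c];
      double ydz = wyv[b] * dzv[c];
      for (int a = 0; a < 4; ++a) {
        double s = row[clampi(i + a - 1, 0, nx - 1)];
        val += wxv[a] * wyz * s;
        gx += dxv[a] * wyz * s;
        gy += wxv[a] * dyz * s;
        gz += wxv[a] * ydz * s;
      }
    }
  }
  g[0] = inx ? gx : 0.0;
  g[1] = iny ? gy : 0.0;
  g[2] = inz ? gz : 0.0;
  return val;
}

// Similarity metric (0 = mean SSD, 1 = 1 - NCC) between the fixed image and
// the moving image warped by u = u0 + B c, with analytic gradient with
// respect to the control coefficients. The moving image is sampled with a
// cubic Keys interpolant whose analytic spatial gradient feeds the chain
// rule, so value and gradient are exactly consistent.
// [[Rcpp::export]]
List cpp_metric_grad(NumericVector fixed, IntegerVector fdim,
                     NumericVector fspacing, NumericVector forigin,
                     NumericVector mov, IntegerVector mdim,
                     NumericVector mspacing, NumericVector morigin,
                     NumericVector u0, bool has_u0,
                     NumericVector coef, IntegerVector ncp,
                     IntegerVector i0x, NumericMatrix wx,
                     IntegerVector i0y, NumericMatrix wy,
                     IntegerVector i0z, NumericMatrix wz,
                     int metric, double fill, bool want_grad,
                     NumericVector vweight) {
  const bool has_w = vweight.size() > 0;
  const int nx = fdim[0], ny = fdim[1], nz = fdim[2];
  const int mnx = mdim[0], mny = mdim[1], mnz = mdim[2];
  const int ncx = ncp[0], ncy = ncp[1], ncz = ncp[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t cstride = (R_xlen_t)ncx * ncy * ncz;
  const double* C = coef.begin();
  const double* F = fixed.begin();
  const double* M = mov.begin();
  const double* U0 = has_u0 ? u0.begin() : (double*)0;

  std::vector<double> wv(nvox), gx, gy, gz;
  if (want_grad) { gx.resize(nvox); gy.resize(nvox); gz.resize(nvox); }

  // pass 1: warp and sample
  for (int k = 0; k < nz; ++k) {
    const double* wzk = &wz(k, 0);
    int k0 = i0z[k];
    double pz0 = forigin[2] + k * fspacing[2];
    for (int j = 0; j < ny; ++j) {
      const double* wyj = &wy(j, 0);
      int j0 = i0y[j];
      double py0 = forigin[1] + j * fspacing[1];
      for (int i = 0; i < nx; ++i) {
        const double* wxi = &wx(i, 0);
        int i0 = i0x[i];
        double ux = 0, uy = 0, uz = 0;
        for (int c = 0; c < 4; ++c) {
          double az = wzk[c * (R_xlen_t)nz];
          R_xlen_t zoff = (R_xlen_t)(k0 + c) * ncx * ncy;
          for (int b = 0; b < 4; ++b) {
            double ayz = az * wyj[b * (R_xlen_t)ny];
            R_xlen_t yzoff = zoff + (R_xlen_t)(j0 + b) * ncx + i0;
            const double* c0 = C + yzoff;
            const double* c1 = c0 + cstride;
            const double* c2 = c1 + cstride;
            for (int a = 0; a < 4; ++a) {
              double w = ayz * wxi[a * (R_xlen_t)nx];
              ux += w * c0[a]; uy += w * c1[a]; uz += w * c2[a];
            }
          }
        }
        R_xlen_t v = i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
        if (has_u0) {
          ux += U0[v]; uy += U0[v + nvox]; uz += U0[v + 2 * nvox];
        }
        double qx = (forigin[0] + i * fspacing[0] + ux - morigin[0]) / mspacing[0];
        double qy = (py0 + uy - morigin[1]) / mspacing[1];
        double qz = (pz0 + uz - morigin[2]) / mspacing[2];
        if (want_grad) {
          double gv[3];
          wv[v] = sample_cub_grad(M, mnx, mny, mnz, qx, qy, qz, gv);
          gx[v] = gv[0] / mspacing[0];   // d value / d position (per mm)
          gy[v] = gv[1] / mspacing[1];
          gz[v] = gv[2] / mspacing[2];
        } else {
          double cqx = qx < 0.0 ? 0.0 : (qx > mnx - 1.0 ? mnx - 1.0 : qx);
          double cqy = qy < 0.0 ? 0.0 : (qy > mny - 1.0 ? mny - 1.0 : qy);
          double cqz = qz < 0.0 ? 0.0 : (qz > mnz - 1.0 ? mnz - 1.0 : qz);
          wv[v] = sample_cub(M, mnx, mny, mnz, cqx, cqy, cqz, fill);
        }
      }
    }
  }

  // metric value and per-voxel dMetric/dm (optionally voxel-weighted)
  const double* W = has_w ? vweight.begin() : (double*)0;
  double wsum = 0.0;
  if (has_w) { for (R_xlen_t v = 0; v < nvox; ++v) wsum += W[v]; }
  else wsum = (double)nvox;
  if (wsum <= 0.0) stop("all metric voxel weights are zero");
  double value = 0.0;
  std::vector<double> dval;
  if (want_grad) dval.resize(nvox);
  if (metric == 0) {
    double acc = 0.0;
    for (R_xlen_t v = 0; v < nvox; ++v) {
      double wgt = has_w ? W[v] : 1.0;
      double r = wv[v] - F[v];
      acc += wgt * r * r;
      if (want_grad) dval[v] = 2.0 * wgt * r / wsum;
    }
    value = acc / wsum;
  } else {
    double mf = 0.0, mm = 0.0;
    for (R_xlen_t v = 0; v < nvox; ++v) {
      double wgt = has_w ? W[v] : 1.0;
      mf += wgt * F[v]; mm += wgt * wv[v];
    }
    mf /= wsum; mm /= wsum;
    double A = 0, B = 0, Cc = 0;
    for (R_xlen_t v = 0; v < nvox; ++v) {
      double wgt = has_w ? W[v] : 1.0;
      double fh = F[v] - mf, mh = wv[v] - mm;
      A += wgt * fh * mh; B += wgt * mh * mh; Cc += wgt * fh * fh;
    }
    double den = std::sqrt(B * Cc);
    if (den <= 0.0) {
      value = 1.0;
      if (want_grad) std::fill(dval.begin(), dval.end(), 0.0);
    } else {
      value = 1.0 - A / den;
      if (want_grad) {
        for (R_xlen_t v = 0; v < nvox; ++v) {
          double wgt = has_w ? W[v] : 1.0;
          double fh = F[v] - mf, mh = wv[v] - mm;
          dval[v] = -wgt * (fh / den - A * mh / (B * den));
        }
      }
    }
  }

  if (!want_grad) return List::create(_["value"] = value);

  NumericVector grad(cstride * 3);
  double* G = grad.begin();
  // pass 2: scatter dval * grad(moving) through the B-spline weights
  for (int k = 0; k < nz; ++k) {
    const double* wzk = &wz(k, 0);
    int k0 = i0z[k];
    for (int j = 0; j < ny; ++j) {
      const double* wyj = &wy(j, 0);
      int j0 = i0y[j];
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
        double d = dval[v];
        if (d == 0.0) continue;
        double dgx = d * gx[v], dgy = d * gy[v], dgz = d * gz[v];
        if (dgx == 0.0 && dgy == 0.0 && dgz == 0.0) continue;
        const double* wxi = &wx(i, 0);
        int i0 = i0x[i];
        for (int c = 0; c < 4; ++c) {
          double az = wzk[c * (R_xlen_t)nz];
          R_xlen_t zoff = (R_xlen_t)(k0 + c) * ncx * ncy;
          for (int b = 0; b < 4; ++b) {
            double ayz = az * wyj[b * (R_xlen_t)ny];
            R_xlen_t yzoff = zoff + (R_xlen_t)(j0 + b) * ncx + i0;
            double* g0 = G + yzoff;
            double* g1 = g0 + cstride;
            double* g2 = g1 + cstride;
            for (int a = 0; a < 4; ++a) {
              double w = ayz * wxi[a * (R_xlen_t)nx];
              g0[a] += w * dgx; g1[a] += w * dgy; g2[a] += w * dgz;
            }
          }
        }
      }
    }
  }
  grad.attr("dim") = IntegerVector::create(ncx, ncy, ncz, 3);
  return List::create(_["value"] = value, _["grad"] = grad);
}

// Exhaustive block matching between two images on the same grid. For every
// node on a stride grid whose fixed-image block has enough intensity spread,
// search all integer displacements in [-range, range]^3 (voxels) for the
// minimum mean SSD over the block, then refine each axis to sub-voxel
// precision by fitting a parabola through the three scores around the best
// offset. Being exhaustive, the search cannot be trapped by local minima.
// Returns one row per accepted node: voxel indices (0-based), displacement
// in voxels (possibly fractional), and the best mean SSD.
// [[Rcpp::export]]
NumericMatrix cpp_block_match(NumericVector fixed, NumericVector moving,
                              IntegerVector dim, int stride, int half_block,
                              int range, double min_sd) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* F = fixed.begin();
  const double* M = moving.begin();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  std::vector<double> rows;
  const int margin = half_block + range;
  const int bs = 2 * half_block + 1;
  const int nb = bs * bs * bs;
  std::vector<double> fb(nb);
  for (int ck = margin; ck < nz - margin; ck += stride) {
    for (int cj = margin; cj < ny - margin; cj += stride) {
      for (int ci = margin; ci < nx - margin; ci += stride) {
        // cache the fixed block and its spread
        double s1 = 0, s2 = 0;
        int t = 0;
        for (int dk = -half_block; dk <= half_block; ++dk)
          for (int dj = -half_block; dj <= half_block; ++dj)
            for (int di = -half_block; di <= half_block; ++di) {
              double v = F[(ci + di) + (R_xlen_t)(cj + dj) * sy + (R_xlen_t)(ck + dk) * sz];
              fb[t++] = v;
              s1 += v; s2 += v * v;
            }
        double sd = std::sqrt(std::max(0.0, s2 / nb - (s1 / nb) * (s1 / nb)));
        if (sd < min_sd) continue;
        // null-hypothesis score at zero offset
        double ssd0 = 0;
        t = 0;
        {
          const double* base0 = M + ci + (R_xlen_t)cj * sy + (R_xlen_t)ck * sz;
          for (int dk = -half_block; dk <= half_block; ++dk)
            for (int dj = -half_block; dj <= half_block; ++dj) {
              const double* row = base0 + (R_xlen_t)dj * sy + (R_xlen_t)dk * sz;
              for (int di = -half_block; di <= half_block; ++di) {
                double r = row[di] - fb[t++];
                ssd0 += r * r;
              }
            }
        }
        double best = R_PosInf;
        int bi = 0, bj = 0, bk = 0;
        for (int ok = -range; ok <= range; ++ok)
          for (int oj = -range; oj <= range; ++oj)
            for (int oi = -range; oi <= range; ++oi) {
              double acc = 0;
              t = 0;
              const double* base = M + (ci + oi) + (R_xlen_t)(cj + oj) * sy +
                                   (R_xlen_t)(ck + ok) * sz;
              for (int dk = -half_block; dk <= half_block; ++dk)
                for (int dj = -half_block; dj <= half_block; ++dj) {
                  const double* row = base + (R_xlen_t)dj * sy + (R_xlen_t)dk * sz;
                  for (int di = -half_block; di <= half_block; ++di) {
                    double r = row[di] - fb[t++];
                    acc += r * r;
                  }
                }
              // relative magnitude penalty: a genuine match lowers the SSD by
              // far more than a few percent, while blocks inside
              // translation-invariant structures (aperture problem) vary only
              // marginally along the degenerate direction and must stay at 0
              acc *= 1.0 + 2e-3 * (oi * oi + oj * oj + ok * ok);
              if (acc < best) { best = acc; bi = oi; bj = oj; bk = ok; }
            }
        // A displaced match must clearly beat the zero-offset score. When it
        // does not, the block either is already aligned (zero-offset residual
        // small next to the block contrast: keep it as a zero anchor) or is
        // an ambiguous smooth ramp (drop it).
        if (best >= 0.7 * ssd0) {
          if (ssd0 <= 0.5 * nb * sd * sd) {
            rows.push_back(ci); rows.push_back(cj); rows.push_back(ck);
            rows.push_back(0); rows.push_back(0); rows.push_back(0);
            rows.push_back(ssd0 / nb);
          }
          continue;
        }
        // sub-voxel refinement: per-axis parabola through the neighbours
        double off[3] = {(double)bi, (double)bj, (double)bk};
        int ibest[3] = {bi, bj, bk};
        for (int ax = 0; ax < 3; ++ax) {
          if (ibest[ax] <= -range || ibest[ax] >= range) continue;
          double sc[3];
          for (int q = -1; q <= 1; ++q) {
            int oi = ibest[0] + (ax == 0 ? q : 0);
            int oj = ibest[1] + (ax == 1 ? q : 0);
            int ok = ibest[2] + (ax == 2 ? q : 0);
            double acc = 0;
            t = 0;
            const double* base = M + (ci + oi) + (R_xlen_t)(cj + oj) * sy +
                                 (R_xlen_t)(ck + ok) * sz;
            for (int dk = -half_block; dk <= half_block; ++dk)
              for (int dj = -half_block; dj <= half_block; ++dj) {
                const double* row = base + (R_xlen_t)dj * sy + (R_xlen_t)dk * sz;
                for (int di = -half_block; di <= half_block; ++di) {
                  double r = row[di] - fb[t++];
                  acc += r * r;
                }
              }
            sc[q + 1] = acc;
          }
          double den = sc[0] - 2 * sc[1] + sc[2];
          if (den > 1e-12) {
            double frac = 0.5 * (sc[0] - sc[2]) / den;
            if (frac > -1 && frac < 1) off[ax] += frac;
          }
        }
        rows.push_back(ci); rows.push_back(cj); rows.push_back(ck);
        rows.push_back(off[0]); rows.push_back(off[1]); rows.push_back(off[2]);
        rows.push_back(best / nb);
      }
    }
  }
  int nr = (int)(rows.size() / 7);
  NumericMatrix out(nr, 7);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < 7; ++c) out(r, c) = rows[r * 7 + c];
  return out;
}

// Least-squares objective for fitting scattered displacement observations
// with a cubic B-spline lattice: value = mean_n w_n ||B(p_n) coef - u_n||^2
// and its gradient with respect to coef. Node positions are given in
// continuous lattice units s = (pos - x0) / cspacing (one column per axis).
// [[Rcpp::export]]
List cpp_bspline_fit_grad(NumericMatrix svox, NumericMatrix uobs,
                          NumericVector wobs, NumericVector coef,
                          IntegerVector ncp, bool want_grad) {
  const int ncx = ncp[0], ncy = ncp[1], ncz = ncp[2];
  const R_xlen_t cstride = (R_xlen_t)ncx * ncy * ncz;
  const double* C = coef.begin();
  const R_xlen_t n = svox.nrow();
  NumericVector grad(want_grad ? cstride * 3 : 0);
  double* G = want_grad ? grad.begin() : (double*)0;
  double acc = 0.0, wsum = 0.0;
  double wx[4], wy[4], wz[4];
  for (R_xlen_t t = 0; t < n; ++t) {
    double sx = svox(t, 0), sy = svox(t, 1), sz = svox(t, 2);
    int i = (int)std::floor(sx), j = (int)std::floor(sy), k = (int)std::floor(sz);
    double fx = sx - i, fy = sy - j, fz = sz - k;
    double w;
    w = 1 - fx; wx[0] = w * w * w / 6.0;
    wx[1] = (3 * fx * fx * fx - 6 * fx * fx + 4) / 6.0;
    wx[2] = (-3 * fx * fx * fx + 3 * fx * fx + 3 * fx + 1) / 6.0;
    wx[3] = fx * fx * fx / 6.0;
    w = 1 - fy; wy[0] = w * w * w / 6.0;
    wy[1] = (3 * fy * fy * fy - 6 * fy * fy + 4) / 6.0;
    wy[2] = (-3 * fy * fy * fy + 3 * fy * fy + 3 * fy + 1) / 6.0;
    wy[3] = fy * fy * fy / 6.0;
    w = 1 - fz; wz[0] = w * w * w / 6.0;
    wz[1] = (3 * fz * fz * fz - 6 * fz * fz + 4) / 6.0;
    wz[2] = (-3 * fz * fz * fz + 3 * fz * fz + 3 * fz + 1) / 6.0;
    wz[3] = fz * fz * fz / 6.0;
    int i0 = i - 1, j0 = j - 1, k0 = k - 1;
    if (i0 < 0 || j0 < 0 || k0 < 0 ||
        i0 + 3 >= ncx || j0 + 3 >= ncy || k0 + 3 >= ncz) continue;
    double est[3] = {0, 0, 0};
    for (int c = 0; c < 4; ++c) {
      R_xlen_t zoff = (R_xlen_t)(k0 + c) * ncx * ncy;
      for (int b = 0; b < 4; ++b) {
        R_xlen_t yzoff = zoff + (R_xlen_t)(j0 + b) * ncx + i0;
        double wyz = wz[c] * wy[b];
        for (int a = 0; a < 4; ++a) {
          double ww = wyz * wx[a];
          est[0] += ww * C[yzoff + a];
          est[1] += ww * C[yzoff + a + cstride];
          est[2] += ww * C[yzoff + a + 2 * cstride];
        }
      }
    }
    double wn = wobs[t];
    double r0 = est[0] - uobs(t, 0), r1 = est[1] - uobs(t, 1),
           r2 = est[2] - uobs(t, 2);
    acc += wn * (r0 * r0 + r1 * r1 + r2 * r2);
    wsum += wn;
    if (want_grad) {
      for (int c = 0; c < 4; ++c) {
        R_xlen_t zoff = (R_xlen_t)(k0 + c) * ncx * ncy;
        for (int b = 0; b < 4; ++b) {
          R_xlen_t yzoff = zoff + (R_xlen_t)(j0 + b) * ncx + i0;
          double wyz = wz[c] * wy[b];
          for (int a = 0; a < 4; ++a) {
            double ww = 2.0 * wn * wyz * wx[a];
            G[yzoff + a] += ww * r0;
            G[yzoff + a + cstride] += ww * r1;
            G[yzoff + a + 2 * cstride] += ww * r2;
          }
        }
      }
    }
  }
  if (wsum <= 0) stop("no usable fit nodes");
  if (want_grad) {
    for (R_xlen_t q = 0; q < cstride * 3; ++q) G[q] /= wsum;
    grad.attr("dim") = IntegerVector::create(ncx, ncy, ncz, 3);
    return List::create(_["value"] = acc / wsum, _["grad"] = grad);
  }
  return List::create(_["value"] = acc / wsum);
}

// 6-connected component labelling of a 3D logical mask.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(nvox, 0);
  const int* m = mask.begin();
  int* L = lab.begin();
  std::vector<R_xlen_t> stack;
  int cur = 0;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (!m[s] || L[s]) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    L[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / sz);
      if (i > 0      && m[v - 1]  && !L[v - 1])  { L[v - 1] = cur;  stack.push_back(v - 1); }
      if (i < nx - 1 && m[v + 1]  && !L[v + 1])  { L[v + 1] = cur;  stack.push_back(v + 1); }
      if (j > 0      && m[v - sy] && !L[v - sy]) { L[v - sy] = cur; stack.push_back(v - sy); }
      if (j < ny - 1 && m[v + sy] && !L[v + sy]) { L[v + sy] = cur; stack.push_back(v + sy); }
      if (k > 0      && m[v - sz] && !L[v - sz]) { L[v - sz] = cur; stack.push_back(v - sz); }
      if (k < nz - 1 && m[v + sz] && !L[v + sz]) { L[v + sz] = cur; stack.push_back(v + sz); }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
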