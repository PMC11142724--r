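#include <Rcpp.h>
using namespace Rcpp;

// Multilinear (bi/trilinear) sampling of a (Z, Y, X) volume at fractional
// pixel coordinates, with the analytic gradient of each sample with respect
// to its (x, y, z) pixel position. Degenerate axes (size 1) contribute a
// single plane and a zero gradient. pad: 0 = zero outside, 1 = clamp to
// border. The volume is column-major with dim (Z, Y, X).

static inline double fetch(const double *v, int Z, int Y, int X,
                           int z, int y, int x, int pad) {
  if (pad == 1) {
    z = z < 0 ? 0 : (z >= Z ? Z - 1 : z);
    y = y < 0 ? 0 : (y >= Y ? Y - 1 : y);
    x = x < 0 ? 0 : (x >= X ? X - 1 : x);
  } else {
    if (z < 0 || z >= Z || y < 0 || y >= Y || x < 0 || x >= X) return 0.0;
  }
  return v[z + (R_xlen_t)Z * (y + (R_xlen_t)Y * x)];
}

// [[Rcpp::export]]
List cpp_sample_multilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix pts, int pad) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const double *v = vol.begin();
  const R_xlen_t n = pts.nrow();
  NumericVector val(n);
  NumericMatrix grad(n, 3);

  for (R_xlen_t i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);

    int x0, y0, z0;
    double fx, fy, fz;
    bool dx = X > 1, dy = Y > 1, dz = Z > 1;
    if (dx) { x0 = (int)std::floor(px); fx = px - x0; } else { x0 = 0; fx = 0.0; }
    if (dy) { y0 = (int)std::floor(py); fy = py - y0; } else { y0 = 0; fy = 0.0; }
    if (dz) { z0 = (int)std::floor(pz); fz = pz - z0; } else { z0 = 0; fz = 0.0; }

    double s = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
    const int nx = dx ? 2 : 1, ny = dy ? 2 : 1, nz = dz ? 2 : 1;
    for (int kz = 0; kz < nz; ++kz) {
      const double wz = kz ? fz : 1.0 - fz;
      const double dwz = dz ? (kz ? 1.0 : -1.0) : 0.0;
      for (int ky = 0; ky < ny; ++ky) {
        const double wy = ky ? fy : 1.0 - fy;
        const double dwy = dy ? (ky ? 1.0 : -1.0) : 0.0;
        for (int kx = 0; kx < nx; ++kx) {
          const double wx = kx ? fx : 1.0 - fx;
          const double dwx = dx ? (kx ? 1.0 : -1.0) : 0.0;
          const double vv = fetch(v, Z, Y, X, z0 + kz, y0 + ky, x0 + kx, pad);
          s  += vv * wx * wy * wz;
          gx += vv * dwx * wy * wz;
          gy += vv * wx * dwy * wz;
          gz += vv * wx * wy * dwz;
        }
      }
    }
    val[i] = s;
    grad(i, 0) = gx; grad(i, 1) = gy; grad(i, 2) = gz;
  }
  return List::create(_["value"] = val, _["grad"] = grad);
}

// Render a sum of anisotropic Gaussian blobs into a (Z, Y, X) volume.
// centers: n x 3 pixel coordinates (x, y, z); amp: n intensities;
// sigma: (z, y, x) standard deviations in pixels. Each blob is evaluated
// on a +/- 4 sigma window.
// [[Rcpp::export]]
NumericVector cpp_render_blobs(IntegerVector dims, NumericMatrix centers,
                               NumericVector amp, NumericVector sigma) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  NumericVector out((R_xlen_t)Z * Y * X);
  const double sz = sigma[0], sy = sigma[1], sx = sigma[2];
  const int rz = Z > 1 ? (int)std::ceil(4.0 * sz) : 0;
  const int ry = (int)std::ceil(4.0 * sy);
  const int rx = (int)std::ceil(4.0 * sx);
  for (int i = 0; i < centers.nrow(); ++i) {
    const double cx = centers(i, 0), cy = centers(i, 1), cz = centers(i, 2);
    const double a = amp[i];
    const int z0 = std::max(0, (int)std::floor(cz) - rz);
    const int z1 = std::min(Z - 1, (int)std::ceil(cz) + rz);
    const int y0 = std::max(0, (int)std::floor(cy) - ry);
    const int y1 = std::min(Y - 1, (int)std::ceil(cy) + ry);
    const int x0 = std::max(0, (int)std::floor(cx) - rx);
    const int x1 = std::min(X - 1, (int)std::ceil(cx) + rx);
    for (int x = x0; x <= x1; ++x) {
      const double ex = (x - cx) / sx;
      for (int y = y0; y <= y1; ++y) {
        const double ey = (y - cy) / sy;
        for (int z = z0; z <= z1; ++z) {
          const double ez = Z > 1 ? (z - cz) / sz : 0.0;
          out[z + (R_xlen_t)Z * (y + (R_xlen_t)Y * x)] +=
            a * std::exp(-0.5 * (ex * ex + ey * ey + ez * ez));
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Full registration term for one epoch: sample descriptors for all
// keypoints, apply the separable foveation blur, correlate against the
// reference descriptor matrix, and backpropagate to the pixel-space
// keypoint centers. Mirrors the R reference path (sample_descriptor_batch
// + blur_stack + corr_columns) but in one pass.
//
// vols: list of C channel volumes, each (Z, Y, X); centers: n x 3 pixel
// coords; offsets: G x 3 pixel offsets (z-fastest ordering, matching
// grid_shape (d, h, w)); refM: (G*C) x n blurred reference descriptors.

static void make_kernel(int len, double sigma, std::vector<double> &k, int &rad) {
  rad = (int)std::ceil(3.0 * sigma);
  k.assign(2 * rad + 1, 0.0);
  for (int i = -rad; i <= rad; ++i)
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
}

// In-place separable blur (or its exact adjoint) of a (d, h, w) block
// with per-position renormalized truncated Gaussian kernels.
static void blur_block(std::vector<double> &a, const int gs[3], double sigma,
                       bool adjoint, std::vector<double> &tmp) {
  if (sigma <= 0) return;
  std::vector<double> kern;
  int rad;
  make_kernel(0, sigma, kern, rad);
  const int d = gs[0], h = gs[1], w = gs[2];
  const int strides[3] = {1, d, d * h};
  const int sizes[3] = {d, h, w};
  tmp.resize(a.size());
  for (int ax = 0; ax < 3; ++ax) {
    const int n = sizes[ax];
    if (n == 1) continue;
    const int stride = strides[ax];
    // rowsum[i] = sum of kernel weights within range at position i
    std::vector<double> rowsum(n, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = std::max(0, i - rad); j <= std::min(n - 1, i + rad); ++j)
        rowsum[i] += kern[j - i + rad];
    std::fill(tmp.begin(), tmp.end(), 0.0);
    const int total = d * h * w;
    for (int base = 0; base < total; ++base) {
      const int i = (base / stride) % n;
      // index of this lane's position-0 element
      if (!adjoint) {
        double s = 0.0;
        for (int j = std::max(0, i - rad); j <= std::min(n - 1, i + rad); ++j)
          s += kern[j - i + rad] * a[base + (j - i) * stride];
        tmp[base] = s / rowsum[i];
      } else {
        // adjoint: tmp[j] += k(|i-j|)/rowsum[i] * a[i]
        double s = 0.0;
        for (int j = std::max(0, i - rad); j <= std::min(n - 1, i + rad); ++j)
          s += kern[j - i + rad] / rowsum[j] * a[base + (j - i) * stride];
        tmp[base] = s;
      }
    }
    a = tmp;
  }
}

// [[Rcpp::export]]
List cpp_registration_term(List vols, IntegerVector dims,
                           NumericMatrix centers, NumericMatrix offsets,
                           IntegerVector grid_shape, NumericMatrix refM,
                           double sigma, int pad,
                           NumericVector fovea_w) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int n = centers.nrow();
  const int G = offsets.nrow();
  const int C = vols.size();
  const int gs[3] = {grid_shape[0], grid_shape[1], grid_shape[2]};
  std::vector<const double *> vptr(C);
  std::vector<NumericVector> keep(C);
  for (int c = 0; c < C; ++c) {
    keep[c] = as<NumericVector>(vols[c]);
    vptr[c] = keep[c].begin();
  }
  NumericVector rvec(n);
  NumericMatrix grad_px(n, 3);
  double loss = 0.0;

  std::vector<double> desc(G * C), tmp, gdesc(G * C), gblk;
  std::vector<double> gx(G * C), gy(G * C), gz(G * C);

  for (int i = 0; i < n; ++i) {
    const double cx = centers(i, 0), cy = centers(i, 1), cz = centers(i, 2);
    // sample all channels with gradients
    for (int c = 0; c < C; ++c) {
      const double *v = vptr[c];
      for (int g = 0; g < G; ++g) {
        const double px = cx + offsets(g, 0);
        const double py = cy + offsets(g, 1);
        const double pz = cz + offsets(g, 2);
        int x0, y0, z0;
        double fx, fy, fz;
        const bool dx = X > 1, dy = Y > 1, dz = Z > 1;
        if (dx) { x0 = (int)std::floor(px); fx = px - x0; } else { x0 = 0; fx = 0.0; }
        if (dy) { y0 = (int)std::floor(py); fy = py - y0; } else { y0 = 0; fy = 0.0; }
        if (dz) { z0 = (int)std::floor(pz); fz = pz - z0; } else { z0 = 0; fz = 0.0; }
        double s = 0, sgx = 0, sgy = 0, sgz = 0;
        const int nx = dx ? 2 : 1, ny = dy ? 2 : 1, nz = dz ? 2 : 1;
        for (int kz = 0; kz < nz; ++kz) {
          const double wz = kz ? fz : 1.0 - fz;
          const double dwz = dz ? (kz ? 1.0 : -1.0) : 0.0;
          for (int ky = 0; ky < ny; ++ky) {
            const double wy = ky ? fy : 1.0 - fy;
            const double dwy = dy ? (ky ? 1.0 : -1.0) : 0.0;
            for (int kx2 = 0; kx2 < nx; ++kx2) {
              const double wx = kx2 ? fx : 1.0 - fx;
              const double dwx = dx ? (kx2 ? 1.0 : -1.0) : 0.0;
              const double vv = fetch(v, Z, Y, X, z0 + kz, y0 + ky, x0 + kx2, pad);
              s += vv * wx * wy * wz;
              sgx += vv * dwx * wy * wz;
              sgy += vv * wx * dwy * wz;
              sgz += vv * wx * wy * dwz;
            }
          }
        }
        desc[c * G + g] = s;
        gx[c * G + g] = sgx; gy[c * G + g] = sgy; gz[c * G + g] = sgz;
      }
    }
    // blur each channel block
    if (sigma > 0) {
      for (int c = 0; c < C; ++c) {
        gblk.assign(desc.begin() + c * G, desc.begin() + (c + 1) * G);
        blur_block(gblk, gs, sigma, false, tmp);
        std::copy(gblk.begin(), gblk.end(), desc.begin() + c * G);
      }
    }
    // (optionally foveated) Pearson correlation with the reference column
    const int m = G * C;
    const bool have_w = fovea_w.size() == G;
    double sw = 0, mc = 0, mr = 0;
    for (int g = 0; g < m; ++g) {
      const double wg = have_w ? fovea_w[g % G] : 1.0;
      sw += wg; mc += wg * desc[g]; mr += wg * refM(g, i);
    }
    mc /= sw; mr /= sw;
    double sc2 = 0, sr2 = 0, dot = 0;
    for (int g = 0; g < m; ++g) {
      const double wg = have_w ? fovea_w[g % G] : 1.0;
      const double a = desc[g] - mc, b = refM(g, i) - mr;
      sc2 += wg * a * a; sr2 += wg * b * b; dot += wg * a * b;
    }
    double r = 0.0;
    const bool ok = sc2 > 0 && sr2 > 0;
    if (ok) r = dot / std::sqrt(sc2 * sr2);
    rvec[i] = r;
    loss += 1.0 - r;
    // d(1 - r)/d desc_j = -w_j * (ref_c/(|c||r|) - r * desc_c / |c|^2)
    if (ok) {
      const double inv = 1.0 / std::sqrt(sc2 * sr2);
      for (int g = 0; g < m; ++g) {
        const double wg = have_w ? fovea_w[g % G] : 1.0;
        const double a = desc[g] - mc, b = refM(g, i) - mr;
        gdesc[g] = -wg * (b * inv - r * a / sc2);
      }
    } else {
      std::fill(gdesc.begin(), gdesc.end(), 0.0);
    }
    // adjoint blur, then chain through sampling gradients
    double gpx = 0, gpy = 0, gpz = 0;
    for (int c = 0; c < C; ++c) {
      if (sigma > 0) {
        gblk.assign(gdesc.begin() + c * G, gdesc.begin() + (c + 1) * G);
        blur_block(gblk, gs, sigma, true, tmp);
        std::copy(gblk.begin(), gblk.end(), gdesc.begin() + c * G);
      }
      for (int g = 0; g < G; ++g) {
        const double gg = gdesc[c * G + g];
        gpx += gg * gx[c * G + g];
        gpy += gg * gy[c * G + g];
        gpz += gg * gz[c * G + g];
      }
    }
    grad_px(i, 0) = gpx; grad_px(i, 1) = gpy; grad_px(i, 2) = gpz;
  }
  return List::create(_["loss"] = loss, _["r"] = rvec,
                      _["grad_px"] = grad_px);
}

// In-place shifted accumulation for the detection combiner:
// dst[p] += coef * src[p + o] (zero outside), over a (Z, Y, X) volume.
// dst must be a freshly allocated, unshared vector.
// [[Rcpp::export]]
void cpp_shift_add(NumericVector dst, NumericVector src, IntegerVector dims,
                   IntegerVector o, double coef) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int oz = o[0], oy = o[1], ox = o[2];
  double *d = dst.begin();
  const double *s = src.begin();
  const int z0 = std::max(0, -oz), z1 = std::min(Z, Z - oz);
  const int y0 = std::max(0, -oy), y1 = std::min(Y, Y - oy);
  const int x0 = std::max(0, -ox), x1 = std::min(X, X - ox);
  for (int x = x0; x < x1; ++x)
    for (int y = y0; y < y1; ++y) {
      const R_xlen_t db = (R_xlen_t)Z * (y + (R_xlen_t)Y * x);
      const R_xlen_t sb = (R_xlen_t)Z * (y + oy + (R_xlen_t)Y * (x + ox)) + oz;
      for (int z = z0; z < z1; ++z) d[db + z] += coef * s[sb + z];
    }
}

// Shifted dot product: sum_p a[p] * b[p + o] (zero outside).
// [[Rcpp::export]]
double cpp_shift_dot(NumericVector a, NumericVector b, IntegerVector dims,
                     IntegerVector o) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int oz = o[0], oy = o[1], ox = o[2];
  const double *pa = a.begin(), *pb = b.begin();
  const int z0 = std::max(0, -oz), z1 = std::min(Z, Z - oz);
  const int y0 = std::max(0, -oy), y1 = std::min(Y, Y - oy);
  const int x0 = std::max(0, -ox), x1 = std::min(X, X - ox);
  double s = 0.0;
  for (int x = x0; x < x1; ++x)
    for (int y = y0; y < y1; ++y) {
      const R_xlen_t ab = (R_xlen_t)Z * (y + (R_xlen_t)Y * x);
      const R_xlen_t bb = (R_xlen_t)Z * (y + oy + (R_xlen_t)Y * (x + ox)) + oz;
      for (int z = z0; z < z1; ++z) s += pa[ab + z] * pb[bb + z];
    }
  return s;
}
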