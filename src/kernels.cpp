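#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Local Shannon entropy (base 2) over a digital disk neighbourhood.
// `q` holds quantized symbols in [0, levels); at the image border the disk is
// cropped to valid pixels.  O(npix * ndisk) with a scratch histogram that is
// cleared incrementally, so the cost does not depend on `levels`.
// [[Rcpp::export]]
NumericMatrix local_entropy_cpp(IntegerMatrix q, int radius, int levels) {
  const int ny = q.nrow(), nx = q.ncol();
  std::vector<int> dy, dx;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { dy.push_back(a); dx.push_back(b); }
  const int nd = (int)dy.size();
  std::vector<int> count(levels, 0);
  std::vector<int> used;
  used.reserve(nd);
  const double inv_log2 = 1.0 / std::log(2.0);
  NumericMatrix out(ny, nx);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      used.clear();
      int n = 0;
      for (int k = 0; k < nd; ++k) {
        const int ii = i + dy[k], jj = j + dx[k];
        if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
        const int v = q(ii, jj);
        if (count[v] == 0) used.push_back(v);
        ++count[v];
        ++n;
      }
      double h = 0.0;
      for (size_t u = 0; u < used.size(); ++u) {
        const double p = (double)count[used[u]] / n;
        h -= p * std::log(p) * inv_log2;
        count[used[u]] = 0;
      }
      out(i, j) = h;
    }
  }
  return out;
}

// Resample a volume under a rotation about a centre point, with trilinear
// interpolation.  `vol` is a (nz, ny, nx) array; spacings are physical.
// For output voxel at physical position p the source position is
// s = Rinv * (p - c) + c, i.e. the volume content is rotated by R = Rinv^-1.
// Output voxels whose source position falls outside the volume are NA
// ("not covered by this view").
// [[Rcpp::export]]
NumericVector resample_rotated_cpp(NumericVector vol, IntegerVector dims,
                                   double pixel_size, double plane_spacing,
                                   NumericMatrix rinv) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double cz = nz * plane_spacing / 2.0;
  const double cy = ny * pixel_size / 2.0;
  const double cx = nx * pixel_size / 2.0;
  NumericVector out(vol.size(), NA_REAL);
  const double r11 = rinv(0, 0), r12 = rinv(0, 1), r13 = rinv(0, 2);
  const double r21 = rinv(1, 0), r22 = rinv(1, 1), r23 = rinv(1, 2);
  const double r31 = rinv(2, 0), r32 = rinv(2, 1), r33 = rinv(2, 2);
  // index helper: vol[(k) + nz*(j) + nz*ny*(i)] for (z=k, y=j, x=i)
  const int sy = nz, sx = nz * ny;
  for (int i = 0; i < nx; ++i) {
    const double px = (i + 0.5) * pixel_size - cx;
    for (int j = 0; j < ny; ++j) {
      const double py = (j + 0.5) * pixel_size - cy;
      for (int k = 0; k < nz; ++k) {
        const double pz = (k + 0.5) * plane_spacing - cz;
        // source physical position (x, y, z)
        const double qx = r11 * px + r12 * py + r13 * pz;
        const double qy = r21 * px + r22 * py + r23 * pz;
        const double qz = r31 * px + r32 * py + r33 * pz;
        // continuous voxel coordinates (0-based, voxel centres at idx+0.5)
        const double fx = (qx + cx) / pixel_size - 0.5;
        const double fy = (qy + cy) / pixel_size - 0.5;
        const double fz = (qz + cz) / plane_spacing - 0.5;
        // covered if inside the physical extent (voxel centres +- half a
        // voxel); interpolation clamps to the edge value in the outer half
        if (fx < -0.5 || fx > nx - 0.5 || fy < -0.5 || fy > ny - 0.5 ||
            fz < -0.5 || fz > nz - 0.5) continue;
        const double gx = std::min(std::max(fx, 0.0), (double)(nx - 1));
        const double gy = std::min(std::max(fy, 0.0), (double)(ny - 1));
        const double gz = std::min(std::max(fz, 0.0), (double)(nz - 1));
        int x0 = (int)std::floor(gx), y0 = (int)std::floor(gy), z0 = (int)std::floor(gz);
        if (x0 >= nx - 1) x0 = nx - 2;
        if (x0 < 0) x0 = 0;
        if (y0 >= ny - 1) y0 = ny - 2;
        if (y0 < 0) y0 = 0;
        if (z0 >= nz - 1) z0 = nz - 2;
        if (z0 < 0) z0 = 0;
        const int x1 = (nx > 1) ? x0 + 1 : x0;
        const int y1 = (ny > 1) ? y0 + 1 : y0;
        const int z1 = (nz > 1) ? z0 + 1 : z0;
        const double tx = (nx > 1) ? gx - x0 : 0.0;
        const double ty = (ny > 1) ? gy - y0 : 0.0;
        const double tz = (nz > 1) ? gz - z0 : 0.0;
        const double c000 = vol[z0 + sy * y0 + sx * x0];
        const double c001 = vol[z0 + sy * y0 + sx * x1];
        const double c010 = vol[z0 + sy * y1 + sx * x0];
        const double c011 = vol[z0 + sy * y1 + sx * x1];
        const double c100 = vol[z1 + sy * y0 + sx * x0];
        const double c101 = vol[z1 + sy * y0 + sx * x1];
        const double c110 = vol[z1 + sy * y1 + sx * x0];
        const double c111 = vol[z1 + sy * y1 + sx * x1];
        const double v =
          (1 - tz) * ((1 - ty) * ((1 - tx) * c000 + tx * c001) +
                      ty * ((1 - tx) * c010 + tx * c011)) +
          tz * ((1 - ty) * ((1 - tx) * c100 + tx * c101) +
                ty * ((1 - tx) * c110 + tx * c111));
        out[k + sy * j + sx * i] = v;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
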