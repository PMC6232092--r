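#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Tilt geometry (declared once, used everywhere): rotation about the +y
// axis, right-handed, projection along +z. Volumes are arrays indexed
// (x, y, z); images are matrices indexed (row = y, col = x). Angles in
// degrees. Voxel (X, Z) relative to the center lands on detector column
//   t = cx + ca*(X) - sa*(Z)
// and is deposited there with linear (hat) weights, so projected mass is
// conserved exactly for any angle and the 0-degree projection is exactly
// the axis sum. This splat scheme is the exact adjoint of the
// interpolation used by cpp_backproject_y.

// [[Rcpp::export]]
NumericMatrix cpp_project_y(NumericVector vol, int nx, int ny, int nz,
                            double angleDeg) {
  const double th = angleDeg * M_PI / 180.0;
  const double ca = std::cos(th), sa = std::sin(th);
  const double cx = 0.5 * (nx - 1), cz = 0.5 * (nz - 1);
  NumericMatrix out(ny, nx);
  const double *v = vol.begin();
  for (int iz = 0; iz < nz; ++iz) {
    const double Z = iz - cz;
    for (int ix = 0; ix < nx; ++ix) {
      const double t = cx + ca * (ix - cx) - sa * Z;
      if (t < 0 || t > nx - 1) continue;
      int t0 = (int)std::floor(t);
      if (t0 == nx - 1) t0 = nx - 2;
      const double ft = t - t0;
      const double *s = v + ix + (size_t)nx * ny * iz;
      double *o0 = &out(0, t0);
      double *o1 = &out(0, t0 + 1);
      for (int iy = 0; iy < ny; ++iy) {
        const double val = s[(size_t)nx * iy];
        o0[iy] += (1 - ft) * val;
        o1[iy] += ft * val;
      }
    }
  }
  return out;
}

// Adjoint smear of (already r-weighted) projections back through the
// volume: voxel (X, Z) reads detector column t = cx + ca*(X-cx) - sa*(Z-cz)
// of each projection, linearly interpolated, consistent with
// cpp_project_y's forward geometry.

// [[Rcpp::export]]
NumericVector cpp_backproject_y(NumericVector imgs, int ny, int nx, int nk,
                                NumericVector anglesDeg, int nz) {
  NumericVector vol((size_t)nx * ny * nz);
  double *v = vol.begin();
  const double *P = imgs.begin();
  const double cx = 0.5 * (nx - 1), cz = 0.5 * (nz - 1);
  for (int k = 0; k < nk; ++k) {
    const double th = anglesDeg[k] * M_PI / 180.0;
    const double ca = std::cos(th), sa = std::sin(th);
    const double *Pk = P + (size_t)ny * nx * k;
    for (int iz = 0; iz < nz; ++iz) {
      const double Z = iz - cz;
      for (int ix = 0; ix < nx; ++ix) {
        const double X = ix - cx;
        const double t = cx + ca * X - sa * Z;
        if (t < 0 || t > nx - 1) continue;
        int t0 = (int)std::floor(t);
        if (t0 == nx - 1) t0 = nx - 2;
        const double ft = t - t0;
        const double *c0 = Pk + (size_t)ny * t0;
        const double *c1 = c0 + ny;
        double *o = v + ix + (size_t)nx * ny * iz;
        for (int iy = 0; iy < ny; ++iy)
          o[(size_t)nx * iy] += (1 - ft) * c0[iy] + ft * c1[iy];
      }
    }
  }
  return vol;
}
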