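#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Bz (lab frame, Hz per ampere) of a polygonally discretised circular loop.
// points: N x 3 matrix of world coordinates in mm. center (mm), normal (unit),
// radius (mm). Biot-Savart midpoint rule over n_segments chords; the only
// discretisation error is polygon-vs-circle, O(n_segments^-2).
// Returns NaN for points closer than min_dist_mm to any chord midpoint.
// [[Rcpp::export(name = ".loop_bz_cpp")]]
NumericVector loop_bz_cpp(NumericMatrix points, NumericVector center,
                          NumericVector normal, double radius, int turns,
                          int n_segments, double min_dist_mm,
                          double gamma_hz_per_t) {
  const int np = points.nrow();
  const double mu0_over_4pi = 1e-7;            // T m / A
  const double a = radius * 1e-3;              // m

  // orthonormal frame (u, v, n)
  double nx = normal[0], ny = normal[1], nz = normal[2];
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  nx /= nn; ny /= nn; nz /= nn;
  double ux, uy, uz;
  if (std::fabs(nx) < 0.9) { ux = 1.0; uy = 0.0; uz = 0.0; }
  else                     { ux = 0.0; uy = 1.0; uz = 0.0; }
  double d = ux * nx + uy * ny + uz * nz;
  ux -= d * nx; uy -= d * ny; uz -= d * nz;
  double un = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= un; uy /= un; uz /= un;
  double vx = ny * uz - nz * uy;
  double vy = nz * ux - nx * uz;
  double vz = nx * uy - ny * ux;

  const int ns = n_segments;
  std::vector<double> mx(ns), my(ns), mz(ns), lx(ns), ly(ns), lz(ns);
  const double cx = center[0] * 1e-3, cy = center[1] * 1e-3,
               cz = center[2] * 1e-3;
  for (int s = 0; s < ns; ++s) {
    double t0 = 2.0 * M_PI * s / ns;
    double t1 = 2.0 * M_PI * (s + 1) / ns;
    double p0x = cx + a * (std::cos(t0) * ux + std::sin(t0) * vx);
    double p0y = cy + a * (std::cos(t0) * uy + std::sin(t0) * vy);
    double p0z = cz + a * (std::cos(t0) * uz + std::sin(t0) * vz);
    double p1x = cx + a * (std::cos(t1) * ux + std::sin(t1) * vx);
    double p1y = cy + a * (std::cos(t1) * uy + std::sin(t1) * vy);
    double p1z = cz + a * (std::cos(t1) * uz + std::sin(t1) * vz);
    mx[s] = 0.5 * (p0x + p1x);
    my[s] = 0.5 * (p0y + p1y);
    mz[s] = 0.5 * (p0z + p1z);
    lx[s] = p1x - p0x; ly[s] = p1y - p0y; lz[s] = p1z - p0z;
  }

  const double min_d2 = (min_dist_mm * 1e-3) * (min_dist_mm * 1e-3);
  const double scale = mu0_over_4pi * turns * gamma_hz_per_t;
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    const double px = points(i, 0) * 1e-3, py = points(i, 1) * 1e-3,
                 pz = points(i, 2) * 1e-3;
    double bz = 0.0;
    bool singular = false;
    for (int s = 0; s < ns; ++s) {
      double rx = px - mx[s], ry = py - my[s], rz = pz - mz[s];
      double r2 = rx * rx + ry * ry + rz * rz;
      if (r2 < min_d2) { singular = true; break; }
      double inv_r3 = 1.0 / (r2 * std::sqrt(r2));
      // z-component of dl x r
      bz += (lx[s] * ry - ly[s] * rx) * inv_r3;
    }
    out[i] = singular ? NA_REAL : scale * bz;
  }
  return out;
}
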