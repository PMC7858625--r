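// Grid resampling for 3D volumes: cubic B-spline (with the standard
// causal/anti-causal prefilter so the interpolant passes through the
// samples), trilinear, and nearest-neighbour. Also an in-plane rotation
// about the slice axis used for training augmentation. All arithmetic in
// double; arrays are column-major (x fastest).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double POLE = -0.26794919243112270647; // sqrt(3) - 2

// In-place cubic B-spline prefilter of one line (Unser et al.).
static void prefilter_line(double* c, int n, int stride) {
  if (n == 1) return;
  const double z = POLE;
  const double lambda = 6.0;
  for (int i = 0; i < n; ++i) c[(size_t)i * stride] *= lambda;
  // causal initialization (mirror boundary, truncated horizon)
  int horizon = (int)std::ceil(std::log(1e-10) / std::log(std::fabs(z)));
  if (horizon > n) horizon = n;
  double sum = c[0];
  double zk = z;
  for (int k = 1; k < horizon; ++k) {
    sum += zk * c[(size_t)k * stride];
    zk *= z;
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i)
    c[(size_t)i * stride] += z * c[(size_t)(i - 1) * stride];
  // anti-causal initialization
  c[(size_t)(n - 1) * stride] =
    (z / (z * z - 1.0)) *
    (z * c[(size_t)(n - 2) * stride] + c[(size_t)(n - 1) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[(size_t)i * stride] =
      z * (c[(size_t)(i + 1) * stride] - c[(size_t)i * stride]);
}

static void prefilter_volume(std::vector<double>& v, int nx, int ny, int nz) {
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      prefilter_line(&v[(size_t)nx * (y + (size_t)ny * z)], nx, 1);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      prefilter_line(&v[(size_t)x + (size_t)nx * ny * z], ny, nx);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      prefilter_line(&v[(size_t)x + (size_t)nx * y], nz, nx * ny);
}

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

static inline void bspline_weights(double t, int& i0, double w[4]) {
  const double fl = std::floor(t);
  const double u = t - fl;
  i0 = (int)fl - 1;
  const double u2 = u * u, u3 = u2 * u;
  w[0] = (1.0 - 3.0 * u + 3.0 * u2 - u3) / 6.0;
  w[1] = (3.0 * u3 - 6.0 * u2 + 4.0) / 6.0;
  w[2] = (-3.0 * u3 + 3.0 * u2 + 3.0 * u + 1.0) / 6.0;
  w[3] = u3 / 6.0;
}

// Sample volume at continuous index (tx,ty,tz); method 0=nearest, 1=linear,
// 2=cubic B-spline on prefiltered coefficients.
static double sample_at(const double* v, int nx, int ny, int nz,
                        double tx, double ty, double tz, int method) {
  if (method == 0) {
    const int x = clampi((int)std::lround(tx), 0, nx - 1);
    const int y = clampi((int)std::lround(ty), 0, ny - 1);
    const int z = clampi((int)std::lround(tz), 0, nz - 1);
    return v[(size_t)x + (size_t)nx * (y + (size_t)ny * z)];
  }
  if (method == 1) {
    const int x0 = clampi((int)std::floor(tx), 0, nx - 1);
    const int y0 = clampi((int)std::floor(ty), 0, ny - 1);
    const int z0 = clampi((int)std::floor(tz), 0, nz - 1);
    const int x1 = clampi(x0 + 1, 0, nx - 1);
    const int y1 = clampi(y0 + 1, 0, ny - 1);
    const int z1 = clampi(z0 + 1, 0, nz - 1);
    const double fx = tx - std::floor(tx), fy = ty - std::floor(ty),
                 fz = tz - std::floor(tz);
    double out = 0.0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                           (dz ? fz : 1 - fz);
          const int xi = dx ? x1 : x0, yi = dy ? y1 : y0, zi = dz ? z1 : z0;
          out += w * v[(size_t)xi + (size_t)nx * (yi + (size_t)ny * zi)];
        }
    return out;
  }
  int ix, iy, iz;
  double wx[4], wy[4], wz[4];
  bspline_weights(tx, ix, wx);
  bspline_weights(ty, iy, wy);
  bspline_weights(tz, iz, wz);
  double out = 0.0;
  for (int a = 0; a < 4; ++a) {
    const int zi = clampi(iz + a, 0, nz - 1);
    double sy = 0.0;
    for (int bb = 0; bb < 4; ++bb) {
      const int yi = clampi(iy + bb, 0, ny - 1);
      double sx = 0.0;
      for (int cc = 0; cc < 4; ++cc) {
        const int xi = clampi(ix + cc, 0, nx - 1);
        sx += wx[cc] * v[(size_t)xi + (size_t)nx * (yi + (size_t)ny * zi)];
      }
      sy += wy[bb] * sx;
    }
    out += wz[a] * sy;
  }
  return out;
}

static int method_code(const std::string& m) {
  if (m == "nearest") return 0;
  if (m == "linear") return 1;
  if (m == "bspline") return 2;
  stop("unknown interpolation method '%s'", m.c_str());
}

// Resample onto a new grid; output index i maps to input continuous index
// i * out_spacing / in_spacing (axis-wise, voxel centres aligned at 0).
// [[Rcpp::export(name = ".resample_grid")]]
NumericVector resample_grid(NumericVector vol, IntegerVector in_dims,
                            NumericVector in_spacing, IntegerVector out_dims,
                            NumericVector out_spacing, std::string method) {
  const int nx = in_dims[0], ny = in_dims[1], nz = in_dims[2];
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  const int mc = method_code(method);
  std::vector<double> buf(vol.begin(), vol.end());
  if (mc == 2) prefilter_volume(buf, nx, ny, nz);
  const double rx = out_spacing[0] / in_spacing[0];
  const double ry = out_spacing[1] / in_spacing[1];
  const double rz = out_spacing[2] / in_spacing[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  double* dst = out.begin();
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x)
        dst[(size_t)x + (size_t)ox * (y + (size_t)oy * z)] =
          sample_at(buf.data(), nx, ny, nz, x * rx, y * ry, z * rz, mc);
  out.attr("dim") = out_dims;
  return out;
}

// Rotate about the slice (z) axis around the in-plane centre; same grid out.
// [[Rcpp::export(name = ".rotate_inplane")]]
NumericVector rotate_inplane(NumericVector vol, IntegerVector dims,
                             double angle_deg, std::string method) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mc = method_code(method);
  std::vector<double> buf(vol.begin(), vol.end());
  if (mc == 2) prefilter_volume(buf, nx, ny, nz);
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* dst = out.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        // inverse rotation of the destination coordinate
        const double xr = ct * (x - cx) + st * (y - cy) + cx;
        const double yr = -st * (x - cx) + ct * (y - cy) + cy;
        double val;
        if (xr < -0.5 || xr > nx - 0.5 || yr < -0.5 || yr > ny - 0.5)
          val = 0.0;
        else
          val = sample_at(buf.data(), nx, ny, nz, xr, yr, (double)z, mc);
        dst[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] = val;
      }
  out.attr("dim") = dims;
  return out;
}
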