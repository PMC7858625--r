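// Neural-network kernels: 3x3x3 convolution (same padding) via chunked
// im2col + GEMM, 2x max/average pooling, and 2x2x2 stride-2 transposed
// convolution. Feature maps are (nx*ny*nz) x C matrices, voxels in
// column-major order (x fastest). GEMM work is done in single precision;
// the R interface is double.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::fmat to_float(const NumericMatrix& X) {
  arma::fmat F(X.nrow(), X.ncol());
  const double* src = X.begin();
  float* dst = F.memptr();
  const R_xlen_t n = (R_xlen_t)X.nrow() * X.ncol();
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return F;
}

static NumericMatrix to_double(const arma::fmat& F) {
  NumericMatrix X(F.n_rows, F.n_cols);
  const float* src = F.memptr();
  double* dst = X.begin();
  const R_xlen_t n = (R_xlen_t)F.n_rows * F.n_cols;
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = (double)src[i];
  return X;
}

// Fill the im2col matrix for output slices z in [z0, z1). Columns are
// indexed k*Cin + cin with k = (dz+1)*9 + (dy+1)*3 + (dx+1).
static void fill_im2col(const arma::fmat& X, int nx, int ny, int nz,
                        int z0, int z1, arma::fmat& Xcol) {
  const int Cin = X.n_cols;
  const size_t nxy = (size_t)nx * ny;
  Xcol.zeros();
  for (int k = 0; k < 27; ++k) {
    const int dz = k / 9 - 1, dy = (k / 3) % 3 - 1, dx = k % 3 - 1;
    for (int cin = 0; cin < Cin; ++cin) {
      float* dst = Xcol.colptr((size_t)k * Cin + cin);
      const float* src = X.colptr(cin);
      for (int z = z0; z < z1; ++z) {
        const int zi = z + dz;
        if (zi < 0 || zi >= nz) continue;
        for (int y = 0; y < ny; ++y) {
          const int yi = y + dy;
          if (yi < 0 || yi >= ny) continue;
          const int xlo = std::max(0, -dx), xhi = std::min(nx, nx - dx);
          if (xhi <= xlo) continue;
          std::memcpy(dst + xlo + (size_t)nx * (y + (size_t)ny * (z - z0)),
                      src + (xlo + dx) + (size_t)nx * (yi + (size_t)ny * zi),
                      (size_t)(xhi - xlo) * sizeof(float));
        }
      }
    }
  }
}

// Scatter-add the transpose of fill_im2col.
static void add_col2im(const arma::fmat& Gcol, int nx, int ny, int nz,
                       int z0, int z1, arma::fmat& GX) {
  const int Cin = GX.n_cols;
  const size_t nxy = (size_t)nx * ny;
  (void)nxy;
  for (int k = 0; k < 27; ++k) {
    const int dz = k / 9 - 1, dy = (k / 3) % 3 - 1, dx = k % 3 - 1;
    for (int cin = 0; cin < Cin; ++cin) {
      const float* src = Gcol.colptr((size_t)k * Cin + cin);
      float* dst = GX.colptr(cin);
      for (int z = z0; z < z1; ++z) {
        const int zi = z + dz;
        if (zi < 0 || zi >= nz) continue;
        for (int y = 0; y < ny; ++y) {
          const int yi = y + dy;
          if (yi < 0 || yi >= ny) continue;
          const int xlo = std::max(0, -dx), xhi = std::min(nx, nx - dx);
          for (int x = xlo; x < xhi; ++x) {
            dst[(x + dx) + (size_t)nx * (yi + (size_t)ny * zi)] +=
              src[x + (size_t)nx * (y + (size_t)ny * (z - z0))];
          }
        }
      }
    }
  }
}

static int chunk_slices(int nx, int ny, int cols) {
  // keep the im2col chunk near 64 MB
  const double budget = 64.0 * 1024 * 1024 / sizeof(float);
  int cz = (int)std::floor(budget / ((double)nx * ny * cols));
  return std::max(1, cz);
}

// [[Rcpp::export(name = ".conv3d_fw")]]
NumericMatrix conv3d_fw(NumericMatrix X, IntegerVector dims,
                        NumericMatrix W, NumericVector b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = X.ncol(), Cout = W.ncol();
  if (W.nrow() != 27 * Cin) stop("conv3d: weight rows != 27*Cin");
  arma::fmat Xf = to_float(X), Wf = to_float(W);
  arma::frowvec bf(Cout);
  for (int c = 0; c < Cout; ++c) bf[c] = (float)b[c];
  arma::fmat Y((size_t)nx * ny * nz, Cout);
  const int cz = chunk_slices(nx, ny, 27 * Cin);
  arma::fmat Xcol;
  for (int z0 = 0; z0 < nz; z0 += cz) {
    const int z1 = std::min(nz, z0 + cz);
    const size_t nch = (size_t)nx * ny * (z1 - z0);
    Xcol.set_size(nch, (size_t)27 * Cin);
    fill_im2col(Xf, nx, ny, nz, z0, z1, Xcol);
    Y.rows((size_t)nx * ny * z0, (size_t)nx * ny * z1 - 1) =
      Xcol * Wf + arma::repmat(bf, nch, 1);
  }
  return to_double(Y);
}

// [[Rcpp::export(name = ".conv3d_bw")]]
List conv3d_bw(NumericMatrix X, IntegerVector dims,
               NumericMatrix W, NumericMatrix gY) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = X.ncol(), Cout = W.ncol();
  arma::fmat Xf = to_float(X), Wf = to_float(W), gYf = to_float(gY);
  arma::fmat gX((size_t)nx * ny * nz, Cin, arma::fill::zeros);
  arma::fmat gW((size_t)27 * Cin, Cout, arma::fill::zeros);
  const int cz = chunk_slices(nx, ny, 27 * Cin);
  arma::fmat Xcol, gcol;
  for (int z0 = 0; z0 < nz; z0 += cz) {
    const int z1 = std::min(nz, z0 + cz);
    const size_t r0 = (size_t)nx * ny * z0, r1 = (size_t)nx * ny * z1 - 1;
    Xcol.set_size((size_t)nx * ny * (z1 - z0), (size_t)27 * Cin);
    fill_im2col(Xf, nx, ny, nz, z0, z1, Xcol);
    arma::fmat gYc = gYf.rows(r0, r1);
    gW += Xcol.t() * gYc;
    gcol = gYc * Wf.t();
    add_col2im(gcol, nx, ny, nz, z0, z1, gX);
  }
  arma::frowvec gb = arma::sum(gYf, 0);
  NumericVector gbv(Cout);
  for (int c = 0; c < Cout; ++c) gbv[c] = (double)gb[c];
  return List::create(_["gx"] = to_double(gX), _["gw"] = to_double(gW),
                      _["gb"] = gbv);
}

// 2x2x2 max pooling; returns pooled values and 1-based argmax row indices.
// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericMatrix X, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = X.ncol();
  if (nx % 2 || ny % 2 || nz % 2) stop("maxpool: dims must be even");
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const size_t No = (size_t)ox * oy * oz;
  NumericMatrix Y(No, C);
  IntegerMatrix idx(No, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &X(0, c);
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x) {
          double best = -HUGE_VAL; size_t barg = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const size_t r = (size_t)(2 * x + dx) +
                  (size_t)nx * ((2 * y + dy) + (size_t)ny * (2 * z + dz));
                if (src[r] > best) { best = src[r]; barg = r; }
              }
          const size_t ro = (size_t)x + (size_t)ox * (y + (size_t)oy * z);
          Y(ro, c) = best;
          idx(ro, c) = (int)barg + 1;
        }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericMatrix maxpool_bw(IntegerMatrix idx, NumericMatrix gY, int n_in) {
  const int C = gY.ncol();
  NumericMatrix gX(n_in, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < gY.nrow(); ++r)
      gX(idx(r, c) - 1, c) += gY(r, c);
  return gX;
}

// [[Rcpp::export(name = ".avgpool_fw")]]
NumericMatrix avgpool_fw(NumericMatrix X, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = X.ncol();
  if (nx % 2 || ny % 2 || nz % 2) stop("avgpool: dims must be even");
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  NumericMatrix Y((size_t)ox * oy * oz, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &X(0, c);
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x) {
          double s = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx)
                s += src[(size_t)(2 * x + dx) +
                         (size_t)nx * ((2 * y + dy) + (size_t)ny * (2 * z + dz))];
          Y((size_t)x + (size_t)ox * (y + (size_t)oy * z), c) = s / 8.0;
        }
  }
  return Y;
}

// Transposed convolution, kernel 2, stride 2 (non-overlapping): output voxel
// (2x+dx, 2y+dy, 2z+dz) = sum_cin X[x,y,z,cin] * W[k*Cin+cin, cout],
// k = dz*4 + dy*2 + dx.
// [[Rcpp::export(name = ".upconv_fw")]]
NumericMatrix upconv_fw(NumericMatrix X, IntegerVector dims,
                        NumericMatrix W, NumericVector b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = X.ncol(), Cout = W.ncol();
  if (W.nrow() != 8 * Cin) stop("upconv: weight rows != 8*Cin");
  arma::fmat Xf = to_float(X), Wf = to_float(W);
  const int Ox = 2 * nx, Oy = 2 * ny;
  arma::fmat Y((size_t)8 * nx * ny * nz, Cout);
  for (int c = 0; c < Cout; ++c) Y.col(c).fill((float)b[c]);
  for (int k = 0; k < 8; ++k) {
    const int dz = k / 4, dy = (k / 2) % 2, dx = k % 2;
    arma::fmat Yk = Xf * Wf.rows((size_t)k * Cin, (size_t)(k + 1) * Cin - 1);
    for (int c = 0; c < Cout; ++c) {
      const float* src = Yk.colptr(c);
      float* dst = Y.colptr(c);
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x)
            dst[(size_t)(2 * x + dx) +
                (size_t)Ox * ((2 * y + dy) + (size_t)Oy * (2 * z + dz))] +=
              src[(size_t)x + (size_t)nx * (y + (size_t)ny * z)];
    }
  }
  return to_double(Y);
}

// [[Rcpp::export(name = ".upconv_bw")]]
List upconv_bw(NumericMatrix X, IntegerVector dims,
               NumericMatrix W, NumericMatrix gY) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = X.ncol(), Cout = W.ncol();
  arma::fmat Xf = to_float(X), Wf = to_float(W), gYf = to_float(gY);
  const int Ox = 2 * nx, Oy = 2 * ny;
  arma::fmat gX((size_t)nx * ny * nz, Cin, arma::fill::zeros);
  arma::fmat gW((size_t)8 * Cin, Cout);
  arma::fmat gYk((size_t)nx * ny * nz, Cout);
  for (int k = 0; k < 8; ++k) {
    const int dz = k / 4, dy = (k / 2) % 2, dx = k % 2;
    for (int c = 0; c < Cout; ++c) {
      const float* src = gYf.colptr(c);
      float* dst = gYk.colptr(c);
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x)
            dst[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] =
              src[(size_t)(2 * x + dx) +
                  (size_t)Ox * ((2 * y + dy) + (size_t)Oy * (2 * z + dz))];
    }
    gW.rows((size_t)k * Cin, (size_t)(k + 1) * Cin - 1) = Xf.t() * gYk;
    gX += gYk * Wf.rows((size_t)k * Cin, (size_t)(k + 1) * Cin - 1).t();
  }
  arma::frowvec gb = arma::sum(gYf, 0);
  NumericVector gbv(Cout);
  for (int c = 0; c < Cout; ++c) gbv[c] = (double)gb[c];
  return List::create(_["gx"] = to_double(gX), _["gw"] = to_double(gW),
                      _["gb"] = gbv);
}
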