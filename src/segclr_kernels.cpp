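// Low-level kernels: 3D convolution via im2col + GEMM, 3D max pooling,
// and sphere-sweep rasterization for the synthetic volume generator.
// Array layout is R column-major with dims (x, y, z, channel[, batch]).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Fill the im2col matrix (k^3*Cin rows, ox*oy*oz cols) for one example.
// Row ordering: dx fastest, then dy, dz, cin. Out-of-bounds -> 0.
static void im2col(const double* x, int X, int Y, int Z, int C,
                   int k, int s, int p, arma::mat& col) {
  const int ox = out_size(X, k, s, p);
  const int oy = out_size(Y, k, s, p);
  const int oz = out_size(Z, k, s, p);
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * X * Y * Z;
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx) {
          const int row = dx + k * (dy + k * (dz + k * c));
          double* crow = col.memptr() + row; // stride = col.n_rows
          const size_t nr = col.n_rows;
          for (int oz_i = 0; oz_i < oz; ++oz_i) {
            const int z = oz_i * s - p + dz;
            for (int oy_i = 0; oy_i < oy; ++oy_i) {
              const int y = oy_i * s - p + dy;
              const size_t base = nr * ((size_t)oy_i * ox + (size_t)oz_i * ox * oy);
              if (z < 0 || z >= Z || y < 0 || y >= Y) continue;
              for (int ox_i = 0; ox_i < ox; ++ox_i) {
                const int xx = ox_i * s - p + dx;
                if (xx < 0 || xx >= X) continue;
                crow[base + nr * ox_i] =
                  xc[(size_t)xx + (size_t)X * (y + (size_t)Y * z)];
              }
            }
          }
        }
  }
}

// Scatter-add a column matrix back into the input gradient (col2im).
static void col2im(const arma::mat& col, int X, int Y, int Z, int C,
                   int k, int s, int p, double* dx_out) {
  const int ox = out_size(X, k, s, p);
  const int oy = out_size(Y, k, s, p);
  const int oz = out_size(Z, k, s, p);
  for (int c = 0; c < C; ++c) {
    double* xc = dx_out + (size_t)c * X * Y * Z;
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx) {
          const int row = dx + k * (dy + k * (dz + k * c));
          const size_t nr = col.n_rows;
          const double* crow = col.memptr() + row;
          for (int oz_i = 0; oz_i < oz; ++oz_i) {
            const int z = oz_i * s - p + dz;
            if (z < 0 || z >= Z) continue;
            for (int oy_i = 0; oy_i < oy; ++oy_i) {
              const int y = oy_i * s - p + dy;
              if (y < 0 || y >= Y) continue;
              const size_t base = nr * ((size_t)oy_i * ox + (size_t)oz_i * ox * oy);
              for (int ox_i = 0; ox_i < ox; ++ox_i) {
                const int xx = ox_i * s - p + dx;
                if (xx < 0 || xx >= X) continue;
                xc[(size_t)xx + (size_t)X * (y + (size_t)Y * z)] +=
                  crow[base + nr * ox_i];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(NumericVector x, NumericMatrix w,
                                 int kernel, int stride, int pad) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 5) stop("x must have dims (x, y, z, channel, batch)");
  const int X = dm[0], Y = dm[1], Z = dm[2], C = dm[3], B = dm[4];
  const int Cout = w.nrow();
  if (w.ncol() != kernel * kernel * kernel * C)
    stop("weight shape does not match kernel/in-channels");
  const int ox = out_size(X, kernel, stride, pad);
  const int oy = out_size(Y, kernel, stride, pad);
  const int oz = out_size(Z, kernel, stride, pad);
  if (ox < 1 || oy < 1 || oz < 1) stop("output size would be empty");
  const size_t O = (size_t)ox * oy * oz;
  NumericVector out((size_t)O * Cout * B);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, Cout, B);
  arma::mat W(w.begin(), Cout, w.ncol(), false);
  arma::mat col(w.ncol(), O);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)b * X * Y * Z * C, X, Y, Z, C,
           kernel, stride, pad, col);
    arma::mat Yb = W * col;                      // Cout x O
    double* ob = out.begin() + (size_t)b * O * Cout;
    // transpose scatter: out is (space, channel)
    for (int co = 0; co < Cout; ++co)
      for (size_t i = 0; i < O; ++i)
        ob[i + O * co] = Yb(co, i);
  }
  return out;
}

// [[Rcpp::export]]
List conv3d_backward_cpp(NumericVector x, NumericMatrix w, NumericVector dy,
                         int kernel, int stride, int pad) {
  IntegerVector dm = x.attr("dim");
  const int X = dm[0], Y = dm[1], Z = dm[2], C = dm[3], B = dm[4];
  IntegerVector dmo = dy.attr("dim");
  const int ox = dmo[0], oy = dmo[1], oz = dmo[2], Cout = dmo[3];
  const size_t O = (size_t)ox * oy * oz;
  arma::mat W(w.begin(), Cout, w.ncol(), false);
  arma::mat dW(Cout, w.ncol(), arma::fill::zeros);
  NumericVector dx((size_t)X * Y * Z * C * B);
  dx.attr("dim") = dm;
  arma::mat col(w.ncol(), O);
  arma::mat dYb(Cout, O);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)b * X * Y * Z * C, X, Y, Z, C,
           kernel, stride, pad, col);
    const double* db = dy.begin() + (size_t)b * O * Cout;
    for (int co = 0; co < Cout; ++co)
      for (size_t i = 0; i < O; ++i)
        dYb(co, i) = db[i + O * co];
    dW += dYb * col.t();
    arma::mat dcol = W.t() * dYb;
    col2im(dcol, X, Y, Z, C, kernel, stride, pad,
           dx.begin() + (size_t)b * X * Y * Z * C);
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericMatrix(Cout, w.ncol(), dW.memptr()));
}

// [[Rcpp::export]]
List maxpool3d_forward_cpp(NumericVector x, int kernel, int stride) {
  IntegerVector dm = x.attr("dim");
  const int X = dm[0], Y = dm[1], Z = dm[2], C = dm[3], B = dm[4];
  const int ox = out_size(X, kernel, stride, 0);
  const int oy = out_size(Y, kernel, stride, 0);
  const int oz = out_size(Z, kernel, stride, 0);
  const size_t O = (size_t)ox * oy * oz;
  NumericVector out(O * C * B);
  IntegerVector arg(O * C * B);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, C, B);
  size_t pos = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(b * C + c) * X * Y * Z;
      for (int oz_i = 0; oz_i < oz; ++oz_i)
        for (int oy_i = 0; oy_i < oy; ++oy_i)
          for (int ox_i = 0; ox_i < ox; ++ox_i) {
            double best = -INFINITY; size_t besti = 0;
            for (int dz = 0; dz < kernel; ++dz)
              for (int dy2 = 0; dy2 < kernel; ++dy2)
                for (int dx2 = 0; dx2 < kernel; ++dx2) {
                  const int xx = ox_i * stride + dx2, yy = oy_i * stride + dy2,
                            zz = oz_i * stride + dz;
                  if (xx >= X || yy >= Y || zz >= Z) continue;
                  const size_t idx = (size_t)xx + (size_t)X * (yy + (size_t)Y * zz);
                  if (xc[idx] > best) { best = xc[idx]; besti = idx; }
                }
            // out index in (x,y,z) order within this channel plane
            const size_t oidx = (size_t)ox_i + (size_t)ox * (oy_i + (size_t)oy * oz_i);
            out[pos + oidx] = best;
            arg[pos + oidx] = (int)besti;
          }
      pos += O;
    }
  return List::create(_["y"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_backward_cpp(NumericVector dy, IntegerVector arg,
                                     IntegerVector in_dim) {
  const int X = in_dim[0], Y = in_dim[1], Z = in_dim[2],
            C = in_dim[3], B = in_dim[4];
  IntegerVector dmo = dy.attr("dim");
  const size_t O = (size_t)dmo[0] * dmo[1] * dmo[2];
  NumericVector dx((size_t)X * Y * Z * C * B);
  dx.attr("dim") = in_dim;
  size_t pos = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + (size_t)(b * C + c) * X * Y * Z;
      for (size_t i = 0; i < O; ++i) xc[arg[pos + i]] += dy[pos + i];
      pos += O;
    }
  return dx;
}

// Rasterize spheres (centers in nm, radii in nm) into an integer ID volume.
// Anisotropic voxel size honoured per axis; first-writer-wins: a voxel
// already owned by a different ID is never overwritten. Returns the number
// of distinct voxels this ID wanted but could not claim.
// [[Rcpp::export]]
int raster_spheres_cpp(IntegerVector seg, NumericVector voxel_nm,
                       NumericMatrix centers_nm, NumericVector radii_nm,
                       int id) {
  IntegerVector dm = seg.attr("dim");
  const int X = dm[0], Y = dm[1], Z = dm[2];
  const double vx = voxel_nm[0], vy = voxel_nm[1], vz = voxel_nm[2];
  int collisions = 0;
  std::vector<char> contested((size_t)X * Y * Z, 0);
  for (int i = 0; i < centers_nm.nrow(); ++i) {
    const double cx = centers_nm(i, 0), cy = centers_nm(i, 1),
                 cz = centers_nm(i, 2), r = radii_nm[i];
    const int x0 = std::max(0, (int)std::floor((cx - r) / vx));
    const int x1 = std::min(X - 1, (int)std::floor((cx + r) / vx));
    const int y0 = std::max(0, (int)std::floor((cy - r) / vy));
    const int y1 = std::min(Y - 1, (int)std::floor((cy + r) / vy));
    const int z0 = std::max(0, (int)std::floor((cz - r) / vz));
    const int z1 = std::min(Z - 1, (int)std::floor((cz + r) / vz));
    const double r2 = r * r;
    for (int z = z0; z <= z1; ++z) {
      const double dz = (z + 0.5) * vz - cz;
      for (int y = y0; y <= y1; ++y) {
        const double dy = (y + 0.5) * vy - cy;
        for (int x = x0; x <= x1; ++x) {
          const double dx = (x + 0.5) * vx - cx;
          if (dx * dx + dy * dy + dz * dz > r2) continue;
          const size_t idx = (size_t)x + (size_t)X * (y + (size_t)Y * z);
          if (seg[idx] == 0) {
            seg[idx] = id;
          } else if (seg[idx] != id && !contested[idx]) {
            contested[idx] = 1;
            ++collisions;
          }
        }
      }
    }
  }
  return collisions;
}
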