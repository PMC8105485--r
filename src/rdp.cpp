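#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Relative-difference prior over the 3D 26-neighbourhood with
// inverse-distance weights:
//   R(x) = sum over unordered neighbour pairs (j,k) of
//          w_jk * (x_j - x_k)^2 / (x_j + x_k + gamma * |x_j - x_k| + eps)
// Weights are normalised so the nearest in-plane neighbour has weight 1.

static void offsets(const NumericVector &vs, int off[13][3], double w[13]) {
  int n = 0;
  double vmin = std::min(vs[0], std::min(vs[1], vs[2]));
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        // keep one representative of each +/- pair
        if (dz < 0 || (dz == 0 && (dy < 0 || (dy == 0 && dx < 0)))) continue;
        off[n][0] = dx; off[n][1] = dy; off[n][2] = dz;
        double d = std::sqrt(dx * vs[0] * dx * vs[0] +
                             dy * vs[1] * dy * vs[1] +
                             dz * vs[2] * dz * vs[2]);
        w[n] = vmin / d;
        ++n;
      }
}

// [[Rcpp::export]]
NumericVector rdp_grad_cpp(NumericVector x, IntegerVector dims,
                           double gamma, NumericVector voxel_size,
                           double eps) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int off[13][3]; double w[13];
  offsets(voxel_size, off, w);
  NumericVector g(x.size());
  for (int m = 0; m < 13; ++m) {
    int ox = off[m][0], oy = off[m][1], oz = off[m][2];
    double wm = w[m];
    for (int k = std::max(0, -oz); k < nz - std::max(0, oz); ++k)
      for (int j = std::max(0, -oy); j < ny - std::max(0, oy); ++j) {
        int base1 = (k * ny + j) * nx;
        int base2 = ((k + oz) * ny + (j + oy)) * nx + ox;
        int i0 = std::max(0, -ox), i1 = nx - std::max(0, ox);
        for (int i = i0; i < i1; ++i) {
          double a = x[base1 + i], b = x[base2 + i];
          double u = a - b;
          if (u == 0.0) continue;
          double au = std::fabs(u);
          double v = a + b + gamma * au + eps;
          if (v <= 0.0) continue;
          double s = (u > 0) ? 1.0 : -1.0;
          double v2 = v * v;
          g[base1 + i] += wm * (2.0 * u * v - u * u * (1.0 + gamma * s)) / v2;
          g[base2 + i] += wm * (-2.0 * u * v - u * u * (1.0 - gamma * s)) / v2;
        }
      }
  }
  return g;
}

// [[Rcpp::export]]
double rdp_value_cpp(NumericVector x, IntegerVector dims,
                     double gamma, NumericVector voxel_size, double eps) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int off[13][3]; double w[13];
  offsets(voxel_size, off, w);
  double val = 0.0;
  for (int m = 0; m < 13; ++m) {
    int ox = off[m][0], oy = off[m][1], oz = off[m][2];
    double wm = w[m];
    for (int k = std::max(0, -oz); k < nz - std::max(0, oz); ++k)
      for (int j = std::max(0, -oy); j < ny - std::max(0, oy); ++j) {
        int base1 = (k * ny + j) * nx;
        int base2 = ((k + oz) * ny + (j + oy)) * nx + ox;
        int i0 = std::max(0, -ox), i1 = nx - std::max(0, ox);
        for (int i = i0; i < i1; ++i) {
          double a = x[base1 + i], b = x[base2 + i];
          double u = a - b;
          if (u == 0.0) continue;
          double v = a + b + gamma * std::fabs(u) + eps;
          if (v <= 0.0) continue;
          val += wm * u * u / v;
        }
      }
  }
  return val;
}
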