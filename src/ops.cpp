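// Low-level numeric kernels: 3x3x3 convolution (shifted-GEMM formulation),
// instance normalization, 2x average pooling, 2x trilinear upsampling,
// trilinear point sampling, and separable Gaussian blur. Feature maps are
// (channels x voxels) matrices, voxels flattened x-fastest (R array order).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

// copy x shifted by voxel offset (dx,dy,dz) into xs: xs(:, (i,j,k)) =
// x(:, (i+dx, j+dy, k+dz)) where the source is in bounds, 0 elsewhere.
static void shifted_copy(const mat& x, mat& xs, int d1, int d2, int d3,
                         int dx, int dy, int dz) {
  xs.zeros();
  int lo_i = std::max(0, -dx), hi_i = d1 - 1 - std::max(0, dx);
  int lo_j = std::max(0, -dy), hi_j = d2 - 1 - std::max(0, dy);
  int lo_k = std::max(0, -dz), hi_k = d3 - 1 - std::max(0, dz);
  if (lo_i > hi_i || lo_j > hi_j || lo_k > hi_k) return;
  int len = hi_i - lo_i + 1;
  for (int k = lo_k; k <= hi_k; ++k) {
    for (int j = lo_j; j <= hi_j; ++j) {
      int t0 = lo_i + d1 * (j + d2 * k);
      int s0 = (lo_i + dx) + d1 * ((j + dy) + d2 * (k + dz));
      xs.cols(t0, t0 + len - 1) = x.cols(s0, s0 + len - 1);
    }
  }
}

// xs(:, (i+dx,j+dy,k+dz)) += x(:, (i,j,k)) for in-bounds targets (adjoint of
// shifted_copy with the opposite offset).
static void shifted_add(const mat& x, mat& acc, int d1, int d2, int d3,
                        int dx, int dy, int dz) {
  int lo_i = std::max(0, -dx), hi_i = d1 - 1 - std::max(0, dx);
  int lo_j = std::max(0, -dy), hi_j = d2 - 1 - std::max(0, dy);
  int lo_k = std::max(0, -dz), hi_k = d3 - 1 - std::max(0, dz);
  if (lo_i > hi_i || lo_j > hi_j || lo_k > hi_k) return;
  int len = hi_i - lo_i + 1;
  for (int k = lo_k; k <= hi_k; ++k) {
    for (int j = lo_j; j <= hi_j; ++j) {
      int t0 = lo_i + d1 * (j + d2 * k);
      int s0 = (lo_i + dx) + d1 * ((j + dy) + d2 * (k + dz));
      acc.cols(s0, s0 + len - 1) += x.cols(t0, t0 + len - 1);
    }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
arma::mat conv3d_fwd(const arma::mat& x, const arma::mat& W,
                     const arma::vec& b, int d1, int d2, int d3) {
  int cin = x.n_rows, n = x.n_cols, cout = W.n_rows;
  if ((int)W.n_cols != cin * 27) stop("conv3d: weight shape mismatch");
  mat y(cout, n, arma::fill::zeros);
  mat xs(cin, n);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        shifted_copy(x, xs, d1, d2, d3, dx, dy, dz);
        y += W.cols(o * cin, (o + 1) * cin - 1) * xs;
      }
  y.each_col() += b;
  return y;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(const arma::mat& x, const arma::mat& W, const arma::mat& gy,
                int d1, int d2, int d3) {
  int cin = x.n_rows, n = x.n_cols;
  mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  mat dx(cin, n, arma::fill::zeros);
  mat xs(cin, n), tmp;
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int ddx = -1; ddx <= 1; ++ddx, ++o) {
        shifted_copy(x, xs, d1, d2, d3, ddx, dy, dz);
        dW.cols(o * cin, (o + 1) * cin - 1) = gy * xs.t();
        tmp = W.cols(o * cin, (o + 1) * cin - 1).t() * gy;
        shifted_add(tmp, dx, d1, d2, d3, ddx, dy, dz);
      }
  vec db = arma::sum(gy, 1);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".instnorm_fwd")]]
List instnorm_fwd(const arma::mat& x, const arma::vec& gamma,
                  const arma::vec& beta, double eps) {
  vec m = arma::mean(x, 1);
  mat xc = x.each_col() - m;
  vec v = arma::mean(arma::square(xc), 1);
  vec invstd = 1.0 / arma::sqrt(v + eps);
  mat xhat = xc.each_col() % invstd;
  mat y = xhat.each_col() % gamma;
  y.each_col() += beta;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".instnorm_bwd")]]
List instnorm_bwd(const arma::mat& gy, const arma::mat& xhat,
                  const arma::vec& invstd, const arma::vec& gamma) {
  double n = (double)gy.n_cols;
  vec dgamma = arma::sum(gy % xhat, 1);
  vec dbeta = arma::sum(gy, 1);
  mat dxhat = gy.each_col() % gamma;
  vec s1 = arma::sum(dxhat, 1);
  vec s2 = arma::sum(dxhat % xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= s1 / n;
  dx -= xhat.each_col() % (s2 / n);
  dx.each_col() %= invstd;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".avgpool2_fwd")]]
arma::mat avgpool2_fwd(const arma::mat& x, int d1, int d2, int d3) {
  if (d1 % 2 || d2 % 2 || d3 % 2) stop("avgpool2: odd input extent");
  int c = x.n_rows, e1 = d1 / 2, e2 = d2 / 2, e3 = d3 / 2;
  mat y(c, e1 * e2 * e3, arma::fill::zeros);
  for (int k = 0; k < e3; ++k)
    for (int j = 0; j < e2; ++j)
      for (int i = 0; i < e1; ++i) {
        int t = i + e1 * (j + e2 * k);
        for (int kk = 0; kk < 2; ++kk)
          for (int jj = 0; jj < 2; ++jj)
            for (int ii = 0; ii < 2; ++ii)
              y.col(t) += x.col((2 * i + ii) + d1 * ((2 * j + jj) + d2 * (2 * k + kk)));
        y.col(t) *= 0.125;
      }
  return y;
}

// [[Rcpp::export(name = ".avgpool2_bwd")]]
arma::mat avgpool2_bwd(const arma::mat& gy, int d1, int d2, int d3) {
  int c = gy.n_rows, e1 = d1 / 2, e2 = d2 / 2, e3 = d3 / 2;
  mat gx(c, d1 * d2 * d3, arma::fill::zeros);
  for (int k = 0; k < e3; ++k)
    for (int j = 0; j < e2; ++j)
      for (int i = 0; i < e1; ++i) {
        int t = i + e1 * (j + e2 * k);
        vec g = gy.col(t) * 0.125;
        for (int kk = 0; kk < 2; ++kk)
          for (int jj = 0; jj < 2; ++jj)
            for (int ii = 0; ii < 2; ++ii)
              gx.col((2 * i + ii) + d1 * ((2 * j + jj) + d2 * (2 * k + kk))) += g;
      }
  return gx;
}

// per-axis source indices and weights for factor-2 trilinear upsampling with
// half-voxel alignment: out index i samples input coordinate (i+0.5)/2-0.5.
static void up2_axis(int e, std::vector<int>& i0, std::vector<int>& i1,
                     std::vector<double>& w1) {
  int n = 2 * e;
  i0.resize(n); i1.resize(n); w1.resize(n);
  for (int i = 0; i < n; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    int f = (int)std::floor(s);
    double w = s - f;
    int a = std::min(std::max(f, 0), e - 1);
    int b = std::min(std::max(f + 1, 0), e - 1);
    i0[i] = a; i1[i] = b; w1[i] = w;
  }
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
arma::mat upsample2_fwd(const arma::mat& x, int e1, int e2, int e3) {
  int c = x.n_rows, n1 = 2 * e1, n2 = 2 * e2, n3 = 2 * e3;
  std::vector<int> a0, a1, b0, b1, c0, c1;
  std::vector<double> wa, wb, wc;
  up2_axis(e1, a0, a1, wa); up2_axis(e2, b0, b1, wb); up2_axis(e3, c0, c1, wc);
  mat y(c, n1 * n2 * n3);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int t = i + n1 * (j + n2 * k);
        vec acc(c, arma::fill::zeros);
        for (int kk = 0; kk < 2; ++kk) {
          int sk = kk ? c1[k] : c0[k];
          double wk = kk ? wc[k] : 1 - wc[k];
          if (wk == 0) continue;
          for (int jj = 0; jj < 2; ++jj) {
            int sj = jj ? b1[j] : b0[j];
            double wj = jj ? wb[j] : 1 - wb[j];
            if (wj == 0) continue;
            for (int ii = 0; ii < 2; ++ii) {
              int si = ii ? a1[i] : a0[i];
              double wi = ii ? wa[i] : 1 - wa[i];
              if (wi == 0) continue;
              acc += (wk * wj * wi) * x.col(si + e1 * (sj + e2 * sk));
            }
          }
        }
        y.col(t) = acc;
      }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
arma::mat upsample2_bwd(const arma::mat& gy, int e1, int e2, int e3) {
  int c = gy.n_rows, n1 = 2 * e1, n2 = 2 * e2, n3 = 2 * e3;
  std::vector<int> a0, a1, b0, b1, c0, c1;
  std::vector<double> wa, wb, wc;
  up2_axis(e1, a0, a1, wa); up2_axis(e2, b0, b1, wb); up2_axis(e3, c0, c1, wc);
  mat gx(c, e1 * e2 * e3, arma::fill::zeros);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int t = i + n1 * (j + n2 * k);
        for (int kk = 0; kk < 2; ++kk) {
          int sk = kk ? c1[k] : c0[k];
          double wk = kk ? wc[k] : 1 - wc[k];
          if (wk == 0) continue;
          for (int jj = 0; jj < 2; ++jj) {
            int sj = jj ? b1[j] : b0[j];
            double wj = jj ? wb[j] : 1 - wb[j];
            if (wj == 0) continue;
            for (int ii = 0; ii < 2; ++ii) {
              int si = ii ? a1[i] : a0[i];
              double wi = ii ? wa[i] : 1 - wa[i];
              if (wi == 0) continue;
              gx.col(si + e1 * (sj + e2 * sk)) += (wk * wj * wi) * gy.col(t);
            }
          }
        }
      }
  return gx;
}

// Trilinear sampling of a 3D volume at arbitrary physical points.
// Points outside the grid return 0 with inside = 0.
// [[Rcpp::export(name = ".sample_trilinear")]]
List sample_trilinear(const arma::vec& values, int d1, int d2, int d3,
                      const arma::vec& spacing, const arma::vec& origin,
                      const arma::mat& pts) {
  int n = pts.n_rows;
  vec out(n, arma::fill::zeros);
  vec inside(n, arma::fill::zeros);
  for (int p = 0; p < n; ++p) {
    double cx = (pts(p, 0) - origin(0)) / spacing(0);
    double cy = (pts(p, 1) - origin(1)) / spacing(1);
    double cz = (pts(p, 2) - origin(2)) / spacing(2);
    if (cx < 0 || cy < 0 || cz < 0 || cx > d1 - 1 || cy > d2 - 1 || cz > d3 - 1)
      continue;
    int fx = std::min((int)std::floor(cx), d1 - 2 >= 0 ? d1 - 2 : 0);
    int fy = std::min((int)std::floor(cy), d2 - 2 >= 0 ? d2 - 2 : 0);
    int fz = std::min((int)std::floor(cz), d3 - 2 >= 0 ? d3 - 2 : 0);
    double wx = cx - fx, wy = cy - fy, wz = cz - fz;
    double acc = 0;
    for (int kk = 0; kk < 2; ++kk) {
      int z = std::min(fz + kk, d3 - 1);
      double wk = kk ? wz : 1 - wz;
      for (int jj = 0; jj < 2; ++jj) {
        int y = std::min(fy + jj, d2 - 1);
        double wj = jj ? wy : 1 - wy;
        for (int ii = 0; ii < 2; ++ii) {
          int x = std::min(fx + ii, d1 - 1);
          double wi = ii ? wx : 1 - wx;
          acc += wk * wj * wi * values(x + d1 * (y + d2 * z));
        }
      }
    }
    out(p) = acc;
    inside(p) = 1;
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// Separable Gaussian blur with border renormalization (kernel weights
// falling outside the volume are dropped and the rest rescaled).
// [[Rcpp::export(name = ".gaussian_blur3")]]
arma::vec gaussian_blur3(const arma::vec& values, int d1, int d2, int d3,
                         double sigma, int radius) {
  vec kern(2 * radius + 1);
  for (int t = -radius; t <= radius; ++t)
    kern(t + radius) = std::exp(-0.5 * t * t / (sigma * sigma));
  kern /= arma::sum(kern);
  vec cur = values, nxt(values.n_elem);
  int dims[3] = {d1, d2, d3};
  int strides[3] = {1, d1, d1 * d2};
  for (int ax = 0; ax < 3; ++ax) {
    int n = dims[ax], st = strides[ax];
    // iterate all lines along axis ax
    int o1 = (ax == 0) ? 1 : 0, o2 = (ax == 2) ? 1 : 2;
    int n1 = dims[o1], n2 = dims[o2];
    int st1 = strides[o1], st2 = strides[o2];
    for (int b = 0; b < n2; ++b) {
      for (int a = 0; a < n1; ++a) {
        int base = a * st1 + b * st2;
        for (int t = 0; t < n; ++t) {
          double acc = 0, wsum = 0;
          int lo = std::max(-radius, -t), hi = std::min(radius, n - 1 - t);
          for (int u = lo; u <= hi; ++u) {
            acc += kern(u + radius) * cur(base + (t + u) * st);
            wsum += kern(u + radius);
          }
          nxt(base + t * st) = acc / wsum;
        }
      }
    }
    cur = nxt;
  }
  return cur;
}
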