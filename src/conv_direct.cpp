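#include <Rcpp.h>
using namespace Rcpp;

// Direct (no im2col materialization) 3D convolution kernels, stride 1,
// same-size zero padding, odd cubic kernel k. Activation layout matches
// kernels.cpp: (n*V) x C matrices, voxels in R array order, samples
// stacked along rows. Weight layout matches the lowered convention:
// W[(c_in * k^3) + o, c_out] with o = (oz*k + oy)*k + ox.
//
// All three passes iterate the same valid (v, v+offset) voxel pairs; the
// forward accumulates into out[v], the input gradient scatters into
// dx[v+offset], and the weight gradient reduces products over the pairs.

// [[Rcpp::export]]
NumericMatrix cpp_conv3_fwd(NumericMatrix x, IntegerVector dims, int n,
                            NumericMatrix W, NumericVector b, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  const int C = x.ncol();
  const int Cout = W.ncol();
  const int k3 = k * k * k;
  const int p = (k - 1) / 2;
  NumericMatrix out(n * V, Cout);
  for (int j = 0; j < Cout; ++j) {
    double* oj = &out(0, j);
    const double bj = b[j];
    for (int i = 0; i < n * V; ++i) oj[i] = bj;
  }
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int o = 0; o < k3; ++o) {
      const int ox = o % k - p;
      const int oy = (o / k) % k - p;
      const int oz = o / (k * k) - p;
      const int z0 = (oz < 0) ? -oz : 0, z1 = (oz > 0) ? nz - oz : nz;
      const int y0 = (oy < 0) ? -oy : 0, y1 = (oy > 0) ? ny - oy : ny;
      const int x0 = (ox < 0) ? -ox : 0, x1 = (ox > 0) ? nx - ox : nx;
      for (int j = 0; j < Cout; ++j) {
        const double w = W(c * k3 + o, j);
        if (w == 0.0) continue;
        double* oj = &out(0, j);
        for (int s = 0; s < n; ++s) {
          const int base = s * V;
          for (int iz = z0; iz < z1; ++iz)
            for (int iy = y0; iy < y1; ++iy) {
              const int row0 = base + nx * (iy + ny * iz);
              const int src0 = base + nx * ((iy + oy) + ny * (iz + oz)) + ox;
              for (int ix = x0; ix < x1; ++ix)
                oj[row0 + ix] += w * xc[src0 + ix];
            }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(NumericMatrix x, NumericMatrix dout, IntegerVector dims,
                   int n, NumericMatrix W, int k, bool need_dx) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  const int C = x.ncol();
  const int Cout = dout.ncol();
  const int k3 = k * k * k;
  const int p = (k - 1) / 2;
  NumericMatrix dW(C * k3, Cout);
  NumericVector db(Cout);
  NumericMatrix dx(need_dx ? n * V : 1, need_dx ? C : 1);
  for (int j = 0; j < Cout; ++j) {
    const double* dj = &dout(0, j);
    double acc = 0.0;
    for (int i = 0; i < n * V; ++i) acc += dj[i];
    db[j] = acc;
  }
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double* dxc = need_dx ? &dx(0, c) : (double*)0;
    for (int o = 0; o < k3; ++o) {
      const int ox = o % k - p;
      const int oy = (o / k) % k - p;
      const int oz = o / (k * k) - p;
      const int z0 = (oz < 0) ? -oz : 0, z1 = (oz > 0) ? nz - oz : nz;
      const int y0 = (oy < 0) ? -oy : 0, y1 = (oy > 0) ? ny - oy : ny;
      const int x0 = (ox < 0) ? -ox : 0, x1 = (ox > 0) ? nx - ox : nx;
      for (int j = 0; j < Cout; ++j) {
        const double w = W(c * k3 + o, j);
        const double* dj = &dout(0, j);
        double acc = 0.0;
        for (int s = 0; s < n; ++s) {
          const int base = s * V;
          for (int iz = z0; iz < z1; ++iz)
            for (int iy = y0; iy < y1; ++iy) {
              const int row0 = base + nx * (iy + ny * iz);
              const int src0 = base + nx * ((iy + oy) + ny * (iz + oz)) + ox;
              if (need_dx && w != 0.0) {
                for (int ix = x0; ix < x1; ++ix) {
                  acc += xc[src0 + ix] * dj[row0 + ix];
                  dxc[src0 + ix] += w * dj[row0 + ix];
                }
              } else {
                for (int ix = x0; ix < x1; ++ix)
                  acc += xc[src0 + ix] * dj[row0 + ix];
              }
            }
        }
        dW(c * k3 + o, j) = acc;
      }
    }
  }
  if (need_dx)
    return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = R_NilValue);
}

// Depthwise convolution: one k^3 filter per channel, Wd is k3 x C.
// [[Rcpp::export]]
NumericMatrix cpp_dwconv3_fwd(NumericMatrix x, IntegerVector dims, int n,
                              NumericMatrix Wd, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  const int C = x.ncol();
  const int k3 = k * k * k;
  const int p = (k - 1) / 2;
  NumericMatrix out(n * V, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double* oc = &out(0, c);
    for (int o = 0; o < k3; ++o) {
      const double w = Wd(o, c);
      if (w == 0.0) continue;
      const int ox = o % k - p;
      const int oy = (o / k) % k - p;
      const int oz = o / (k * k) - p;
      const int z0 = (oz < 0) ? -oz : 0, z1 = (oz > 0) ? nz - oz : nz;
      const int y0 = (oy < 0) ? -oy : 0, y1 = (oy > 0) ? ny - oy : ny;
      const int x0 = (ox < 0) ? -ox : 0, x1 = (ox > 0) ? nx - ox : nx;
      for (int s = 0; s < n; ++s) {
        const int base = s * V;
        for (int iz = z0; iz < z1; ++iz)
          for (int iy = y0; iy < y1; ++iy) {
            const int row0 = base + nx * (iy + ny * iz);
            const int src0 = base + nx * ((iy + oy) + ny * (iz + oz)) + ox;
            for (int ix = x0; ix < x1; ++ix)
              oc[row0 + ix] += w * xc[src0 + ix];
          }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv3_bwd(NumericMatrix x, NumericMatrix dout, IntegerVector dims,
                     int n, NumericMatrix Wd, int k, bool need_dx) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  const int C = x.ncol();
  const int k3 = k * k * k;
  const int p = (k - 1) / 2;
  NumericMatrix dWd(k3, C);
  NumericMatrix dx(need_dx ? n * V : 1, need_dx ? C : 1);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    const double* dc = &dout(0, c);
    double* dxc = need_dx ? &dx(0, c) : (double*)0;
    for (int o = 0; o < k3; ++o) {
      const double w = Wd(o, c);
      const int ox = o % k - p;
      const int oy = (o / k) % k - p;
      const int oz = o / (k * k) - p;
      const int z0 = (oz < 0) ? -oz : 0, z1 = (oz > 0) ? nz - oz : nz;
      const int y0 = (oy < 0) ? -oy : 0, y1 = (oy > 0) ? ny - oy : ny;
      const int x0 = (ox < 0) ? -ox : 0, x1 = (ox > 0) ? nx - ox : nx;
      double acc = 0.0;
      for (int s = 0; s < n; ++s) {
        const int base = s * V;
        for (int iz = z0; iz < z1; ++iz)
          for (int iy = y0; iy < y1; ++iy) {
            const int row0 = base + nx * (iy + ny * iz);
            const int src0 = base + nx * ((iy + oy) + ny * (iz + oz)) + ox;
            if (need_dx && w != 0.0) {
              for (int ix = x0; ix < x1; ++ix) {
                acc += xc[src0 + ix] * dc[row0 + ix];
                dxc[src0 + ix] += w * dc[row0 + ix];
              }
            } else {
              for (int ix = x0; ix < x1; ++ix)
                acc += xc[src0 + ix] * dc[row0 + ix];
            }
          }
      }
      dWd(o, c) = acc;
    }
  }
  if (need_dx)
    return List::create(_["dWd"] = dWd, _["dx"] = dx);
  return List::create(_["dWd"] = dWd, _["dx"] = R_NilValue);
}
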