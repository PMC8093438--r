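#include <Rcpp.h>
using namespace Rcpp;

// Activations are stored as (n_samples * n_voxels) x n_channels matrices.
// Voxel linear order inside one sample follows R array order:
//   v = ix + nx * (iy + ny * iz), 0-based.
// Samples are stacked along rows: row = s * V + v.

// 2x2x2 max pooling with stride 2 (floor output dims; trailing odd slices
// are dropped). Returns pooled values and the 1-based argmax row index into
// the input matrix, per channel, for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool3(NumericMatrix x, IntegerVector dims, int n) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox_ = nx / 2, oy_ = ny / 2, oz_ = nz / 2;
  const int V = nx * ny * nz;
  const int Vo = ox_ * oy_ * oz_;
  const int C = x.ncol();
  NumericMatrix out(n * Vo, C);
  IntegerMatrix idx(n * Vo, C);
  for (int s = 0; s < n; ++s) {
    for (int c = 0; c < C; ++c) {
      const double* xc = &x(0, c);
      for (int iz = 0; iz < oz_; ++iz)
        for (int iy = 0; iy < oy_; ++iy)
          for (int ix = 0; ix < ox_; ++ix) {
            double best = R_NegInf;
            int besti = -1;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const int r = s * V +
                    (2 * ix + dx) + nx * ((2 * iy + dy) + ny * (2 * iz + dz));
                  if (xc[r] > best) { best = xc[r]; besti = r; }
                }
            const int ro = s * Vo + ix + ox_ * (iy + oy_ * iz);
            out(ro, c) = best;
            idx(ro, c) = besti + 1;
          }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool3_bwd(NumericMatrix dout, IntegerMatrix idx,
                               int nrow_in) {
  const int C = dout.ncol();
  NumericMatrix dx(nrow_in, C);
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < dout.nrow(); ++i)
      dx(idx(i, c) - 1, c) += dout(i, c);
  return dx;
}
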