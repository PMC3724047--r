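#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Reflect an out-of-range 0-based index into [0, n) using half-sample
// (Neumann) reflection, which keeps the convolution operator symmetric:
// -1 -> 0, -2 -> 1, n -> n-1, n+1 -> n-2.
static inline int reflect_idx(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - 1 - i;
  if (i < 0) i = 0;
  if (i >= n) i = n - 1;
  return i;
}

// Scatter-convolve every line of `vol` along one axis: for each source
// position j the kernel mass w[k] is added at the reflected position
// j + k - r, so each kernel distributes to exactly the positions the
// reflective convolution matrix prescribes and line mass is preserved.
static void convolve_axis(std::vector<double> &vol, std::vector<double> &tmp,
                          int n, int stride, int nlines, int line_jump,
                          const NumericVector &w) {
  int r = (w.size() - 1) / 2;
  for (int l = 0; l < nlines; ++l) {
    // lines are enumerated so that consecutive l map to the start offsets
    // of each 1D fibre along the axis
    int base = (l / line_jump) * line_jump * n + (l % line_jump);
    for (int i = 0; i < n; ++i) tmp[i] = 0.0;
    for (int j = 0; j < n; ++j) {
      double v = vol[base + j * stride];
      if (v == 0.0) continue;
      for (int k = -r; k <= r; ++k)
        tmp[reflect_idx(j + k, n)] += w[k + r] * v;
    }
    for (int i = 0; i < n; ++i) vol[base + i * stride] = tmp[i];
  }
}

// [[Rcpp::export(name = ".gauss_smooth_frames")]]
NumericMatrix gauss_smooth_frames(NumericMatrix data, int nx, int ny, int nz,
                                  NumericVector kernel) {
  int V = data.nrow(), T = data.ncol();
  if (V != nx * ny * nz) stop("grid dimensions do not match data rows");
  NumericMatrix out(V, T);
  std::vector<double> vol(V), tmp(std::max(std::max(nx, ny), nz));
  for (int t = 0; t < T; ++t) {
    for (int v = 0; v < V; ++v) vol[v] = data(v, t);
    // x: fibres have stride 1, starts at multiples of nx
    convolve_axis(vol, tmp, nx, 1, ny * nz, 1, kernel);
    // y: stride nx; starts enumerate (x, z) with jump nx
    convolve_axis(vol, tmp, ny, nx, nx * nz, nx, kernel);
    // z: stride nx*ny; starts enumerate (x, y)
    convolve_axis(vol, tmp, nz, nx * ny, nx * ny, nx * ny, kernel);
    for (int v = 0; v < V; ++v) out(v, t) = vol[v];
  }
  return out;
}
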