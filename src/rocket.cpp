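#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Dilated multichannel convolution + (ppv, max) pooling for a bank of
// random kernels. X is (length x channels x samples); kernels come from
// generate_kernels(). The accumulation runs tap-by-tap over a contiguous
// output buffer so the inner loop vectorizes; results match the naive
// apply_kernel() loop to floating-point accumulation order.
// [[Rcpp::export]]
NumericMatrix rocket_transform_cpp(arma::cube X, List kernels) {
  const int L = X.n_rows;
  const int n = X.n_slices;
  const int K = kernels.size();
  NumericMatrix out(n, 2 * K);
  std::vector<double> buf(2 * L);

  for (int ki = 0; ki < K; ++ki) {
    List k = kernels[ki];
    const int len = as<int>(k["length"]);
    const int dil = as<int>(k["dilation"]);
    const bool padding = as<bool>(k["padding"]);
    const double bias = as<double>(k["bias"]);
    IntegerVector ch = k["channels"];
    NumericMatrix w = k["weights"]; // |channels| x len
    const int nch = ch.size();
    const int span = (len - 1) * dil;
    const int pad = padding ? span / 2 : 0;
    const int t0 = -pad; // 0-based start offset of the output window
    const int t1 = (L - 1) + pad - span;
    const int nout = t1 - t0 + 1;
    if (nout < 1) stop("kernel span exceeds input length");

    for (int s = 0; s < n; ++s) {
      double *o = buf.data();
      std::fill(o, o + nout, bias);
      const double *slice = &X(0, 0, s); // column-major L x C
      for (int j = 0; j < len; ++j) {
        const int off = j * dil;
        // valid output positions for this tap: t in [max(t0,-off), min(t1, L-1-off)]
        const int lo = std::max(t0, -off);
        const int hi = std::min(t1, L - 1 - off);
        if (hi < lo) continue;
        for (int c = 0; c < nch; ++c) {
          const double wj = w(c, j);
          const double *col = slice + (size_t)(ch[c] - 1) * L + off;
          double *dst = o + (lo - t0);
          const int m = hi - lo + 1;
          const double *src = col + lo;
          for (int t = 0; t < m; ++t) dst[t] += wj * src[t];
        }
      }
      int npos = 0;
      double mx = o[0];
      for (int t = 0; t < nout; ++t) {
        if (o[t] > 0) ++npos;
        if (o[t] > mx) mx = o[t];
      }
      out(s, 2 * ki) = (double)npos / nout;
      out(s, 2 * ki + 1) = mx;
    }
  }
  return out;
}
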