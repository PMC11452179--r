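#include <Rcpp.h>
using namespace Rcpp;

// Frame-wise im2col gather.
// x: [D x T x B] flattened frame stack (column-major, D = values per frame).
// widx: [P x E] within-frame patch index table, 1-based; 0 means zero padding.
// Returns [(P*B*T) x E]; rows ordered p fastest, then b, then t.
// [[Rcpp::export]]
NumericMatrix im2col_frames(NumericVector x, IntegerMatrix widx,
                            int D, int T, int B) {
  const int P = widx.nrow(), E = widx.ncol();
  const R_xlen_t R = (R_xlen_t)P * T * B;
  NumericMatrix out((int)R, E);
  const double *xp = x.begin();
  const int *wp = widx.begin();
  double *op = out.begin();
  for (int e = 0; e < E; ++e) {
    const int *we = wp + (R_xlen_t)e * P;
    double *col = op + (R_xlen_t)e * R;
    for (int t = 0; t < T; ++t) {
      for (int b = 0; b < B; ++b) {
        const double *xf = xp + ((R_xlen_t)b * T + t) * D;
        double *orow = col + (R_xlen_t)(t * B + b) * P;
        for (int p = 0; p < P; ++p) {
          int id = we[p];
          orow[p] = (id > 0) ? xf[id - 1] : 0.0;
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_frames: scatter-add the gradient back onto the frames.
// [[Rcpp::export]]
NumericVector col2im_frames(NumericMatrix gp, IntegerMatrix widx,
                            int D, int T, int B) {
  const int P = widx.nrow(), E = widx.ncol();
  const R_xlen_t R = (R_xlen_t)P * T * B;
  NumericVector gx((R_xlen_t)D * T * B);
  const double *gpp = gp.begin();
  const int *wp = widx.begin();
  double *gxp = gx.begin();
  for (int e = 0; e < E; ++e) {
    const int *we = wp + (R_xlen_t)e * P;
    const double *col = gpp + (R_xlen_t)e * R;
    for (int t = 0; t < T; ++t) {
      for (int b = 0; b < B; ++b) {
        double *xf = gxp + ((R_xlen_t)b * T + t) * D;
        const double *orow = col + (R_xlen_t)(t * B + b) * P;
        for (int p = 0; p < P; ++p) {
          int id = we[p];
          if (id > 0) xf[id - 1] += orow[p];
        }
      }
    }
  }
  return gx;
}
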