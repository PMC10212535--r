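#include <Rcpp.h>
using namespace Rcpp;

// Fixed-window sliding extremum.  The vector is split into non-overlapping
// blocks of size W.  A forward pass keeps the running prefix extremum (minL)
// of the current block in a single scalar; when a block is complete, a
// backward pass materializes its suffix extrema (minR) directly inside v.
// The answer for window start i is min(minL[i+W-1], minR[i]) (max for
// maximum=true) and is written over v[i], which has already been consumed.
// Auxiliary storage is a constant number of scalars; each position is touched
// at most twice, so the runtime is O(|v|) independent of W.
template <typename T>
static void fixed_window_extreme(T *v, R_xlen_t n, R_xlen_t W, bool maximum) {
  T run = v[0];
  R_xlen_t block_start = 0;
  for (R_xlen_t t = 0; t < n; ++t) {
    R_xlen_t o = t - block_start;
    if (o == 0) run = v[t];
    else run = maximum ? std::max(run, v[t]) : std::min(run, v[t]);
    R_xlen_t i = t - W + 1;
    if (i >= 0) {
      T r;
      if (o == W - 1) r = run;  // the window is exactly the current block
      else r = maximum ? std::max(run, v[i]) : std::min(run, v[i]);
      v[i] = r;
    }
    if (o == W - 1 || t == n - 1) {
      for (R_xlen_t u = t - 1; u >= block_start; --u)
        v[u] = maximum ? std::max(v[u], v[u + 1]) : std::min(v[u], v[u + 1]);
      block_start = t + 1;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_sliding_extreme(NumericVector v, double W, bool maximum,
                                  bool in_place) {
  R_xlen_t n = v.size();
  R_xlen_t w = (R_xlen_t)W;
  if (w < 1 || w > n) stop("window size must satisfy 1 <= W <= length(v)");
  NumericVector work = in_place ? v : clone(v);
  fixed_window_extreme(REAL(work), n, w, maximum);
  NumericVector out(n - w + 1);
  for (R_xlen_t i = 0; i < n - w + 1; ++i) out[i] = work[i];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_sliding_extreme_int(IntegerVector v, double W, bool maximum) {
  R_xlen_t n = v.size();
  R_xlen_t w = (R_xlen_t)W;
  if (w < 1 || w > n) stop("window size must satisfy 1 <= W <= length(v)");
  IntegerVector work = clone(v);
  fixed_window_extreme(INTEGER(work), n, w, maximum);
  IntegerVector out(n - w + 1);
  for (R_xlen_t i = 0; i < n - w + 1; ++i) out[i] = work[i];
  return out;
}
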