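#include <Rcpp.h>
using namespace Rcpp;

//' @useDynLib cohesinmeta, .registration = TRUE
//' @importFrom Rcpp sourceCpp

template <typename T>
static void window_sums_loop(const T *pv, R_xlen_t L, int window, int step,
                             double *po, R_xlen_t n) {
  double acc = 0.0;
  for (R_xlen_t i = 0; i < window; ++i) acc += pv[i];
  po[0] = acc;
  for (R_xlen_t a = 1; a < n; ++a) {
    R_xlen_t s = a * step;
    for (R_xlen_t i = s - step; i < s; ++i) acc -= pv[i];
    for (R_xlen_t i = s + window - step; i < s + window; ++i) acc += pv[i];
    po[a] = acc;
  }
}

// Sliding-window sums: sum of v over [a*step, a*step + window) for each
// full window, accumulated in double so deep integer coverage cannot
// overflow. Integer and double inputs are handled without coercion.
// [[Rcpp::export(name = ".window_sums")]]
NumericVector window_sums_c(SEXP v, int window, int step) {
  R_xlen_t L = Rf_xlength(v);
  if (L < window) return NumericVector(0);
  R_xlen_t n = (L - window) / step + 1;
  NumericVector out(no_init(n));
  if (TYPEOF(v) == INTSXP) {
    window_sums_loop(INTEGER(v), L, window, step, REAL(out), n);
  } else if (TYPEOF(v) == REALSXP) {
    window_sums_loop(REAL(v), L, window, step, REAL(out), n);
  } else {
    stop("window sums need an integer or double vector");
  }
  return out;
}

// Fused ChIP read simulation for one chromosome: per-base Poisson read
// starts with rate lam[i] * scale * block_mult[i / block], extended by
// frag_len bp into integer coverage, in a single pass. `lam` may be a
// scalar (constant occupancy) and `block_mult` may be empty (no replicate
// noise field). Uses R's RNG, so set.seed() upstream gives determinism.
// [[Rcpp::export(name = ".simulate_coverage")]]
IntegerVector simulate_coverage_c(NumericVector lam, R_xlen_t L,
                                  NumericVector block_mult, int block,
                                  double scale, int frag_len) {
  IntegerVector out(no_init(L));
  int *po = INTEGER(out);
  const double *pl = REAL(lam);
  const bool lam_scalar = lam.size() == 1;
  const double *pm = block_mult.size() ? REAL(block_mult) : nullptr;
  std::vector<int> starts(frag_len, 0); // ring buffer of recent start counts
  int acc = 0;
  R_xlen_t i = 0;
  while (i < L) {
    R_xlen_t stop_at = pm ? std::min<R_xlen_t>(L, (i / block + 1) * block) : L;
    double mult = pm ? pm[i / block] * scale : scale;
    for (; i < stop_at; ++i) {
      double rate = (lam_scalar ? pl[0] : pl[i]) * mult;
      int k = (int)R::rpois(rate);
      int slot = (int)(i % frag_len);
      acc += k - (i >= frag_len ? starts[slot] : 0);
      starts[slot] = k;
      po[i] = acc;
    }
  }
  return out;
}
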