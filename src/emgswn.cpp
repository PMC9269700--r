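#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Causal IIR filter (direct form II transposed), applied down each column.
// b, a are transfer-function coefficients with a[0] == 1 (normalized in R).
// [[Rcpp::export]]
NumericMatrix iir_filter_cols(const NumericMatrix& x,
                              const NumericVector& b,
                              const NumericVector& a) {
  const int n = x.nrow(), p = x.ncol();
  const int nb = b.size(), na = a.size();
  const int nz = std::max(nb, na) - 1;
  NumericMatrix y(n, p);
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  for (int j = 0; j < p; ++j) {
    std::vector<double> z(nz, 0.0);
    for (int t = 0; t < n; ++t) {
      const double xt = x(t, j);
      const double yt = bb[0] * xt + (nz > 0 ? z[0] : 0.0);
      for (int k = 0; k < nz - 1; ++k)
        z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
      if (nz > 0) z[nz - 1] = bb[nz] * xt - aa[nz] * yt;
      y(t, j) = yt;
    }
  }
  return y;
}

// Streaming sliding-window normalization, one output sample per input sample.
// For t < L the window expands from the first sample (warm-up region); from
// t >= L it is the trailing L samples. Mean and population SD use long-double
// accumulation in sample order so results match R's sum()-based arithmetic.
// Zero-variance windows emit 0 for the newest sample.
// [[Rcpp::export]]
List swn_stream(const NumericMatrix& x, const int L) {
  const int n = x.nrow(), p = x.ncol();
  NumericMatrix y(n, p);
  int n_zero = 0;
  for (int j = 0; j < p; ++j) {
    const double* xc = &x(0, j);
    double* yc = &y(0, j);
    for (int t = 0; t < n; ++t) {
      const int i0 = (t + 1 >= L) ? (t + 1 - L) : 0;
      const int len = t - i0 + 1;
      if (len == 1) {  // single-sample warm-up window: no scale, emit 0
        yc[t] = 0.0;
        continue;
      }
      long double acc = 0.0L;
      for (int i = i0; i <= t; ++i) acc += xc[i];
      const double m = static_cast<double>(acc) / len;
      long double ss = 0.0L;
      for (int i = i0; i <= t; ++i) {
        const double d = xc[i] - m;
        ss += d * d;
      }
      const double s = std::sqrt(static_cast<double>(ss) / len);
      if (s == 0.0) {
        yc[t] = 0.0;
        ++n_zero;
      } else {
        yc[t] = (xc[t] - m) / s;
      }
    }
  }
  return List::create(_["y"] = y, _["n_zero_windows"] = n_zero);
}

// Softmax terms for the classifier objective: given the linear predictor Z
// (n x K), case weights w and 1-based class index yi, returns the weighted
// log-likelihood sum(w * (z_y - logsumexp)) and the gradient factor
// G = P * w - Y * w (n x K), computed in one stabilized pass.
// [[Rcpp::export]]
List softmax_terms(const NumericMatrix& Z, const NumericVector& w,
                   const IntegerVector& yi) {
  const int n = Z.nrow(), K = Z.ncol();
  NumericMatrix G(n, K);
  long double ll = 0.0L;
  std::vector<double> e(K);
  for (int i = 0; i < n; ++i) {
    double zmax = Z(i, 0);
    for (int k = 1; k < K; ++k) zmax = std::max(zmax, Z(i, k));
    double se = 0.0;
    for (int k = 0; k < K; ++k) {
      e[k] = std::exp(Z(i, k) - zmax);
      se += e[k];
    }
    const double lse = zmax + std::log(se);
    ll += w[i] * (Z(i, yi[i] - 1) - lse);
    const double wi = w[i];
    for (int k = 0; k < K; ++k) {
      G(i, k) = wi * (e[k] / se - (yi[i] - 1 == k ? 1.0 : 0.0));
    }
  }
  return List::create(_["loglik"] = static_cast<double>(ll), _["G"] = G);
}

// Trailing-window time-domain features at selected sample indices.
// kept: 1-based end indices of windows (each must be >= L).
// Columns: MAV, MWL, DRMS, SD (population SD of the raw window), CMAV
// (mean absolute deviation from the window mean).
// [[Rcpp::export]]
NumericMatrix td_features_win(const NumericVector& x,
                              const IntegerVector& kept,
                              const int L) {
  const int m = kept.size();
  NumericMatrix out(m, 5);
  for (int w = 0; w < m; ++w) {
    const int end = kept[w] - 1;       // 0-based inclusive end
    const int i0 = end - L + 1;
    long double sabs = 0.0L, sum = 0.0L;
    for (int i = i0; i <= end; ++i) {
      sabs += std::fabs(x[i]);
      sum += x[i];
    }
    const double mav = static_cast<double>(sabs) / L;
    const double mean = static_cast<double>(sum) / L;
    long double sd1 = 0.0L, sd2 = 0.0L, ss = 0.0L, sc = 0.0L;
    for (int i = i0 + 1; i <= end; ++i) {
      const double d = x[i] - x[i - 1];
      sd1 += std::fabs(d);
      sd2 += d * d;
    }
    for (int i = i0; i <= end; ++i) {
      const double c = x[i] - mean;
      ss += c * c;
      sc += std::fabs(c);
    }
    out(w, 0) = mav;
    out(w, 1) = static_cast<double>(sd1) / (L - 1);
    out(w, 2) = std::sqrt(static_cast<double>(sd2) / (L - 1));
    out(w, 3) = std::sqrt(static_cast<double>(ss) / L);
    out(w, 4) = static_cast<double>(sc) / L;
  }
  return out;
}

// Stationary wavelet transform level-3 detail feature on trailing windows.
// Each window is symmetrically padded to the next multiple of 8, run through
// a 3-level a-trous analysis with the supplied decomposition filters, and
// summarized as mean(|cD3|) over the padded support cropped back to the
// original window extent.
// [[Rcpp::export]]
NumericVector swt_cd3_win(const NumericVector& x,
                          const IntegerVector& kept,
                          const int L,
                          const NumericVector& dec_lo,
                          const NumericVector& dec_hi) {
  const int m = kept.size();
  const int nf = dec_lo.size();
  const int N = ((L + 7) / 8) * 8;
  const int pad = N - L;
  const int pl = pad / 2;
  NumericVector out(m);
  std::vector<double> a(N), a2(N), d(N);
  for (int w = 0; w < m; ++w) {
    const int end = kept[w] - 1;
    const int i0 = end - L + 1;
    // symmetric (half-point) padding: [x_pl ... x_1 | x_1 ... x_L | x_L ...]
    for (int i = 0; i < pl; ++i) a[i] = x[i0 + (pl - 1 - i)];
    for (int i = 0; i < L; ++i) a[pl + i] = x[i0 + i];
    for (int i = 0; i < pad - pl; ++i) a[pl + L + i] = x[end - i];
    // levels 1 and 2: approximation chain with upsampled low-pass
    for (int lev = 1; lev <= 2; ++lev) {
      const int step = 1 << (lev - 1);
      for (int n = 0; n < N; ++n) {
        double acc = 0.0;
        for (int k = 0; k < nf; ++k) {
          int idx = n - k * step;
          idx %= N;
          if (idx < 0) idx += N;
          acc += dec_lo[k] * a[idx];
        }
        a2[n] = acc;
      }
      std::swap(a, a2);
    }
    // level 3 detail
    const int step = 4;
    long double sabs = 0.0L;
    for (int n = 0; n < N; ++n) {
      double acc = 0.0;
      for (int k = 0; k < nf; ++k) {
        int idx = n - k * step;
        idx %= N;
        if (idx < 0) idx += N;
        acc += dec_hi[k] * a[idx];
      }
      d[n] = acc;
    }
    // crop back to the original window extent
    for (int n = pl; n < pl + L; ++n) sabs += std::fabs(d[n]);
    out[w] = static_cast<double>(sabs) / L;
  }
  return out;
}
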