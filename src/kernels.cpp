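#include <Rcpp.h>
using namespace Rcpp;

// Add the span x channels block E, tiled n_rep times along rows, into sig
// starting at 0-based row start0. sig is modified in place; callers own it.
// [[Rcpp::export(rng = false)]]
void tile_add_inplace(NumericMatrix sig, NumericMatrix E, int start0,
                      int n_rep) {
  const int span = E.nrow();
  const int nch = E.ncol();
  const int nrow = sig.nrow();
  if (start0 + (R_xlen_t)span * n_rep > nrow) stop("tile exceeds signal");
  for (int ch = 0; ch < nch; ++ch) {
    double* s = &sig(start0, ch);
    const double* e = &E(0, ch);
    for (int r = 0; r < n_rep; ++r) {
      double* block = s + (R_xlen_t)r * span;
      for (int i = 0; i < span; ++i) block[i] += e[i];
    }
  }
}

// Per-sample trial mean and standard error over epochs cut at the given
// 0-based onsets, window [rel0, rel0 + len) samples. data is samples x
// channels; returns mean and se as channels x len matrices.
// [[Rcpp::export(rng = false)]]
List epoch_mean_se(NumericMatrix data, IntegerVector onsets0, int rel0,
                   int len) {
  const int nch = data.ncol();
  const int ntr = onsets0.size();
  const int nrow = data.nrow();
  NumericMatrix mean(nch, len), se(nch, len);
  std::vector<double> sum(len), sumsq(len);
  for (int ch = 0; ch < nch; ++ch) {
    std::fill(sum.begin(), sum.end(), 0.0);
    std::fill(sumsq.begin(), sumsq.end(), 0.0);
    const double* col = &data(0, ch);
    for (int t = 0; t < ntr; ++t) {
      const int base = onsets0[t] + rel0;
      if (base < 0 || base + len > nrow) stop("epoch outside the recording");
      const double* x = col + base;
      for (int i = 0; i < len; ++i) {
        sum[i] += x[i];
        sumsq[i] += x[i] * x[i];
      }
    }
    for (int i = 0; i < len; ++i) {
      const double mu = sum[i] / ntr;
      mean(ch, i) = mu;
      if (ntr > 1) {
        double s2 = (sumsq[i] - ntr * mu * mu) / (ntr - 1);
        se(ch, i) = s2 > 0 ? std::sqrt(s2 / ntr) : 0.0;
      }
    }
  }
  return List::create(_["mean"] = mean, _["se"] = se);
}

// Returns data with each column's mean subtracted (DC removal).
// [[Rcpp::export(rng = false)]]
NumericMatrix center_columns(NumericMatrix data) {
  const int n = data.nrow(), p = data.ncol();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double* x = &data(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += x[i];
    const double mu = s / n;
    double* o = &out(0, j);
    for (int i = 0; i < n; ++i) o[i] = x[i] - mu;
  }
  return out;
}

// Returns data with the across-column (channel) mean subtracted at every
// row (average re-reference).
// [[Rcpp::export(rng = false)]]
NumericMatrix subtract_row_means(NumericMatrix data) {
  const int n = data.nrow(), p = data.ncol();
  std::vector<double> rm(n, 0.0);
  for (int j = 0; j < p; ++j) {
    const double* x = &data(0, j);
    for (int i = 0; i < n; ++i) rm[i] += x[i];
  }
  for (int i = 0; i < n; ++i) rm[i] /= p;
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double* x = &data(0, j);
    double* o = &out(0, j);
    for (int i = 0; i < n; ++i) o[i] = x[i] - rm[i];
  }
  return out;
}

// Linear interpolation of a low-rate series onto n_out samples at unit
// spacing scaled by ratio (= fs_low / fs_high).
// [[Rcpp::export(rng = false)]]
NumericVector lin_upsample(NumericVector low, double ratio, int n_out) {
  NumericVector out(n_out);
  const int n_low = low.size();
  for (int t = 0; t < n_out; ++t) {
    const double pos = t * ratio;
    int i = (int)pos;
    if (i >= n_low - 1) i = n_low - 2;
    const double w = pos - i;
    out[t] = (1.0 - w) * low[i] + w * low[i + 1];
  }
  return out;
}

// Cascade of direct-form-I IIR sections: for each section k, y[t] =
// sum_i b[k][i] x[t-i] - sum_{j>=1} a[k][j] y[t-j] (a[k][0] = 1).
// [[Rcpp::export(rng = false)]]
NumericVector iir_cascade(NumericVector x, List b_list, List a_list) {
  NumericVector cur = clone(x);
  const int n = cur.size();
  for (int k = 0; k < b_list.size(); ++k) {
    NumericVector b = b_list[k], a = a_list[k];
    NumericVector out(n);
    const int nb = b.size(), na = a.size();
    for (int t = 0; t < n; ++t) {
      double acc = 0.0;
      for (int i = 0; i < nb && i <= t; ++i) acc += b[i] * cur[t - i];
      for (int j = 1; j < na && j <= t; ++j) acc -= a[j] * out[t - j];
      out[t] = acc;
    }
    cur = out;
  }
  return cur;
}
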