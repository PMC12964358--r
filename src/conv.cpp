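#include <Rcpp.h>
using namespace Rcpp;

// Truncated grid convolution in log space, column-wise over samples.
//
// a, b: G x S matrices of log masses indexed by grid mass i/(G-1), i = 0..G-1.
// Returns c with c[k, s] = log sum_{i+j=k} exp(a[i,s] + b[j,s]) (sum mode) or
// max_{i+j=k} (a[i,s] + b[j,s]) (max mode, used for MAP backtracking).
// Entries with mass index sums above G-1 are dropped: total mass never
// exceeds 1 on the simplex grid.
// [[Rcpp::export(name = ".conv_log_cpp")]]
NumericMatrix conv_log_cpp(NumericMatrix a, NumericMatrix b, bool max_mode) {
  const int G = a.nrow(), S = a.ncol();
  if (b.nrow() != G || b.ncol() != S)
    stop("conv_log: dimension mismatch");
  NumericMatrix out(G, S);
  std::vector<double> ea(G), eb(G);
  for (int s = 0; s < S; ++s) {
    if (max_mode) {
      for (int k = 0; k < G; ++k) {
        double m = R_NegInf;
        for (int i = 0; i <= k; ++i) {
          double v = a(i, s) + b(k - i, s);
          if (v > m) m = v;
        }
        out(k, s) = m;
      }
      continue;
    }
    double ma = R_NegInf, mb = R_NegInf;
    for (int i = 0; i < G; ++i) {
      if (a(i, s) > ma) ma = a(i, s);
      if (b(i, s) > mb) mb = b(i, s);
    }
    if (ma == R_NegInf || mb == R_NegInf) {
      for (int k = 0; k < G; ++k) out(k, s) = R_NegInf;
      continue;
    }
    // support windows: entries more than TH nats below the column maximum
    // are numerically irrelevant (relative mass < G * exp(-TH) ~ 1e-33)
    const double TH = 80.0;
    int a0 = G, a1 = -1, b0 = G, b1 = -1;
    for (int i = 0; i < G; ++i) {
      if (a(i, s) > ma - TH) { if (i < a0) a0 = i; a1 = i; }
      if (b(i, s) > mb - TH) { if (i < b0) b0 = i; b1 = i; }
    }
    for (int i = a0; i <= a1; ++i)
      ea[i] = (a(i, s) > ma - TH) ? std::exp(a(i, s) - ma) : 0.0;
    for (int i = b0; i <= b1; ++i)
      eb[i] = (b(i, s) > mb - TH) ? std::exp(b(i, s) - mb) : 0.0;
    // clipped entries are floored, not -Inf: states whose mass constraints
    // conflict badly must stay finitely comparable for the samplers
    const double FLOOR = ma + mb - 500.0;
    for (int k = 0; k < G; ++k) out(k, s) = FLOOR;
    const int k1 = std::min(G - 1, a1 + b1);
    for (int k = a0 + b0; k <= k1; ++k) {
      double acc = 0.0;
      const int ilo = std::max(a0, k - b1), ihi = std::min(a1, k - b0);
      for (int i = ilo; i <= ihi; ++i) acc += ea[i] * eb[k - i];
      double v = (acc > 0.0) ? std::log(acc) + ma + mb : FLOOR;
      out(k, s) = (v > FLOOR) ? v : FLOOR;
    }
  }
  return out;
}

// Fold a list of G x S log-mass matrices by repeated truncated convolution.
// [[Rcpp::export(name = ".fold_conv_log_cpp")]]
NumericMatrix fold_conv_log_cpp(List mats, bool max_mode) {
  const int M = mats.size();
  if (M == 0) stop("fold_conv_log: empty list");
  NumericMatrix acc = clone(as<NumericMatrix>(mats[0]));
  for (int m = 1; m < M; ++m)
    acc = conv_log_cpp(acc, as<NumericMatrix>(mats[m]), max_mode);
  return acc;
}
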