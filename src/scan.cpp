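#include <Rcpp.h>
using namespace Rcpp;

// Window scores of a PWM over an encoded sequence (A=1,C=2,G=3,T=4,N=0).
// smat is w x 4; windows containing N score NA.
// [[Rcpp::export]]
NumericVector pwm_window_scores_cpp(IntegerVector seq, NumericMatrix smat) {
  int L = seq.size(), w = smat.nrow();
  if (L < w) return NumericVector(0);
  NumericVector out(L - w + 1);
  for (int i = 0; i <= L - w; ++i) {
    double s = 0.0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      int b = seq[i + j];
      if (b == 0) { ok = false; break; }
      s += smat(j, b - 1);
    }
    out[i] = ok ? s : NA_REAL;
  }
  return out;
}

// Best window score per strand and valid-window count per promoter.
// seqs: length x promoters matrix (one encoded promoter per column, so the
// inner scan walks contiguous memory); fwd/rev: w x 4 score matrices
// (rev = reverse-complement scoring matrix applied to the forward strand).
// Returns promoters x 3: [best fwd, best rev, m (both strands)];
// bests are NA when m == 0.
// [[Rcpp::export]]
NumericMatrix pwm_best_scores_cpp(IntegerMatrix seqs, NumericMatrix fwd,
                                  NumericMatrix rev) {
  int L = seqs.nrow(), n = seqs.ncol(), w = fwd.nrow();
  NumericMatrix out(n, 3);
  // flat copies of the score matrices: sf[j*4 + b]
  std::vector<double> f(w * 4), rv(w * 4);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b) {
      f[j * 4 + b] = fwd(j, b);
      rv[j * 4 + b] = rev(j, b);
    }
  for (int r = 0; r < n; ++r) {
    const int *col = &seqs(0, r);
    double bf = R_NegInf, br = R_NegInf;
    int m = 0;
    for (int i = 0; i <= L - w; ++i) {
      double sf = 0.0, sr = 0.0;
      bool ok = true;
      for (int j = 0; j < w; ++j) {
        int b = col[i + j];
        if (b == 0) { ok = false; break; }
        sf += f[j * 4 + b - 1];
        sr += rv[j * 4 + b - 1];
      }
      if (!ok) continue;
      m += 2;
      if (sf > bf) bf = sf;
      if (sr > br) br = sr;
    }
    out(r, 0) = (m > 0) ? bf : NA_REAL;
    out(r, 1) = (m > 0) ? br : NA_REAL;
    out(r, 2) = m;
  }
  return out;
}
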