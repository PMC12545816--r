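#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ZOOPS EM inner loop. Wt holds integer base codes (1..4 = ACGT, 5 = N) of
// every candidate window (both strands), transposed to w x n_windows so the
// per-window column scan is contiguous; group maps windows to their sequence
// (1..n_seq); nwin is the number of candidate windows per sequence. The
// objective is the ZOOPS log likelihood minus the background-only log
// likelihood (nats). The pseudocounted M-step makes this MAP-EM under a
// Dirichlet(pseudo * bg) prior, so the monotone quantity is the penalized
// objective (log likelihood + log prior); check_monotone asserts it.
// [[Rcpp::export]]
List zoops_em_cpp(IntegerMatrix Wt, IntegerVector group, NumericVector nwin,
                  NumericMatrix probs0, NumericVector bg, double lambda0,
                  double tol, int max_iter, double pseudo,
                  bool check_monotone) {
  const int w = Wt.nrow(), n = Wt.ncol();
  const int nseq = nwin.size();
  NumericMatrix probs(clone(probs0));
  double lambda = lambda0;
  const int* wt = INTEGER(Wt);
  const int* grp = INTEGER(group);

  std::vector<double> lw(5 * w);
  std::vector<double> score(n), denom(nseq), se(nseq), lognwin(nseq);
  std::vector<double> z(n), Qi(nseq), cnt(4 * w);
  for (int g = 0; g < nseq; ++g) lognwin[g] = std::log(nwin[g]);
  double obj = 0.0, obj_old = R_NegInf, pen_old = R_NegInf;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    for (int c = 0; c < w; ++c) {
      for (int b = 0; b < 4; ++b) lw[c * 5 + b] = std::log(probs(b, c) / bg[b]);
      lw[c * 5 + 4] = 0.0;
    }
    const double log_lambda = std::log(lambda);
    const double one_minus = 1.0 - lambda;

    std::fill(se.begin(), se.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const int* wi = wt + (size_t)i * w;
      double s = 0.0;
      for (int c = 0; c < w; ++c) s += lw[c * 5 + (wi[c] - 1)];
      score[i] = s;
      double t = log_lambda - lognwin[grp[i] - 1] + s;
      if (t > 600.0) t = 600.0;
      se[grp[i] - 1] += std::exp(t);
    }
    obj = 0.0;
    for (int g = 0; g < nseq; ++g) {
      denom[g] = std::log(se[g] + one_minus);
      obj += denom[g];
    }
    if (check_monotone) {
      double prior = 0.0;
      for (int c = 0; c < w; ++c) {
        for (int b = 0; b < 4; ++b) {
          prior += pseudo * bg[b] * std::log(probs(b, c));
        }
      }
      double pen = obj + prior;
      if (pen < pen_old - 1e-8 * (std::fabs(pen_old) + 1.0)) {
        stop("EM objective decreased: %f -> %f", pen_old, pen);
      }
      pen_old = pen;
    }

    // E-step responsibilities and M-step accumulation
    std::fill(Qi.begin(), Qi.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int g = grp[i] - 1;
      double t = log_lambda - lognwin[g] + score[i];
      double zi = std::exp(t - denom[g]);
      z[i] = zi;
      Qi[g] += zi;
      const int* wi = wt + (size_t)i * w;
      for (int c = 0; c < w; ++c) {
        int b = wi[c] - 1;
        if (b < 4) cnt[c * 4 + b] += zi;
      }
    }
    double mq = 0.0;
    for (int g = 0; g < nseq; ++g) mq += std::min(Qi[g], 1.0);
    lambda = mq / nseq;
    if (lambda < 1e-8) lambda = 1e-8;
    if (lambda > 1.0 - 1e-8) lambda = 1.0 - 1e-8;
    for (int c = 0; c < w; ++c) {
      double tot = 0.0;
      for (int b = 0; b < 4; ++b) tot += cnt[c * 4 + b];
      for (int b = 0; b < 4; ++b) {
        probs(b, c) = (cnt[c * 4 + b] + pseudo * bg[b]) / (tot + pseudo);
      }
    }
    if (R_finite(obj_old) &&
        std::fabs(obj - obj_old) <= tol * (std::fabs(obj_old) + 1e-8)) {
      obj_old = obj;
      break;
    }
    obj_old = obj;
  }

  NumericMatrix counts(4, w);
  for (int c = 0; c < w; ++c) {
    for (int b = 0; b < 4; ++b) counts(b, c) = cnt[c * 4 + b];
  }
  return List::create(
    _["probs"] = probs, _["lambda"] = lambda,
    _["z"] = NumericVector(z.begin(), z.end()),
    _["Qi"] = NumericVector(Qi.begin(), Qi.end()),
    _["counts"] = counts, _["llr"] = obj_old,
    _["iter"] = std::min(iter, max_iter));
}
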