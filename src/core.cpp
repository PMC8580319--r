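#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Window scores of a PSSM along an integer-encoded sequence.
// seq: 1-based letter indices, 0 = ambiguous (contributes zero log-odds).
// lo: width x K log-odds (bits); q: width x K integer-quantised log-odds.
// Windows with > max_ambig_frac ambiguous letters are flagged skipped.
// [[Rcpp::export]]
List cpp_window_scores(IntegerVector seq, NumericMatrix lo, IntegerMatrix q,
                       double max_ambig_frac) {
  int L = seq.size(), w = lo.nrow();
  int n = L - w + 1;
  if (n < 1) return List::create(_["bits"] = NumericVector(0),
                                 _["qscore"] = IntegerVector(0),
                                 _["skipped"] = LogicalVector(0));
  NumericVector bits(n);
  IntegerVector qs(n);
  LogicalVector skip(n);
  for (int s = 0; s < n; ++s) {
    double b = 0.0; int iq = 0, namb = 0;
    for (int i = 0; i < w; ++i) {
      int a = seq[s + i];
      if (a <= 0) { ++namb; continue; }
      b += lo(i, a - 1);
      iq += q(i, a - 1);
    }
    bits[s] = b; qs[s] = iq;
    skip[s] = (double)namb / w > max_ambig_frac;
  }
  return List::create(_["bits"] = bits, _["qscore"] = qs, _["skipped"] = skip);
}

// Exact PMF of the integer-quantised window score under the background,
// by column-wise convolution. q: width x K integer scores (rows shifted
// internally so indices stay non-negative). Returns pmf over
// [min_total, max_total] as a dense vector plus the offset.
// [[Rcpp::export]]
List cpp_score_pmf(IntegerMatrix q, NumericVector bg) {
  int w = q.nrow(), K = q.ncol();
  long min_total = 0, max_total = 0;
  std::vector<int> rmin(w), rmax(w);
  for (int i = 0; i < w; ++i) {
    int mn = q(i, 0), mx = q(i, 0);
    for (int a = 1; a < K; ++a) { mn = std::min(mn, q(i, a)); mx = std::max(mx, q(i, a)); }
    rmin[i] = mn; rmax[i] = mx; min_total += mn; max_total += mx;
  }
  size_t span = (size_t)(max_total - min_total) + 1;
  std::vector<double> cur(1, 1.0);
  size_t cur_len = 1;
  std::vector<double> nxt;
  for (int i = 0; i < w; ++i) {
    size_t add = (size_t)(rmax[i] - rmin[i]);
    nxt.assign(cur_len + add, 0.0);
    for (int a = 0; a < K; ++a) {
      size_t off = (size_t)(q(i, a) - rmin[i]);
      double p = bg[a];
      if (p <= 0.0) continue;
      for (size_t s = 0; s < cur_len; ++s) nxt[s + off] += cur[s] * p;
    }
    cur.swap(nxt);
    cur_len = cur.size();
  }
  NumericVector pmf(cur.begin(), cur.end());
  if ((size_t)pmf.size() != span) stop("pmf span mismatch");
  return List::create(_["pmf"] = pmf, _["offset"] = (double)min_total);
}

// ZOOPS expectation-maximisation for one ungapped motif.
// seqs: list of integer-encoded sequences (1..K, 0 ambiguous).
// theta0: w x K initial probability matrix. bg: background. erase: list of
// per-position retention weights in [0,1] (probabilistic erasure of
// previously discovered occurrences). Returns fitted theta (with
// pseudocount), gamma, per-sequence window posteriors, and the final
// ZOOPS log likelihood ratio vs the pure-background model.
// [[Rcpp::export]]
List cpp_em_zoops(List seqs, int w, NumericMatrix theta0, NumericVector bg,
                  double gamma0, List erase, double pseudo, int maxit,
                  double tol) {
  int nseq = seqs.size(), K = bg.size();
  std::vector<std::vector<int>> X(nseq);
  std::vector<std::vector<double>> lw(nseq); // log window retention weights
  for (int s = 0; s < nseq; ++s) {
    IntegerVector v = seqs[s];
    X[s].assign(v.begin(), v.end());
    NumericVector e = erase[s];
    int L = v.size(), m = L - w + 1;
    // sentinel for log(0) kept moderate: a cumulative sum of huge
    // magnitudes would lose the precision of differences between
    // nearby entries (the per-window weights)
    std::vector<double> cl(L + 1, 0.0);
    for (int p = 0; p < L; ++p) {
      double ep = e[p];
      double lp = ep <= 0 ? -1e4 : std::log(ep);
      cl[p + 1] = cl[p] + std::max(lp, -1e4);
    }
    lw[s].resize(std::max(m, 0));
    for (int j = 0; j < m; ++j) lw[s][j] = cl[j + w] - cl[j];
  }
  NumericMatrix theta = clone(theta0);
  double gamma = gamma0;
  std::vector<double> lbg(K);
  for (int a = 0; a < K; ++a) lbg[a] = std::log(bg[a]);
  double ll_old = -std::numeric_limits<double>::infinity(), ll = ll_old;
  std::vector<std::vector<double>> Z(nseq);
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    // E-step
    std::vector<double> ltheta(w * K);
    for (int i = 0; i < w; ++i)
      for (int a = 0; a < K; ++a)
        ltheta[i * K + a] = std::log(std::max(theta(i, a), 1e-300)) - lbg[a];
    ll = 0.0;
    std::vector<std::vector<double>> counts(w, std::vector<double>(K, 0.0));
    double zsum_all = 0.0;
    for (int s = 0; s < nseq; ++s) {
      int L = X[s].size(), m = L - w + 1;
      if (m < 1) { Z[s].clear(); continue; }
      std::vector<double> lr(m);
      for (int j = 0; j < m; ++j) {
        double v = lw[s][j];
        for (int i = 0; i < w; ++i) {
          int a = X[s][j + i];
          if (a > 0) v += ltheta[i * K + a - 1];
        }
        lr[j] = v + std::log(gamma / m);
      }
      double l0 = std::log(std::max(1.0 - gamma, 1e-300));
      double mx = l0;
      for (int j = 0; j < m; ++j) mx = std::max(mx, lr[j]);
      double den = std::exp(l0 - mx);
      for (int j = 0; j < m; ++j) den += std::exp(lr[j] - mx);
      ll += mx + std::log(den);
      Z[s].resize(m);
      double zs = 0.0;
      for (int j = 0; j < m; ++j) {
        double z = std::exp(lr[j] - mx) / den;
        Z[s][j] = z; zs += z;
        if (z > 1e-12)
          for (int i = 0; i < w; ++i) {
            int a = X[s][j + i];
            if (a > 0) counts[i][a - 1] += z;
          }
      }
      zsum_all += zs;
    }
    // M-step
    gamma = std::min(0.999, std::max(1e-6, zsum_all / nseq));
    for (int i = 0; i < w; ++i) {
      double tot = 0.0;
      for (int a = 0; a < K; ++a) tot += counts[i][a] + pseudo * bg[a] * K / K;
      for (int a = 0; a < K; ++a)
        theta(i, a) = (counts[i][a] + pseudo * bg[a]) / (zsum_all + pseudo);
      // renormalise against ambiguous-letter mass loss
      double rs = 0.0;
      for (int a = 0; a < K; ++a) rs += theta(i, a);
      for (int a = 0; a < K; ++a) theta(i, a) /= rs;
      (void)tot;
    }
    if (std::isfinite(ll_old) && ll - ll_old < tol) break;
    ll_old = ll;
  }
  List zout(nseq);
  for (int s = 0; s < nseq; ++s) zout[s] = NumericVector(Z[s].begin(), Z[s].end());
  return List::create(_["theta"] = theta, _["gamma"] = gamma, _["z"] = zout,
                      _["loglik"] = ll, _["iterations"] = it + 1);
}

// Global (end-gap penalised) affine-gap alignment of two profiles given the
// precomputed column-pair score matrix S (n1 x n2). A gap of length k costs
// gap_open + k * gap_extend. Traceback tie-break: diagonal > up > left
// (up consumes a row of A). Returns 1-based column indices with 0 = gap.
// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix S, double gap_open, double gap_extend) {
  int n1 = S.nrow(), n2 = S.ncol();
  const double NEG = -1e300;
  double go = gap_open + gap_extend, ge = gap_extend;
  // DP matrices: M (diag), Xm (gap in B: consume A row), Ym (gap in A)
  std::vector<double> M((n1 + 1) * (n2 + 1), NEG), Xm(M), Ym(M);
  auto idx = [n2](int i, int j) { return i * (n2 + 1) + j; };
  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n1; ++i) Xm[idx(i, 0)] = -(gap_open + i * ge);
  for (int j = 1; j <= n2; ++j) Ym[idx(0, j)] = -(gap_open + j * ge);
  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      double d = std::max(M[idx(i - 1, j - 1)],
                          std::max(Xm[idx(i - 1, j - 1)], Ym[idx(i - 1, j - 1)]));
      M[idx(i, j)] = d + S(i - 1, j - 1);
      Xm[idx(i, j)] = std::max(std::max(M[idx(i - 1, j)] - go,
                                        Xm[idx(i - 1, j)] - ge),
                               Ym[idx(i - 1, j)] - go);
      Ym[idx(i, j)] = std::max(std::max(M[idx(i, j - 1)] - go,
                                        Ym[idx(i, j - 1)] - ge),
                               Xm[idx(i, j - 1)] - go);
    }
  }
  double best = std::max(M[idx(n1, n2)], std::max(Xm[idx(n1, n2)], Ym[idx(n1, n2)]));
  // traceback
  std::vector<int> pa, pb;
  int i = n1, j = n2;
  int state; // 0 = M, 1 = X(up), 2 = Y(left); tie-break prefers smaller state
  if (M[idx(i, j)] >= best - 1e-9) state = 0;
  else if (Xm[idx(i, j)] >= best - 1e-9) state = 1;
  else state = 2;
  const double EPS = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) stop("traceback error (M at border)");
      pa.push_back(i); pb.push_back(j);
      double need = M[idx(i, j)] - S(i - 1, j - 1);
      --i; --j;
      if (std::fabs(M[idx(i, j)] - need) < EPS) state = 0;
      else if (std::fabs(Xm[idx(i, j)] - need) < EPS) state = 1;
      else if (std::fabs(Ym[idx(i, j)] - need) < EPS) state = 2;
      else stop("traceback error (M)");
    } else if (state == 1) {
      if (i == 0) stop("traceback error (X at border)");
      pa.push_back(i); pb.push_back(0);
      double cur = Xm[idx(i, j)];
      --i;
      if (std::fabs(M[idx(i, j)] - go - cur) < EPS) state = 0;
      else if (std::fabs(Xm[idx(i, j)] - ge - cur) < EPS) state = 1;
      else if (std::fabs(Ym[idx(i, j)] - go - cur) < EPS) state = 2;
      else stop("traceback error (X)");
    } else {
      if (j == 0) stop("traceback error (Y at border)");
      pa.push_back(0); pb.push_back(j);
      double cur = Ym[idx(i, j)];
      --j;
      if (std::fabs(M[idx(i, j)] - go - cur) < EPS) state = 0;
      else if (std::fabs(Ym[idx(i, j)] - ge - cur) < EPS) state = 2;
      else if (std::fabs(Xm[idx(i, j)] - go - cur) < EPS) state = 1;
      else stop("traceback error (Y)");
    }
    if (i == 0 && j == 0) break;
    if (i == 0 && state != 2) state = 2;
    if (j == 0 && state != 1) state = 1;
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = best,
                      _["a"] = IntegerVector(pa.begin(), pa.end()),
                      _["b"] = IntegerVector(pb.begin(), pb.end()));
}
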