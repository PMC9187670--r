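#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Circular binary segmentation scan statistic
// ---------------------------------------------------------------------------

// Maximal circular two-sample t statistic over all arcs (i, j] of x.
// Arc vs complement; pooled-variance t. Returns t_max and the arc bounds.
static double max_circ_t(const std::vector<double>& x, int& bi, int& bj) {
  const int n = (int)x.size();
  bi = 0; bj = 0;
  if (n < 2) return 0.0;
  std::vector<double> S(n + 1, 0.0), Q(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + x[i];
    Q[i + 1] = Q[i] + x[i] * x[i];
  }
  const double Sn = S[n], Qn = Q[n];
  double tmax = 0.0;
  const int df = n - 2;
  if (df <= 0) return 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      const int k = j - i;
      if (k >= n) continue; // complement must be non-empty
      const double s1 = S[j] - S[i];
      const double q1 = Q[j] - Q[i];
      const double m1 = s1 / k;
      const double m2 = (Sn - s1) / (n - k);
      const double ss = (q1 - k * m1 * m1) + ((Qn - q1) - (n - k) * m2 * m2);
      const double s2 = (ss > 0.0 ? ss : 0.0) / df;
      const double diff = std::fabs(m1 - m2);
      double t;
      const double denom2 = s2 * (1.0 / k + 1.0 / (n - k));
      if (denom2 < 1e-300) {
        t = (diff < 1e-12) ? 0.0 : 1e9;
      } else {
        t = diff / std::sqrt(denom2);
      }
      if (t > tmax) { tmax = t; bi = i; bj = j; }
    }
  }
  return tmax;
}

// Scan a segment for its best circular split and assess it by permutation.
// Permutation loop stops early once significance at level alpha is impossible
// (count of exceedances already >= ceil(alpha * (n_perm + 1))).
// Returns: i, j (0-based; arc is bins i..j-1 when read half-open), t_max,
// n_ge (permutation maxima >= observed), n_perm_done.
// [[Rcpp::export]]
List cbs_split_cpp(NumericVector x, int n_perm, double alpha) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  int bi, bj;
  const double tobs = max_circ_t(v, bi, bj);
  int n_ge = 0, done = 0;
  const int stop_at = (int)std::ceil(alpha * (n_perm + 1));
  if (tobs > 0.0 && n > 3) {
    RNGScope scope;
    std::vector<double> p(v);
    for (int r = 0; r < n_perm; ++r) {
      // Fisher-Yates shuffle driven by R's RNG (seeded from R side)
      for (int k = n - 1; k > 0; --k) {
        int idx = (int)(unif_rand() * (k + 1));
        if (idx > k) idx = k;
        std::swap(p[k], p[idx]);
      }
      int pi, pj;
      const double tp = max_circ_t(p, pi, pj);
      ++done;
      if (tp >= tobs) {
        ++n_ge;
        if (n_ge >= stop_at) break; // cannot reach p < alpha any more
      }
    }
  } else {
    done = 0;
  }
  return List::create(_["i"] = bi, _["j"] = bj, _["t_max"] = tobs,
                      _["n_ge"] = n_ge, _["n_perm_done"] = done);
}

// ---------------------------------------------------------------------------
// Gaussian-emission HMM: EM (Baum-Welch) with shared variance, and Viterbi
// ---------------------------------------------------------------------------

// x: concatenated observations; seq_lens: lengths of independent sequences
// (one per chromosome; no transitions across boundaries).

static void check_seqs(const NumericVector& x, const IntegerVector& seq_lens) {
  int tot = 0;
  for (int s = 0; s < seq_lens.size(); ++s) tot += seq_lens[s];
  if (tot != x.size()) stop("sequence lengths do not sum to data length");
}

// [[Rcpp::export]]
List hmm_em_cpp(NumericVector x, IntegerVector seq_lens, NumericVector means0,
                double var0, double diag0, int max_iter, double tol,
                double var_floor, double diag_prior) {
  check_seqs(x, seq_lens);
  const int n = x.size(), K = means0.size(), S = seq_lens.size();
  std::vector<double> mu(means0.begin(), means0.end());
  double sigma2 = std::max(var0, var_floor);
  std::vector<double> A(K * K), pi0(K, 1.0 / K);
  for (int a = 0; a < K; ++a)
    for (int b = 0; b < K; ++b)
      A[a * K + b] = (a == b) ? diag0 : (1.0 - diag0) / (K - 1);

  std::vector<double> B(n * K);           // emission densities
  std::vector<double> alpha(n * K), beta(n * K), c(n); // scaled FB
  std::vector<double> gamma(n * K);
  double loglik = R_NegInf, loglik_prev = R_NegInf;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // E step ---------------------------------------------------------------
    const double inv2s = 1.0 / (2.0 * sigma2);
    const double norm = 1.0 / std::sqrt(2.0 * M_PI * sigma2);
    for (int t = 0; t < n; ++t)
      for (int k = 0; k < K; ++k) {
        const double d = x[t] - mu[k];
        double e = norm * std::exp(-d * d * inv2s);
        B[t * K + k] = (e < 1e-300) ? 1e-300 : e;
      }
    loglik = 0.0;
    int off = 0;
    for (int s = 0; s < S; ++s) {
      const int L = seq_lens[s];
      // forward
      double cs = 0.0;
      for (int k = 0; k < K; ++k) {
        alpha[(off) * K + k] = pi0[k] * B[(off) * K + k];
        cs += alpha[(off) * K + k];
      }
      c[off] = cs;
      for (int k = 0; k < K; ++k) alpha[(off) * K + k] /= cs;
      for (int t = 1; t < L; ++t) {
        const int at = off + t;
        cs = 0.0;
        for (int k = 0; k < K; ++k) {
          double acc = 0.0;
          for (int a = 0; a < K; ++a) acc += alpha[(at - 1) * K + a] * A[a * K + k];
          alpha[at * K + k] = acc * B[at * K + k];
          cs += alpha[at * K + k];
        }
        c[at] = cs;
        for (int k = 0; k < K; ++k) alpha[at * K + k] /= cs;
      }
      // backward
      for (int k = 0; k < K; ++k) beta[(off + L - 1) * K + k] = 1.0;
      for (int t = L - 2; t >= 0; --t) {
        const int at = off + t;
        for (int a = 0; a < K; ++a) {
          double acc = 0.0;
          for (int k = 0; k < K; ++k)
            acc += A[a * K + k] * B[(at + 1) * K + k] * beta[(at + 1) * K + k];
          beta[at * K + a] = acc / c[at + 1];
        }
      }
      for (int t = 0; t < L; ++t) loglik += std::log(c[off + t]);
      off += L;
    }
    // gamma
    for (int t = 0; t < n; ++t) {
      double gs = 0.0;
      for (int k = 0; k < K; ++k) {
        gamma[t * K + k] = alpha[t * K + k] * beta[t * K + k];
        gs += gamma[t * K + k];
      }
      for (int k = 0; k < K; ++k) gamma[t * K + k] /= gs;
    }
    // M step ---------------------------------------------------------------
    std::vector<double> Anum(K * K, 0.0), Aden(K, 0.0), pinew(K, 0.0);
    off = 0;
    for (int s = 0; s < S; ++s) {
      const int L = seq_lens[s];
      for (int k = 0; k < K; ++k) pinew[k] += gamma[off * K + k];
      for (int t = 0; t < L - 1; ++t) {
        const int at = off + t;
        for (int a = 0; a < K; ++a) {
          const double lhs = alpha[at * K + a];
          for (int b = 0; b < K; ++b) {
            const double xi = lhs * A[a * K + b] * B[(at + 1) * K + b] *
                              beta[(at + 1) * K + b] / c[at + 1];
            Anum[a * K + b] += xi;
          }
        }
      }
      off += L;
    }
    // sticky prior: pseudo-count on self-transitions discourages decoding
    // bin-level noise as state toggles
    for (int a = 0; a < K; ++a) Anum[a * K + a] += diag_prior;
    for (int a = 0; a < K; ++a) {
      double den = 0.0;
      for (int b = 0; b < K; ++b) den += Anum[a * K + b];
      Aden[a] = den;
    }
    for (int a = 0; a < K; ++a)
      for (int b = 0; b < K; ++b)
        A[a * K + b] = (Aden[a] > 0) ? Anum[a * K + b] / Aden[a]
                                     : (a == b ? 1.0 : 0.0);
    double psum = 0.0;
    for (int k = 0; k < K; ++k) psum += pinew[k];
    for (int k = 0; k < K; ++k) pi0[k] = pinew[k] / psum;
    double vnum = 0.0;
    for (int k = 0; k < K; ++k) {
      double gs = 0.0, gx = 0.0;
      for (int t = 0; t < n; ++t) {
        gs += gamma[t * K + k];
        gx += gamma[t * K + k] * x[t];
      }
      if (gs > 0) mu[k] = gx / gs;
    }
    for (int t = 0; t < n; ++t)
      for (int k = 0; k < K; ++k) {
        const double d = x[t] - mu[k];
        vnum += gamma[t * K + k] * d * d;
      }
    sigma2 = std::max(vnum / n, var_floor);

    if (iter > 0 && std::fabs(loglik - loglik_prev) <
        tol * (1.0 + std::fabs(loglik_prev))) {
      converged = true;
      ++iter;
      break;
    }
    loglik_prev = loglik;
  }

  return List::create(_["means"] = NumericVector(mu.begin(), mu.end()),
                      _["variance"] = sigma2,
                      _["trans"] = NumericVector(A.begin(), A.end()),
                      _["init"] = NumericVector(pi0.begin(), pi0.end()),
                      _["loglik"] = loglik, _["n_iter"] = iter,
                      _["converged"] = converged);
}

// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector x, IntegerVector seq_lens,
                              NumericVector means, double variance,
                              NumericVector trans, NumericVector init) {
  check_seqs(x, seq_lens);
  const int n = x.size(), K = means.size(), S = seq_lens.size();
  IntegerVector path(n);
  std::vector<double> logA(K * K), logpi(K);
  for (int i = 0; i < K * K; ++i)
    logA[i] = trans[i] > 0 ? std::log(trans[i]) : -1e300;
  for (int k = 0; k < K; ++k)
    logpi[k] = init[k] > 0 ? std::log(init[k]) : -1e300;
  const double inv2s = 1.0 / (2.0 * variance);
  const double lognorm = -0.5 * std::log(2.0 * M_PI * variance);

  int off = 0;
  for (int s = 0; s < S; ++s) {
    const int L = seq_lens[s];
    std::vector<double> delta(L * K);
    std::vector<int> psi(L * K, 0);
    for (int k = 0; k < K; ++k) {
      const double d = x[off] - means[k];
      delta[k] = logpi[k] + lognorm - d * d * inv2s;
    }
    for (int t = 1; t < L; ++t) {
      for (int k = 0; k < K; ++k) {
        double best = -1e300;
        int barg = 0;
        for (int a = 0; a < K; ++a) {
          const double v = delta[(t - 1) * K + a] + logA[a * K + k];
          if (v > best) { best = v; barg = a; }
        }
        const double d = x[off + t] - means[k];
        delta[t * K + k] = best + lognorm - d * d * inv2s;
        psi[t * K + k] = barg;
      }
    }
    double best = -1e300;
    int cur = 0;
    for (int k = 0; k < K; ++k)
      if (delta[(L - 1) * K + k] > best) { best = delta[(L - 1) * K + k]; cur = k; }
    path[off + L - 1] = cur;
    for (int t = L - 2; t >= 0; --t) {
      cur = psi[(t + 1) * K + cur];
      path[off + t] = cur;
    }
    off += L;
  }
  return path;
}
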