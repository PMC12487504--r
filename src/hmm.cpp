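// Core HMM routines: scaled forward/backward, multi-sequence Baum-Welch EM,
// and Viterbi decoding. Emissions are either Gaussian (one mean/sd per state)
// or categorical over the 11 integer scores -5..+5. Written as plain loops
// over a small state count (K = 3 in practice) for speed: the permutation
// test refits both group models for every label shuffle.
#include <Rcpp.h>
#include <cmath>
#include <cfloat>
#include <vector>

using namespace Rcpp;

static const double INV_SQRT_2PI = 0.3989422804014327;

// emission density of observation x under state k
static inline double emis_dens(double x, int family, int k,
                               const std::vector<double>& mu,
                               const std::vector<double>& sigma,
                               const std::vector<double>& B, int ncat) {
  if (family == 0) {
    double z = (x - mu[k]) / sigma[k];
    return INV_SQRT_2PI / sigma[k] * std::exp(-0.5 * z * z);
  }
  int c = (int)x; // caller maps scores to 0..ncat-1
  return B[k * ncat + c];
}

// scaled forward pass over one sequence; returns log-likelihood and fills
// alpha (T x K, row-normalized) and the scaling factors c (length T).
static double forward_scaled(const double* obs, int T, int K,
                             const std::vector<double>& pi,
                             const std::vector<double>& A,
                             int family,
                             const std::vector<double>& mu,
                             const std::vector<double>& sigma,
                             const std::vector<double>& B, int ncat,
                             std::vector<double>& alpha,
                             std::vector<double>& cvec) {
  double ll = 0.0;
  for (int k = 0; k < K; ++k)
    alpha[k] = pi[k] * emis_dens(obs[0], family, k, mu, sigma, B, ncat);
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) c0 += alpha[k];
  if (c0 <= 0.0 || !std::isfinite(c0)) c0 = DBL_MIN;
  for (int k = 0; k < K; ++k) alpha[k] /= c0;
  cvec[0] = c0;
  ll += std::log(c0);
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha[(t - 1) * K + i] * A[i * K + j];
      double a = s * emis_dens(obs[t], family, j, mu, sigma, B, ncat);
      alpha[t * K + j] = a;
      ct += a;
    }
    if (ct <= 0.0 || !std::isfinite(ct)) ct = DBL_MIN;
    for (int j = 0; j < K; ++j) alpha[t * K + j] /= ct;
    cvec[t] = ct;
    ll += std::log(ct);
  }
  return ll;
}

// [[Rcpp::export(name = ".hmm_loglik_cpp")]]
double hmm_loglik_cpp(NumericVector obs, NumericVector pi, NumericMatrix A,
                      int family, NumericVector mu, NumericVector sigma,
                      NumericMatrix Bmat) {
  int K = pi.size(), T = obs.size();
  int ncat = Bmat.ncol();
  std::vector<double> piv(pi.begin(), pi.end());
  std::vector<double> Av(K * K), Bv(K * ncat);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) Av[i * K + j] = A(i, j);
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < ncat; ++c) Bv[k * ncat + c] = Bmat(k, c);
  std::vector<double> muv(mu.begin(), mu.end());
  std::vector<double> sdv(sigma.begin(), sigma.end());
  std::vector<double> alpha(T * K), cvec(T);
  return forward_scaled(&obs[0], T, K, piv, Av, family, muv, sdv, Bv, ncat,
                        alpha, cvec);
}

// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
List hmm_viterbi_cpp(NumericVector obs, NumericVector pi, NumericMatrix A,
                     int family, NumericVector mu, NumericVector sigma,
                     NumericMatrix Bmat) {
  int K = pi.size(), T = obs.size();
  int ncat = Bmat.ncol();
  std::vector<double> muv(mu.begin(), mu.end());
  std::vector<double> sdv(sigma.begin(), sigma.end());
  std::vector<double> Bv(K * ncat);
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < ncat; ++c) Bv[k * ncat + c] = Bmat(k, c);
  std::vector<double> logd(T * K), logA(K * K), logpi(K);
  for (int k = 0; k < K; ++k)
    logpi[k] = std::log(pi[k]);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) logA[i * K + j] = std::log(A(i, j));
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      logd[t * K + k] =
          std::log(emis_dens(obs[t], family, k, muv, sdv, Bv, ncat));

  std::vector<double> delta(T * K);
  std::vector<int> psi(T * K);
  for (int k = 0; k < K; ++k) delta[k] = logpi[k] + logd[k];
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      // ties broken toward the lower predecessor index (strict >)
      double best = delta[(t - 1) * K] + logA[j];
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        double v = delta[(t - 1) * K + i] + logA[i * K + j];
        if (v > best) { best = v; arg = i; }
      }
      delta[t * K + j] = best + logd[t * K + j];
      psi[t * K + j] = arg;
    }
  }
  double best = delta[(T - 1) * K];
  int arg = 0;
  for (int k = 1; k < K; ++k)
    if (delta[(T - 1) * K + k] > best) { best = delta[(T - 1) * K + k]; arg = k; }
  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi[(t + 1) * K + path[t + 1]];
  return List::create(_["path"] = path, _["log_prob"] = best);
}

// Multi-sequence Baum-Welch. obs holds all sequences concatenated; lengths
// gives the per-sequence lengths. Sufficient statistics are summed across
// sequences, each restarting from pi. Returns final parameters plus the
// per-iteration total log-likelihood trace.
// [[Rcpp::export(name = ".hmm_em_cpp")]]
List hmm_em_cpp(NumericVector obs, IntegerVector lengths, int family,
                NumericVector pi0, NumericMatrix A0, NumericVector mu0,
                NumericVector sigma0, NumericMatrix B0, int max_iter,
                double tol, double var_floor, bool fix_pi) {
  int K = pi0.size();
  int nseq = lengths.size();
  int ncat = B0.ncol();
  std::vector<double> pi(pi0.begin(), pi0.end());
  std::vector<double> A(K * K), B(K * ncat);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A[i * K + j] = A0(i, j);
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < ncat; ++c) B[k * ncat + c] = B0(k, c);
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sigma(sigma0.begin(), sigma0.end());

  int Tmax = 0, Ttot = 0;
  std::vector<int> offset(nseq);
  for (int s = 0; s < nseq; ++s) {
    offset[s] = Ttot;
    Ttot += lengths[s];
    if (lengths[s] > Tmax) Tmax = lengths[s];
  }

  std::vector<double> alpha(Tmax * K), beta(Tmax * K), cvec(Tmax);
  std::vector<double> trace;
  trace.reserve(max_iter);
  bool converged = false;
  double ll_prev = 0.0;
  double sd_floor = std::sqrt(var_floor);

  for (int iter = 0; iter < max_iter; ++iter) {
    double ll = 0.0;
    std::vector<double> pi_acc(K, 0.0), A_num(K * K, 0.0), A_den(K, 0.0);
    std::vector<double> w(K, 0.0), wx(K, 0.0), wxx(K, 0.0);
    std::vector<double> Cnt(K * ncat, 0.0);

    for (int s = 0; s < nseq; ++s) {
      const double* o = &obs[0] + offset[s];
      int T = lengths[s];
      ll += forward_scaled(o, T, K, pi, A, family, mu, sigma, B, ncat, alpha,
                           cvec);
      // scaled backward
      for (int k = 0; k < K; ++k) beta[(T - 1) * K + k] = 1.0;
      for (int t = T - 2; t >= 0; --t) {
        double ct1 = cvec[t + 1];
        for (int i = 0; i < K; ++i) {
          double s2 = 0.0;
          for (int j = 0; j < K; ++j)
            s2 += A[i * K + j] *
                  emis_dens(o[t + 1], family, j, mu, sigma, B, ncat) *
                  beta[(t + 1) * K + j];
          beta[t * K + i] = s2 / ct1;
        }
      }
      // gamma accumulation (gamma_t(k) = alpha_hat * beta_hat, sums to 1)
      for (int t = 0; t < T; ++t) {
        double g[8]; // K <= 8 assumed; K is 3 in practice
        double gs = 0.0;
        for (int k = 0; k < K; ++k) {
          g[k] = alpha[t * K + k] * beta[t * K + k];
          gs += g[k];
        }
        if (gs <= 0.0) gs = 1.0;
        for (int k = 0; k < K; ++k) {
          double gk = g[k] / gs;
          if (t == 0) pi_acc[k] += gk;
          if (t < T - 1) A_den[k] += gk;
          if (family == 0) {
            w[k] += gk;
            wx[k] += gk * o[t];
            wxx[k] += gk * o[t] * o[t];
          } else {
            w[k] += gk;
            Cnt[k * ncat + (int)o[t]] += gk;
          }
        }
      }
      // xi accumulation
      for (int t = 0; t < T - 1; ++t) {
        double ct1 = cvec[t + 1];
        for (int i = 0; i < K; ++i) {
          double ai = alpha[t * K + i];
          for (int j = 0; j < K; ++j) {
            double x = ai * A[i * K + j] *
                       emis_dens(o[t + 1], family, j, mu, sigma, B, ncat) *
                       beta[(t + 1) * K + j] / ct1;
            A_num[i * K + j] += x;
          }
        }
      }
    }

    trace.push_back(ll);
    // M-step
    if (!fix_pi) {
      double ps = 0.0;
      for (int k = 0; k < K; ++k) ps += pi_acc[k];
      if (ps > 0) for (int k = 0; k < K; ++k) pi[k] = pi_acc[k] / ps;
    }
    for (int i = 0; i < K; ++i) {
      if (A_den[i] > 0) {
        double rs = 0.0;
        for (int j = 0; j < K; ++j) rs += A_num[i * K + j];
        if (rs > 0)
          for (int j = 0; j < K; ++j) A[i * K + j] = A_num[i * K + j] / rs;
      }
    }
    if (family == 0) {
      for (int k = 0; k < K; ++k) {
        if (w[k] > 1e-10) {
          double m = wx[k] / w[k];
          double v = wxx[k] / w[k] - m * m;
          if (v < var_floor) v = var_floor;
          mu[k] = m;
          sigma[k] = std::sqrt(v);
          if (sigma[k] < sd_floor) sigma[k] = sd_floor;
        }
      }
    } else {
      for (int k = 0; k < K; ++k) {
        if (w[k] > 1e-10)
          for (int c = 0; c < ncat; ++c) B[k * ncat + c] = Cnt[k * ncat + c] / w[k];
      }
    }

    if (iter > 0) {
      double rel = (ll - ll_prev) / (std::fabs(ll_prev) + DBL_EPSILON);
      if (std::fabs(rel) < tol) { converged = true; ll_prev = ll; break; }
    }
    ll_prev = ll;
  }

  NumericMatrix Aout(K, K), Bout(K, ncat);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) Aout(i, j) = A[i * K + j];
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < ncat; ++c) Bout(k, c) = B[k * ncat + c];
  return List::create(
      _["pi"] = NumericVector(pi.begin(), pi.end()),
      _["A"] = Aout, _["mu"] = NumericVector(mu.begin(), mu.end()),
      _["sigma"] = NumericVector(sigma.begin(), sigma.end()),
      _["B"] = Bout,
      _["log_likelihood_trace"] = NumericVector(trace.begin(), trace.end()),
      _["converged"] = converged, _["n_iter"] = (int)trace.size());
}
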