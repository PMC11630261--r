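#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward for one observation sequence.
// B: T x K matrix of per-position emission likelihoods P(x_t | state k).
// Returns log-likelihood, posterior marginals gamma (T x K) and the matrix of
// expected transition counts xi (K x K) summed over t = 1..T-1.
// Internal buffers are K x T so every per-position vector is contiguous.
// [[Rcpp::export(name = ".cpp_forward_backward")]]
List cpp_forward_backward(NumericMatrix B, NumericVector pi, NumericMatrix A) {
  const int T = B.nrow(), K = B.ncol();
  std::vector<double> At(K * K);        // A transposed: At[j + k*K] = A(j,k) col k contiguous
  std::vector<double> Ar(K * K);        // row-major copy: Ar[k*K + j] = A(k,j)
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) { At[j + k * K] = A(j, k); Ar[j * K + k] = A(j, k); }
  std::vector<double> Bt(K * T);        // Bt[k + t*K] = B(t,k)
  const double* Bp = B.begin();
  for (int k = 0; k < K; ++k)
    for (int t = 0; t < T; ++t) Bt[k + t * K] = Bp[t + k * T];

  std::vector<double> alpha(K * T), beta(K * T), scale(T);

  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha[k] = pi[k] * Bt[k]; s += alpha[k]; }
  if (s <= 0) stop("zero forward probability at position 1");
  scale[0] = s;
  for (int k = 0; k < K; ++k) alpha[k] /= s;

  for (int t = 1; t < T; ++t) {
    double* at = &alpha[t * K];
    const double* ap = &alpha[(t - 1) * K];
    const double* bt = &Bt[t * K];
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      const double* Ak = &At[k * K];
      double acc = 0.0;
      for (int j = 0; j < K; ++j) acc += ap[j] * Ak[j];
      at[k] = acc * bt[k];
      s += at[k];
    }
    if (s <= 0) stop("zero forward probability at position %d", t + 1);
    scale[t] = s;
    const double inv = 1.0 / s;
    for (int k = 0; k < K; ++k) at[k] *= inv;
  }

  for (int k = 0; k < K; ++k) beta[(T - 1) * K + k] = 1.0;
  std::vector<double> bb(K);  // B(t+1,j) * beta(t+1,j), reused for xi
  NumericMatrix xi(K, K);
  double* xip = xi.begin();
  for (int t = T - 2; t >= 0; --t) {
    const double* bnext = &Bt[(t + 1) * K];
    const double* betan = &beta[(t + 1) * K];
    const double inv = 1.0 / scale[t + 1];
    for (int j = 0; j < K; ++j) bb[j] = bnext[j] * betan[j] * inv;
    double* bt_ = &beta[t * K];
    for (int k = 0; k < K; ++k) {
      const double* Ak = &Ar[k * K];  // row k of A, contiguous
      double acc = 0.0;
      for (int j = 0; j < K; ++j) acc += Ak[j] * bb[j];
      bt_[k] = acc;
    }
    // xi(j,k) += alpha(t,j) * A(j,k) * bb[k]
    const double* at = &alpha[t * K];
    for (int k = 0; k < K; ++k) {
      const double* Ak = &At[k * K];
      const double bbk = bb[k];
      double* xcol = xip + k * K;
      for (int j = 0; j < K; ++j) xcol[j] += at[j] * Ak[j] * bbk;
    }
  }

  NumericMatrix gamma(T, K);
  double* gp = gamma.begin();
  for (int t = 0; t < T; ++t) {
    const double* at = &alpha[t * K];
    const double* bt_ = &beta[t * K];
    double g = 0.0;
    for (int k = 0; k < K; ++k) g += at[k] * bt_[k];
    const double inv = 1.0 / g;
    for (int k = 0; k < K; ++k) gp[t + k * T] = at[k] * bt_[k] * inv;
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(scale[t]);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding in log space. logB: T x K log emission likelihoods.
// [[Rcpp::export(name = ".cpp_viterbi")]]
IntegerVector cpp_viterbi(NumericMatrix logB, NumericVector logpi, NumericMatrix logA) {
  const int T = logB.nrow(), K = logB.ncol();
  std::vector<double> lAt(K * K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) lAt[j + k * K] = logA(j, k);
  const double* lBp = logB.begin();
  std::vector<double> prev(K), cur(K);
  std::vector<int> psi(static_cast<size_t>(T) * K);
  for (int k = 0; k < K; ++k) prev[k] = logpi[k] + lBp[0 + k * T];
  for (int t = 1; t < T; ++t) {
    int* pst = &psi[static_cast<size_t>(t) * K];
    for (int k = 0; k < K; ++k) {
      const double* Ak = &lAt[k * K];
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        const double v = prev[j] + Ak[j];
        if (v > best) { best = v; arg = j; }
      }
      cur[k] = best + lBp[t + k * T];
      pst[k] = arg;
    }
    std::swap(prev, cur);
  }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k) if (prev[k] > best) { best = prev[k]; arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi[static_cast<size_t>(t + 1) * K + arg];
    path[t] = arg + 1;
  }
  return path;
}
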