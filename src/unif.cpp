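#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Truncation point for the uniformization series at Poisson mean lt.
static int series_K(double lt) {
  int K = (int)std::ceil(lt + 8.0 * std::sqrt(lt + 1.0) + 14.0);
  if (K < 10) K = 10;
  if (K > 100000) K = 100000;
  return K;
}

// Poisson weights dpois(0:K, lt) with the truncated tail folded into the
// last term.
static void pois_weights(double lt, int K, std::vector<double> &w) {
  w.resize(K + 1);
  w[0] = std::exp(-lt);
  double sum = w[0];
  for (int k = 1; k <= K; ++k) {
    w[k] = w[k - 1] * lt / k;
    if (k < K) sum += w[k];
  }
  w[K] = std::max(0.0, 1.0 - sum);
}

// exp(Q t) for each of C stacked ns x ns rate matrices (column-major), by
// uniformization: P = sum_k Pois(k; Lambda t) (I + Q/Lambda)^k.
// [[Rcpp::export(name = ".unif_P_many_cpp")]]
NumericVector unif_P_many(NumericVector Qarr, int ns, double t) {
  const int nn = ns * ns;
  const int C = Qarr.size() / nn;
  NumericVector out(Qarr.size());
  std::vector<double> A(nn), M(nn), Mn(nn), P(nn), w;
  for (int c = 0; c < C; ++c) {
    const double *Q = &Qarr[c * nn];
    double lambda = 1e-12;
    for (int i = 0; i < ns; ++i) lambda = std::max(lambda, -Q[i + i * ns]);
    double lt = lambda * t;
    int K = series_K(lt);
    pois_weights(lt, K, w);
    for (int j = 0; j < nn; ++j) A[j] = Q[j] / lambda;
    for (int i = 0; i < ns; ++i) A[i + i * ns] += 1.0;
    std::fill(P.begin(), P.end(), 0.0);
    std::fill(M.begin(), M.end(), 0.0);
    for (int i = 0; i < ns; ++i) { P[i + i * ns] = w[0]; M[i + i * ns] = 1.0; }
    for (int k = 1; k <= K; ++k) {
      for (int j = 0; j < ns; ++j)
        for (int i = 0; i < ns; ++i) {
          double s = 0.0;
          for (int l = 0; l < ns; ++l) s += M[i + l * ns] * A[l + j * ns];
          Mn[i + j * ns] = s;
        }
      std::swap(M, Mn);
      const double wk = w[k];
      for (int j = 0; j < nn; ++j) P[j] += wk * M[j];
    }
    std::copy(P.begin(), P.end(), &out[c * nn]);
  }
  return out;
}

// exp(Q t_j) v for one rate matrix and many times, by uniformization with
// a shared rate; returns an ns x J matrix.
// [[Rcpp::export(name = ".expm_action_cpp")]]
NumericMatrix expm_action(NumericMatrix Q, NumericVector v, NumericVector tvec) {
  const int ns = Q.nrow();
  const int J = tvec.size();
  double lambda = 1e-12;
  for (int i = 0; i < ns; ++i) lambda = std::max(lambda, -Q(i, i));
  double maxt = 0.0;
  for (int j = 0; j < J; ++j) maxt = std::max(maxt, tvec[j]);
  int K = series_K(lambda * maxt);
  // M[, k] = (I + Q/Lambda)^k v
  std::vector<double> M((K + 1) * ns);
  for (int i = 0; i < ns; ++i) M[i] = v[i];
  for (int k = 1; k <= K; ++k) {
    const double *prev = &M[(k - 1) * ns];
    double *cur = &M[k * ns];
    for (int i = 0; i < ns; ++i) {
      double s = prev[i];
      for (int l = 0; l < ns; ++l) s += Q(i, l) / lambda * prev[l];
      cur[i] = s;
    }
  }
  NumericMatrix W(ns, J);
  std::vector<double> w;
  for (int j = 0; j < J; ++j) {
    pois_weights(lambda * tvec[j], K, w);
    for (int i = 0; i < ns; ++i) {
      double s = 0.0;
      for (int k = 0; k <= K; ++k) s += w[k] * M[k * ns + i];
      W(i, j) = s;
    }
  }
  return W;
}
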