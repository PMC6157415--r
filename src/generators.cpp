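#include <Rcpp.h>
using namespace Rcpp;

// Sequential samplers for the three generative models. Types are labelled by
// integer creation order (1, 2, ...); the seed element occupies position 1.
// At the step that emits token n+1 the history holds n tokens, so per-step
// probabilities sum to one exactly:
//   Simon:      alpha (new)            + sum_i (1-alpha) S_i / n
//   Pitman-Yor: (a K + b)/(n + b)      + sum_i (S_i - a)/(n + b)
//   conjunct:   eta = (a K + b)/(n+b)  + sum_i (1-eta) S_i / n
// All draws go through R's RNG so set.seed() makes runs reproducible.

// [[Rcpp::export(name = ".simon_generate_cpp")]]
IntegerVector simon_generate_cpp(double alpha, int M) {
  IntegerVector x(M);
  x[0] = 1;
  int K = 1;
  for (int n = 1; n < M; ++n) {
    if (unif_rand() < alpha) {
      x[n] = ++K;
    } else {
      int j = (int)(unif_rand() * n); // uniform position in history
      if (j >= n) j = n - 1;          // guard against unif_rand() == 1
      x[n] = x[j];
    }
  }
  return x;
}

// [[Rcpp::export(name = ".pitman_yor_generate_cpp")]]
IntegerVector py_generate_cpp(double a, double b, int M) {
  IntegerVector x(M);
  std::vector<int> S;
  S.reserve(1024);
  x[0] = 1;
  S.push_back(1);
  int K = 1;
  for (int n = 1; n < M; ++n) {
    double pnew = (a * K + b) / (n + b);
    if (unif_rand() < pnew) {
      x[n] = ++K;
      S.push_back(1);
    } else {
      // Reuse type i with probability (S_i - a) / (n - a K) given reuse.
      // Propose i from a uniform history position (prob S_i / n) and accept
      // with probability (S_i - a) / S_i; the realized law is exact.
      int i;
      for (;;) {
        int j = (int)(unif_rand() * n);
        if (j >= n) j = n - 1;
        i = x[j];
        double Si = S[i - 1];
        if (unif_rand() * Si < Si - a) break;
      }
      x[n] = i;
      S[i - 1] += 1;
    }
  }
  return x;
}

// [[Rcpp::export(name = ".conjunct_generate_cpp")]]
IntegerVector conjunct_generate_cpp(double a, double b, int M) {
  IntegerVector x(M);
  x[0] = 1;
  int K = 1;
  for (int n = 1; n < M; ++n) {
    double eta = (a * K + b) / (n + b);
    if (eta > 1.0) eta = 1.0; // unreachable for a < 1, kept as a guard
    if (unif_rand() < eta) {
      x[n] = ++K;
    } else {
      int j = (int)(unif_rand() * n);
      if (j >= n) j = n - 1;
      x[n] = x[j];
    }
  }
  return x;
}

// One Pitman-Yor step from an explicit count vector, for distributional
// checks: returns 0 for "new type", otherwise the reused type index.
// [[Rcpp::export(name = ".pitman_yor_step_cpp")]]
int py_step_cpp(IntegerVector S, double a, double b) {
  int K = S.size();
  double t = 0;
  for (int i = 0; i < K; ++i) t += S[i];
  double pnew = (a * K + b) / (t + b);
  if (unif_rand() < pnew) return 0;
  for (;;) {
    double v = unif_rand() * t, acc = 0;
    int i = K - 1;
    for (int k = 0; k < K; ++k) {
      acc += S[k];
      if (v < acc) { i = k; break; }
    }
    double Si = S[i];
    if (unif_rand() * Si < Si - a) return i + 1;
  }
}
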