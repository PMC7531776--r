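#include <Rcpp.h>
using namespace Rcpp;

// Forward value pass of the single-option RL models.
//
// The choice probability on trial t uses the value held *before* the trial's
// (choice, reward) outcome is observed; the outcome then updates the value
// carried into trial t+1.  Chosen branch: Q += alpha * (R - Q); unchosen
// branch: Q -= phi * Q (phi = 0 for RW, alpha for FQ, alpha_F for FQaF).
// Probabilities are clamped to [1e-12, 1 - 1e-12] before taking logs.
// [[Rcpp::export]]
List cpp_rl_forward(double alpha, double beta, double bias, double phi,
                    double q0, IntegerVector rewards, IntegerVector choices) {
  int n = rewards.size();
  NumericVector Q(n), P(n);
  double q = q0;
  double ll = 0.0;
  const double eps = 1e-12;
  for (int t = 0; t < n; ++t) {
    Q[t] = q;
    double p = 1.0 / (1.0 + std::exp(beta * (bias - q)));
    if (p < eps) p = eps;
    if (p > 1.0 - eps) p = 1.0 - eps;
    P[t] = p;
    int c = choices[t];
    ll += (c == 1) ? std::log(p) : std::log(1.0 - p);
    if (c == 1) {
      q += alpha * (static_cast<double>(rewards[t]) - q);
    } else {
      q -= phi * q;
    }
  }
  return List::create(_["Q"] = Q, _["P"] = P, _["logL_mean"] = ll / n);
}

// Negative mean log-likelihood only (hot path of the multistart fitter).
// [[Rcpp::export]]
double cpp_rl_negll(double alpha, double beta, double bias, double phi,
                    double q0, IntegerVector rewards, IntegerVector choices) {
  int n = rewards.size();
  double q = q0;
  double ll = 0.0;
  const double eps = 1e-12;
  for (int t = 0; t < n; ++t) {
    double p = 1.0 / (1.0 + std::exp(beta * (bias - q)));
    if (p < eps) p = eps;
    if (p > 1.0 - eps) p = 1.0 - eps;
    ll += (choices[t] == 1) ? std::log(p) : std::log(1.0 - p);
    if (choices[t] == 1) {
      q += alpha * (static_cast<double>(rewards[t]) - q);
    } else {
      q -= phi * q;
    }
  }
  return -ll / n;
}

// Simulate one agent sequence.  Uniform variates are supplied from R so the
// caller controls the RNG stream (seed determinism lives in R code).
// [[Rcpp::export]]
List cpp_rl_simulate(double alpha, double beta, double bias, double phi,
                     double q0, double p_reward, int n,
                     NumericVector u_reward, NumericVector u_choice) {
  IntegerVector R(n), C(n);
  NumericVector Q(n), P(n);
  double q = q0;
  for (int t = 0; t < n; ++t) {
    Q[t] = q;
    double p = 1.0 / (1.0 + std::exp(beta * (bias - q)));
    P[t] = p;
    int r = (u_reward[t] < p_reward) ? 1 : 0;
    int c = (u_choice[t] < p) ? 1 : 0;
    R[t] = r;
    C[t] = c;
    if (c == 1) {
      q += alpha * (static_cast<double>(r) - q);
    } else {
      q -= phi * q;
    }
  }
  return List::create(_["rewards"] = R, _["choices"] = C,
                      _["Q"] = Q, _["P"] = P);
}

// Direct-form II transposed IIR filter with explicit initial state zi
// (length max(length(a), length(b)) - 1).  a[0] must be 1.
// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size();
  int m = std::max(nb, na) - 1;
  std::vector<double> bb(m + 1, 0.0), aa(m + 1, 0.0), z(m + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  for (int i = 0; i < m; ++i) z[i] = zi[i];
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < m - 1; ++j) {
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    }
    if (m > 0) z[m - 1] = bb[m] * xi - aa[m] * yi;
    y[i] = yi;
  }
  return y;
}
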