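#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Numerically stable inverse logit.
static inline double invlogit(double x) {
  if (x >= 0.0) {
    return 1.0 / (1.0 + std::exp(-x));
  }
  double ex = std::exp(x);
  return ex / (1.0 + ex);
}

// Poisson-binomial pmf f[0..n] for success probabilities e[0..n-1],
// optionally skipping index `skip` (pass -1 to use all).
static void pb_pmf(const double* e, int n, int skip, std::vector<double>& f) {
  int m = 0;
  f[0] = 1.0;
  for (int j = 0; j < n; ++j) {
    if (j == skip) continue;
    double ej = e[j];
    f[m + 1] = f[m] * ej;
    for (int t = m; t >= 1; --t) f[t] = f[t] * (1.0 - ej) + f[t - 1] * ej;
    f[0] *= (1.0 - ej);
    ++m;
  }
}

// Log-likelihood (and optionally its gradient) of an EU model.
//
// U: n_cycles x p_u design matrix of the uterus sub-model (intercept included).
// E: n_embryos x p_e design matrix of the embryo sub-model, rows grouped by
//    cycle in the same order as the rows of U.
// estart: 0-based index of the first embryo row of each cycle.
// ntrans: embryos transferred per cycle; kobs: observed implantation count.
//
// The cycle probability is P = (1-u)*I(k==0) + u * S_k where S_k is the
// Poisson-binomial pmf of the embryo viabilities. Cycles whose probability
// underflows to zero are floored at DBL_MIN and reported in `bad`.
// [[Rcpp::export]]
List eu_loglik_cpp(NumericVector beta_u, NumericVector beta_e,
                   NumericMatrix U, NumericMatrix E,
                   IntegerVector estart, IntegerVector ntrans,
                   IntegerVector kobs, bool want_grad) {
  int nc = U.nrow(), pu = U.ncol(), pe = E.ncol();
  double logL = 0.0;
  std::vector<int> bad;
  NumericVector gu(pu), ge(pe);
  std::vector<double> evec, f, fno;

  for (int i = 0; i < nc; ++i) {
    int n = ntrans[i], k = kobs[i], s0 = estart[i];
    double eta_u = 0.0;
    for (int c = 0; c < pu; ++c) eta_u += U(i, c) * beta_u[c];
    double u = invlogit(eta_u);

    evec.resize(n);
    for (int j = 0; j < n; ++j) {
      double eta_e = 0.0;
      for (int c = 0; c < pe; ++c) eta_e += E(s0 + j, c) * beta_e[c];
      evec[j] = invlogit(eta_e);
    }

    f.assign(n + 1, 0.0);
    pb_pmf(evec.data(), n, -1, f);
    double Sk = f[k];
    double P = u * Sk + (k == 0 ? (1.0 - u) : 0.0);
    bool flo = false;
    if (P < DBL_MIN) { P = DBL_MIN; flo = true; bad.push_back(i + 1); }
    logL += std::log(P);

    if (want_grad && !flo) {
      // d log P / d eta_u
      double dPdu = Sk - (k == 0 ? 1.0 : 0.0);
      double wu = dPdu * u * (1.0 - u) / P;
      for (int c = 0; c < pu; ++c) gu[c] += wu * U(i, c);
      // d log P / d eta_{e,j}: S_k = e_j S^{(-j)}_{k-1} + (1-e_j) S^{(-j)}_k
      fno.assign(n + 1, 0.0);
      for (int j = 0; j < n; ++j) {
        pb_pmf(evec.data(), n, j, fno);
        double d = (k >= 1 ? fno[k - 1] : 0.0) - (k <= n - 1 ? fno[k] : 0.0);
        double we = u * d * evec[j] * (1.0 - evec[j]) / P;
        for (int c = 0; c < pe; ++c) ge[c] += we * E(s0 + j, c);
      }
    }
  }

  List out = List::create(_["logL"] = logL,
                          _["bad_cycles"] = wrap(bad));
  if (want_grad) {
    out["grad_u"] = gu;
    out["grad_e"] = ge;
  }
  return out;
}

// Per-cycle probabilities P_{i,k_i} under the model (diagnostic helper).
// [[Rcpp::export]]
NumericVector eu_cycle_prob_cpp(NumericVector beta_u, NumericVector beta_e,
                                NumericMatrix U, NumericMatrix E,
                                IntegerVector estart, IntegerVector ntrans,
                                IntegerVector kobs) {
  int nc = U.nrow(), pu = U.ncol(), pe = E.ncol();
  NumericVector out(nc);
  std::vector<double> evec, f;
  for (int i = 0; i < nc; ++i) {
    int n = ntrans[i], k = kobs[i], s0 = estart[i];
    double eta_u = 0.0;
    for (int c = 0; c < pu; ++c) eta_u += U(i, c) * beta_u[c];
    double u = invlogit(eta_u);
    evec.resize(n);
    for (int j = 0; j < n; ++j) {
      double eta_e = 0.0;
      for (int c = 0; c < pe; ++c) eta_e += E(s0 + j, c) * beta_e[c];
      evec[j] = invlogit(eta_e);
    }
    f.assign(n + 1, 0.0);
    pb_pmf(evec.data(), n, -1, f);
    out[i] = u * f[k] + (k == 0 ? (1.0 - u) : 0.0);
  }
  return out;
}
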