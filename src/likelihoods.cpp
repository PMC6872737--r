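// Fast trial-wise choice probabilities for the four PGG choice models.
// Mirrors the reference implementations in R/predict.R exactly; the test
// suite asserts equality between the two paths on random sessions.
#include <Rcpp.h>
using namespace Rcpp;

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// probability that i of the N-1 others free-ride given belief g
static inline double belief_pmf_c(int i, int N, double g) {
  return R::dbinom(i, N - 1, g, 0);
}

// probability of success given own contribution: at most N-k others free-ride
static inline double succ_prob_c(int k, int N, double g) {
  return R::pbinom(N - k, N - 1, g, 1, 0);
}

// model codes: 1 = sl, 2 = myopic, 3 = gu, 4 = ia
// linear_rate: 0 = logistic learning-rate link, 1 = clipped linear
// [[Rcpp::export(name = ".model_probs_cpp")]]
NumericVector model_probs_cpp(int model, NumericVector par,
                              IntegerVector decision, IntegerVector n_free,
                              NumericVector reward, IntegerVector round,
                              IntegerVector k, int N, int T, double R,
                              double gamma1, double p_c1, int order,
                              int linear_rate) {
  int n = decision.size();
  NumericVector p(n);

  double omega = 0, pi = 0, lambda = 0, alpha = 0, theta = 0;
  double chi = 0, zeta = 0, delta = 0, eps = 0, kappa = 0;
  if (model == 1 || model == 2) {
    omega = par[0]; pi = par[1]; lambda = par[2]; alpha = par[3]; theta = par[4];
  } else if (model == 3) {
    chi = par[0]; zeta = par[1]; alpha = par[2]; theta = par[3];
  } else if (model == 4) {
    delta = par[0]; eps = par[1]; kappa = par[2];
  } else {
    stop("unknown model code");
  }

  double gamma = gamma1, acc = 0.0;
  for (int t = 0; t < n; ++t) {
    if (round[t] == 1) {            // block boundary: new partners
      gamma = gamma1;
      acc = 0.0;
    } else {
      if (model == 4) {
        double cbar = (double)(N - 1 - n_free[t - 1]) / (N - 1);
        acc += eps * reward[t - 1] - delta * (decision[t - 1] - cbar);
      } else {
        double pe_s = (double)n_free[t - 1] / (N - 1) - gamma;
        double pe_r = std::fabs(R * succ_prob_c(k[t - 1], N, gamma) - reward[t - 1]);
        double rate = linear_rate
          ? std::min(std::max(alpha + theta * pe_r, 0.0), 1.0)
          : logistic(alpha + theta * pe_r);
        gamma += rate * pe_s;
      }
    }

    if (model == 4) {
      p[t] = (round[t] == 1) ? p_c1 : p_c1 * logistic(kappa * acc);
      continue;
    }

    double belief = gamma;
    if (order >= 2) belief = belief_pmf_c(N - k[t], N, belief);
    if (order >= 3) belief = belief_pmf_c(N - k[t], N, belief);

    double Q;
    if (model == 3) {
      double sp = succ_prob_c(k[t], N, belief);
      double K = (double)k[t] / N;
      double mult = (K == 1.0) ? (double)(T - round[t] + 1)
                               : (1.0 - std::pow(K, T - round[t] + 1)) / (1.0 - K);
      Q = zeta + chi * mult * R * sp;
    } else {
      double gpiv = belief_pmf_c(N - k[t], N, belief);
      double I = lambda + gpiv * R + pi * gpiv * R * (N - 1);
      if (model == 2) {
        Q = omega * I;
      } else {
        double sp = succ_prob_c(k[t], N, belief);
        double K = (double)k[t] / N;
        double mult = (K == 1.0) ? (double)(T - round[t] + 1)
                                 : (1.0 - std::pow(K, T - round[t] + 1)) / (1.0 - K);
        double G = mult * R * sp;
        Q = omega * I + (1.0 - omega) * G;
      }
    }
    p[t] = logistic(Q);
  }
  return p;
}

// negative Bernoulli log-likelihood of the observed decisions under the
// model's per-trial probabilities, clamped at `clamp`
// [[Rcpp::export(name = ".model_nll_cpp")]]
double model_nll_cpp(int model, NumericVector par, IntegerVector decision,
                     IntegerVector n_free, NumericVector reward,
                     IntegerVector round, IntegerVector k, int N, int T,
                     double R, double gamma1, double p_c1, int order,
                     int linear_rate, double clamp) {
  NumericVector p = model_probs_cpp(model, par, decision, n_free, reward,
                                    round, k, N, T, R, gamma1, p_c1, order,
                                    linear_rate);
  double nll = 0.0;
  for (int t = 0; t < p.size(); ++t) {
    double pt = std::min(std::max(p[t], clamp), 1.0 - clamp);
    nll -= decision[t] ? std::log(pt) : std::log1p(-pt);
  }
  return nll;
}
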