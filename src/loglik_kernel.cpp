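#include <Rcpp.h>
using namespace Rcpp;

// Observation-level binomial-probit log-likelihood and its partials,
// accumulated per (drug, animal) cell. Scores s (successes) and f
// (failures) out of n_stim stimuli; latent concentration 100 - (1 - adr*v) t;
// eta = (mu_cell - conc) / sigma_cell; p = Phi(eta).
// Returns ll (without binomial coefficients), per-cell d(ll)/d(mu) and
// d(ll)/d(log sigma), and the raw adrenaline partial (before the logit
// chain rule).

// [[Rcpp::export(name = ".score_ll_grad")]]
List score_ll_grad(NumericVector s, NumericVector f, NumericVector t,
                   NumericVector v, IntegerVector k,
                   NumericVector mu_c, NumericVector sig_c,
                   double adr, int K) {
  const int n = s.size();
  double ll = 0.0, g_adr = 0.0;
  NumericVector A_mu(K), A_ls(K);
  for (int o = 0; o < n; ++o) {
    const int kc = k[o] - 1;
    const double sig = sig_c[kc];
    const double conc = 100.0 - (1.0 - adr * v[o]) * t[o];
    const double eta = (mu_c[kc] - conc) / sig;
    const double phi = R::dnorm(eta, 0.0, 1.0, 1);
    double g_eta = 0.0;
    // saturated scores need only one tail of the probit
    if (s[o] > 0.0) {
      const double lp1 = R::pnorm(eta, 0.0, 1.0, 1, 1);
      ll += s[o] * lp1;
      g_eta += s[o] * std::exp(phi - lp1);
    }
    if (f[o] > 0.0) {
      const double lp0 = R::pnorm(-eta, 0.0, 1.0, 1, 1);
      ll += f[o] * lp0;
      g_eta -= f[o] * std::exp(phi - lp0);
    }
    const double gmu = g_eta / sig;
    A_mu[kc] += gmu;
    A_ls[kc] -= g_eta * eta;
    g_adr -= gmu * v[o] * t[o];
  }
  return List::create(_["ll"] = ll, _["A_mu"] = A_mu, _["A_ls"] = A_ls,
                      _["g_adr_raw"] = g_adr);
}

// Pointwise log-likelihood for one draw: returns the per-observation
// binomial log-pmf without the binomial coefficient.

// [[Rcpp::export(name = ".score_ll_pointwise")]]
NumericVector score_ll_pointwise(NumericVector s, NumericVector f,
                                 NumericVector t, NumericVector v,
                                 IntegerVector k, NumericVector mu_c,
                                 NumericVector sig_c, double adr) {
  const int n = s.size();
  NumericVector out(n);
  for (int o = 0; o < n; ++o) {
    const int kc = k[o] - 1;
    const double conc = 100.0 - (1.0 - adr * v[o]) * t[o];
    const double eta = (mu_c[kc] - conc) / sig_c[kc];
    out[o] = s[o] * R::pnorm(eta, 0.0, 1.0, 1, 1) +
             f[o] * R::pnorm(-eta, 0.0, 1.0, 1, 1);
  }
  return out;
}
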