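#include <Rcpp.h>
using namespace Rcpp;

// Three-level binary-outcome HGF, multi-arm bandit configuration.
//
// Level 1: win/loss perception for the chosen deck.
// Level 2: one logit-scale stimulus-outcome tendency per deck; only the
//          chosen deck's belief is updated, the others receive the
//          autoregressive prediction step (mean-reverting drift plus
//          variance inflation) only.
// Level 3: a single log-volatility state shared by all decks, updated
//          from the chosen deck's volatility prediction error.
//
// The response model is a softmax over the decks' predicted win
// probabilities with inverse temperature beta_t = beta0 * exp(-mu3hat_t)
// (or beta0 * exp(-mu3_0) when trialwise coupling is off).
//
// Ill-posed updates (non-positive predicted variance or posterior
// precision) abort with the 1-based trial index.

// [[Rcpp::export]]
List hgf_forward_cpp(NumericVector mu2_0, double sigma2_0,
                     double mu3_0, double sigma3_0,
                     double omega2, double kappa, double omega3,
                     double phi2, double phi3, double m2, double m3,
                     double beta0, int trialwise_beta,
                     IntegerVector choices, IntegerVector outcomes) {
  const int n = choices.size();
  const int J = mu2_0.size();
  NumericMatrix mu2hat(n, J), sigma2hat(n, J), mu2(n, J), sigma2(n, J),
    mu1hat(n, J), prob(n, J);
  NumericVector mu3(n), sigma3(n), mu3hat_out(n), da1(n), da2(n);

  std::vector<double> m2v(mu2_0.begin(), mu2_0.end());
  std::vector<double> s2v(J, sigma2_0);
  double m3v = mu3_0, s3v = sigma3_0;
  double ll = 0.0;
  int bad_trial = 0;

  std::vector<double> m2h(J), s2h(J), m1h(J), ex(J);

  for (int t = 0; t < n; ++t) {
    // ---- prediction step ----
    const double mu3hat = m3v + phi3 * (m3 - m3v);
    const double sigma3hat = s3v + std::exp(omega3);
    const double v2 = std::exp(kappa * mu3hat + omega2);
    const double beta = beta0 * std::exp(-(trialwise_beta ? mu3hat : mu3_0));

    double vmax = R_NegInf;
    for (int j = 0; j < J; ++j) {
      m2h[j] = m2v[j] + phi2 * (m2 - m2v[j]);
      s2h[j] = s2v[j] + v2;
      m1h[j] = 1.0 / (1.0 + std::exp(-m2h[j]));
      const double v = beta * m1h[j];
      if (v > vmax) vmax = v;
    }
    double denom = 0.0;
    for (int j = 0; j < J; ++j) {
      ex[j] = std::exp(beta * m1h[j] - vmax);
      denom += ex[j];
    }
    for (int j = 0; j < J; ++j) {
      mu2hat(t, j) = m2h[j];
      sigma2hat(t, j) = s2h[j];
      mu1hat(t, j) = m1h[j];
      prob(t, j) = ex[j] / denom;
    }
    mu3hat_out[t] = mu3hat;

    const int c = choices[t] - 1;
    if (c < 0 || c >= J) stop("Choice out of range at trial %d.", t + 1);
    ll += std::log(prob(t, c));

    // ---- update step (chosen deck) ----
    if (!(s2h[c] > 0.0) || !(sigma3hat > 0.0)) { bad_trial = t + 1; break; }
    const double u = outcomes[t];
    const double d1 = u - m1h[c];
    const double pihat2 = 1.0 / s2h[c];
    const double pi2 = pihat2 + m1h[c] * (1.0 - m1h[c]);
    if (!(pi2 > 0.0)) { bad_trial = t + 1; break; }
    const double mu2new = m2h[c] + d1 / pi2;

    // ---- volatility update ----
    const double w2 = v2 * pihat2;
    const double d2 =
      (1.0 / pi2 + (mu2new - m2h[c]) * (mu2new - m2h[c])) * pihat2 - 1.0;
    const double pihat3 = 1.0 / sigma3hat;
    const double pi3 =
      pihat3 + 0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * d2);
    if (!(pi3 > 0.0)) { bad_trial = t + 1; break; }
    const double mu3new = mu3hat + 0.5 * kappa * (w2 / pi3) * d2;

    // ---- commit: unchosen decks keep the prediction (drift) only ----
    for (int j = 0; j < J; ++j) { m2v[j] = m2h[j]; s2v[j] = s2h[j]; }
    m2v[c] = mu2new;
    s2v[c] = 1.0 / pi2;
    m3v = mu3new;
    s3v = 1.0 / pi3;

    for (int j = 0; j < J; ++j) { mu2(t, j) = m2v[j]; sigma2(t, j) = s2v[j]; }
    mu3[t] = m3v;
    sigma3[t] = s3v;
    da1[t] = d1;
    da2[t] = d2;
  }

  return List::create(
    _["mu2hat"] = mu2hat, _["sigma2hat"] = sigma2hat,
    _["mu2"] = mu2, _["sigma2"] = sigma2,
    _["mu1hat"] = mu1hat, _["choice_prob"] = prob,
    _["mu3hat"] = mu3hat_out, _["mu3"] = mu3, _["sigma3"] = sigma3,
    _["da1"] = da1, _["da2"] = da2,
    _["loglik"] = ll, _["bad_trial"] = bad_trial);
}
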