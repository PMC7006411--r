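// Adaptive Metropolis-within-Gibbs sampler for the hierarchical Bayesian
// GLMs: negative binomial (log link) or binomial (logit link) fixed effects,
// clinical-site random intercepts, and a fixed log-exposure offset.
//
//   family 0 (relapse): y_i ~ NB(mean = exp(eta_i), shape = phi)
//   family 1 (cdp):     y_i ~ Bernoulli(plogis(eta_i))
//   eta_i = x_i' beta + u_{site(i)} + offset_i
//   beta_j ~ N(0, prior_sd_j), u_s | sigma ~ N(0, sigma^2)
//   sigma ~ Gamma(shape, rate), phi ~ Half-Cauchy(0, scale)
//
// The fixed effects are updated componentwise in a likelihood-whitened basis:
// the caller passes Z (the design rotated so its columns are orthogonal, with
// Z[,0] = 1) and the map T with beta = T gamma. Componentwise Gaussian
// random walks on gamma with Robbins-Monro scale adaptation during warmup
// (target acceptance 0.44) then mix essentially independently, whatever the
// collinearity of the raw design. A joint "recentering" move shifts mass
// between the intercept and the random intercepts (eta-invariant, prior-only
// Metropolis ratio). Uses R's RNG, so chains are reproducible via set.seed()
// from the caller.

#include <Rcpp.h>
using namespace Rcpp;

static inline double log1p_exp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// eta-dependent part of the log-likelihood for one observation
static inline double ll_eta(double y, double eta, double phi, int family) {
  if (family == 1) {
    return y * eta - log1p_exp(eta);
  }
  // NB: y*eta - (y+phi)*log(phi + exp(eta)), in logsumexp form
  double lphi = std::log(phi);
  return y * eta - (y + phi) * (lphi + log1p_exp(eta - lphi));
}

static double ll_eta_sum(const NumericVector& y, const NumericVector& eta,
                         double phi, int family) {
  double s = 0.0;
  for (int i = 0; i < y.size(); ++i) s += ll_eta(y[i], eta[i], phi, family);
  return s;
}

// phi-only part of the NB log-likelihood (terms free of eta)
static double ll_phi_part(const NumericVector& y, double phi) {
  double s = 0.0;
  for (int i = 0; i < y.size(); ++i) s += R::lgammafn(y[i] + phi);
  int n = y.size();
  return s - n * R::lgammafn(phi) + n * phi * std::log(phi);
}

struct Adapt {
  std::vector<double> lsc;    // log proposal sd
  std::vector<int> acc, att;
  int batch;
  Adapt(int k, double init) : lsc(k, std::log(init)), acc(k, 0), att(k, 0),
                              batch(1) {}
  double sd(int j) const { return std::exp(lsc[j]); }
  void note(int j, bool accepted) { att[j]++; if (accepted) acc[j]++; }
  void maybe_adapt() {
    double step = 1.0 / std::sqrt((double)batch);
    for (size_t j = 0; j < lsc.size(); ++j) {
      if (att[j] >= 50) {
        double rate = (double)acc[j] / att[j];
        lsc[j] += (rate - 0.44) * step;
        acc[j] = 0; att[j] = 0;
      }
    }
    batch++;
  }
};

// [[Rcpp::export(name = ".mcmc_chain")]]
List mcmc_chain(NumericVector y, NumericMatrix Z, NumericMatrix T,
                NumericVector offset, IntegerVector site, int n_sites,
                int family, NumericVector prior_sd,
                double prior_phi_scale, double prior_sigma_shape,
                double prior_sigma_rate,
                int iter, int warmup, NumericVector gamma_init) {
  const int n = y.size(), p = Z.ncol(), S = n_sites;

  std::vector<double> gamma(p, 0.0), beta(p, 0.0);
  for (int j = 0; j < p && j < gamma_init.size(); ++j) gamma[j] = gamma_init[j];
  for (int k = 0; k < p; ++k) {
    double b = 0.0;
    for (int j = 0; j < p; ++j) b += T(k, j) * gamma[j];
    beta[k] = b;
  }
  std::vector<double> u(S, 0.0);
  double sigma = 0.5;
  double phi = 1.0;

  std::vector< std::vector<int> > site_rows(S);
  for (int i = 0; i < n; ++i) site_rows[site[i]].push_back(i);

  NumericVector eta(n);
  for (int i = 0; i < n; ++i) {
    double e = offset[i] + u[site[i]];
    for (int j = 0; j < p; ++j) e += Z(i, j) * gamma[j];
    eta[i] = e;
  }

  Adapt a_gam(p, 0.05), a_u(S, 0.3), a_sig(1, 0.3), a_phi(1, 0.3),
        a_rec(1, 0.2), a_resc(1, 0.2);

  NumericMatrix draws_beta(iter, p), draws_u(iter, S);
  NumericVector draws_sigma(iter), draws_phi(iter);

  const int total = warmup + iter;

  for (int it = 0; it < total; ++it) {
    // --- fixed effects (whitened basis) ---
    for (int j = 0; j < p; ++j) {
      double delta = R::norm_rand() * a_gam.sd(j);
      double d = 0.0;
      for (int i = 0; i < n; ++i) {
        double e_new = eta[i] + delta * Z(i, j);
        d += ll_eta(y[i], e_new, phi, family) - ll_eta(y[i], eta[i], phi, family);
      }
      // prior evaluated on beta = T gamma; only components with T(k,j) != 0
      // change
      for (int k = 0; k < p; ++k) {
        double t = T(k, j);
        if (t != 0.0) {
          d += R::dnorm(beta[k] + delta * t, 0.0, prior_sd[k], 1) -
               R::dnorm(beta[k], 0.0, prior_sd[k], 1);
        }
      }
      bool ok = std::log(R::unif_rand()) < d;
      if (ok) {
        for (int i = 0; i < n; ++i) eta[i] += delta * Z(i, j);
        for (int k = 0; k < p; ++k) beta[k] += delta * T(k, j);
        gamma[j] += delta;
      }
      if (it < warmup) a_gam.note(j, ok);
    }

    // --- site intercepts ---
    for (int s = 0; s < S; ++s) {
      double delta = R::norm_rand() * a_u.sd(s);
      double cand = u[s] + delta;
      double d = 0.0;
      for (int k : site_rows[s]) {
        d += ll_eta(y[k], eta[k] + delta, phi, family) -
             ll_eta(y[k], eta[k], phi, family);
      }
      d += R::dnorm(cand, 0.0, sigma, 1) - R::dnorm(u[s], 0.0, sigma, 1);
      bool ok = std::log(R::unif_rand()) < d;
      if (ok) {
        for (int k : site_rows[s]) eta[k] += delta;
        u[s] = cand;
      }
      if (it < warmup) a_u.note(s, ok);
    }

    // --- recentering move: gamma_0 += delta (Z[,0] = 1), all u_s -= delta;
    //     eta is unchanged, only priors enter the ratio ---
    {
      double delta = R::norm_rand() * a_rec.sd(0);
      double t00 = T(0, 0);
      double d = R::dnorm(beta[0] + delta * t00, 0.0, prior_sd[0], 1) -
                 R::dnorm(beta[0], 0.0, prior_sd[0], 1);
      for (int s = 0; s < S; ++s) {
        d += R::dnorm(u[s] - delta, 0.0, sigma, 1) -
             R::dnorm(u[s], 0.0, sigma, 1);
      }
      bool ok = std::log(R::unif_rand()) < d;
      if (ok) {
        gamma[0] += delta;
        beta[0] += delta * t00;
        for (int s = 0; s < S; ++s) u[s] -= delta;
      }
      if (it < warmup) a_rec.note(0, ok);
    }

    // --- joint rescaling (sigma, u) -> (c sigma, c u): breaks the funnel
    //     coupling; the u-prior terms cancel against the Jacobian, leaving
    //     likelihood, sigma-prior and log-scale terms ---
    {
      double c = std::exp(R::norm_rand() * a_resc.sd(0));
      double cand = c * sigma;
      double d = R::dgamma(cand, prior_sigma_shape, 1.0 / prior_sigma_rate, 1) -
                 R::dgamma(sigma, prior_sigma_shape, 1.0 / prior_sigma_rate, 1) +
                 std::log(cand) - std::log(sigma);
      for (int i = 0; i < n; ++i) {
        double e_new = eta[i] + (c - 1.0) * u[site[i]];
        d += ll_eta(y[i], e_new, phi, family) - ll_eta(y[i], eta[i], phi, family);
      }
      bool ok = std::log(R::unif_rand()) < d;
      if (ok) {
        for (int i = 0; i < n; ++i) eta[i] += (c - 1.0) * u[site[i]];
        for (int s = 0; s < S; ++s) u[s] *= c;
        sigma = cand;
      }
      if (it < warmup) a_resc.note(0, ok);
    }

    // --- sigma (random walk on log scale; Gamma prior + Jacobian) ---
    {
      double lcand = std::log(sigma) + R::norm_rand() * a_sig.sd(0);
      double cand = std::exp(lcand);
      double d = 0.0;
      for (int s = 0; s < S; ++s) {
        d += R::dnorm(u[s], 0.0, cand, 1) - R::dnorm(u[s], 0.0, sigma, 1);
      }
      d += R::dgamma(cand, prior_sigma_shape, 1.0 / prior_sigma_rate, 1) -
           R::dgamma(sigma, prior_sigma_shape, 1.0 / prior_sigma_rate, 1);
      d += lcand - std::log(sigma); // Jacobian of the log transform
      bool ok = std::log(R::unif_rand()) < d;
      if (ok) sigma = cand;
      if (it < warmup) a_sig.note(0, ok);
    }

    // --- NB shape (relapse model only) ---
    if (family == 0) {
      double lcand = std::log(phi) + R::norm_rand() * a_phi.sd(0);
      double cand = std::exp(lcand);
      double d = ll_phi_part(y, cand) + ll_eta_sum(y, eta, cand, 0) -
                 ll_phi_part(y, phi) - ll_eta_sum(y, eta, phi, 0);
      // Half-Cauchy(0, scale) density on phi, plus log-scale Jacobian
      double sc = prior_phi_scale;
      d += -std::log1p((cand / sc) * (cand / sc)) +
           std::log1p((phi / sc) * (phi / sc));
      d += lcand - std::log(phi);
      bool ok = std::log(R::unif_rand()) < d;
      if (ok) phi = cand;
      if (it < warmup) a_phi.note(0, ok);
    }

    if (it < warmup) {
      a_gam.maybe_adapt(); a_u.maybe_adapt(); a_sig.maybe_adapt();
      a_phi.maybe_adapt(); a_rec.maybe_adapt(); a_resc.maybe_adapt();
    } else {
      int r = it - warmup;
      for (int j = 0; j < p; ++j) draws_beta(r, j) = beta[j];
      for (int s = 0; s < S; ++s) draws_u(r, s) = u[s];
      draws_sigma[r] = sigma;
      draws_phi[r] = phi;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["beta"] = draws_beta, _["u"] = draws_u,
                      _["sigma"] = draws_sigma, _["phi"] = draws_phi);
}
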