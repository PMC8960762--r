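// Metropolis-within-Gibbs sampler for the Bayesian phylogenetic
// cumulative-logit model:
//   P(y_i <= k) = logistic(tau_k - x_i' beta - u_i),
//   u ~ MVN(0, sigma_u^2 * C_scaled).
// Priors: beta_j ~ N(0, slope_sd^2); thresholds Student-t(tau_nu, 0,
// tau_scale) subject to ordering (the weakly-informative anchor that keeps
// the latent scale identified); sigma_u ~ half-Student-t(nu, 0, scale). The phylogenetic effects u are
// updated site-wise using the precision matrix Cinv of the (unit-max-diag)
// scaled tree covariance; sigma_u moves on the log scale. Step sizes adapt
// toward a 0.44 acceptance rate during the first half of each chain
// (discarded as burn-in). Each chain has its own Mersenne-Twister stream
// seeded from `seed + chain`, so runs are bit-reproducible.

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log P(y = k | eta) for cumulative logit with thresholds tau (size K-1)
static double obs_loglik(int y, double eta, const std::vector<double>& tau) {
  const int K = (int)tau.size() + 1;
  // F(tau_k - eta) with F logistic; log of the difference of CDFs
  if (y == 1) {
    return -softplus(-(tau[0] - eta));
  } else if (y == K) {
    return -softplus(tau[K - 2] - eta);
  } else {
    double a = tau[y - 2] - eta, b = tau[y - 1] - eta;
    double Fa = 1.0 / (1.0 + std::exp(-a));
    double Fb = 1.0 / (1.0 + std::exp(-b));
    double p = Fb - Fa;
    if (p <= 1e-300) return -690.0;
    return std::log(p);
  }
}

struct Adapt {
  double step;
  int acc, tries;
  Adapt() : step(0.5), acc(0), tries(0) {}
  void tune() {
    if (tries >= 50) {
      double rate = (double)acc / tries;
      step *= std::exp(rate - 0.44);
      step = std::min(std::max(step, 1e-3), 10.0);
      acc = 0; tries = 0;
    }
  }
};

// [[Rcpp::export(name = ".ordinal_mcmc_cpp")]]
List ordinal_mcmc_cpp(IntegerVector y, NumericMatrix X, NumericMatrix Cinv,
                      int n_levels, int iter, int chains, int seed,
                      double slope_sd, double tau_nu, double tau_scale,
                      double sigma_nu, double sigma_scale,
                      bool fix_sigma_zero) {
  const int n = y.size();
  const int p = X.ncol();
  const int K = n_levels;
  const int n_tau = K - 1;
  const int burn = iter / 2;
  const int keep = iter - burn;
  const int n_par = p + n_tau + 1;  // beta, tau, sigma_u

  List chain_draws(chains);

  for (int ch = 0; ch < chains; ++ch) {
    std::mt19937_64 rng((uint64_t)seed + (uint64_t)ch * 1000003ULL);
    std::normal_distribution<double> rnorm01(0.0, 1.0);
    std::uniform_real_distribution<double> runif01(0.0, 1.0);

    std::vector<double> beta(p, 0.0);
    std::vector<double> tau(n_tau);
    for (int k = 0; k < n_tau; ++k)
      tau[k] = -1.0 + 2.0 * k / std::max(1, n_tau - 1);
    if (n_tau == 1) tau[0] = 0.0;
    std::vector<double> u(n, 0.0);
    double sigma = fix_sigma_zero ? 0.0 : 0.5;

    std::vector<double> eta(n, 0.0);          // X beta + u
    std::vector<double> w(n, 0.0);            // Cinv * u
    double quad = 0.0;                        // u' Cinv u

    std::vector<double> ll(n);
    double ll_sum = 0.0;
    for (int i = 0; i < n; ++i) {
      ll[i] = obs_loglik(y[i], eta[i], tau);
      ll_sum += ll[i];
    }

    std::vector<Adapt> ad_beta(p), ad_tau(n_tau);
    Adapt ad_u, ad_sigma, ad_resc;
    ad_u.step = 1.0;
    ad_sigma.step = 0.5;
    ad_resc.step = 0.3;

    NumericMatrix draws(keep, n_par);

    for (int it = 0; it < iter; ++it) {
      bool adapting = it < burn;

      // beta and tau are cheap O(n) scalar updates but strongly correlated
      // a posteriori; refreshing them a few times per cycle speeds mixing
      for (int scan = 0; scan < 3; ++scan) {
      // --- beta updates (scalar random walk) ---
      for (int j = 0; j < p; ++j) {
        double prop = beta[j] + ad_beta[j].step * rnorm01(rng);
        double d = prop - beta[j];
        double new_sum = 0.0;
        std::vector<double> new_ll(n);
        for (int i = 0; i < n; ++i) {
          new_ll[i] = obs_loglik(y[i], eta[i] + d * X(i, j), tau);
          new_sum += new_ll[i];
        }
        double lprior = -(prop * prop - beta[j] * beta[j]) /
                        (2.0 * slope_sd * slope_sd);
        double lacc = new_sum - ll_sum + lprior;
        ad_beta[j].tries++;
        if (std::log(runif01(rng)) < lacc) {
          ad_beta[j].acc++;
          beta[j] = prop;
          for (int i = 0; i < n; ++i) eta[i] += d * X(i, j);
          ll = new_ll;
          ll_sum = new_sum;
        }
        if (adapting) ad_beta[j].tune();
      }

      // --- threshold updates (Student-t prior, ordering enforced) ---
      for (int k = 0; k < n_tau; ++k) {
        double prop = tau[k] + ad_tau[k].step * rnorm01(rng);
        bool ok = (k == 0 || prop > tau[k - 1]) &&
                  (k == n_tau - 1 || prop < tau[k + 1]);
        ad_tau[k].tries++;
        if (ok) {
          std::vector<double> tprop(tau);
          tprop[k] = prop;
          double new_sum = 0.0;
          std::vector<double> new_ll(n);
          for (int i = 0; i < n; ++i) {
            new_ll[i] = obs_loglik(y[i], eta[i], tprop);
            new_sum += new_ll[i];
          }
          auto t_lp = [&](double t) {
            return -((tau_nu + 1.0) / 2.0) *
                   std::log1p((t / tau_scale) * (t / tau_scale) / tau_nu);
          };
          double lprior = t_lp(prop) - t_lp(tau[k]);
          if (std::log(runif01(rng)) < new_sum - ll_sum + lprior) {
            ad_tau[k].acc++;
            tau[k] = prop;
            ll = new_ll;
            ll_sum = new_sum;
          }
        }
        if (adapting) ad_tau[k].tune();
      }
      }  // end beta/tau scans

      if (!fix_sigma_zero) {
        // --- phylogenetic effects, site-wise ---
        double s2 = sigma * sigma;
        for (int i = 0; i < n; ++i) {
          double d = ad_u.step * rnorm01(rng);
          double prop_ll = obs_loglik(y[i], eta[i] + d, tau);
          double dquad = 2.0 * d * w[i] + d * d * Cinv(i, i);
          double lacc = prop_ll - ll[i] - dquad / (2.0 * s2);
          ad_u.tries++;
          if (std::log(runif01(rng)) < lacc) {
            ad_u.acc++;
            u[i] += d;
            eta[i] += d;
            ll_sum += prop_ll - ll[i];
            ll[i] = prop_ll;
            quad += dquad;
            for (int r = 0; r < n; ++r) w[r] += d * Cinv(r, i);
          }
        }
        if (adapting) ad_u.tune();

        // --- sigma_u on the log scale, half-t prior ---
        double ls = std::log(sigma);
        double lsp = ls + ad_sigma.step * rnorm01(rng);
        double sp = std::exp(lsp);
        auto lp = [&](double s, double lg) {
          // MVN(0, s^2 C) density of u + half-t prior + log-Jacobian
          double v = -n * lg - quad / (2.0 * s * s);
          double t = -((sigma_nu + 1.0) / 2.0) *
                     std::log1p((s / sigma_scale) * (s / sigma_scale) /
                                sigma_nu);
          return v + t + lg;  // Jacobian of the log transform
        };
        double lacc = lp(sp, lsp) - lp(sigma, ls);
        ad_sigma.tries++;
        if (std::log(runif01(rng)) < lacc) {
          ad_sigma.acc++;
          sigma = sp;
        }
        if (adapting) ad_sigma.tune();

        // --- joint rescale of (sigma_u, u): non-centered move that breaks
        // the funnel correlation between the variance and the effects ---
        double lc = ad_resc.step * rnorm01(rng);
        double c = std::exp(lc);
        double new_sum = 0.0;
        std::vector<double> new_ll(n);
        for (int i = 0; i < n; ++i) {
          new_ll[i] = obs_loglik(y[i], eta[i] + (c - 1.0) * u[i], tau);
          new_sum += new_ll[i];
        }
        double sc = sigma * c;
        auto lt_prior = [&](double s) {
          return -((sigma_nu + 1.0) / 2.0) *
                 std::log1p((s / sigma_scale) * (s / sigma_scale) /
                            sigma_nu);
        };
        // prior of u given sigma and Jacobian of the scaling cancel to +lc
        double lacc2 = new_sum - ll_sum + lc + lt_prior(sc) -
                       lt_prior(sigma);
        ad_resc.tries++;
        if (std::log(runif01(rng)) < lacc2) {
          ad_resc.acc++;
          for (int i = 0; i < n; ++i) {
            eta[i] += (c - 1.0) * u[i];
            u[i] *= c;
            w[i] *= c;
          }
          quad *= c * c;
          sigma = sc;
          ll = new_ll;
          ll_sum = new_sum;
        }
        if (adapting) ad_resc.tune();
      }

      if (it >= burn) {
        int r = it - burn;
        for (int j = 0; j < p; ++j) draws(r, j) = beta[j];
        for (int k = 0; k < n_tau; ++k) draws(r, p + k) = tau[k];
        draws(r, p + n_tau) = sigma;
      }
    }
    chain_draws[ch] = draws;
  }

  return List::create(_["chains"] = chain_draws,
                      _["n_kept"] = keep);
}
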