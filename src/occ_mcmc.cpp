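// Metropolis-within-Gibbs sampler for the multi-species occupancy model:
// species fixed effects on occupancy (uniform prior, conjugate Beta update
// given the latent z), community hyperparameters on every detection
// parameter family (intercept, canopy slope, two period contrasts), exact
// Gibbs update of the latent occupancy state, random-walk Metropolis on the
// detection parameters with burn-in-only adaptation.  Uses R's RNG, so runs
// are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double lse_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Bernoulli detection log-likelihood for one species over occupied sites.
// period is 1-based (1 = reference); bP2/bP3 are the period-2/3 contrasts.
static double det_loglik(const IntegerMatrix &y, const std::vector<int> &z,
                         const NumericVector &canopy,
                         const IntegerVector &period,
                         double alpha, double bC, double bP2, double bP3) {
  const int I = y.nrow(), J = y.ncol();
  double ll = 0.0;
  for (int i = 0; i < I; ++i) {
    if (!z[i]) continue;
    const double base = alpha + bC * canopy[i];
    for (int j = 0; j < J; ++j) {
      double eta = base;
      if (period[j] == 2) eta += bP2;
      else if (period[j] == 3) eta += bP3;
      ll += y(i, j) ? -lse_(-eta) : -lse_(eta);
    }
  }
  return ll;
}

// [[Rcpp::export]]
List occ_chain_cpp(List y_list, NumericVector canopy, IntegerVector period,
                   int n_iter, int burn_in, int thin, int n_sweeps,
                   bool use_canopy, bool use_period, bool update_hypers,
                   NumericVector mu, NumericVector sigma,
                   double hyper_mu_sd, double hyper_sd_max,
                   NumericVector psi, NumericVector alpha, NumericVector bC,
                   NumericVector bP2, NumericVector bP3) {
  const int S = y_list.size();
  const int I = canopy.size();
  const int J = period.size();

  // work on copies: the caller's init vectors must stay untouched
  psi = clone(psi); alpha = clone(alpha); bC = clone(bC);
  bP2 = clone(bP2); bP3 = clone(bP3);

  std::vector<IntegerMatrix> y(S);
  std::vector<std::vector<int> > z(S, std::vector<int>(I));
  std::vector<std::vector<bool> > detected(S, std::vector<bool>(I, false));
  for (int s = 0; s < S; ++s) {
    y[s] = as<IntegerMatrix>(y_list[s]);
    if (y[s].nrow() != I || y[s].ncol() != J)
      stop("detection array dimensions do not match covariates");
    for (int i = 0; i < I; ++i) {
      bool det = false;
      for (int j = 0; j < J; ++j) if (y[s](i, j)) { det = true; break; }
      detected[s][i] = det;
      z[s][i] = det ? 1 : (R::unif_rand() < psi[s] ? 1 : 0);
    }
  }

  // parameter families: 0 alpha, 1 canopy, 2 period-2, 3 period-3
  std::vector<bool> active(4, false);
  active[0] = true; active[1] = use_canopy;
  active[2] = use_period; active[3] = use_period;
  NumericVector mu_ = clone(mu), sigma_ = clone(sigma);

  NumericMatrix pscale(S, 4);
  std::fill(pscale.begin(), pscale.end(), 0.5);
  NumericVector sd_scale(4, 0.5);
  IntegerMatrix acc(S, 4), att(S, 4);
  IntegerVector sd_acc(4), sd_att(4);

  const int n_keep = (n_iter - burn_in) / thin;
  int n_fam = 0;
  for (int k = 0; k < 4; ++k) if (active[k]) ++n_fam;
  int n_mon = 2 * S;                 // psi, alpha
  if (use_canopy) n_mon += S;
  if (use_period) n_mon += 2 * S;
  if (update_hypers) n_mon += 2 * n_fam;
  n_mon += S;                        // zprop (derived)
  NumericMatrix draws(n_keep, n_mon);
  int row = 0;

  std::vector<double *> fam_val(4);

  for (int iter = 1; iter <= n_iter; ++iter) {
    // one iteration applies the full transition kernel n_sweeps times;
    // retained-sample bookkeeping (burn-in, thinning) counts iterations
    for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int s = 0; s < S; ++s) {
      const double a = alpha[s], bc = bC[s], b2 = bP2[s], b3 = bP3[s];
      // 1. latent occupancy (exact full conditional)
      int sumz = 0;
      for (int i = 0; i < I; ++i) {
        if (detected[s][i]) { z[s][i] = 1; ++sumz; continue; }
        double lq = 0.0;
        const double base = a + bc * canopy[i];
        for (int j = 0; j < J; ++j) {
          double eta = base;
          if (period[j] == 2) eta += b2;
          else if (period[j] == 3) eta += b3;
          lq += -lse_(eta);      // log(1 - p)
        }
        const double pq = psi[s] * std::exp(lq);
        const double pz = pq / (pq + 1.0 - psi[s]);
        z[s][i] = (R::unif_rand() < pz) ? 1 : 0;
        sumz += z[s][i];
      }
      // 2. occupancy probability (conjugate under the uniform prior)
      psi[s] = R::rbeta(1.0 + sumz, 1.0 + I - sumz);

      // 3. detection parameters, random-walk Metropolis per family
      double cur = det_loglik(y[s], z[s], canopy, period, alpha[s], bC[s],
                              bP2[s], bP3[s]);
      fam_val[0] = &alpha[s]; fam_val[1] = &bC[s];
      fam_val[2] = &bP2[s]; fam_val[3] = &bP3[s];
      for (int k = 0; k < 4; ++k) {
        if (!active[k]) continue;
        const double old = *fam_val[k];
        const double prop = old + R::norm_rand() * pscale(s, k);
        *fam_val[k] = prop;
        const double prop_ll = det_loglik(y[s], z[s], canopy, period,
                                          alpha[s], bC[s], bP2[s], bP3[s]);
        const double logr = prop_ll - cur +
          R::dnorm(prop, mu_[k], sigma_[k], 1) -
          R::dnorm(old, mu_[k], sigma_[k], 1);
        ++att(s, k);
        if (std::log(R::unif_rand()) < logr) {
          cur = prop_ll;
          ++acc(s, k);
        } else {
          *fam_val[k] = old;
        }
      }
    }

    // 4. community hyperparameters
    if (update_hypers) {
      for (int k = 0; k < 4; ++k) {
        if (!active[k]) continue;
        double sum = 0.0;
        const NumericVector &v = (k == 0) ? alpha : (k == 1) ? bC
                                 : (k == 2) ? bP2 : bP3;
        for (int s = 0; s < S; ++s) sum += v[s];
        // conjugate normal update for the mean
        const double prec = S / (sigma_[k] * sigma_[k]) +
          1.0 / (hyper_mu_sd * hyper_mu_sd);
        const double mean = (sum / (sigma_[k] * sigma_[k])) / prec;
        mu_[k] = mean + R::norm_rand() / std::sqrt(prec);
        // Metropolis on the sd under its Uniform(0, hyper_sd_max) prior
        const double sprop = sigma_[k] + R::norm_rand() * sd_scale[k];
        ++sd_att[k];
        if (sprop > 0.0 && sprop <= hyper_sd_max) {
          double logr = 0.0;
          for (int s = 0; s < S; ++s)
            logr += R::dnorm(v[s], mu_[k], sprop, 1) -
                    R::dnorm(v[s], mu_[k], sigma_[k], 1);
          if (std::log(R::unif_rand()) < logr) {
            sigma_[k] = sprop;
            ++sd_acc[k];
          }
        }
      }
    }
    }  // end sweeps

    // 5. proposal adaptation, burn-in only (frozen afterwards to preserve
    //    detailed balance)
    if (iter <= burn_in && iter % 50 == 0) {
      for (int s = 0; s < S; ++s)
        for (int k = 0; k < 4; ++k) {
          if (!active[k] || att(s, k) == 0) continue;
          const double rate = (double)acc(s, k) / att(s, k);
          double f = std::exp(2.0 * (rate - 0.44));   // 1-d RW optimum
          pscale(s, k) = std::min(10.0, std::max(1e-3, pscale(s, k) * f));
          acc(s, k) = att(s, k) = 0;
        }
      for (int k = 0; k < 4; ++k) {
        if (!active[k] || !update_hypers || sd_att[k] == 0) continue;
        const double rate = (double)sd_acc[k] / sd_att[k];
        sd_scale[k] = std::min(10.0,
          std::max(1e-3, sd_scale[k] * std::exp(2.0 * (rate - 0.44))));
        sd_acc[k] = sd_att[k] = 0;
      }
    }

    // 6. record
    if (iter > burn_in && (iter - burn_in) % thin == 0 && row < n_keep) {
      int c = 0;
      for (int s = 0; s < S; ++s) draws(row, c++) = psi[s];
      for (int s = 0; s < S; ++s) draws(row, c++) = alpha[s];
      if (use_canopy) for (int s = 0; s < S; ++s) draws(row, c++) = bC[s];
      if (use_period) {
        for (int s = 0; s < S; ++s) draws(row, c++) = bP2[s];
        for (int s = 0; s < S; ++s) draws(row, c++) = bP3[s];
      }
      if (update_hypers)
        for (int k = 0; k < 4; ++k) {
          if (!active[k]) continue;
          draws(row, c++) = mu_[k];
          draws(row, c++) = sigma_[k];
        }
      for (int s = 0; s < S; ++s) {
        int sumz = 0;
        for (int i = 0; i < I; ++i) sumz += z[s][i];
        draws(row, c++) = (double)sumz / I;
      }
      ++row;
    }
  }

  return List::create(_["draws"] = draws,
                      _["pscale"] = pscale,
                      _["sd_scale"] = sd_scale);
}
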