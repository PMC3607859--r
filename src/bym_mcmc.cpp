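// Metropolis-within-Gibbs sampler for the BYM convolution CAR Poisson model
//
//   O_i ~ Poisson(E_i * lambda_i),  log lambda_i = alpha + X_i beta + eps_i + phi_i
//
// eps_i ~ N(0, 1/tau_eps) iid; phi ~ intrinsic CAR with conditional
// precision tau_phi * n_i, kept identifiable by recentring phi to mean zero
// over non-isolated units each sweep (the WinBUGS car.normal convention).
// tau_eps, tau_phi get conjugate gamma Gibbs updates; alpha, beta and the
// per-unit random effects get random-walk Metropolis steps whose scales
// adapt toward 44% acceptance during burn-in only. Uses R's RNG, so
// set.seed() in R makes chains reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static inline double pois_delta(double O, double mu, double d) {
  // change in Poisson log-lik for one unit when eta_i increases by d
  return O * d - mu * (std::exp(d) - 1.0);
}

// [[Rcpp::export(name = ".bym_mcmc_cpp")]]
List bym_mcmc_cpp(NumericVector O, NumericVector logE, NumericMatrix X,
                  IntegerVector nb_index, IntegerVector nb_start,
                  IntegerVector n_nb, int car_rank,
                  NumericMatrix Qvec, NumericVector Qval,
                  bool use_phi, bool use_eps,
                  double prior_alpha_var, double prior_beta_var,
                  double tau_shape, double tau_rate,
                  int n_burnin, int n_keep, int adapt_interval, int field_thin,
                  List init, List scales_in) {
  const int n = O.size();
  const int p = X.ncol();
  const int n_iter = n_burnin + n_keep;
  const int n_field = n_keep / field_thin;

  double alpha = as<double>(init["alpha"]);
  NumericVector beta = clone(as<NumericVector>(init["beta"]));
  NumericVector eps = clone(as<NumericVector>(init["eps"]));
  NumericVector phi = clone(as<NumericVector>(init["phi"]));
  double tau_eps = as<double>(init["tau_eps"]);
  double tau_phi = as<double>(init["tau_phi"]);

  double s_alpha = as<double>(scales_in["alpha"]);
  NumericVector s_beta = clone(as<NumericVector>(scales_in["beta"]));
  double s_eps = as<double>(scales_in["eps"]);
  double s_phi = as<double>(scales_in["phi"]);
  const bool adapt = as<bool>(scales_in["adapt"]);

  // linear predictor eta = logE + alpha + X beta + eps + phi
  NumericVector eta(n), mu(n);
  for (int i = 0; i < n; ++i) {
    double xb = 0.0;
    for (int k = 0; k < p; ++k) xb += X(i, k) * beta[k];
    eta[i] = logE[i] + alpha + xb + eps[i] + phi[i];
    mu[i] = std::exp(eta[i]);
  }

  int n_active = 0;  // units participating in the CAR field
  for (int i = 0; i < n; ++i) if (n_nb[i] > 0) ++n_active;

  NumericVector keep_alpha(n_keep), keep_tau_eps(n_keep), keep_tau_phi(n_keep),
      keep_dev(n_keep);
  NumericMatrix keep_beta(n_keep, p), keep_eps(n_field, n), keep_phi(n_field, n),
      keep_lambda(n_field, n);

  double acc_alpha = 0, acc_eps = 0, acc_phi = 0;
  NumericVector acc_beta(p);
  int win_alpha = 0, win_eps = 0, win_phi = 0;
  IntegerVector win_beta(p);

  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    // --- alpha: random-walk MH ---
    {
      double d = R::rnorm(0.0, s_alpha);
      double lr = 0.0;
      for (int i = 0; i < n; ++i) lr += pois_delta(O[i], mu[i], d);
      double a_new = alpha + d;
      lr += (alpha * alpha - a_new * a_new) / (2.0 * prior_alpha_var);
      ++win_alpha;
      if (std::log(R::unif_rand()) < lr) {
        alpha = a_new;
        for (int i = 0; i < n; ++i) { eta[i] += d; mu[i] = std::exp(eta[i]); }
        acc_alpha += 1.0;
      }
    }

    // --- beta_k: random-walk MH, one coordinate at a time ---
    for (int k = 0; k < p; ++k) {
      double d = R::rnorm(0.0, s_beta[k]);
      double lr = 0.0;
      for (int i = 0; i < n; ++i) lr += pois_delta(O[i], mu[i], X(i, k) * d);
      double b_new = beta[k] + d;
      lr += (beta[k] * beta[k] - b_new * b_new) / (2.0 * prior_beta_var);
      ++win_beta[k];
      if (std::log(R::unif_rand()) < lr) {
        beta[k] = b_new;
        for (int i = 0; i < n; ++i) {
          eta[i] += X(i, k) * d; mu[i] = std::exp(eta[i]);
        }
        acc_beta[k] += 1.0;
      }
    }

    // --- eps_i: conditionally independent single-site MH ---
    if (use_eps) {
      for (int i = 0; i < n; ++i) {
        double d = R::rnorm(0.0, s_eps);
        double e_new = eps[i] + d;
        double lr = pois_delta(O[i], mu[i], d) +
          0.5 * tau_eps * (eps[i] * eps[i] - e_new * e_new);
        ++win_eps;
        if (std::log(R::unif_rand()) < lr) {
          eps[i] = e_new; eta[i] += d; mu[i] = std::exp(eta[i]);
          acc_eps += 1.0;
        }
      }
      // Translation moves: shift (alpha, eps) and (beta_k, eps) along
      // likelihood-invariant directions. alpha + d, eps_i - d leaves every
      // eta_i unchanged, so the conditional of d is Gaussian from the
      // priors alone and can be Gibbs-sampled exactly. This decorrelates
      // the intercept and coefficients from the heterogeneity field.
      {
        double prec = n * tau_eps + 1.0 / prior_alpha_var;
        double mean = 0.0;
        for (int i = 0; i < n; ++i) mean += eps[i];
        mean = (tau_eps * mean - alpha / prior_alpha_var) / prec;
        double d = R::rnorm(mean, 1.0 / std::sqrt(prec));
        alpha += d;
        for (int i = 0; i < n; ++i) eps[i] -= d;
      }
      for (int k = 0; k < p; ++k) {
        double sxx = 0.0, sex = 0.0;
        for (int i = 0; i < n; ++i) {
          sxx += X(i, k) * X(i, k);
          sex += eps[i] * X(i, k);
        }
        if (sxx <= 0.0) continue;
        double prec = tau_eps * sxx + 1.0 / prior_beta_var;
        double mean = (tau_eps * sex - beta[k] / prior_beta_var) / prec;
        double d = R::rnorm(mean, 1.0 / std::sqrt(prec));
        beta[k] += d;
        for (int i = 0; i < n; ++i) eps[i] -= d * X(i, k);
      }
      // Gibbs for tau_eps
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += eps[i] * eps[i];
      tau_eps = R::rgamma(tau_shape + 0.5 * n, 1.0 / (tau_rate + 0.5 * ss));
    }

    // --- phi_i: single-site MH against the ICAR full conditional ---
    if (use_phi) {
      for (int i = 0; i < n; ++i) {
        if (n_nb[i] == 0) continue;  // isolated unit: phi fixed at 0
        double nb_sum = 0.0;
        for (int j = nb_start[i]; j < nb_start[i] + n_nb[i]; ++j)
          nb_sum += phi[nb_index[j]];
        double prec = tau_phi * n_nb[i];
        double m = nb_sum / n_nb[i];
        double d = R::rnorm(0.0, s_phi);
        double p_new = phi[i] + d;
        double lr = pois_delta(O[i], mu[i], d) +
          0.5 * prec * ((phi[i] - m) * (phi[i] - m) - (p_new - m) * (p_new - m));
        ++win_phi;
        if (std::log(R::unif_rand()) < lr) {
          phi[i] = p_new; eta[i] += d; mu[i] = std::exp(eta[i]);
          acc_phi += 1.0;
        }
      }
      // Only eps_i + phi_i enters the likelihood: resample the split
      // between the two fields exactly from the priors given the sum
      // (eta unchanged). This breaks the slow random-walk exchange between
      // the structured and unstructured fields and lets both precisions
      // mix. The split's full conditional has precision
      // tau_eps I + tau_phi Q, diagonal in the eigenbasis of the graph
      // Laplacian Q, so with the spectral basis available (no isolated
      // units) the whole split is redrawn jointly; the sum-to-zero
      // constraint assigns the null mode entirely to eps. Otherwise fall
      // back to single-site Gibbs on the split.
      if (use_eps && Qvec.ncol() == n) {
        std::vector<double> st(n), et(n);
        for (int k = 0; k < n; ++k) {
          double acc = 0.0;
          for (int i = 0; i < n; ++i) acc += Qvec(i, k) * (eps[i] + phi[i]);
          st[k] = acc;
        }
        for (int k = 0; k < n; ++k) {
          if (Qval[k] <= 0.0) {
            et[k] = st[k];
          } else {
            double prec = tau_eps + tau_phi * Qval[k];
            double mean = tau_phi * Qval[k] * st[k] / prec;
            et[k] = R::rnorm(mean, 1.0 / std::sqrt(prec));
          }
        }
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          for (int k = 0; k < n; ++k) acc += Qvec(i, k) * et[k];
          double s = eps[i] + phi[i];
          eps[i] = acc;
          phi[i] = s - acc;
        }
      } else if (use_eps) {
        for (int i = 0; i < n; ++i) {
          if (n_nb[i] == 0) continue;
          double s = eps[i] + phi[i];
          double nb_sum = 0.0;
          for (int j = nb_start[i]; j < nb_start[i] + n_nb[i]; ++j)
            nb_sum += phi[nb_index[j]];
          double m = nb_sum / n_nb[i];
          double prec = tau_eps + tau_phi * n_nb[i];
          double mean = tau_phi * n_nb[i] * (s - m) / prec;
          eps[i] = R::rnorm(mean, 1.0 / std::sqrt(prec));
          phi[i] = s - eps[i];
        }
      }
      // sum-to-zero constraint: recentre phi and absorb the mean into
      // alpha (and, for isolated units with phi fixed at 0, into eps) so
      // the linear predictor is exactly unchanged
      double pm = 0.0;
      for (int i = 0; i < n; ++i) if (n_nb[i] > 0) pm += phi[i];
      pm /= n_active;
      if (use_eps || n_active == n) {
        for (int i = 0; i < n; ++i) {
          if (n_nb[i] > 0) phi[i] -= pm;
          else eps[i] -= pm;  // isolated unit: shift carried by eps
        }
        alpha += pm;
      } else {
        // no heterogeneity term to carry the shift for isolated units:
        // plain recentring (the car.normal convention)
        for (int i = 0; i < n; ++i) {
          if (n_nb[i] > 0) {
            phi[i] -= pm; eta[i] -= pm; mu[i] = std::exp(eta[i]);
          }
        }
      }
      // Gibbs for tau_phi from the pairwise-difference quadratic form
      double qf = 0.0;
      for (int i = 0; i < n; ++i)
        for (int j = nb_start[i]; j < nb_start[i] + n_nb[i]; ++j) {
          double diff = phi[i] - phi[nb_index[j]];
          qf += diff * diff;  // counts each unordered pair twice
        }
      qf *= 0.5;
      tau_phi = R::rgamma(tau_shape + 0.5 * car_rank, 1.0 / (tau_rate + 0.5 * qf));
    }

    // --- adaptation (burn-in only) ---
    if (adapt && it < n_burnin && ((it + 1) % adapt_interval == 0)) {
      const double lo = 0.3, hi = 0.5, f_up = 1.3, f_dn = 0.77;
      double r;
      r = acc_alpha / std::max(1, win_alpha);
      if (r > hi) s_alpha *= f_up; else if (r < lo) s_alpha *= f_dn;
      acc_alpha = 0; win_alpha = 0;
      for (int k = 0; k < p; ++k) {
        r = acc_beta[k] / std::max(1, (int)win_beta[k]);
        if (r > hi) s_beta[k] *= f_up; else if (r < lo) s_beta[k] *= f_dn;
        acc_beta[k] = 0; win_beta[k] = 0;
      }
      if (use_eps) {
        r = acc_eps / std::max(1, win_eps);
        if (r > hi) s_eps *= f_up; else if (r < lo) s_eps *= f_dn;
        acc_eps = 0; win_eps = 0;
      }
      if (use_phi) {
        r = acc_phi / std::max(1, win_phi);
        if (r > hi) s_phi *= f_up; else if (r < lo) s_phi *= f_dn;
        acc_phi = 0; win_phi = 0;
      }
    }

    // --- store ---
    if (it >= n_burnin) {
      int s = it - n_burnin;
      keep_alpha[s] = alpha;
      for (int k = 0; k < p; ++k) keep_beta(s, k) = beta[k];
      keep_tau_eps[s] = tau_eps;
      keep_tau_phi[s] = tau_phi;
      double dev = 0.0;
      for (int i = 0; i < n; ++i) dev += R::dpois(O[i], mu[i], 1);
      keep_dev[s] = -2.0 * dev;
      if (s % field_thin == 0 && s / field_thin < n_field) {
        int sf = s / field_thin;
        for (int i = 0; i < n; ++i) {
          keep_eps(sf, i) = eps[i];
          keep_phi(sf, i) = phi[i];
          keep_lambda(sf, i) = std::exp(eta[i] - logE[i]);
        }
      }
    }
  }

  List state = List::create(_["alpha"] = alpha, _["beta"] = beta,
                            _["eps"] = eps, _["phi"] = phi,
                            _["tau_eps"] = tau_eps, _["tau_phi"] = tau_phi);
  List scales = List::create(_["alpha"] = s_alpha, _["beta"] = s_beta,
                             _["eps"] = s_eps, _["phi"] = s_phi,
                             _["adapt"] = adapt);
  return List::create(_["alpha"] = keep_alpha, _["beta"] = keep_beta,
                      _["eps"] = keep_eps, _["phi"] = keep_phi,
                      _["tau_eps"] = keep_tau_eps, _["tau_phi"] = keep_tau_phi,
                      _["lambda"] = keep_lambda, _["deviance"] = keep_dev,
                      _["state"] = state, _["scales"] = scales);
}
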