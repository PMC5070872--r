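#include <Rcpp.h>
using namespace Rcpp;

// Partially collapsed Metropolis-within-Gibbs sampler for the zero-inflated
// binomial occupancy model, optionally with an intrinsic CAR spatial random
// effect on the logit-suitability scale:
//   y_i ~ Binomial(n_i, z_i * delta),  z_i ~ Bernoulli(theta_i),
//   logit(theta_i) = x_i' beta (+ rho_{cell(i)}),
//   rho_c | rho_{N(c)} ~ Normal(mean(rho_{N(c)}), V_rho / |N(c)|).
// Per sweep: beta by component-wise adaptive random-walk Metropolis and rho
// by a single-site sweep (CAR full conditional as the proposal), both
// against the likelihood with z marginalized analytically — collapsing z
// removes the absorbing state at theta ~ 1 that conditional updates suffer
// under vague priors; z is then refreshed from its exact full conditional
// and delta drawn from its conjugate Beta full conditional given z; V_rho
// from its truncated inverse-gamma full conditional. The sum-to-zero
// constraint is enforced by recentring rho each sweep, with the shift
// absorbed into the intercept (column 0 of X must be the intercept).

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// z-marginalized log-likelihood terms that vary with eta = logit(theta):
//   y > 0:  log(theta)
//   y = 0:  log((1 - theta) + theta * (1 - delta)^n) = log(q + (1 - q) * (1 - theta))
// with q = (1 - delta)^n, computed stably for |eta| large.
static inline double marg_ll(bool detected, double eta, double q) {
  if (detected) {
    // log(theta) = -log(1 + exp(-eta))
    return eta > 0 ? -std::log1p(std::exp(-eta))
                   : eta - std::log1p(std::exp(eta));
  }
  double one_minus_theta = inv_logit(-eta);
  return std::log(q + (1.0 - q) * one_minus_theta);
}

// [[Rcpp::export]]
List zib_chain_cpp(IntegerVector y, IntegerVector n, NumericMatrix X,
                   IntegerVector cell_of_obs, bool spatial, int ncell,
                   IntegerVector adj_ids, IntegerVector adj_start,
                   int n_comp, int n_iter, int n_burn, int thin,
                   double beta_var, double vrho_max,
                   NumericVector beta0, double delta0, double vrho0) {
  const int m = y.size();
  const int p = X.ncol();
  const int n_keep = (n_iter - n_burn + thin - 1) / thin;

  std::vector<double> beta(beta0.begin(), beta0.end());
  double delta = delta0;
  double vrho = vrho0;
  std::vector<double> rho(spatial ? ncell : 0, 0.0);
  std::vector<int> z(m, 1);
  std::vector<double> eta(m);    // current linear predictor incl. rho
  std::vector<double> q0(m);     // (1 - delta)^n per obs, refreshed with delta

  std::vector<int> obs_at(ncell, -1);
  if (spatial)
    for (int i = 0; i < m; ++i) obs_at[cell_of_obs[i]] = i;
  for (int i = 0; i < m; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
    q0[i] = std::pow(1.0 - delta, (double)n[i]);
  }

  std::vector<double> step(p, 0.1), acc(p, 0.0), tries(p, 0.0);

  NumericMatrix beta_draws(n_keep, p);
  NumericVector delta_draws(n_keep), vrho_draws(n_keep), dev_draws(n_keep);
  NumericMatrix rho_draws(spatial ? n_keep : 0, spatial ? ncell : 0);
  int keep = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- beta | delta, rho, y (z collapsed): component-wise RW Metropolis ---
    for (int j = 0; j < p; ++j) {
      double bj = beta[j];
      double bn = bj + step[j] * norm_rand();
      double d = 0.0;
      for (int i = 0; i < m; ++i) {
        double shift = (bn - bj) * X(i, j);
        if (shift != 0.0)
          d += marg_ll(y[i] > 0, eta[i] + shift, q0[i]) -
               marg_ll(y[i] > 0, eta[i], q0[i]);
      }
      d += (bj * bj - bn * bn) / (2.0 * beta_var);
      tries[j] += 1.0;
      if (std::log(unif_rand()) < d) {
        for (int i = 0; i < m; ++i) eta[i] += (bn - bj) * X(i, j);
        beta[j] = bn;
        acc[j] += 1.0;
      }
      // adapt toward ~0.44 acceptance during burn-in
      if (it < n_burn && tries[j] >= 50.0) {
        double rate = acc[j] / tries[j];
        step[j] *= (rate > 0.44) ? 1.2 : 0.85;
        acc[j] = 0.0; tries[j] = 0.0;
      }
    }

    if (spatial) {
      // --- rho | beta, delta, V_rho, y (z collapsed): single-site sweep ---
      for (int c = 0; c < ncell; ++c) {
        int s0 = adj_start[c], s1 = adj_start[c + 1];
        int nn = s1 - s0;
        if (nn == 0) { rho[c] = 0.0; continue; }   // isolated cell
        double msum = 0.0;
        for (int k = s0; k < s1; ++k) msum += rho[adj_ids[k]];
        double mu = msum / nn;
        double prop = mu + std::sqrt(vrho / nn) * norm_rand();
        int i = obs_at[c];
        if (i < 0) {
          rho[c] = prop;                 // pure Gibbs: no data in this cell
        } else {
          double eta_new = eta[i] - rho[c] + prop;
          double lr = marg_ll(y[i] > 0, eta_new, q0[i]) -
                      marg_ll(y[i] > 0, eta[i], q0[i]);
          if (std::log(unif_rand()) < lr) { rho[c] = prop; eta[i] = eta_new; }
        }
      }
      // recentre (sum-to-zero); the intercept absorbs the shift
      double mbar = 0.0;
      for (int c = 0; c < ncell; ++c) mbar += rho[c];
      mbar /= ncell;
      for (int c = 0; c < ncell; ++c) rho[c] -= mbar;
      beta[0] += mbar;

      // --- V_rho | rho: inverse-gamma truncated to (0, vrho_max) ---
      double S = 0.0;
      for (int c = 0; c < ncell; ++c)
        for (int k = adj_start[c]; k < adj_start[c + 1]; ++k) {
          double dd = rho[c] - rho[adj_ids[k]];
          S += dd * dd;
        }
      S *= 0.5;  // each edge counted twice above
      double shape = 0.5 * (ncell - n_comp) - 1.0;
      if (shape > 0.0 && S > 0.0) {
        double rate = 0.5 * S;
        double plo = R::pgamma(1.0 / vrho_max, shape, 1.0 / rate, 1, 0);
        double u = plo + unif_rand() * (1.0 - plo);
        if (u >= 1.0) u = 1.0 - 1e-12;
        double g = R::qgamma(u, shape, 1.0 / rate, 1, 0);
        if (g > 0.0 && R_finite(g)) vrho = 1.0 / g;
        if (vrho > vrho_max) vrho = vrho_max;
      }
    }

    // --- z refreshed from its exact full conditional ---
    // y > 0 forces z = 1; for y = 0, logit P(z = 1) = eta + n log(1 - delta)
    double log1md = std::log(1.0 - delta);
    for (int i = 0; i < m; ++i) {
      if (y[i] > 0) { z[i] = 1; continue; }
      double lo = eta[i] + n[i] * log1md;
      z[i] = unif_rand() < inv_logit(lo) ? 1 : 0;
    }

    // --- delta | z, y: conjugate Beta (uniform prior) ---
    double a = 1.0, b = 1.0;
    for (int i = 0; i < m; ++i)
      if (z[i] == 1) { a += y[i]; b += n[i] - y[i]; }
    delta = R::rbeta(a, b);
    if (delta < 1e-12) delta = 1e-12;
    if (delta > 1.0 - 1e-12) delta = 1.0 - 1e-12;
    for (int i = 0; i < m; ++i) q0[i] = std::pow(1.0 - delta, (double)n[i]);

    // --- record thinned post-burn-in draws ---
    if (it >= n_burn && (it - n_burn) % thin == 0 && keep < n_keep) {
      for (int j = 0; j < p; ++j) beta_draws(keep, j) = beta[j];
      delta_draws[keep] = delta;
      vrho_draws[keep] = spatial ? vrho : NA_REAL;
      if (spatial)
        for (int c = 0; c < ncell; ++c) rho_draws(keep, c) = rho[c];
      // marginal deviance: z integrated out analytically
      double dev = 0.0;
      for (int i = 0; i < m; ++i) {
        double ll = marg_ll(y[i] > 0, eta[i], q0[i]);
        if (y[i] > 0) ll += R::dbinom(y[i], n[i], delta, 1);
        dev += -2.0 * ll;
      }
      dev_draws[keep] = dev;
      ++keep;
    }
  }

  return List::create(
    _["beta"] = beta_draws, _["delta"] = delta_draws,
    _["vrho"] = vrho_draws, _["rho"] = rho_draws,
    _["deviance"] = dev_draws);
}
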