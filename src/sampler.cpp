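// Adaptive Metropolis-within-Gibbs sampler for hierarchical beta / Gaussian
// regression with an optional phylogenetic (MVN) random effect.
//
// Model:
//   eta_i = x_i' beta + u_i
//   gaussian: y_i ~ N(eta_i, sigma_e^2)
//   beta:     y_i ~ Beta(mu_i * phi, (1 - mu_i) * phi), logit(mu_i) = eta_i
//   u ~ MVN(0, sigma_p^2 * C), C a normalized phylogenetic correlation
// Priors: flat on beta; half-t(nu, 0, scale) on sigma_p and sigma_e;
// Gamma(shape, rate) on phi.
//
// All randomness comes from R's RNG so seeds set in R control the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int FAM_GAUSSIAN = 0;
static const int FAM_BETA = 1;

// log density of one observation given its linear predictor
static inline double ll_obs(double y, double eta, double disp, int family,
                            double logy, double log1my) {
  if (family == FAM_GAUSSIAN) {
    double r = y - eta;
    return -std::log(disp) - 0.5 * r * r / (disp * disp);
  }
  double mu = 1.0 / (1.0 + std::exp(-eta));
  double a = mu * disp, b = (1.0 - mu) * disp;
  if (!(a > 0.0) || !(b > 0.0)) return R_NegInf;
  return R::lgammafn(disp) - R::lgammafn(a) - R::lgammafn(b)
       + (a - 1.0) * logy + (b - 1.0) * log1my;
}

static double ll_full(const arma::vec& y, const arma::vec& eta, double disp,
                      int family, const arma::vec& logy,
                      const arma::vec& log1my) {
  double s = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i)
    s += ll_obs(y[i], eta[i], disp, family, logy[i], log1my[i]);
  return s;
}

// half-Student-t log density on a standard deviation, up to a constant
static inline double half_t_lpdf(double x, double nu, double s) {
  return -0.5 * (nu + 1.0) * std::log1p(x * x / (nu * s * s));
}

// Robbins-Monro style scale adaptation toward a target acceptance rate
static inline void adapt(double& lsd, double rate, int batch) {
  double step = std::min(0.25, 2.0 / std::sqrt(static_cast<double>(batch)));
  lsd += (rate - 0.44) * step;
  if (lsd < -8.0) lsd = -8.0;
  if (lsd > 4.0) lsd = 4.0;
}

// [[Rcpp::export]]
arma::mat run_chain_cpp(const arma::vec& y, const arma::mat& X,
                        const arma::mat& Cinv, int family, bool use_phylo,
                        int n_iter, int burnin, int thin,
                        double sd_prior_df, double sd_prior_scale,
                        double phi_prior_shape, double phi_prior_rate,
                        const arma::vec& beta_init, const arma::vec& u_init,
                        double sigma_p_init, double disp_init) {
  const arma::uword n = y.n_elem, p = X.n_cols;
  arma::vec logy(n, arma::fill::zeros), log1my(n, arma::fill::zeros);
  if (family == FAM_BETA) { logy = arma::log(y); log1my = arma::log1p(-y); }

  arma::vec beta = beta_init;
  arma::vec u = use_phylo ? u_init : arma::vec(n, arma::fill::zeros);
  double sigma_p = sigma_p_init, disp = disp_init;

  arma::vec eta = X * beta + u;
  arma::vec v = use_phylo ? arma::vec(Cinv * u) : arma::vec(n, arma::fill::zeros);
  double quad = use_phylo ? arma::dot(u, v) : 0.0;
  double ll = ll_full(y, eta, disp, family, logy, log1my);

  // precomputations for the likelihood-invariant translation moves
  arma::mat WX;       // Cinv * X
  arma::vec xCx(p);   // X_j' Cinv X_j
  arma::mat Rprec;    // upper Cholesky of Cinv; solve(Rprec, z) ~ N(0, C)
  if (use_phylo) {
    WX = Cinv * X;
    for (arma::uword j = 0; j < p; ++j) xCx[j] = arma::dot(X.col(j), WX.col(j));
    Rprec = arma::chol(Cinv);
  }

  // proposal log-sds and batch acceptance counters
  arma::vec ls_beta(p, arma::fill::value(-1.0)), acc_beta(p, arma::fill::zeros);
  arma::vec ls_tr(p, arma::fill::value(-1.0)), acc_tr(p, arma::fill::zeros);
  arma::vec ls_u(n, arma::fill::value(-0.7)), acc_u(n, arma::fill::zeros);
  double ls_uj = -2.0, acc_uj = 0.0;
  double ls_sp = -1.5, acc_sp = 0.0;
  double ls_spnc = -1.5, acc_spnc = 0.0;
  double ls_disp = -1.5, acc_disp = 0.0;
  const int batch_len = 50;
  int batch = 0;

  const int n_keep = (n_iter - burnin) / thin;
  const arma::uword n_par = p + (use_phylo ? 2 + n : 1);
  arma::mat out(n_keep, n_par);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // fixed effects, one at a time (flat prior); repeated sweeps since each
    // costs only O(n) against the O(n^2) species-effect cycle
    for (int sweep = 0; sweep < 3; ++sweep)
    for (arma::uword j = 0; j < p; ++j) {
      double delta = R::rnorm(0.0, std::exp(ls_beta[j]));
      arma::vec eta_prop = eta + delta * X.col(j);
      double ll_prop = ll_full(y, eta_prop, disp, family, logy, log1my);
      if (std::log(R::runif(0.0, 1.0)) < ll_prop - ll) {
        beta[j] += delta; eta = eta_prop; ll = ll_prop; acc_beta[j] += 1.0;
      }
    }

    if (use_phylo) {
      double sp2 = sigma_p * sigma_p;
      // species effects: two kinds of univariate update with O(n) deltas.
      // (a) random-walk MH on u_i;
      // (b) an independence draw from the prior full conditional
      //     u_i | u_-i ~ N(u_i - v_i / Cinv_ii, sigma_p^2 / Cinv_ii),
      //     accepted on the likelihood ratio alone -- essential for tips
      //     whose effects are almost perfectly coupled by short branches.
      for (int sweep = 0; sweep < 2; ++sweep)
      for (arma::uword i = 0; i < n; ++i) {
        double delta;
        bool rw = (sweep == 0);
        if (rw) {
          delta = R::rnorm(0.0, std::exp(ls_u[i]));
        } else {
          double m_i = u[i] - v[i] / Cinv(i, i);
          delta = m_i + std::sqrt(sp2 / Cinv(i, i)) * R::rnorm(0.0, 1.0) - u[i];
        }
        double dll = ll_obs(y[i], eta[i] + delta, disp, family,
                            logy[i], log1my[i])
                   - ll_obs(y[i], eta[i], disp, family, logy[i], log1my[i]);
        double dquad = 2.0 * delta * v[i] + delta * delta * Cinv(i, i);
        double logacc = rw ? dll - 0.5 * dquad / sp2 : dll;
        if (std::log(R::runif(0.0, 1.0)) < logacc) {
          u[i] += delta; eta[i] += delta; quad += dquad;
          v += delta * Cinv.col(i); ll += dll;
          if (rw) acc_u[i] += 1.0;
        }
      }

      // joint move along the prior correlation: u' = u + s * sigma_p * x with
      // x ~ N(0, C); explores coherent directions the single-site updates
      // traverse slowly
      {
        double s = std::exp(ls_uj);
        arma::vec z(n);
        for (arma::uword i = 0; i < n; ++i) z[i] = R::rnorm(0.0, 1.0);
        arma::vec x = arma::solve(arma::trimatu(Rprec), z);
        arma::vec step = s * sigma_p * x;
        arma::vec eta_prop = eta + step;
        double ll_prop = ll_full(y, eta_prop, disp, family, logy, log1my);
        double dquad = 2.0 * arma::dot(step, v)
                     + s * s * sp2 * arma::dot(z, z);
        if (std::log(R::runif(0.0, 1.0)) < ll_prop - ll - 0.5 * dquad / sp2) {
          u += step; eta = eta_prop; v += Rprec.t() * (s * sigma_p * z);
          quad += dquad; ll = ll_prop; acc_uj += 1.0;
        }
      }

      // translation moves: beta_j += delta, u -= delta * X_j leaves eta (and
      // the likelihood) unchanged; acceptance is driven by the MVN prior on
      // u. Breaks the posterior ridge between fixed and species effects.
      for (arma::uword j = 0; j < p; ++j) {
        double delta = R::rnorm(0.0, std::exp(ls_tr[j]));
        double dquad = -2.0 * delta * arma::dot(X.col(j), v)
                     + delta * delta * xCx[j];
        if (std::log(R::runif(0.0, 1.0)) < -0.5 * dquad / sp2) {
          beta[j] += delta; u -= delta * X.col(j); v -= delta * WX.col(j);
          quad += dquad; acc_tr[j] += 1.0;
        }
      }

      // sigma_p, centered move (u fixed)
      for (int rep = 0; rep < 2; ++rep) {
        double e = R::rnorm(0.0, std::exp(ls_sp));
        double sp_new = sigma_p * std::exp(e);
        double dn = static_cast<double>(n);
        double d = half_t_lpdf(sp_new, sd_prior_df, sd_prior_scale)
                 - half_t_lpdf(sigma_p, sd_prior_df, sd_prior_scale)
                 + e  // Jacobian of the log-scale walk
                 - dn * std::log(sp_new) - 0.5 * quad / (sp_new * sp_new)
                 + dn * std::log(sigma_p) + 0.5 * quad / (sigma_p * sigma_p);
        if (std::log(R::runif(0.0, 1.0)) < d) { sigma_p = sp_new; acc_sp += 1.0; }
      }

      // sigma_p, non-centered scale move (u/sigma_p fixed): the MVN prior
      // term and the Jacobian cancel, leaving likelihood x half-t ratio
      for (int rep = 0; rep < 2; ++rep) {
        double e = R::rnorm(0.0, std::exp(ls_spnc));
        double r = std::exp(e);
        double sp_new = sigma_p * r;
        arma::vec eta_prop = eta + (r - 1.0) * u;
        double ll_prop = ll_full(y, eta_prop, disp, family, logy, log1my);
        double d = ll_prop - ll
                 + half_t_lpdf(sp_new, sd_prior_df, sd_prior_scale)
                 - half_t_lpdf(sigma_p, sd_prior_df, sd_prior_scale)
                 + e;
        if (std::log(R::runif(0.0, 1.0)) < d) {
          u *= r; v *= r; quad *= r * r; eta = eta_prop;
          sigma_p = sp_new; ll = ll_prop; acc_spnc += 1.0;
        }
      }
    }

    // dispersion: sigma_e (gaussian) or phi (beta), log-scale walk
    for (int rep = 0; rep < 3; ++rep) {
      double e = R::rnorm(0.0, std::exp(ls_disp));
      double d_new = disp * std::exp(e);
      double ll_prop = ll_full(y, eta, d_new, family, logy, log1my);
      double dprior;
      if (family == FAM_GAUSSIAN)
        dprior = half_t_lpdf(d_new, sd_prior_df, sd_prior_scale)
               - half_t_lpdf(disp, sd_prior_df, sd_prior_scale) + e;
      else
        dprior = phi_prior_shape * (std::log(d_new) - std::log(disp))
               - phi_prior_rate * (d_new - disp);
      if (std::log(R::runif(0.0, 1.0)) < ll_prop - ll + dprior) {
        disp = d_new; ll = ll_prop; acc_disp += 1.0;
      }
    }

    // adapt proposal scales during burn-in only (detailed balance afterwards)
    if (it <= burnin && it % batch_len == 0) {
      ++batch;
      for (arma::uword j = 0; j < p; ++j) {
        adapt(ls_beta[j], acc_beta[j] / (3.0 * batch_len), batch);
        acc_beta[j] = 0.0;
      }
      if (use_phylo) {
        for (arma::uword i = 0; i < n; ++i) {
          adapt(ls_u[i], acc_u[i] / batch_len, batch); acc_u[i] = 0.0;
        }
        for (arma::uword j = 0; j < p; ++j) {
          adapt(ls_tr[j], acc_tr[j] / batch_len, batch); acc_tr[j] = 0.0;
        }
        // multivariate proposal: aim lower than the univariate 0.44
        {
          double step = std::min(0.25, 2.0 / std::sqrt(static_cast<double>(batch)));
          ls_uj += (acc_uj / batch_len - 0.234) * step;
          acc_uj = 0.0;
        }
        adapt(ls_sp, acc_sp / (2.0 * batch_len), batch); acc_sp = 0.0;
        adapt(ls_spnc, acc_spnc / (2.0 * batch_len), batch); acc_spnc = 0.0;
      }
      adapt(ls_disp, acc_disp / (3.0 * batch_len), batch); acc_disp = 0.0;
    }

    if (it > burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      arma::uword k = 0;
      for (arma::uword j = 0; j < p; ++j) out(kept, k++) = beta[j];
      if (use_phylo) out(kept, k++) = sigma_p;
      out(kept, k++) = disp;
      if (use_phylo) for (arma::uword i = 0; i < n; ++i) out(kept, k++) = u[i];
      ++kept;
    }
  }
  return out;
}
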