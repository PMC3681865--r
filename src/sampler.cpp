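// Metropolis-within-Gibbs sampler for the LHFI model.
//
// Latent health H_i and the metric/group effects (whose full conditionals
// involve the multinomial observation model) are updated by adaptive
// random-walk Metropolis; the Gaussian regression layers (health-on-covariates,
// salinity-on-DD) and all variances/covariances are conjugate Gibbs updates.
// All randomness comes from R's RNG so that set.seed() on the R side gives
// bit-reproducible chains.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct ModelData {
  arma::mat y;          // nrec x 5 counts
  arma::vec total;      // nrec
  arma::uvec site;      // nrec, 0-based
  arma::mat X;          // S x p centered design
  arma::uvec month;     // S, 0 = Sep, 1 = Oct
  arma::vec s_c, d_c;   // centered salinity / dd (two-level)
  int S = 0, p = 0, nrec = 0;
  std::vector<std::vector<int>> site_recs;
  double lg_const = 0.0;  // multinomial normalizing constants (both groups)
};

// log(1 + sum(exp(e))) with overflow guard
double lse0(const arma::vec& e) {
  double m = 0.0;
  for (arma::uword i = 0; i < e.n_elem; ++i) m = std::max(m, e(i));
  double s = std::exp(-m);
  for (arma::uword i = 0; i < e.n_elem; ++i) s += std::exp(e(i) - m);
  return m + std::log(s);
}

// multinomial log kernel of record r for the plus group (metrics 1-2)
double plus_kernel(const ModelData& d, int r, double H, const arma::vec& gamma) {
  arma::vec e(2);
  e(0) = gamma(0) + H;
  e(1) = gamma(1) + H;
  return d.y(r, 0) * e(0) + d.y(r, 1) * e(1) - d.total(r) * lse0(e);
}

// multinomial log kernel of record r for the minus group (metrics 3-5)
double minus_kernel(const ModelData& d, int r, double H, double delta,
                    const arma::vec& gamma) {
  arma::vec e(3);
  for (int m = 0; m < 3; ++m) e(m) = delta + gamma(2 + m) - H;
  double ll = 0.0;
  for (int m = 0; m < 3; ++m) ll += d.y(r, 2 + m) * e(m);
  return ll - d.total(r) * lse0(e);
}

double site_obs_kernel(const ModelData& d, int i, double H, double delta,
                       const arma::vec& gamma) {
  double ll = 0.0;
  for (int r : d.site_recs[i])
    ll += plus_kernel(d, r, H, gamma) + minus_kernel(d, r, H, delta, gamma);
  return ll;
}

double obs_kernel_all(const ModelData& d, const arma::vec& H, double delta,
                      const arma::vec& gamma) {
  double ll = 0.0;
  for (int r = 0; r < d.nrec; ++r) {
    double h = H(d.site(r));
    ll += plus_kernel(d, r, h, gamma) + minus_kernel(d, r, h, delta, gamma);
  }
  return ll;
}

// kernel restricted to the group containing metric m (for gamma updates)
double group_kernel_all(const ModelData& d, const arma::vec& H, double delta,
                        const arma::vec& gamma, bool plus) {
  double ll = 0.0;
  for (int r = 0; r < d.nrec; ++r) {
    double h = H(d.site(r));
    ll += plus ? plus_kernel(d, r, h, gamma) : minus_kernel(d, r, h, delta, gamma);
  }
  return ll;
}

double rnorm1() { return norm_rand(); }

// variance draw from inverse-Gamma(shape, scale)
double rinvgamma(double shape, double scale) {
  return 1.0 / R::rgamma(shape, 1.0 / scale);
}

// draw from N(mean, V) via Cholesky
arma::vec rmvnorm1(const arma::vec& mean, const arma::mat& V) {
  arma::mat L = arma::chol(arma::symmatu(V), "lower");
  arma::vec z(mean.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = rnorm1();
  return mean + L * z;
}

// inverse-Wishart(df, Psi) draw via Bartlett decomposition, R RNG
arma::mat riwish(double df, const arma::mat& Psi) {
  int q = Psi.n_rows;
  arma::mat L = arma::chol(arma::symmatu(arma::inv_sympd(Psi)), "lower");
  arma::mat A(q, q, arma::fill::zeros);
  for (int i = 0; i < q; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = rnorm1();
  }
  arma::mat W = L * A;           // chol factor of Wishart(df, Psi^-1)
  arma::mat Wmat = W * W.t();
  return arma::inv_sympd(arma::symmatu(Wmat));
}

// conditional N(mean, var) of gamma[m] | gamma[-m] under MVN(0, Sigma)
void gamma_conditional(const arma::mat& Sigma, const arma::vec& gamma, int m,
                       double& mean, double& var) {
  arma::uvec idx(4);
  int k = 0;
  for (int j = 0; j < 5; ++j) if (j != m) idx(k++) = j;
  arma::mat S22 = Sigma.submat(idx, idx);
  arma::rowvec s12 = Sigma.row(m);
  arma::vec s12v(4);
  for (int j = 0; j < 4; ++j) s12v(j) = s12(idx(j));
  arma::vec w = arma::solve(S22, s12v);
  arma::vec g2 = gamma.elem(idx);
  mean = arma::dot(w, g2);
  var = Sigma(m, m) - arma::dot(w, s12v);
  if (var < 1e-12) var = 1e-12;
}

struct Adapt {
  double lstep = 0.0;
  int acc = 0, tries = 0, batch = 0;
  double step() const { return std::exp(lstep); }
  void tally(bool a) { ++tries; if (a) ++acc; }
  void maybe_adapt() {
    if (tries >= 50) {
      ++batch;
      double d = std::min(0.05, 1.0 / std::sqrt((double)batch));
      if ((double)acc / tries > 0.44) lstep += d; else lstep -= d;
      acc = 0; tries = 0;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".sampler_cpp")]]
List sampler_cpp(List data_in, List spec_in, List priors_in, List init,
                 List control) {
  ModelData d;
  d.y = as<arma::mat>(data_in["y"]);
  d.total = as<arma::vec>(data_in["total"]);
  d.site = as<arma::uvec>(data_in["site"]);  // 0-based
  d.X = as<arma::mat>(data_in["X"]);
  d.month = as<arma::uvec>(data_in["month"]);
  d.S = d.X.n_rows;
  d.p = d.X.n_cols;
  d.nrec = d.y.n_rows;
  d.site_recs.assign(d.S, {});
  for (int r = 0; r < d.nrec; ++r) d.site_recs[d.site(r)].push_back(r);
  for (int r = 0; r < d.nrec; ++r) {
    double yp = d.y(r, 0) + d.y(r, 1), ym = d.y(r, 2) + d.y(r, 3) + d.y(r, 4);
    d.lg_const += 2.0 * std::lgamma(d.total(r) + 1.0);
    for (int m = 0; m < 5; ++m) d.lg_const -= std::lgamma(d.y(r, m) + 1.0);
    d.lg_const -= std::lgamma(d.total(r) - yp + 1.0);
    d.lg_const -= std::lgamma(d.total(r) - ym + 1.0);
  }

  const bool two_level = as<bool>(spec_in["two_level"]);
  const bool bivariate = as<bool>(spec_in["b_bivariate"]);
  const bool month_var = as<bool>(spec_in["month_specific_variance"]);
  const int structure = as<int>(spec_in["structure"]);  // 0 iid, 1 block, 2 full
  if (two_level) {
    d.s_c = as<arma::vec>(data_in["s_c"]);
    d.d_c = as<arma::vec>(data_in["d_c"]);
  }

  const double nv = as<double>(priors_in["normal_variance"]);
  const double ig_a = as<double>(priors_in["ig_shape"]);
  const double ig_b = as<double>(priors_in["ig_scale"]);
  const double w_off = as<double>(priors_in["wishart_df_offset"]);
  const double w_scale = as<double>(priors_in["wishart_scale"]);

  const int n_iter = as<int>(control["n_iter"]);
  const int adapt_until = as<int>(control["adapt_until"]);
  List upd = control["update"];
  const bool upd_H = as<bool>(upd["H"]);
  const bool upd_delta = as<bool>(upd["delta"]);
  const bool upd_gamma = as<bool>(upd["gamma"]);
  const bool upd_beta = as<bool>(upd["beta"]);
  const bool upd_sigma_eps = as<bool>(upd["sigma_eps"]);
  const bool upd_gamma_var = as<bool>(upd["gamma_var"]);
  const bool upd_b = as<bool>(upd["b"]);

  // state
  arma::vec H = as<arma::vec>(init["H"]);
  double delta = as<double>(init["delta_minus"]);
  arma::vec gamma = as<arma::vec>(init["gamma"]);
  double beta0 = as<double>(init["beta0"]);
  arma::vec beta = as<arma::vec>(init["beta"]);
  arma::vec sig_eps = as<arma::vec>(init["sigma_eps"]);  // length 1 or 2
  double sig_gamma = as<double>(init["sigma_gamma"]);
  arma::mat Sigma = as<arma::mat>(init["Sigma"]);        // full 5x5
  double b0 = as<double>(init["b0"]), b1 = as<double>(init["b1"]);
  double sig_s = as<double>(init["sigma_s"]), rho = as<double>(init["rho"]);

  std::vector<Adapt> ad_H(d.S);
  Adapt ad_delta;
  std::vector<Adapt> ad_gamma(5);

  // rho grid (griddy Gibbs)
  const int K = 199;
  arma::vec rho_grid(K), rho_logw(K);
  for (int k = 0; k < K; ++k) rho_grid(k) = -0.99 + 1.98 * k / (K - 1.0);

  const int n_sig_eps = month_var ? 2 : 1;
  int n_sig_cols = (structure == 0) ? 1 : (structure == 1 ? 9 : 15);
  int npar = d.S + 1 + 5 + 1 + d.p + n_sig_eps + n_sig_cols +
             (two_level ? 3 + (bivariate ? 1 : 0) : 0) + (two_level ? 2 : 1);
  arma::mat out(n_iter, npar);

  arma::mat Xt(d.S, d.p + 1, arma::fill::ones);
  if (d.p > 0) Xt.cols(1, d.p) = d.X;
  arma::mat Z;
  if (two_level) {
    Z.set_size(d.S, 2);
    Z.col(0).ones();
    Z.col(1) = d.d_c;
  }

  bool divergent = false;

  for (int it = 0; it < n_iter; ++it) {
    const bool adapting = it < adapt_until;

    // per-site latent regression mean and sd
    arma::vec mu = Xt * arma::join_cols(arma::vec{beta0}, beta);
    arma::vec sd_site(d.S);
    for (int i = 0; i < d.S; ++i)
      sd_site(i) = month_var ? sig_eps(d.month(i)) : sig_eps(0);

    if (upd_H) {
      for (int i = 0; i < d.S; ++i) {
        double cur = H(i);
        double prop = cur + ad_H[i].step() * rnorm1();
        double la = site_obs_kernel(d, i, prop, delta, gamma) -
                    site_obs_kernel(d, i, cur, delta, gamma) +
                    R::dnorm(prop, mu(i), sd_site(i), 1) -
                    R::dnorm(cur, mu(i), sd_site(i), 1);
        bool acc = std::log(unif_rand()) < la;
        if (acc) H(i) = prop;
        if (adapting) { ad_H[i].tally(acc); ad_H[i].maybe_adapt(); }
      }
    }

    if (upd_delta) {
      double prop = delta + ad_delta.step() * rnorm1();
      double la = group_kernel_all(d, H, prop, gamma, false) -
                  group_kernel_all(d, H, delta, gamma, false) +
                  R::dnorm(prop, 0.0, std::sqrt(nv), 1) -
                  R::dnorm(delta, 0.0, std::sqrt(nv), 1);
      bool acc = std::log(unif_rand()) < la;
      if (acc) delta = prop;
      if (adapting) { ad_delta.tally(acc); ad_delta.maybe_adapt(); }
    }

    if (upd_gamma) {
      for (int m = 0; m < 5; ++m) {
        bool plus = m < 2;
        double pm, pv;
        if (structure == 0) { pm = 0.0; pv = sig_gamma * sig_gamma; }
        else gamma_conditional(Sigma, gamma, m, pm, pv);
        arma::vec gprop = gamma;
        gprop(m) = gamma(m) + ad_gamma[m].step() * rnorm1();
        double la = group_kernel_all(d, H, delta, gprop, plus) -
                    group_kernel_all(d, H, delta, gamma, plus) +
                    R::dnorm(gprop(m), pm, std::sqrt(pv), 1) -
                    R::dnorm(gamma(m), pm, std::sqrt(pv), 1);
        bool acc = std::log(unif_rand()) < la;
        if (acc) gamma = gprop;
        if (adapting) { ad_gamma[m].tally(acc); ad_gamma[m].maybe_adapt(); }
      }
    }

    // Hierarchical recentering: exact Gibbs moves along the two
    // likelihood-invariant ridges that otherwise cripple mixing.
    // (a) delta <- delta + c, gamma_minus <- gamma_minus - c
    // (b) gamma_plus <- gamma_plus + c, H <- H - c, delta <- delta - c,
    //     beta0 <- beta0 - c   (latent-regression residuals unchanged)
    if (upd_delta && upd_gamma) {
      arma::mat Sg = (structure == 0)
        ? arma::mat(arma::eye(5, 5) * (sig_gamma * sig_gamma)) : Sigma;
      arma::vec e_m(5, arma::fill::zeros), e_p(5, arma::fill::zeros);
      e_m(2) = e_m(3) = e_m(4) = 1.0;
      e_p(0) = e_p(1) = 1.0;
      arma::vec Sig_g = arma::solve(Sg, gamma);
      arma::vec Sig_em = arma::solve(Sg, e_m);
      {
        double tau = 1.0 / nv + arma::dot(e_m, Sig_em);
        double mn = (-delta / nv + arma::dot(e_m, Sig_g)) / tau;
        double c = mn + rnorm1() / std::sqrt(tau);
        delta += c;
        for (int m = 2; m < 5; ++m) gamma(m) -= c;
      }
      if (upd_H && upd_beta) {
        arma::vec Sig_ep = arma::solve(Sg, e_p);
        Sig_g = arma::solve(Sg, gamma);
        double tau = 2.0 / nv + arma::dot(e_p, Sig_ep);
        double mn = (delta / nv + beta0 / nv - arma::dot(e_p, Sig_g)) / tau;
        double c = mn + rnorm1() / std::sqrt(tau);
        gamma(0) += c; gamma(1) += c;
        H -= c; delta -= c; beta0 -= c;
      }
    }

    if (upd_beta) {
      arma::vec w(d.S);
      for (int i = 0; i < d.S; ++i) w(i) = 1.0 / (sd_site(i) * sd_site(i));
      arma::mat A = Xt.t() * (Xt.each_col() % w) +
                    arma::eye(d.p + 1, d.p + 1) / nv;
      arma::vec rhs = Xt.t() * (w % H);
      arma::mat V = arma::inv_sympd(arma::symmatu(A));
      arma::vec bdraw = rmvnorm1(V * rhs, V);
      beta0 = bdraw(0);
      if (d.p > 0) beta = bdraw.subvec(1, d.p);
      mu = Xt * bdraw;
    }

    if (upd_sigma_eps) {
      if (month_var) {
        for (int t = 0; t < 2; ++t) {
          double rss = 0.0; int n_t = 0;
          for (int i = 0; i < d.S; ++i) if ((int)d.month(i) == t) {
            double r = H(i) - mu(i); rss += r * r; ++n_t;
          }
          sig_eps(t) = std::sqrt(rinvgamma(ig_a + n_t / 2.0, ig_b + rss / 2.0));
        }
      } else {
        double rss = 0.0;
        for (int i = 0; i < d.S; ++i) { double r = H(i) - mu(i); rss += r * r; }
        sig_eps(0) = std::sqrt(rinvgamma(ig_a + d.S / 2.0, ig_b + rss / 2.0));
      }
    }

    if (upd_gamma_var) {
      if (structure == 0) {
        sig_gamma = std::sqrt(rinvgamma(ig_a + 2.5, ig_b + arma::dot(gamma, gamma) / 2.0));
      } else if (structure == 1) {
        arma::vec gp = gamma.subvec(0, 1), gm = gamma.subvec(2, 4);
        arma::mat Spp = riwish(2 + w_off + 1, w_scale * arma::eye(2, 2) + gp * gp.t());
        arma::mat Smm = riwish(3 + w_off + 1, w_scale * arma::eye(3, 3) + gm * gm.t());
        Sigma.zeros();
        Sigma.submat(0, 0, 1, 1) = Spp;
        Sigma.submat(2, 2, 4, 4) = Smm;
      } else {
        Sigma = riwish(5 + w_off + 1, w_scale * arma::eye(5, 5) + gamma * gamma.t());
      }
    }

    if (two_level && upd_b) {
      arma::mat Rinv(2, 2, arma::fill::eye);
      if (bivariate) {
        double det = 1.0 - rho * rho;
        Rinv(0, 0) = 1.0 / det; Rinv(1, 1) = 1.0 / det;
        Rinv(0, 1) = Rinv(1, 0) = -rho / det;
      }
      arma::mat A = Z.t() * Z / (sig_s * sig_s) + Rinv / nv;
      arma::vec rhs = Z.t() * d.s_c / (sig_s * sig_s);
      arma::mat V = arma::inv_sympd(arma::symmatu(A));
      arma::vec bd = rmvnorm1(V * rhs, V);
      b0 = bd(0); b1 = bd(1);
      arma::vec res = d.s_c - Z * bd;
      sig_s = std::sqrt(rinvgamma(ig_a + d.S / 2.0, ig_b + arma::dot(res, res) / 2.0));
      if (bivariate) {
        for (int k = 0; k < K; ++k) {
          double r = rho_grid(k), det = 1.0 - r * r;
          double q = (b0 * b0 - 2.0 * r * b0 * b1 + b1 * b1) / det;
          rho_logw(k) = -0.5 * std::log(det) - q / (2.0 * nv);
        }
        double mx = rho_logw.max();
        arma::vec wgt = arma::exp(rho_logw - mx);
        double u = unif_rand() * arma::accu(wgt), csum = 0.0;
        for (int k = 0; k < K; ++k) {
          csum += wgt(k);
          if (u <= csum || k == K - 1) { rho = rho_grid(k); break; }
        }
      }
    }

    // deviance: -2 * observation loglik (and salinity loglik) at current state
    double dev_obs = -2.0 * (obs_kernel_all(d, H, delta, gamma) + d.lg_const);
    double dev_sal = 0.0;
    if (two_level) {
      double ll = 0.0;
      for (int i = 0; i < d.S; ++i)
        ll += R::dnorm(d.s_c(i), b0 + b1 * d.d_c(i), sig_s, 1);
      dev_sal = -2.0 * ll;
    }

    int c = 0;
    for (int i = 0; i < d.S; ++i) out(it, c++) = H(i);
    out(it, c++) = delta;
    for (int m = 0; m < 5; ++m) out(it, c++) = gamma(m);
    out(it, c++) = beta0;
    for (int j = 0; j < d.p; ++j) out(it, c++) = beta(j);
    for (int t = 0; t < n_sig_eps; ++t) out(it, c++) = sig_eps(t);
    if (structure == 0) {
      out(it, c++) = sig_gamma;
    } else if (structure == 1) {
      out(it, c++) = Sigma(0, 0); out(it, c++) = Sigma(0, 1); out(it, c++) = Sigma(1, 1);
      out(it, c++) = Sigma(2, 2); out(it, c++) = Sigma(2, 3); out(it, c++) = Sigma(2, 4);
      out(it, c++) = Sigma(3, 3); out(it, c++) = Sigma(3, 4); out(it, c++) = Sigma(4, 4);
    } else {
      for (int i = 0; i < 5; ++i)
        for (int j = i; j < 5; ++j) out(it, c++) = Sigma(i, j);
    }
    if (two_level) {
      out(it, c++) = b0; out(it, c++) = b1; out(it, c++) = sig_s;
      if (bivariate) out(it, c++) = rho;
    }
    out(it, c++) = dev_obs;
    if (two_level) out(it, c++) = dev_sal;

    if (!out.row(it).is_finite()) divergent = true;
  }

  return List::create(
    _["draws"] = out,
    _["divergent"] = divergent
  );
}
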