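// Gibbs samplers for the random-intercept mixed models used in the
// repeatability and correlation-decomposition analyses.  All conjugate
// updates; R's RNG is used throughout so results are reproducible via
// set.seed() on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec rmvnorm_prec(const arma::vec &rhs, const arma::mat &prec) {
  // Draw from N(prec^{-1} rhs, prec^{-1}) given the precision matrix.
  arma::mat U = arma::chol(prec);            // prec = U'U, U upper
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), rhs));
  arma::vec z(rhs.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z[i] = norm_rand();
  return mu + arma::solve(arma::trimatu(U), z);
}

static double rinvgamma(double shape, double scale) {
  // X ~ IG(shape, scale) <=> 1/X ~ Gamma(shape, rate = scale)
  double g = R::rgamma(shape, 1.0 / scale);
  if (g < 1e-300) g = 1e-300;
  return 1.0 / g;
}

static arma::mat rinvwishart2(double df, const arma::mat &scale) {
  // Bartlett decomposition; scale is the inverse-Wishart scale matrix.
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(scale));
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(2, 2, arma::fill::zeros);
  A(0, 0) = std::sqrt(R::rchisq(df));
  A(1, 1) = std::sqrt(R::rchisq(df - 1.0));
  A(1, 0) = norm_rand();
  arma::mat LA = L * A;
  arma::mat W = LA * LA.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// Univariate Gaussian mixed model y = X beta + u[fish] + e.
// include_random = false gives the fixed-effects-only (V_ind constrained to
// zero) model used for the Delta-DIC significance test.
// [[Rcpp::export(name = ".gibbs_lmm")]]
List gibbs_lmm(const arma::vec &y, const arma::mat &X,
               const arma::ivec &fish, int q, int nitt, int burnin, int thin,
               double nu_ind, double V_ind_prior, double nu_e,
               double V_e_prior, double beta_prior_var, bool include_random) {
  const int n = y.n_elem, p = X.n_cols;
  const int m = (nitt - burnin) / thin;
  arma::mat XtX = X.t() * X;

  arma::vec beta(p, arma::fill::zeros);
  arma::vec u(q, arma::fill::zeros);
  double Ve = arma::var(y);
  if (!(Ve > 0)) Ve = 1.0;
  double Vind = include_random ? Ve / 2.0 : 0.0;

  arma::ivec nfish(q, arma::fill::zeros);
  for (int i = 0; i < n; ++i) nfish[fish[i]] += 1;

  arma::mat beta_draws(m, p), u_draws(m, q, arma::fill::zeros);
  arma::vec Vind_draws(m), Ve_draws(m), dev_draws(m);

  int kept = 0;
  for (int it = 1; it <= nitt; ++it) {
    // beta | .
    arma::vec yadj = y;
    if (include_random)
      for (int i = 0; i < n; ++i) yadj[i] -= u[fish[i]];
    arma::mat prec = XtX / Ve;
    prec.diag() += 1.0 / beta_prior_var;
    beta = rmvnorm_prec(X.t() * yadj / Ve, prec);

    arma::vec resid = y - X * beta;

    if (include_random) {
      // u_i | .
      arma::vec rsum(q, arma::fill::zeros);
      for (int i = 0; i < n; ++i) rsum[fish[i]] += resid[i];
      for (int j = 0; j < q; ++j) {
        double v = 1.0 / (nfish[j] / Ve + 1.0 / Vind);
        u[j] = v * rsum[j] / Ve + std::sqrt(v) * norm_rand();
      }
      // V_ind | u
      Vind = rinvgamma(0.5 * (nu_ind + q),
                       0.5 * (nu_ind * V_ind_prior + arma::dot(u, u)));
      if (Vind < 1e-12) Vind = 1e-12;
    }

    // V_e | .
    double ssr = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = resid[i] - (include_random ? u[fish[i]] : 0.0);
      ssr += e * e;
    }
    Ve = rinvgamma(0.5 * (nu_e + n), 0.5 * (nu_e * V_e_prior + ssr));
    if (Ve < 1e-12) Ve = 1e-12;

    if (it > burnin && (it - burnin) % thin == 0) {
      double dev = 0.0;
      for (int i = 0; i < n; ++i) {
        double mu = arma::dot(X.row(i), beta) +
                    (include_random ? u[fish[i]] : 0.0);
        dev += R::dnorm(y[i], mu, std::sqrt(Ve), 1);
      }
      beta_draws.row(kept) = beta.t();
      if (include_random) u_draws.row(kept) = u.t();
      Vind_draws[kept] = include_random ? Vind : 0.0;
      Ve_draws[kept] = Ve;
      dev_draws[kept] = -2.0 * dev;
      ++kept;
    }
  }

  return List::create(_["beta"] = beta_draws, _["u"] = u_draws,
                      _["Vind"] = Vind_draws, _["Ve"] = Ve_draws,
                      _["deviance"] = dev_draws);
}

// Bivariate Gaussian mixed model: Y (n x 2) = X B + U[fish, ] + E,
// rows of U ~ N(0, Sigma_ind), rows of E ~ N(0, Sigma_e), inverse-Wishart
// priors IW(df = nu, scale = nu * V).  constrain_ind / constrain_e force the
// corresponding covariance matrix diagonal (off-diagonal fixed at zero, the
// variances sampled from element-wise inverse-gamma conditionals).
// [[Rcpp::export(name = ".gibbs_bivariate")]]
List gibbs_bivariate(const arma::mat &Y, const arma::mat &X,
                     const arma::ivec &fish, int q, int nitt, int burnin,
                     int thin, double nu_ind, const arma::mat &V_ind_prior,
                     double nu_e, const arma::mat &V_e_prior,
                     double beta_prior_var, bool constrain_ind,
                     bool constrain_e) {
  const int n = Y.n_rows, p = X.n_cols;
  const int m = (nitt - burnin) / thin;
  arma::mat XtX = X.t() * X;

  arma::mat B(p, 2, arma::fill::zeros);
  arma::mat U(q, 2, arma::fill::zeros);
  arma::mat Se = arma::cov(Y);
  Se.diag() += 1e-8;
  if (constrain_e) Se(0, 1) = Se(1, 0) = 0.0;
  arma::mat Si = Se / 2.0;
  if (constrain_ind) Si(0, 1) = Si(1, 0) = 0.0;

  arma::ivec nfish(q, arma::fill::zeros);
  for (int i = 0; i < n; ++i) nfish[fish[i]] += 1;

  arma::mat B_draws(m, 2 * p), U1_draws(m, q), U2_draws(m, q);
  arma::mat Si_draws(m, 3), Se_draws(m, 3);
  arma::vec dev_draws(m);

  int kept = 0;
  for (int it = 1; it <= nitt; ++it) {
    arma::mat W = arma::inv_sympd(arma::symmatu(Se));

    // vec(B) | .  (stacked trait-1 coefs then trait-2 coefs)
    arma::mat Yadj = Y;
    for (int i = 0; i < n; ++i) Yadj.row(i) -= U.row(fish[i]);
    arma::mat prec = arma::kron(W, XtX);
    prec.diag() += 1.0 / beta_prior_var;
    arma::vec rhs(2 * p);
    for (int j = 0; j < 2; ++j)
      rhs.subvec(j * p, j * p + p - 1) =
          X.t() * (Yadj * W.col(j));
    arma::vec b = rmvnorm_prec(rhs, prec);
    B.col(0) = b.subvec(0, p - 1);
    B.col(1) = b.subvec(p, 2 * p - 1);

    arma::mat resid = Y - X * B;

    // U | .
    arma::mat Siinv = arma::inv_sympd(arma::symmatu(Si));
    arma::mat rsum(q, 2, arma::fill::zeros);
    for (int i = 0; i < n; ++i) rsum.row(fish[i]) += resid.row(i);
    for (int j = 0; j < q; ++j) {
      arma::mat prec2 = nfish[j] * W + Siinv;
      arma::vec rhs2 = W * rsum.row(j).t();
      U.row(j) = rmvnorm_prec(rhs2, prec2).t();
    }

    // Sigma_ind | U
    if (constrain_ind) {
      for (int k = 0; k < 2; ++k)
        Si(k, k) = rinvgamma(0.5 * (nu_ind + q),
                             0.5 * (nu_ind * V_ind_prior(k, k) +
                                    arma::dot(U.col(k), U.col(k))));
      Si(0, 1) = Si(1, 0) = 0.0;
    } else {
      Si = rinvwishart2(nu_ind + q, nu_ind * V_ind_prior + U.t() * U);
    }

    // Sigma_e | .
    arma::mat E = resid;
    for (int i = 0; i < n; ++i) E.row(i) -= U.row(fish[i]);
    if (constrain_e) {
      for (int k = 0; k < 2; ++k)
        Se(k, k) = rinvgamma(0.5 * (nu_e + n),
                             0.5 * (nu_e * V_e_prior(k, k) +
                                    arma::dot(E.col(k), E.col(k))));
      Se(0, 1) = Se(1, 0) = 0.0;
    } else {
      Se = rinvwishart2(nu_e + n, nu_e * V_e_prior + E.t() * E);
    }

    if (it > burnin && (it - burnin) % thin == 0) {
      arma::mat We = arma::inv_sympd(arma::symmatu(Se));
      double lds, sign;
      arma::log_det(lds, sign, Se);
      double dev = 0.0;
      for (int i = 0; i < n; ++i) {
        arma::vec e = (resid.row(i) - U.row(fish[i])).t();
        dev += -0.5 * (2.0 * std::log(2.0 * M_PI) + lds +
                       arma::as_scalar(e.t() * We * e));
      }
      B_draws.row(kept) = b.t();
      U1_draws.row(kept) = U.col(0).t();
      U2_draws.row(kept) = U.col(1).t();
      Si_draws(kept, 0) = Si(0, 0);
      Si_draws(kept, 1) = Si(1, 1);
      Si_draws(kept, 2) = Si(0, 1);
      Se_draws(kept, 0) = Se(0, 0);
      Se_draws(kept, 1) = Se(1, 1);
      Se_draws(kept, 2) = Se(0, 1);
      dev_draws[kept] = -2.0 * dev;
      ++kept;
    }
  }

  return List::create(_["B"] = B_draws, _["U1"] = U1_draws,
                      _["U2"] = U2_draws, _["SigmaInd"] = Si_draws,
                      _["SigmaE"] = Se_draws, _["deviance"] = dev_draws);
}
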