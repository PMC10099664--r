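// Gibbs sampler for a bivariate (sucrose, yeast) linear mixed model with
// trait-specific population random intercepts and an unstructured 2x2
// residual covariance. All full conditionals are conjugate: multivariate
// normal for fixed and random effects, inverse-gamma for the per-trait
// random-intercept variances, inverse-Wishart for the residual covariance.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Wishart(df, S) draw via the Bartlett decomposition.
static arma::mat rwishart(double df, const arma::mat& S) {
  const int p = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) A(i, i) = std::sqrt(R::rchisq(df - i));
  for (int i = 1; i < p; ++i)
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  arma::mat LA = L * A;
  return LA * LA.t();
}

static arma::mat inv_pd(const arma::mat& M, int iter, const char* what) {
  arma::mat out;
  if (!arma::inv_sympd(out, M)) {
    stop("non-positive-definite %s update at iteration %d", what, iter + 1);
  }
  return out;
}

// [[Rcpp::export]]
List gibbs_bivariate_cpp(const arma::vec& ys, const arma::vec& yy,
                         const arma::mat& Xs, const arma::mat& Xy,
                         const arma::uvec& pop, const int npop,
                         const int n_iter, const int burnin, const int thin,
                         const double beta_prior_var,
                         const double nu_r, const arma::mat& Vr,
                         const double nu_g, const double Vg) {
  const int n = ys.n_elem, k = Xs.n_cols;
  const arma::mat Css = Xs.t() * Xs, Cyy = Xy.t() * Xy, Csy = Xs.t() * Xy;

  arma::vec beta(k, arma::fill::zeros);
  arma::vec us(npop, arma::fill::zeros), uy(npop, arma::fill::zeros);
  const double vs0 = arma::var(ys), vy0 = arma::var(yy);
  arma::mat Rr(2, 2, arma::fill::zeros);
  Rr(0, 0) = std::max(vs0, 1e-8);
  Rr(1, 1) = std::max(vy0, 1e-8);
  double gs = Rr(0, 0) / 10.0 + 1e-8, gy = Rr(1, 1) / 10.0 + 1e-8;

  arma::vec npp(npop, arma::fill::zeros);
  for (int i = 0; i < n; ++i) npp(pop(i)) += 1.0;

  const int m = (n_iter - burnin + thin - 1) / thin;
  arma::mat keep_beta(m, k), keep_g(m, 2), keep_R(m, 3),
            keep_us(m, npop), keep_uy(m, npop);
  arma::vec keep_dev(m);
  int stored = 0;

  for (int it = 0; it < n_iter; ++it) {
    const arma::mat W = inv_pd(Rr, it, "residual-precision");
    const double w11 = W(0, 0), w12 = W(0, 1), w22 = W(1, 1);

    // fixed effects
    arma::vec rs = ys, ry = yy;
    for (int i = 0; i < n; ++i) { rs(i) -= us(pop(i)); ry(i) -= uy(pop(i)); }
    arma::mat A = w11 * Css + w12 * (Csy + Csy.t()) + w22 * Cyy;
    A.diag() += 1.0 / beta_prior_var;
    const arma::vec b = w11 * (Xs.t() * rs) + w12 * (Xs.t() * ry + Xy.t() * rs)
                        + w22 * (Xy.t() * ry);
    const arma::mat Ainv = inv_pd(A, it, "fixed-effect");
    arma::vec z(k);
    for (int j = 0; j < k; ++j) z(j) = R::norm_rand();
    beta = Ainv * b + arma::chol(Ainv, "lower") * z;

    // random intercepts per population
    const arma::vec ds = ys - Xs * beta, dy = yy - Xy * beta;
    arma::vec sum_s(npop, arma::fill::zeros), sum_y(npop, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      sum_s(pop(i)) += ds(i);
      sum_y(pop(i)) += dy(i);
    }
    for (int p = 0; p < npop; ++p) {
      arma::mat P = npp(p) * W;
      P(0, 0) += 1.0 / gs;
      P(1, 1) += 1.0 / gy;
      const arma::mat Pi = inv_pd(P, it, "random-effect");
      arma::vec rhs(2);
      rhs(0) = w11 * sum_s(p) + w12 * sum_y(p);
      rhs(1) = w12 * sum_s(p) + w22 * sum_y(p);
      arma::vec z2(2);
      z2(0) = R::norm_rand();
      z2(1) = R::norm_rand();
      const arma::vec u = Pi * rhs + arma::chol(Pi, "lower") * z2;
      us(p) = u(0);
      uy(p) = u(1);
    }

    // per-trait random-intercept variances (inverse-gamma conditional)
    gs = 1.0 / R::rgamma((nu_g + npop) / 2.0,
                         2.0 / (nu_g * Vg + arma::dot(us, us)));
    gy = 1.0 / R::rgamma((nu_g + npop) / 2.0,
                         2.0 / (nu_g * Vg + arma::dot(uy, uy)));

    // residual covariance (inverse-Wishart conditional)
    arma::vec es = ds, ey = dy;
    for (int i = 0; i < n; ++i) { es(i) -= us(pop(i)); ey(i) -= uy(pop(i)); }
    arma::mat E2(2, 2);
    E2(0, 0) = arma::dot(es, es);
    E2(1, 1) = arma::dot(ey, ey);
    E2(0, 1) = E2(1, 0) = arma::dot(es, ey);
    const arma::mat S = nu_r * Vr + E2;
    const arma::mat Wdraw = rwishart(nu_r + n, inv_pd(S, it, "residual-scale"));
    Rr = inv_pd(Wdraw, it, "residual-covariance");

    if (it >= burnin && (it - burnin) % thin == 0) {
      const arma::mat W2 = inv_pd(Rr, it, "deviance-precision");
      double ldR, sign;
      arma::log_det(ldR, sign, Rr);
      const double quad = W2(0, 0) * E2(0, 0) + 2.0 * W2(0, 1) * E2(0, 1)
                          + W2(1, 1) * E2(1, 1);
      keep_dev(stored) = n * (2.0 * std::log(2.0 * M_PI) + ldR) + quad;
      keep_beta.row(stored) = beta.t();
      keep_g(stored, 0) = gs;
      keep_g(stored, 1) = gy;
      keep_R(stored, 0) = Rr(0, 0);
      keep_R(stored, 1) = Rr(1, 1);
      keep_R(stored, 2) = Rr(0, 1);
      keep_us.row(stored) = us.t();
      keep_uy.row(stored) = uy.t();
      ++stored;
    }
  }

  return List::create(
    _["beta"] = keep_beta.rows(0, stored - 1),
    _["sigma_pop"] = keep_g.rows(0, stored - 1),
    _["rcov"] = keep_R.rows(0, stored - 1),
    _["u_sucrose"] = keep_us.rows(0, stored - 1),
    _["u_yeast"] = keep_uy.rows(0, stored - 1),
    _["deviance"] = keep_dev.subvec(0, stored - 1));
}
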