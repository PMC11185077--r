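// Metropolis-within-Gibbs sampler for Bayesian hierarchical growth models
// (Gompertz likelihood with random-walk Metropolis latent updates, or fully
// conjugate quadratic likelihood), plus posterior-curve summaries.
//
// Conventions shared with the R wrappers:
//  * theta rows are (age115, shape, bw65) for the Gompertz model, or
//    quadratic coefficients on whatever scale the wrapper passes (the
//    wrapper fits the quadratic model on age/100 for conditioning and maps
//    draws back).
//  * All randomness comes from R's RNG, so set.seed() in R fixes chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double clamp50(double x) {
  return x > 50.0 ? 50.0 : (x < -50.0 ? -50.0 : x);
}

// Gompertz curve through (65, bw65) and (age115, 115) with rate `shape`.
static inline double gomp_curve(double t, double a115, double shape,
                                double bw65) {
  double eD = std::exp(-clamp50(shape * (a115 - 65.0)));
  double Et = (eD - std::exp(-clamp50(shape * (t - 65.0)))) / (1.0 - eD);
  return 115.0 * std::exp(Et * std::log(115.0 / bw65));
}

static inline bool gomp_valid(const rowvec &th) {
  return th(0) > 65.0 + 1e-8 && th(1) > 1e-10 && th(2) > 1e-8 &&
         th(2) < 115.0 - 1e-8 && th(1) * (th(0) - 65.0) > 1e-10;
}

// Residual log-likelihood of one animal's records (constants dropped).
static double gomp_loglik(const rowvec &th, const double *age, const double *y,
                          const double *rvar, unsigned int m) {
  double eD = std::exp(-clamp50(th(1) * (th(0) - 65.0)));
  double denom = 1.0 - eD;
  double L = std::log(115.0 / th(2));
  double ll = 0.0;
  for (unsigned int k = 0; k < m; ++k) {
    double Et = (eD - std::exp(-clamp50(th(1) * (age[k] - 65.0)))) / denom;
    double g = 115.0 * std::exp(Et * L);
    double r = y[k] - g;
    ll -= 0.5 * r * r / rvar[k];
  }
  return ll;
}

static inline double prior_quad(const rowvec &th, const rowvec &m,
                                const mat &prec) {
  rowvec d = th - m;
  return -0.5 * as_scalar(d * prec * d.t());
}

// Draw from N(solve(P, rhs), inv(P)) given the upper Cholesky U of P.
static rowvec mvn_prec_draw(const mat &U, const vec &rhs) {
  vec w = solve(trimatl(U.t()), rhs);
  vec mu = solve(trimatu(U), w);
  vec z(3);
  for (int k = 0; k < 3; ++k) z(k) = R::norm_rand();
  return (mu + solve(trimatu(U), z)).t();
}

// [[Rcpp::export]]
Rcpp::List mcmc_growth_cpp(const arma::vec &y, const arma::vec &age,
                           const arma::vec &resvar,
                           const arma::uvec &rec_start,
                           const arma::uvec &rec_count, const arma::mat &G,
                           const arma::mat &sigma_e,
                           const arma::mat &sigma_alpha, int model,
                           int n_iter, int burn_in, int thin,
                           arma::vec prop_scales, bool adapt,
                           double target_acc, const arma::mat &theta_init,
                           const arma::rowvec &mu_init,
                           const arma::mat &alpha_init, bool update_hyper) {
  const unsigned int n = G.n_rows, p = G.n_cols;
  const mat se_inv = inv_sympd(sigma_e);
  const mat sa_inv = p > 0 ? inv_sympd(sigma_alpha) : mat(3, 3, fill::eye);
  const mat se_cholU = chol(sigma_e);  // upper

  mat theta = theta_init;
  rowvec mu = mu_init;
  mat alpha = alpha_init;  // p x 3

  // Quadratic model: per-animal sufficient statistics and constant
  // posterior Cholesky factors (design and residual variances are fixed).
  std::vector<mat> q_cholU(n);
  mat q_xty(3, n, fill::zeros);
  if (model == 1) {
    for (unsigned int i = 0; i < n; ++i) {
      if (rec_count(i) == 0) continue;
      mat A(3, 3, fill::zeros);
      vec b(3, fill::zeros);
      for (unsigned int k = rec_start(i); k < rec_start(i) + rec_count(i); ++k) {
        vec x = {1.0, age(k), age(k) * age(k)};
        A += x * x.t() / resvar(k);
        b += x * y(k) / resvar(k);
      }
      q_cholU[i] = chol(A + se_inv);
      q_xty.col(i) = b;
    }
  }

  // Per-locus posterior precision factors for alpha (constant: depend only
  // on genotype sums of squares).
  std::vector<mat> a_cholU(p);
  vec gss(p, fill::zeros);
  for (unsigned int j = 0; j < p; ++j) {
    gss(j) = dot(G.col(j), G.col(j));
    a_cholU[j] = chol(gss(j) * se_inv + sa_inv);
  }

  // Gompertz state: cached record log-likelihood per animal.
  vec ll_cur(n, fill::zeros);
  if (model == 0) {
    for (unsigned int i = 0; i < n; ++i) {
      if (rec_count(i) == 0) continue;
      ll_cur(i) = gomp_loglik(theta.row(i), age.memptr() + rec_start(i),
                              y.memptr() + rec_start(i),
                              resvar.memptr() + rec_start(i), rec_count(i));
    }
  }

  const int S = (n_iter - burn_in) / thin;
  mat mu_draws(S, 3);
  cube alpha_draws(std::max<unsigned int>(p, 1), 3, S, fill::zeros);
  cube theta_draws(n, 3, S);
  vec log_s = log(prop_scales);
  vec acc_post(3, fill::zeros);
  double post_iters = 0.0;
  unsigned int n_obs = 0;
  for (unsigned int i = 0; i < n; ++i) n_obs += (rec_count(i) > 0);

  int s_idx = 0;
  for (int it = 1; it <= n_iter; ++it) {
    mat prior_mean = repmat(mu, n, 1);
    if (p > 0) prior_mean += G * alpha;

    vec acc_it(3, fill::zeros);
    for (unsigned int i = 0; i < n; ++i) {
      if (rec_count(i) == 0) {
        // No phenotypes in this view: exact draw from the marker prior.
        rowvec z(3);
        for (int k = 0; k < 3; ++k) z(k) = R::norm_rand();
        theta.row(i) = prior_mean.row(i) + z * se_cholU;
        continue;
      }
      if (model == 1) {
        vec rhs = q_xty.col(i) + se_inv * prior_mean.row(i).t();
        theta.row(i) = mvn_prec_draw(q_cholU[i], rhs);
      } else {
        rowvec m_i = prior_mean.row(i);
        double lp_cur = prior_quad(theta.row(i), m_i, se_inv);
        for (int k = 0; k < 3; ++k) {
          rowvec prop = theta.row(i);
          prop(k) += std::exp(log_s(k)) * R::norm_rand();
          if (!gomp_valid(prop)) continue;
          double ll_prop =
              gomp_loglik(prop, age.memptr() + rec_start(i),
                          y.memptr() + rec_start(i),
                          resvar.memptr() + rec_start(i), rec_count(i));
          double lp_prop = prior_quad(prop, m_i, se_inv);
          if (std::log(R::unif_rand()) <
              ll_prop + lp_prop - ll_cur(i) - lp_cur) {
            theta.row(i) = prop;
            ll_cur(i) = ll_prop;
            lp_cur = lp_prop;
            acc_it(k) += 1.0;
          }
        }
      }
    }

    if (model == 0 && n_obs > 0) {
      vec rate = acc_it / double(n_obs);
      if (adapt && it <= burn_in) {
        double gamma = std::min(0.5, 2.0 * std::pow(double(it), -0.6));
        log_s += gamma * (rate - target_acc);
      }
      if (it > burn_in) {
        acc_post += rate;
        post_iters += 1.0;
      }
    }

    // mu | theta, alpha: flat prior -> MVN(rowmean(theta - G alpha), Se/n).
    if (update_hyper) {
      mat D = theta;
      if (p > 0) D -= G * alpha;
      rowvec z(3);
      for (int k = 0; k < 3; ++k) z(k) = R::norm_rand();
      mu = mean(D, 0) + z * se_cholU / std::sqrt(double(n));
    }

    // alpha_j | rest: conjugate MVN; E holds current full residuals.
    if (update_hyper && p > 0) {
      mat E = theta - repmat(mu, n, 1) - G * alpha;
      for (unsigned int j = 0; j < p; ++j) {
        vec b3 = E.t() * G.col(j) + gss(j) * alpha.row(j).t();
        rowvec a_new = mvn_prec_draw(a_cholU[j], se_inv * b3);
        E -= G.col(j) * (a_new - alpha.row(j));
        alpha.row(j) = a_new;
      }
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && s_idx < S) {
      mu_draws.row(s_idx) = mu;
      if (p > 0) alpha_draws.slice(s_idx) = alpha;
      theta_draws.slice(s_idx) = theta;
      ++s_idx;
    }
  }

  vec acc_rate = post_iters > 0 ? vec(acc_post / post_iters)
                                : vec(3, fill::value(NA_REAL));
  return Rcpp::List::create(
      Rcpp::Named("mu") = mu_draws, Rcpp::Named("alpha") = alpha_draws,
      Rcpp::Named("theta") = theta_draws,
      Rcpp::Named("acceptance") = acc_rate,
      Rcpp::Named("prop_scales") = exp(log_s));
}

static inline double curve_at(int model, double t, const rowvec &th) {
  if (model == 1) return th(0) + th(1) * t + th(2) * t * t;
  // Clamp pathological posterior draws to the curve's domain boundary.
  double a115 = std::max(th(0), 65.0 + 1e-6);
  double shape = std::max(th(1), 1e-8);
  double bw65 = std::min(std::max(th(2), 1e-6), 115.0 - 1e-6);
  return gomp_curve(t, a115, shape, bw65);
}

// Posterior-mean EBV surface: mean over draws of the genetic curve
// evaluated at theta_g^(s) = mu^(s) + G alpha^(s).
// [[Rcpp::export]]
arma::mat ebv_surface_cpp(const arma::mat &mu_draws,
                          const arma::cube &alpha_draws, const arma::mat &G,
                          const arma::vec &ages, int model, bool has_alpha) {
  const unsigned int S = mu_draws.n_rows, n = G.n_rows, q = ages.n_elem;
  mat out(n, q, fill::zeros);
  for (unsigned int s = 0; s < S; ++s) {
    mat th_g = repmat(mu_draws.row(s), n, 1);
    if (has_alpha) th_g += G * alpha_draws.slice(s);
    for (unsigned int i = 0; i < n; ++i) {
      for (unsigned int k = 0; k < q; ++k) {
        out(i, k) += curve_at(model, ages(k), th_g.row(i));
      }
    }
  }
  return out / double(S);
}

// Gibbs estimator of per-day genetic variance: for each retained draw,
// the population variance (divisor n) of the genetic curves over the
// supplied animals, averaged across draws.
// [[Rcpp::export]]
arma::vec genetic_variance_cpp(const arma::mat &mu_draws,
                               const arma::cube &alpha_draws,
                               const arma::mat &G, const arma::vec &ages,
                               int model, bool has_alpha) {
  const unsigned int S = mu_draws.n_rows, n = G.n_rows, q = ages.n_elem;
  vec out(q, fill::zeros);
  for (unsigned int s = 0; s < S; ++s) {
    mat th_g = repmat(mu_draws.row(s), n, 1);
    if (has_alpha) th_g += G * alpha_draws.slice(s);
    for (unsigned int k = 0; k < q; ++k) {
      double sum = 0.0, sumsq = 0.0;
      for (unsigned int i = 0; i < n; ++i) {
        double u = curve_at(model, ages(k), th_g.row(i));
        sum += u;
        sumsq += u * u;
      }
      double m = sum / n;
      out(k) += sumsq / n - m * m;
    }
  }
  return out / double(S);
}
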