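// Binomial random-intercept mixed model: Laplace-approximated marginal
// likelihood with a penalised IRLS inner loop and a profiled 1-D outer
// search over log(sigma). Individuals must arrive sorted by group.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double MU_EPS = 1e-10;
static const double BETA_DIVERGE = 40.0;

static inline double clampmu(double m) {
  if (m < MU_EPS) return MU_EPS;
  if (m > 1.0 - MU_EPS) return 1.0 - MU_EPS;
  return m;
}

// Bernoulli log-likelihood of eta against y (stable around large |eta|)
static double bern_ll(const vec& y, const vec& eta) {
  double ll = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    double e = eta[i];
    // y*eta - log(1+exp(eta))
    double l1p = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    ll += y[i] * e - l1p;
  }
  return ll;
}

struct GroupIdx {
  uvec start; // first row of each group (0-based)
  uvec end;   // one past last row
};

// Conditional modes u_g given beta and sigma, by per-group Newton.
// Returns modes in u (updated in place) and Sum of IRLS weights per group in Sg.
static void newton_modes(const vec& y, const vec& xb, const GroupIdx& gi,
                         double sigma, vec& u, vec& Sg) {
  uword G = gi.start.n_elem;
  double inv_s2 = (sigma > 0) ? 1.0 / (sigma * sigma) : 0.0;
  for (uword g = 0; g < G; ++g) {
    double ug = (sigma > 0) ? u[g] : 0.0;
    double S = 0.0;
    // penalised per-group objective h(u); strictly concave, so damped
    // Newton with backtracking is globally convergent
    auto hval = [&](double uu) {
      double h = -0.5 * uu * uu * inv_s2;
      for (uword i = gi.start[g]; i < gi.end[g]; ++i) {
        double e = xb[i] + uu;
        double l1p = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
        h += y[i] * e - l1p;
      }
      return h;
    };
    double hcur = (sigma > 0) ? hval(ug) : 0.0;
    for (int it = 0; it < 100; ++it) {
      double grad = -ug * inv_s2;
      S = 0.0;
      for (uword i = gi.start[g]; i < gi.end[g]; ++i) {
        double mu = clampmu(1.0 / (1.0 + std::exp(-(xb[i] + ug))));
        grad += y[i] - mu;
        S += mu * (1.0 - mu);
      }
      if (sigma <= 0) break;
      double step = grad / (S + inv_s2);
      if (std::fabs(step) < 1e-11) break;
      double unew = ug + step, hnew = hval(unew);
      int bt = 0;
      while (hnew < hcur && bt < 40) {          // backtrack on decrease
        step *= 0.5; unew = ug + step; hnew = hval(unew); ++bt;
      }
      if (hnew <= hcur && std::fabs(step) < 1e-11) { ug = unew; break; }
      ug = unew; hcur = hnew;
    }
    if (sigma > 0) { // refresh curvature at the final point
      S = 0.0;
      for (uword i = gi.start[g]; i < gi.end[g]; ++i) {
        double mu = clampmu(1.0 / (1.0 + std::exp(-(xb[i] + ug))));
        S += mu * (1.0 - mu);
      }
    }
    u[g] = (sigma > 0) ? ug : 0.0;
    Sg[g] = S;
  }
}

// Laplace marginal log-likelihood at (beta, sigma) with u at conditional modes.
static double laplace_ll(const vec& y, const mat& X, const GroupIdx& gi,
                         const vec& beta, double sigma, vec& u, vec& Sg) {
  vec xb = X * beta;
  newton_modes(y, xb, gi, sigma, u, Sg);
  vec eta = xb;
  uword G = gi.start.n_elem;
  for (uword g = 0; g < G; ++g)
    for (uword i = gi.start[g]; i < gi.end[g]; ++i) eta[i] += u[g];
  double ll = bern_ll(y, eta);
  if (sigma > 0) {
    double s2 = sigma * sigma;
    for (uword g = 0; g < G; ++g)
      ll += -0.5 * u[g] * u[g] / s2 - 0.5 * std::log1p(s2 * Sg[g]);
  }
  return ll;
}

// Joint penalised IRLS over (beta, u) at fixed sigma (sigma = 0 gives the
// plain logistic MLE). Returns true on convergence without divergence.
static bool pirls(const vec& y, const mat& X, const GroupIdx& gi,
                  double sigma, vec& beta, vec& u, int maxit, int& iters) {
  uword n = y.n_elem, p = X.n_cols, G = gi.start.n_elem;
  double inv_s2 = (sigma > 0) ? 1.0 / (sigma * sigma) : 0.0;
  if (sigma <= 0) u.zeros();
  double pdev_old = datum::inf;
  vec eta(n), mu(n), w(n), z(n);
  for (int it = 0; it < maxit; ++it) {
    ++iters;
    eta = X * beta;
    for (uword g = 0; g < G; ++g)
      for (uword i = gi.start[g]; i < gi.end[g]; ++i) eta[i] += u[g];
    for (uword i = 0; i < n; ++i) {
      mu[i] = clampmu(1.0 / (1.0 + std::exp(-eta[i])));
      w[i] = mu[i] * (1.0 - mu[i]);
      z[i] = eta[i] + (y[i] - mu[i]) / w[i];
    }
    // penalised weighted LS, u profiled out per group (Schur complement)
    mat Xw = X.each_col() % w;
    mat A = X.t() * Xw;
    vec b = X.t() * (w % z);
    mat R = zeros<mat>(p, G);   // r_g = sum_g w x
    vec q = zeros<vec>(G), d(G);
    for (uword g = 0; g < G; ++g) {
      uword a0 = gi.start[g], a1 = gi.end[g] - 1;
      R.col(g) = sum(Xw.rows(a0, a1), 0).t();
      q[g] = dot(w.subvec(a0, a1), z.subvec(a0, a1));
      d[g] = accu(w.subvec(a0, a1)) + inv_s2;
    }
    if (sigma > 0) {
      for (uword g = 0; g < G; ++g) {
        A -= (R.col(g) * R.col(g).t()) / d[g];
        b -= R.col(g) * (q[g] / d[g]);
      }
    }
    vec beta_new;
    bool ok = solve(beta_new, A, b, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok || !beta_new.is_finite()) return false;
    vec u_new(G, fill::zeros);
    if (sigma > 0)
      for (uword g = 0; g < G; ++g)
        u_new[g] = (q[g] - dot(R.col(g), beta_new)) / d[g];
    // step-halving on the penalised deviance
    double pdev = datum::inf;
    vec beta_try, u_try;
    for (int h = 0; h < 8; ++h) {
      double frac = std::pow(0.5, h);
      beta_try = beta + frac * (beta_new - beta);
      u_try = u + frac * (u_new - u);
      vec eta_t = X * beta_try;
      for (uword g = 0; g < G; ++g)
        for (uword i = gi.start[g]; i < gi.end[g]; ++i) eta_t[i] += u_try[g];
      pdev = -2.0 * bern_ll(y, eta_t);
      if (sigma > 0) pdev += inv_s2 * dot(u_try, u_try);
      if (pdev <= pdev_old + 1e-12 || !std::isfinite(pdev_old)) break;
    }
    beta = beta_try; u = u_try;
    if (beta.has_nan() || std::fabs(beta.max()) > BETA_DIVERGE ||
        std::fabs(beta.min()) > BETA_DIVERGE)
      return false;
    if (std::isfinite(pdev_old) &&
        std::fabs(pdev_old - pdev) < 1e-10 * (1.0 + std::fabs(pdev)))
      return true;
    pdev_old = pdev;
  }
  return false; // maxit reached
}

static GroupIdx make_gi(const arma::uvec& gstart, const arma::uvec& gend) {
  GroupIdx gi; gi.start = gstart; gi.end = gend; return gi;
}

// [[Rcpp::export(name = ".cpp_laplace_loglik")]]
Rcpp::List cpp_laplace_loglik(const arma::vec& y, const arma::mat& X,
                              const arma::uvec& gstart, const arma::uvec& gend,
                              const arma::vec& beta, double sigma) {
  GroupIdx gi = make_gi(gstart, gend);
  vec u(gstart.n_elem, fill::zeros), Sg(gstart.n_elem, fill::zeros);
  double ll = laplace_ll(y, X, gi, beta, sigma, u, Sg);
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("u") = u,
                            Rcpp::Named("Sg") = Sg);
}

// Profile objective: PIRLS at fixed sigma then Laplace log-likelihood.
static double profile_obj(const vec& y, const mat& X, const GroupIdx& gi,
                          double sigma, vec& beta, vec& u, vec& Sg,
                          bool& ok, int& iters) {
  ok = pirls(y, X, gi, sigma, beta, u, 60, iters);
  if (!ok) return -datum::inf;
  return laplace_ll(y, X, gi, beta, sigma, u, Sg);
}

// [[Rcpp::export(name = ".cpp_fit_profile")]]
Rcpp::List cpp_fit_profile(const arma::vec& y, const arma::mat& X,
                           const arma::uvec& gstart, const arma::uvec& gend,
                           const arma::vec& beta_init,
                           double log_sigma_lo, double log_sigma_hi,
                           double tol) {
  GroupIdx gi = make_gi(gstart, gend);
  uword p = X.n_cols, G = gstart.n_elem;
  int iters = 0;
  bool ok0;
  // sigma = 0 boundary: plain logistic IRLS (exact MLE)
  vec beta0 = beta_init, u0(G, fill::zeros), Sg0(G, fill::zeros);
  double ll0 = profile_obj(y, X, gi, 0.0, beta0, u0, Sg0, ok0, iters);

  // coarse grid then golden-section refinement on log sigma
  const int ngrid = 7;
  vec beta_best = ok0 ? beta0 : beta_init;
  double ls_best = datum::nan, f_best = -datum::inf;
  vec beta_cur = beta_best, u_cur(G, fill::zeros), Sg_cur(G, fill::zeros);
  vec grid_f(ngrid);
  for (int k = 0; k < ngrid; ++k) {
    double ls = log_sigma_lo + k * (log_sigma_hi - log_sigma_lo) / (ngrid - 1);
    bool ok;
    double f = profile_obj(y, X, gi, std::exp(ls), beta_cur, u_cur, Sg_cur, ok, iters);
    grid_f[k] = ok ? f : -datum::inf;
    if (ok && f > f_best) { f_best = f; ls_best = ls; beta_best = beta_cur; }
  }
  bool interior_ok = std::isfinite(f_best);
  if (interior_ok) {
    double h = (log_sigma_hi - log_sigma_lo) / (ngrid - 1);
    double a = std::max(log_sigma_lo, ls_best - h);
    double b = std::min(log_sigma_hi, ls_best + h);
    const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
    double c = b - gr * (b - a), d = a + gr * (b - a);
    bool okc, okd;
    vec bc = beta_best, uc = u_cur, sc = Sg_cur;
    vec bd = beta_best, ud = u_cur, sd = Sg_cur;
    double fc = profile_obj(y, X, gi, std::exp(c), bc, uc, sc, okc, iters);
    double fd = profile_obj(y, X, gi, std::exp(d), bd, ud, sd, okd, iters);
    for (int it = 0; it < 60 && (b - a) > tol; ++it) {
      if (fc >= fd) {
        b = d; d = c; fd = fc; bd = bc;
        c = b - gr * (b - a);
        fc = profile_obj(y, X, gi, std::exp(c), bc, uc, sc, okc, iters);
      } else {
        a = c; c = d; fc = fd; bc = bd;
        d = a + gr * (b - a);
        fd = profile_obj(y, X, gi, std::exp(d), bd, ud, sd, okd, iters);
      }
    }
    if (fc >= fd && fc > f_best) { f_best = fc; ls_best = c; beta_best = bc; }
    else if (fd > f_best)        { f_best = fd; ls_best = d; beta_best = bd; }
  }

  bool use_zero = ok0 && (!interior_ok || ll0 >= f_best - 1e-8);
  double sigma_hat, ll_hat;
  vec beta_hat;
  if (use_zero) {
    sigma_hat = 0.0; ll_hat = ll0; beta_hat = beta0;
  } else {
    sigma_hat = std::exp(ls_best); ll_hat = f_best; beta_hat = beta_best;
  }
  bool converged = use_zero ? ok0 : interior_ok;
  // final modes/weights at the chosen optimum
  vec u_hat(G, fill::zeros), Sg_hat(G, fill::zeros);
  double ll_final = converged ?
    laplace_ll(y, X, gi, beta_hat, sigma_hat, u_hat, Sg_hat) : datum::nan;
  if (converged) ll_hat = ll_final;
  vec eta = X * beta_hat;
  for (uword g = 0; g < G; ++g)
    for (uword i = gi.start[g]; i < gi.end[g]; ++i) eta[i] += u_hat[g];
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta_hat,
    Rcpp::Named("sigma") = sigma_hat,
    Rcpp::Named("loglik") = ll_hat,
    Rcpp::Named("u") = u_hat,
    Rcpp::Named("eta") = eta,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("n_iter") = iters,
    Rcpp::Named("loglik_sigma0") = ll0,
    Rcpp::Named("p") = (int)p);
}
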