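// Cumulative-logit (proportional-odds) model core.
//
// Model: P(y <= j | x) = logistic(alpha_j - beta'x), j = 0,1,2, classes 0..3.
// Penalized log-likelihood: ll - ridge * ||beta||^2 (alphas unpenalized).
// Fitted by damped Newton-Raphson with analytic gradient and Hessian; the
// log-likelihood barrier (P(y=j) -> 0 when cutpoints cross) keeps the alphas
// ordered, and the line search rejects any step producing a non-positive
// class probability.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int K = 4;   // classes 0..3, K-1 cutpoints

static inline double logistic(double z) {
  if (z >= 0) {
    double e = std::exp(-z);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(z);
  return e / (1.0 + e);
}

// class probability for observation with linear predictor eta and class y
static inline double class_prob(const vec& alpha, double eta, int y) {
  double Fhi = (y == K - 1) ? 1.0 : logistic(alpha(y) - eta);
  double Flo = (y == 0) ? 0.0 : logistic(alpha(y - 1) - eta);
  return Fhi - Flo;
}

static double loglik(const mat& X, const ivec& y, const vec& alpha,
                     const vec& beta) {
  vec eta = X.n_cols ? vec(X * beta) : zeros<vec>(X.n_rows);
  double ll = 0.0;
  for (uword i = 0; i < X.n_rows; ++i) {
    double p = class_prob(alpha, eta(i), y(i));
    if (!(p > 0.0)) return -datum::inf;
    ll += std::log(p);
  }
  return ll;
}

// gradient and Hessian of the *unpenalized* log-likelihood wrt (alpha, beta)
static void grad_hess(const mat& X, const ivec& y, const vec& alpha,
                      const vec& beta, vec& g, mat& H) {
  const uword n = X.n_rows, p = X.n_cols, d = (K - 1) + p;
  g.zeros(d);
  H.zeros(d, d);
  vec eta = p ? vec(X * beta) : zeros<vec>(n);
  for (uword i = 0; i < n; ++i) {
    int yi = y(i);
    double Fhi = (yi == K - 1) ? 1.0 : logistic(alpha(yi) - eta(i));
    double Flo = (yi == 0) ? 0.0 : logistic(alpha(yi - 1) - eta(i));
    double P = Fhi - Flo;
    double fhi = (yi == K - 1) ? 0.0 : Fhi * (1.0 - Fhi);
    double flo = (yi == 0) ? 0.0 : Flo * (1.0 - Flo);
    double fphi = (yi == K - 1) ? 0.0 : fhi * (1.0 - 2.0 * Fhi);
    double fplo = (yi == 0) ? 0.0 : flo * (1.0 - 2.0 * Flo);
    double u = fhi / P, v = flo / P;

    // z_hi = alpha_{yi} - eta, z_lo = alpha_{yi-1} - eta
    double g_hi = u, g_lo = -v;
    double h_hh = fphi / P - u * u;
    double h_ll = -fplo / P - v * v;
    double h_hl = u * v;

    // d z_hi / d alpha_{yi} = 1, d z / d eta = -1, d eta / d beta = x
    double g_eta = -(g_hi + g_lo);
    double h_ee = h_hh + 2.0 * h_hl + h_ll;   // d2 ll / d eta^2

    if (yi < K - 1) {
      g(yi) += g_hi;
      H(yi, yi) += h_hh;
    }
    if (yi > 0) {
      g(yi - 1) += g_lo;
      H(yi - 1, yi - 1) += h_ll;
    }
    if (yi > 0 && yi < K - 1) {
      H(yi, yi - 1) += h_hl;
      H(yi - 1, yi) += h_hl;
    }
    if (p) {
      const rowvec xi = X.row(i);
      for (uword a = 0; a < p; ++a) {
        double xa = xi(a);
        g(K - 1 + a) += g_eta * xa;
        // alpha-beta cross terms: d2 ll / d alpha d eta
        if (yi < K - 1) H(yi, K - 1 + a) += -(h_hh + h_hl) * xa;
        if (yi > 0) H(yi - 1, K - 1 + a) += -(h_ll + h_hl) * xa;
        for (uword b = 0; b <= a; ++b)
          H(K - 1 + a, K - 1 + b) += h_ee * xa * xi(b);
      }
    }
  }
  // symmetrize
  for (uword a = 0; a < d; ++a)
    for (uword b = a + 1; b < d; ++b) {
      if (a < (uword)(K - 1) && b >= (uword)(K - 1)) H(b, a) = H(a, b);
      else if (b >= (uword)(K - 1)) H(a, b) = H(b, a);
    }
}

// [[Rcpp::export(name = ".ord_loglik_cpp")]]
double ord_loglik_cpp(const arma::mat& X, const arma::ivec& y,
                      const arma::vec& alpha, const arma::vec& beta) {
  return loglik(X, y, alpha, beta);
}

// [[Rcpp::export(name = ".ord_grad_cpp")]]
arma::vec ord_grad_cpp(const arma::mat& X, const arma::ivec& y,
                       const arma::vec& alpha, const arma::vec& beta) {
  vec g;
  mat H;
  grad_hess(X, y, alpha, beta, g, H);
  return g;
}

struct FitResult {
  vec alpha, beta;
  double loglik;
  bool converged;
  int iter;
  double grad_norm;
  bool ok;
};

static FitResult newton_fit(const mat& X, const ivec& y, double ridge,
                            int max_iter, double tol,
                            const vec* alpha_start = nullptr,
                            const vec* beta_start = nullptr) {
  const uword n = X.n_rows, p = X.n_cols, d = (K - 1) + p;
  FitResult res;
  res.ok = false;

  // all classes must be present, otherwise cutpoints collapse
  ivec counts(K, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    if (y(i) < 0 || y(i) >= K) return res;
    counts(y(i))++;
  }
  for (int j = 0; j < K; ++j)
    if (counts(j) == 0) return res;

  // start at empirical cumulative logits, beta = 0 (or a warm start)
  vec alpha(K - 1);
  double cum = 0.0;
  for (int j = 0; j < K - 1; ++j) {
    cum += counts(j);
    double pr = cum / n;
    alpha(j) = std::log(pr / (1.0 - pr));
  }
  vec beta(p, fill::zeros);
  if (alpha_start && beta_start) {
    alpha = *alpha_start;
    beta = *beta_start;
  }

  double pll = loglik(X, y, alpha, beta) - ridge * dot(beta, beta);
  vec g;
  mat H;
  int it = 0;
  double gnorm = datum::inf;
  for (it = 0; it < max_iter; ++it) {
    grad_hess(X, y, alpha, beta, g, H);
    // penalty terms
    for (uword a = 0; a < p; ++a) {
      g(K - 1 + a) -= 2.0 * ridge * beta(a);
      H(K - 1 + a, K - 1 + a) -= 2.0 * ridge;
    }
    gnorm = norm(g, "inf");
    if (gnorm < tol) break;

    vec step;
    bool solved = solve(step, -H, g, solve_opts::no_approx);
    if (!solved || !step.is_finite()) step = g / std::max(1.0, norm(g, 2));

    double t = 1.0;
    bool accepted = false;
    for (int half = 0; half < 40; ++half) {
      vec a_new = alpha + t * step.head(K - 1);
      vec b_new = p ? vec(beta + t * step.tail(p)) : beta;
      double ll_new = loglik(X, y, a_new, b_new) - ridge * dot(b_new, b_new);
      if (std::isfinite(ll_new) && ll_new >= pll - 1e-12) {
        // require ordered cutpoints (barrier usually enforces this)
        bool ordered = true;
        for (int j = 1; j < K - 1; ++j)
          if (a_new(j) <= a_new(j - 1)) ordered = false;
        if (ordered) {
          alpha = a_new;
          beta = b_new;
          if (ll_new <= pll + 1e-12 && t == 1.0) {
            pll = ll_new;
            accepted = true;
            it = max_iter;  // no progress possible; stop outer loop
            break;
          }
          pll = ll_new;
          accepted = true;
          break;
        }
      }
      t *= 0.5;
    }
    if (!accepted) break;
  }

  // final gradient for the convergence flag
  grad_hess(X, y, alpha, beta, g, H);
  for (uword a = 0; a < p; ++a) g(K - 1 + a) -= 2.0 * ridge * beta(a);
  gnorm = norm(g, "inf");

  res.alpha = alpha;
  res.beta = beta;
  res.loglik = loglik(X, y, alpha, beta);
  res.grad_norm = gnorm;
  res.iter = it;
  res.converged = (gnorm < std::max(tol, 1e-6));
  res.ok = true;
  return res;
}

// [[Rcpp::export(name = ".ord_fit_cpp")]]
Rcpp::List ord_fit_cpp(const arma::mat& X, const arma::ivec& y, double ridge,
                       int max_iter = 200, double tol = 1e-8) {
  FitResult r = newton_fit(X, y, ridge, max_iter, tol);
  if (!r.ok) Rcpp::stop("ordinal fit failed: every class 0..3 must be present");
  return Rcpp::List::create(
      Rcpp::Named("alphas") = r.alpha, Rcpp::Named("betas") = r.beta,
      Rcpp::Named("loglik") = r.loglik, Rcpp::Named("converged") = r.converged,
      Rcpp::Named("iterations") = r.iter,
      Rcpp::Named("grad_norm") = r.grad_norm);
}

// Leave-one-out continuous predictions: fit on n-1, predict expected score
// of the held-out row. Folds whose training set misses a class return NA.
// [[Rcpp::export(name = ".ord_loocv_cpp")]]
arma::vec ord_loocv_cpp(const arma::mat& X, const arma::ivec& y, double ridge,
                        int max_iter = 200, double tol = 1e-8) {
  const uword n = X.n_rows;
  vec out(n);
  out.fill(datum::nan);
  // warm-start every fold from the full-data fit: same optimum (the
  // penalized likelihood is unimodal here), far fewer Newton steps
  FitResult full = newton_fit(X, y, ridge, max_iter, tol);
  const vec* a0 = full.ok ? &full.alpha : nullptr;
  const vec* b0 = full.ok ? &full.beta : nullptr;
  for (uword i = 0; i < n; ++i) {
    mat Xt(n - 1, X.n_cols);
    ivec yt(n - 1);
    uword k = 0;
    for (uword j = 0; j < n; ++j) {
      if (j == i) continue;
      Xt.row(k) = X.row(j);
      yt(k) = y(j);
      ++k;
    }
    FitResult r = newton_fit(Xt, yt, ridge, max_iter, tol, a0, b0);
    if (!r.ok) continue;
    double eta = X.n_cols ? dot(X.row(i), r.beta) : 0.0;
    double score = 0.0, Flo = 0.0;
    for (int j = 0; j < K; ++j) {
      double Fhi = (j == K - 1) ? 1.0 : logistic(r.alpha(j) - eta);
      score += j * (Fhi - Flo);
      Flo = Fhi;
    }
    out(i) = score;
  }
  return out;
}
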