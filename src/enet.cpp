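// Elastic-net core: covariance-update coordinate descent, geometric lambda paths with warm starts, leave-one-out
// hyperparameter selection, and a fully nested outer leave-one-out driver
// (median imputation + standardization refitted inside every fold).
//
// Objective, for n rows:
//   (1/(2n)) * sum_i (y_i - b0 - x_i.beta)^2
//     + lambda * ( rho * ||beta||_1 + (1 - rho)/2 * ||beta||_2^2 )
//
// All solves run on centered data (b0 recovered as ybar - xbar.beta); the
// bookkeeping below is in terms of centered cross-products, so a solve never
// touches the data matrix itself.
// iteration stops when a sweep's largest variance-weighted squared
// coefficient change, relative to the response variance, falls below tol
// (the usual coordinate-descent practice for penalized regression).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Coordinate descent on centered data via Gram products.
// Gc = X_c' X_c, gc = X_c' y_c, ytyc = ||y_c||^2, n = row count.
// beta is the warm start and is overwritten; c = gc - Gc*beta is maintained
// incrementally by the caller across lambda values.
// Convergence follows the usual coordinate-descent practice for penalized
// regression: a sweep's largest variance-weighted squared coefficient
// change, relative to the response variance, must drop below tol
// (max_j dbeta_j^2 * (Gc_jj/n) / (ytyc/n) < tol). Inner sweeps run over
// the active set only, with full sweeps to check the inactive
// coordinates. Raw-pointer loops: this kernel dominates the cost of the
// nested cross-validation and the permutation tests built on it.
// Returns sweep count, or -1 if maxit was exhausted.
static int cd_solve(const mat& Gc, const vec& gc, double ytyc, double n,
                    double rho, double lambda, vec& beta, vec& c,
                    double tol, int maxit, uword* active_buf) {
  const uword p = beta.n_elem;
  const double l1 = lambda * rho;
  const double l2 = lambda * (1.0 - rho);
  const double yvar = ytyc / n;
  const double thr = tol * (yvar > 0.0 ? yvar : 1.0);
  const double inv_n = 1.0 / n;
  int sweeps = 0;

  double* b = beta.memptr();
  double* cp = c.memptr();
  const double* G = Gc.memptr();    // column-major p x p

  uword nactive = 0;
  for (uword j = 0; j < p; ++j) if (b[j] != 0.0) active_buf[nactive++] = j;

  bool full_pass = true;
  while (true) {
    double maxdelta = 0.0;
    const uword nidx = full_pass ? p : nactive;
    for (uword k = 0; k < nidx; ++k) {
      const uword j = full_pass ? k : active_buf[k];
      const double* Gj = G + j * p;
      const double gjj = Gj[j];
      const double denom = gjj * inv_n + l2;
      if (denom <= 0.0) continue;      // constant column: leave at 0
      const double bj_old = b[j];
      const double zj = (cp[j] + gjj * bj_old) * inv_n;
      const double bj = soft_threshold(zj, l1) / denom;
      if (bj != bj_old) {
        const double d = bj - bj_old;
        for (uword t = 0; t < p; ++t) cp[t] -= d * Gj[t];
        b[j] = bj;
        const double wdelta = d * d * gjj * inv_n;
        if (wdelta > maxdelta) maxdelta = wdelta;
      }
    }
    ++sweeps;
    if (sweeps >= maxit) return -1;
    if (maxdelta < thr) {
      if (full_pass) break;       // converged on a full sweep: KKT satisfied
      full_pass = true;           // active set converged; verify all coords
    } else {
      if (full_pass) {
        nactive = 0;
        for (uword j = 0; j < p; ++j) {
          if (b[j] != 0.0) active_buf[nactive++] = j;
        }
      }
      full_pass = false;
    }
  }
  return sweeps;
}

// Solve a decreasing lambda path with warm starts. betas: p x nlambda (out).
static bool cd_path(const mat& Gc, const vec& gc, double ytyc, double n,
                    double rho, const vec& lambdas, mat& betas, double tol,
                    int maxit, uword& bad_idx) {
  const uword p = gc.n_elem;
  vec beta(p, fill::zeros);
  vec c = gc;  // gc - Gc*0
  std::vector<uword> abuf(p);
  for (uword l = 0; l < lambdas.n_elem; ++l) {
    int s = cd_solve(Gc, gc, ytyc, n, rho, lambdas[l], beta, c, tol, maxit,
                     abuf.data());
    if (s < 0) { bad_idx = l; return false; }
    betas.col(l) = beta;
  }
  return true;
}

// Geometric path of length nlambda from lam_max down to lam_max * min_ratio.
static vec make_path(double lam_max, int nlambda, double min_ratio) {
  if (lam_max <= 0.0) lam_max = 1.0;  // degenerate (constant y/X): any path
  vec path(nlambda);                  // shrinks everything to zero anyway
  if (nlambda == 1) { path[0] = lam_max; return path; }
  const double step = std::log(min_ratio) / (nlambda - 1);
  for (int l = 0; l < nlambda; ++l) path[l] = lam_max * std::exp(step * l);
  return path;
}

struct CvSelection {
  double rho, lambda;
  uword rho_idx, lambda_idx;
  mat cv_mse;     // n_rho x nlambda
  mat lambdas;    // n_rho x nlambda
};

// Leave-one-out CV over (rho grid) x (lambda path) on rows of X. The path
// per rho is anchored at lambda_max computed on all rows of X. Ties within
// tie_tol of the minimal error resolve to the largest lambda, then the
// smallest rho (the sparser, more regularized model).
static CvSelection inner_cv(const mat& X, const vec& y, const vec& rho_grid,
                            int nlambda, double min_ratio, double tol,
                            int maxit, double tie_tol = 1e-12) {
  const uword n = X.n_rows, p = X.n_cols;
  const uword nr = rho_grid.n_elem;

  const mat G = X.t() * X;
  const vec g = X.t() * y;
  const vec Sx = sum(X, 0).t();
  const double Sy = accu(y);
  const double Syy = dot(y, y);

  // full-data centered correlations, for lambda_max per rho
  const vec gc_full = g - Sx * (Sy / n);
  const double cmax = gc_full.n_elem ? abs(gc_full).max() : 0.0;

  CvSelection sel;
  sel.cv_mse.zeros(nr, nlambda);
  sel.lambdas.zeros(nr, nlambda);

  // per-fold centered Gram products (fold = leave row i out)
  std::vector<mat> Gc_f(n);
  std::vector<vec> gc_f(n);
  vec ytyc_f(n);
  for (uword i = 0; i < n; ++i) {
    const rowvec xi = X.row(i);
    const vec Sxi = Sx - xi.t();
    const double Syi = Sy - y[i];
    const double ni = (double)(n - 1);
    Gc_f[i] = G - xi.t() * xi - (Sxi * Sxi.t()) / ni;
    gc_f[i] = g - y[i] * xi.t() - Sxi * (Syi / ni);
    ytyc_f[i] = Syy - y[i] * y[i] - Syi * Syi / ni;
  }

  for (uword r = 0; r < nr; ++r) {
    const double rho = rho_grid[r];
    const double lam_max = (rho > 0.0) ? cmax / (n * rho) : cmax * 10.0 / n;
    const vec path = make_path(lam_max, nlambda, min_ratio);
    sel.lambdas.row(r) = path.t();

    mat sqerr(n, nlambda, fill::zeros);
    for (uword i = 0; i < n; ++i) {
      const double ni = (double)(n - 1);
      mat betas(p, nlambda);
      uword bad = 0;
      if (!cd_path(Gc_f[i], gc_f[i], ytyc_f[i], ni, rho, path, betas, tol,
                   maxit, bad))
        Rcpp::stop("elastic net failed to converge (rho=%g, lambda=%g)",
                   rho, path[bad]);
      const vec w = X.row(i).t() - (Sx - X.row(i).t()) / ni;
      const double ybar = (Sy - y[i]) / ni;
      const rowvec preds = w.t() * betas;   // pred_l = ybar + (xi - xbar).beta_l
      for (int l = 0; l < nlambda; ++l) {
        const double e = y[i] - (ybar + preds[l]);
        sqerr(i, l) = e * e;
      }
    }
    sel.cv_mse.row(r) = mean(sqerr, 0);
  }

  // tie-aware argmin: largest lambda (smallest lambda index), then smallest
  // rho; rho grid is increasing so scan lambda index outer, rho inner
  const double best = sel.cv_mse.min();
  sel.rho_idx = 0; sel.lambda_idx = 0;
  bool found = false;
  for (uword l = 0; l < (uword)nlambda && !found; ++l) {
    for (uword r = 0; r < nr && !found; ++r) {
      if (sel.cv_mse(r, l) <= best + tie_tol) {
        sel.rho_idx = r; sel.lambda_idx = l; found = true;
      }
    }
  }
  sel.rho = rho_grid[sel.rho_idx];
  sel.lambda = sel.lambdas(sel.rho_idx, sel.lambda_idx);
  return sel;
}

// Fit at a fixed (rho, lambda) on all rows of X; returns beta and b0.
static void fit_at(const mat& X, const vec& y, double rho, double lambda,
                   double tol, int maxit, vec& beta, double& b0) {
  const uword n = X.n_rows, p = X.n_cols;
  const vec Sx = sum(X, 0).t();
  const double Sy = accu(y);
  const mat Gc = X.t() * X - (Sx * Sx.t()) / n;
  const vec gc = X.t() * y - Sx * (Sy / n);
  const double ytyc = dot(y, y) - Sy * Sy / n;
  beta.zeros(p);
  vec c = gc;
  std::vector<uword> abuf(p);
  if (cd_solve(Gc, gc, ytyc, (double)n, rho, lambda, beta, c, tol,
               maxit, abuf.data()) < 0)
    Rcpp::stop("elastic net failed to converge (rho=%g, lambda=%g)",
               rho, lambda);
  b0 = Sy / n - dot(Sx / n, beta);
}

// [[Rcpp::export]]
Rcpp::List enet_solve_cpp(const arma::mat& X, const arma::vec& y, double rho,
                          double lambda, double tol, int maxit) {
  vec beta; double b0;
  fit_at(X, y, rho, lambda, tol, maxit, beta, b0);
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("intercept") = b0);
}

// [[Rcpp::export]]
Rcpp::List enet_path_cpp(const arma::mat& X, const arma::vec& y, double rho,
                         const arma::vec& lambdas, double tol, int maxit) {
  const uword n = X.n_rows, p = X.n_cols;
  const vec Sx = sum(X, 0).t();
  const double Sy = accu(y);
  const mat Gc = X.t() * X - (Sx * Sx.t()) / n;
  const vec gc = X.t() * y - Sx * (Sy / n);
  const double ytyc = dot(y, y) - Sy * Sy / n;
  mat betas(p, lambdas.n_elem);
  uword bad = 0;
  if (!cd_path(Gc, gc, ytyc, (double)n, rho, lambdas, betas, tol, maxit,
               bad))
    Rcpp::stop("elastic net failed to converge (rho=%g, lambda=%g)",
               rho, lambdas[bad]);
  vec b0(lambdas.n_elem);
  for (uword l = 0; l < lambdas.n_elem; ++l)
    b0[l] = Sy / n - dot(Sx / n, betas.col(l));
  return Rcpp::List::create(Rcpp::Named("betas") = betas,
                            Rcpp::Named("intercepts") = b0);
}

// [[Rcpp::export]]
double enet_lambda_max_cpp(const arma::mat& X, const arma::vec& y,
                           double rho) {
  const uword n = X.n_rows;
  const vec Sx = sum(X, 0).t();
  const vec gc = X.t() * y - Sx * (accu(y) / n);
  const double cmax = gc.n_elem ? abs(gc).max() : 0.0;
  return cmax / (n * rho);
}

// [[Rcpp::export]]
Rcpp::List enet_cv_fit_cpp(const arma::mat& X, const arma::vec& y,
                           const arma::vec& rho_grid, int nlambda,
                           double lambda_min_ratio, double tol, int maxit) {
  CvSelection sel = inner_cv(X, y, rho_grid, nlambda, lambda_min_ratio,
                             tol, maxit);
  vec beta; double b0;
  fit_at(X, y, sel.rho, sel.lambda, tol, maxit, beta, b0);
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta,
      Rcpp::Named("intercept") = b0,
      Rcpp::Named("rho") = sel.rho,
      Rcpp::Named("lambda") = sel.lambda,
      Rcpp::Named("cv_mse") = sel.cv_mse,
      Rcpp::Named("lambdas") = sel.lambdas);
}

// median of the finite entries of v (midpoint convention for even counts)
static double finite_median(const vec& v, bool& any_finite) {
  vec f = v(find_finite(v));
  if (f.n_elem == 0) { any_finite = false; return 0.0; }
  any_finite = true;
  f = sort(f);
  const uword m = f.n_elem;
  return (m % 2 == 1) ? f[m / 2] : 0.5 * (f[m / 2 - 1] + f[m / 2]);
}

// Impute missing cells of (train, test row) with training medians, then
// center/scale by training mean and population sd (guard: sd==0 -> scale 1).
static void preprocess_fold(const mat& Xtrain_raw, mat& Xtrain,
                            rowvec& test_row) {
  const uword p = Xtrain_raw.n_cols;
  Xtrain = Xtrain_raw;
  for (uword j = 0; j < p; ++j) {
    bool ok;
    const double med = finite_median(Xtrain_raw.col(j), ok);
    if (!ok) Rcpp::stop("column %d has no non-missing training values",
                        (int)(j + 1));
    vec col = Xtrain.col(j);
    col(find_nonfinite(col)).fill(med);
    const double mu = mean(col);
    const double v = mean(square(col - mu));   // denominator n
    const double sc = (v > 0.0) ? std::sqrt(v) : 1.0;
    Xtrain.col(j) = (col - mu) / sc;
    double t = test_row[j];
    if (!std::isfinite(t)) t = med;
    test_row[j] = (t - mu) / sc;
  }
}

// Outer leave-one-out over raw (possibly NA) encoded features: per fold,
// impute + standardize on the training rows, select (rho, lambda) by inner
// leave-one-out, refit, predict the held-out row.
// [[Rcpp::export]]
Rcpp::List nested_loocv_enet_cpp(const arma::mat& Xraw, const arma::vec& y,
                                 const arma::vec& rho_grid, int nlambda,
                                 double lambda_min_ratio, double tol,
                                 int maxit) {
  const uword n = Xraw.n_rows, p = Xraw.n_cols;
  if (n < 3) Rcpp::stop("need at least 3 rows for nested LOOCV");
  vec preds(n), rhos(n), lambdas(n);
  ivec nretained(n);
  mat betas(p, n);
  vec intercepts(n);

  for (uword i = 0; i < n; ++i) {
    mat Xtr_raw(n - 1, p);
    vec ytr(n - 1);
    uword r = 0;
    for (uword k = 0; k < n; ++k) {
      if (k == i) continue;
      Xtr_raw.row(r) = Xraw.row(k);
      ytr[r] = y[k];
      ++r;
    }
    rowvec xi = Xraw.row(i);
    mat Xtr;
    preprocess_fold(Xtr_raw, Xtr, xi);

    CvSelection sel = inner_cv(Xtr, ytr, rho_grid, nlambda,
                               lambda_min_ratio, tol, maxit);
    vec beta; double b0;
    fit_at(Xtr, ytr, sel.rho, sel.lambda, tol, maxit, beta, b0);

    preds[i] = b0 + dot(xi, beta);
    rhos[i] = sel.rho;
    lambdas[i] = sel.lambda;
    nretained[i] = (int)accu(beta != 0.0);
    betas.col(i) = beta;
    intercepts[i] = b0;
  }

  return Rcpp::List::create(
      Rcpp::Named("predictions") = preds,
      Rcpp::Named("rho") = rhos,
      Rcpp::Named("lambda") = lambdas,
      Rcpp::Named("n_retained") = nretained,
      Rcpp::Named("betas") = betas,
      Rcpp::Named("intercepts") = intercepts);
}
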