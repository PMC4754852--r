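// Per-gene logistic regression by iteratively reweighted least squares.
//
// The association scan fits one small logistic model per gene (outcome =
// ER/PR-positive, predictor = gene mean beta, plus shared covariates) and
// the bootstrap reruns that scan thousands of times, so the IRLS loop lives
// here rather than going through stats::glm. Results are checked against
// stats::glm in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct FitResult {
  double coef;
  double se;
  bool converged;
  int n_used;
};

// IRLS for y ~ X with binomial/logit link. Returns coefficient and SE of
// column `which` of X. Converges on the maximum relative coefficient
// change. Under complete or quasi-complete separation the MLE does not
// exist and the iterates diverge, so the fit runs out of iterations (or
// the weighted cross-product turns singular) and is flagged
// not-converged; finite large coefficients are legitimate for predictors
// compressed into a narrow range, as beta values often are, and are kept.
FitResult irls_fit(const mat& X, const vec& y, uword which,
                   int maxit = 100, double tol = 1e-10) {
  FitResult out{NA_REAL, NA_REAL, false, (int)y.n_elem};
  const uword p = X.n_cols;
  vec beta(p, fill::zeros);
  mat XtWX;
  bool ok = false;

  for (int it = 0; it < maxit; ++it) {
    vec eta = clamp(X * beta, -30.0, 30.0);
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = clamp(mu % (1.0 - mu), 1e-12, 0.25);
    vec z = eta + (y - mu) / w;
    XtWX = X.t() * (X.each_col() % w);
    vec XtWz = X.t() * (w % z);
    vec beta_new;
    bool solved = solve(beta_new, XtWX, XtWz,
                        solve_opts::no_approx + solve_opts::likely_sympd);
    if (!solved || !beta_new.is_finite()) return out;
    double step = abs(beta_new - beta).max();
    beta = beta_new;
    if (step < tol * (1.0 + abs(beta).max())) {
      ok = true;
      break;
    }
  }
  if (!ok) return out;
  // a solution sitting on the linear-predictor clamp is a diverging
  // (separated) fit that only stabilized because of the clamp
  vec eta_fin = X * beta;
  if (abs(eta_fin).max() >= 29.99) return out;

  mat cov;
  if (!inv_sympd(cov, XtWX)) {
    bool inv_ok = inv(cov, XtWX);
    if (!inv_ok) return out;
  }
  double se = std::sqrt(cov(which, which));
  double b = beta(which);
  if (!std::isfinite(se) || se <= 0.0 || !std::isfinite(b) ||
      se > 1e8 || std::abs(b) > 1e6) {
    return out;  // numerically degenerate fit
  }
  out.coef = b;
  out.se = se;
  out.converged = true;
  return out;
}

}  // namespace

// Fit, for each row g of `genes` (genes x samples), the model
//   logit P(y = 1) = b0 + b1 * genes[g, ] + covariates %*% c
// dropping samples where the gene value is NA. Covariate columns that are
// constant within the retained samples are dropped for that gene (keeps
// bootstrap resamples with absent factor levels full-rank).
// [[Rcpp::export(name = ".logistic_scan_cpp")]]
Rcpp::List logistic_scan_cpp(const arma::mat& genes, const arma::vec& y,
                             const arma::mat& covariates) {
  const uword G = genes.n_rows, n = genes.n_cols;
  if (y.n_elem != n) Rcpp::stop("outcome length does not match sample count");
  if (covariates.n_rows != 0 && covariates.n_rows != n)
    Rcpp::stop("covariate rows do not match sample count");

  Rcpp::NumericVector coef(G, NA_REAL), se(G, NA_REAL), pval(G, NA_REAL);
  Rcpp::LogicalVector converged(G);
  Rcpp::IntegerVector n_used(G);

  for (uword g = 0; g < G; ++g) {
    uvec keep = find_finite(genes.row(g).t());
    vec gv = genes.row(g).t();
    gv = gv.elem(keep);
    vec yy = y.elem(keep);
    n_used[g] = (int)keep.n_elem;
    converged[g] = false;

    double n1 = accu(yy), n0 = (double)yy.n_elem - n1;
    if (n1 < 2 || n0 < 2) continue;                 // need >= 2 per class
    if (gv.max() - gv.min() < 1e-12) continue;      // constant predictor

    // design: intercept, gene, then non-constant covariates
    uword pc = covariates.n_cols;
    std::vector<uword> keep_cov;
    mat C;
    if (pc > 0) {
      C = covariates.rows(keep);
      for (uword j = 0; j < pc; ++j)
        if (C.col(j).max() - C.col(j).min() > 1e-12) keep_cov.push_back(j);
    }
    mat X(keep.n_elem, 2 + keep_cov.size());
    X.col(0).ones();
    X.col(1) = gv;
    for (size_t j = 0; j < keep_cov.size(); ++j)
      X.col(2 + j) = C.col(keep_cov[j]);

    FitResult fr = irls_fit(X, yy, 1);
    if (!fr.converged) continue;
    coef[g] = fr.coef;
    se[g] = fr.se;
    pval[g] = 2.0 * R::pnorm(-std::abs(fr.coef / fr.se), 0.0, 1.0, 1, 0);
    if (pval[g] <= 0) pval[g] = std::numeric_limits<double>::min();
    converged[g] = true;
  }

  return Rcpp::List::create(Rcpp::Named("coefficient") = coef,
                            Rcpp::Named("std_error") = se,
                            Rcpp::Named("p_value") = pval,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("n_used") = n_used);
}
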