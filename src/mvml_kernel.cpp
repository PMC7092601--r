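#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Cholesky with escalating diagonal jitter: 1e-8 * mean(diag), x10, at most
// 3 retries. Returns false when the matrix is numerically indefinite even
// after jitter, in which case the caller maps the deviance to +Inf.
static bool chol_jitter(mat& L, const mat& V) {
  if (chol(L, V, "lower")) return true;
  double jit = 1e-8 * mean(V.diag());
  for (int k = 0; k < 3; ++k) {
    if (chol(L, V + jit * eye<mat>(V.n_rows, V.n_cols), "lower")) return true;
    jit *= 10.0;
  }
  return false;
}

//' @title Marginal deviance kernel (internal)
//' @description Per-subject marginal Gaussian deviance for the stacked
//'   multivariate multilevel model. V_j = Z_j Omega_G Z_j' + I ⊗ Omega_R,
//'   with Z_j shared within schedule groups so each distinct visit schedule
//'   is factorised once. When `beta_fixed` is NULL the fixed effects are
//'   profiled out by GLS and returned together with X'V⁻¹X. With
//'   `want_grad` the exact gradient of the (profiled) deviance with
//'   respect to Omega_G and Omega_R is returned: by the envelope theorem
//'   the GLS beta contributes nothing, and
//'   d(-2LL)/dV_j = V_j⁻¹ − w_j w_j' with w_j = V_j⁻¹ (y_j − X_j beta),
//'   mapped through Z_j (for Omega_G) and the visit-diagonal blocks
//'   (for Omega_R).
//' @keywords internal
// [[Rcpp::export]]
Rcpp::List mvml_kernel(const Rcpp::List& y, const Rcpp::List& X,
                       const Rcpp::List& Zg, const Rcpp::IntegerVector& gidx,
                       const arma::mat& omega_g, const arma::mat& omega_r,
                       Rcpp::Nullable<Rcpp::NumericVector> beta_fixed,
                       const bool want_grad = false) {
  const int m = y.size();
  const int G = Zg.size();
  const int K = omega_r.n_rows;

  std::vector<mat> Ls(G);
  for (int g = 0; g < G; ++g) {
    mat Z = Rcpp::as<mat>(Zg[g]);
    const int nv = Z.n_rows / K;
    mat V = Z * omega_g * Z.t();
    for (int t = 0; t < nv; ++t)
      V.submat(t * K, t * K, t * K + K - 1, t * K + K - 1) += omega_r;
    if (!chol_jitter(Ls[g], V))
      return Rcpp::List::create(Rcpp::Named("m2ll") = R_PosInf,
                                Rcpp::Named("ok") = false);
  }

  const int p = Rcpp::as<mat>(X[0]).n_cols;
  mat A(p, p, fill::zeros);
  vec b(p, fill::zeros);
  double yy = 0.0, logdet = 0.0;
  double N = 0.0;
  std::vector<mat> Xts(m);
  std::vector<vec> yts(m);

  for (int j = 0; j < m; ++j) {
    const mat& L = Ls[gidx[j] - 1];
    Xts[j] = solve(trimatl(L), Rcpp::as<mat>(X[j]));
    yts[j] = solve(trimatl(L), Rcpp::as<vec>(y[j]));
    A += Xts[j].t() * Xts[j];
    b += Xts[j].t() * yts[j];
    yy += dot(yts[j], yts[j]);
    logdet += 2.0 * sum(log(L.diag()));
    N += yts[j].n_elem;
  }

  vec beta;
  double quad;
  if (beta_fixed.isNotNull()) {
    beta = Rcpp::as<vec>(Rcpp::NumericVector(beta_fixed.get()));
    quad = yy - 2.0 * dot(b, beta) + as_scalar(beta.t() * A * beta);
  } else {
    bool ok = solve(beta, A, b,
                    solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok || !beta.is_finite())
      return Rcpp::List::create(Rcpp::Named("m2ll") = R_PosInf,
                                Rcpp::Named("ok") = false);
    quad = yy - dot(b, beta);
  }

  double m2ll = logdet + quad + N * std::log(2.0 * M_PI);
  if (!std::isfinite(m2ll)) m2ll = R_PosInf;

  if (!want_grad) {
    return Rcpp::List::create(
        Rcpp::Named("m2ll") = m2ll, Rcpp::Named("beta") = beta,
        Rcpp::Named("XtViX") = A, Rcpp::Named("n_obs") = N,
        Rcpp::Named("ok") = true);
  }

  // accumulate S_g = sum_{j in g} (V⁻¹ − w_j w_j') per schedule group,
  // then dG = sum_g Z_g' S_g Z_g, dR = sum_g sum_t [S_g]_tt-block
  mat dG(2 * K, 2 * K, fill::zeros);
  mat dR(K, K, fill::zeros);
  std::vector<mat> Sg(G);
  std::vector<int> mg(G, 0);
  for (int j = 0; j < m; ++j) {
    const int g = gidx[j] - 1;
    const mat& L = Ls[g];
    vec rt = yts[j] - Xts[j] * beta;
    vec w = solve(trimatu(L.t()), rt);
    if (Sg[g].n_rows == 0) Sg[g].zeros(L.n_rows, L.n_rows);
    Sg[g] -= w * w.t();
    mg[g] += 1;
  }
  for (int g = 0; g < G; ++g) {
    if (mg[g] == 0) continue;
    const mat& L = Ls[g];
    mat Linv = inv(trimatl(L));
    Sg[g] += mg[g] * (Linv.t() * Linv);
    mat Z = Rcpp::as<mat>(Zg[g]);
    dG += Z.t() * Sg[g] * Z;
    const int nv = Z.n_rows / K;
    for (int t = 0; t < nv; ++t)
      dR += Sg[g].submat(t * K, t * K, t * K + K - 1, t * K + K - 1);
  }

  return Rcpp::List::create(
      Rcpp::Named("m2ll") = m2ll, Rcpp::Named("beta") = beta,
      Rcpp::Named("XtViX") = A, Rcpp::Named("n_obs") = N,
      Rcpp::Named("dG") = dG, Rcpp::Named("dR") = dR,
      Rcpp::Named("ok") = true);
}
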