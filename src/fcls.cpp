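#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve min ||E.cols(S) * a - x||^2  s.t. sum(a) = 1 on the support S,
// via the KKT system; pseudo-inverse keeps rank-deficient (duplicate
// endmember) libraries solvable with the minimum-norm tie-break.
static vec kkt_solve(const mat& EtE, const vec& Etx, const uvec& S,
                     double* lambda_out) {
  const uword m = S.n_elem;
  mat K(m + 1, m + 1, fill::zeros);
  K.submat(0, 0, m - 1, m - 1) = 2.0 * EtE.submat(S, S);
  K.submat(0, m, m - 1, m).fill(1.0);
  K.submat(m, 0, m, m - 1).fill(1.0);
  vec rhs(m + 1);
  rhs.head(m) = 2.0 * Etx.elem(S);
  rhs(m) = 1.0;
  vec sol;
  if (!solve(sol, K, rhs, solve_opts::no_approx)) {
    sol = pinv(K) * rhs;
  }
  if (lambda_out) *lambda_out = sol(m);
  return sol.head(m);
}

// Fully constrained least squares for one pixel: active-set method on the
// non-negativity constraints with a release step, so the KKT conditions of
// the quadratic program (sum-to-one, a >= 0) hold at exit.
static vec fcls_one(const mat& E, const mat& EtE, const vec& Etx,
                    const vec& x, double tol) {
  const uword M = E.n_cols;
  uvec support = regspace<uvec>(0, M - 1);
  vec a_full(M, fill::zeros);
  double lambda = 0.0;

  for (uword outer = 0; outer < 4 * M + 8; ++outer) {
    // inner loop: shrink support until feasible (a >= 0)
    for (uword inner = 0; inner <= M; ++inner) {
      vec a = kkt_solve(EtE, Etx, support, &lambda);
      if (support.n_elem == 1 || a.min() >= -tol) {
        a_full.zeros();
        a_full.elem(support) = clamp(a, 0.0, datum::inf);
        a_full /= accu(a_full);
        break;
      }
      uword drop = a.index_min();
      support.shed_row(drop);
    }
    // KKT check on zeroed components: gradient g = 2 E'(E a - x);
    // stationarity gives g_i + lambda = 0 on the support, >= 0 off it.
    vec g = 2.0 * (EtE * a_full - Etx);
    double worst = 0.0;
    sword worst_i = -1;
    for (uword i = 0; i < M; ++i) {
      if (any(support == i)) continue;
      double v = g(i) + lambda;
      if (v < worst) { worst = v; worst_i = i; }
    }
    if (worst_i < 0 || worst >= -tol) break;
    support = sort(join_cols(support, uvec{(uword)worst_i}));
  }
  return a_full;
}

//' @noRd
// [[Rcpp::export(name = ".fcls_batch")]]
Rcpp::List fcls_batch(const arma::mat& X, const arma::mat& E,
                      double tol = 1e-10) {
  // X: n x bands mixed spectra (rows are pixels); E: M x bands endmembers
  const uword n = X.n_rows;
  const uword M = E.n_rows;
  mat Et = E.t();                 // bands x M
  mat EtE = Et.t() * Et;          // M x M
  mat A(n, M);
  vec res(n);
  for (uword i = 0; i < n; ++i) {
    vec x = X.row(i).t();
    vec Etx = Et.t() * x;
    vec a = fcls_one(Et, EtE, Etx, x, tol);
    A.row(i) = a.t();
    res(i) = std::sqrt(accu(square(Et * a - x)) / (double)x.n_elem);
  }
  return Rcpp::List::create(Rcpp::Named("abundance") = A,
                            Rcpp::Named("residual") = res);
}
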