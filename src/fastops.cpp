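#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo (1992) algorithm.
// sire/dam are 1-based pedigree indices in topological order, 0 = unknown.
// Returns F (inbreeding) and d (Mendelian sampling variance fraction,
// inbreeding-adjusted: 0.5 - 0.25(Fs + Fd) with both parents known, etc.).
// [[Rcpp::export]]
List inbreeding_ml_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n), D(n);
  std::vector<double> L(n, 0.0);
  int prev_s = -2, prev_d = -2;
  double prev_F = 0.0;
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;  // -1 = unknown
    if (s >= i || d >= i) stop("pedigree is not in topological order");
    if (s < 0 && d < 0) {
      F[i] = 0.0; D[i] = 1.0; prev_s = -2; prev_d = -2;
      continue;
    }
    if (s >= 0 && d >= 0) {
      D[i] = 0.5 - 0.25 * (F[s] + F[d]);
    } else {
      D[i] = 0.75 - 0.25 * (s >= 0 ? F[s] : F[d]);
    }
    if (s < 0 || d < 0) {  // one unknown parent: cannot be inbred
      F[i] = 0.0; prev_s = s; prev_d = d; prev_F = 0.0;
      continue;
    }
    if (s == prev_s && d == prev_d) {  // full sib of previous animal
      F[i] = prev_F;
      continue;
    }
    double aii = 0.0;
    L[i] = 1.0;
    for (int j = i; j >= 0; --j) {
      const double lj = L[j];
      if (lj == 0.0) continue;
      aii += lj * lj * D[j];
      const int sj = sire[j] - 1, dj = dam[j] - 1;
      if (sj >= 0) L[sj] += 0.5 * lj;
      if (dj >= 0) L[dj] += 0.5 * lj;
      L[j] = 0.0;
    }
    F[i] = aii - 1.0;
    prev_s = s; prev_d = d; prev_F = F[i];
  }
  return List::create(_["F"] = F, _["d"] = D);
}

// Preconditioned conjugate gradient with Jacobi (diagonal) preconditioning.
// Convergence criterion: square root of the relative difference between
// solutions of consecutive iterations, sqrt(||x_t - x_{t-1}||^2 / ||x_t||^2).
// [[Rcpp::export]]
List pcg_cpp(const arma::sp_mat& A, const arma::vec& b, const arma::vec& x0,
             double tol, int maxit) {
  arma::vec diag(A.n_rows);
  for (arma::uword k = 0; k < A.n_rows; ++k) {
    double dk = A(k, k);
    diag[k] = (dk > 0.0) ? 1.0 / dk : 1.0;
  }
  arma::vec x = x0;
  arma::vec r = b - A * x;
  arma::vec z = diag % r;
  arma::vec p = z;
  double rz = arma::dot(r, z);
  double cr = NA_REAL;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= maxit; ++it) {
    arma::vec Ap = A * p;
    double pAp = arma::dot(p, Ap);
    if (!std::isfinite(pAp)) {
      return List::create(_["solution"] = x, _["iterations"] = it,
                          _["criterion"] = cr, _["converged"] = false,
                          _["finite"] = false);
    }
    if (pAp == 0.0) {  // exact solution reached (zero residual)
      converged = arma::accu(arma::square(r)) == 0.0;
      it -= 1;  // this iteration performed no update
      break;
    }
    double alpha = rz / pAp;
    x += alpha * p;
    r -= alpha * Ap;
    double xn = arma::accu(arma::square(x));
    double dn = alpha * alpha * arma::accu(arma::square(p));
    cr = (xn > 0.0) ? std::sqrt(dn / xn) : 0.0;
    if (!std::isfinite(cr)) {
      return List::create(_["solution"] = x, _["iterations"] = it,
                          _["criterion"] = cr, _["converged"] = false,
                          _["finite"] = false);
    }
    if (cr < tol) { converged = true; break; }
    z = diag % r;
    double rz_new = arma::dot(r, z);
    p = z + (rz_new / rz) * p;
    rz = rz_new;
  }
  if (it > maxit) it = maxit;
  return List::create(_["solution"] = x, _["iterations"] = it,
                      _["criterion"] = cr, _["converged"] = converged,
                      _["finite"] = true);
}

// PCG with a mixed preconditioner: diagonal for the first g0 equations,
// dense per-animal blocks of size bs for the genetic equations. Binv holds
// the inverted blocks column-major, one bs*bs slab per animal.
// [[Rcpp::export]]
List pcg_block_cpp(const arma::sp_mat& A, const arma::vec& b,
                   const arma::vec& x0, double tol, int maxit,
                   int g0, int bs, const arma::mat& Binv) {
  const arma::uword n = A.n_rows;
  arma::vec diag(n);
  for (arma::uword k = 0; k < (arma::uword)g0; ++k) {
    double dk = A(k, k);
    diag[k] = (dk > 0.0) ? 1.0 / dk : 1.0;
  }
  const int n_blocks = (n - g0) / bs;
  auto apply_M = [&](const arma::vec& r) {
    arma::vec z(n);
    for (int k = 0; k < g0; ++k) z[k] = diag[k] * r[k];
    for (int a = 0; a < n_blocks; ++a) {
      const arma::mat Ba(const_cast<double*>(Binv.colptr(a)), bs, bs, false);
      z.subvec(g0 + a * bs, g0 + (a + 1) * bs - 1) =
        Ba * r.subvec(g0 + a * bs, g0 + (a + 1) * bs - 1);
    }
    return z;
  };
  arma::vec x = x0;
  arma::vec r = b - A * x;
  arma::vec z = apply_M(r);
  arma::vec p = z;
  double rz = arma::dot(r, z);
  double cr = NA_REAL;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= maxit; ++it) {
    arma::vec Ap = A * p;
    double pAp = arma::dot(p, Ap);
    if (!std::isfinite(pAp)) {
      return List::create(_["solution"] = x, _["iterations"] = it,
                          _["criterion"] = cr, _["converged"] = false,
                          _["finite"] = false);
    }
    if (pAp == 0.0) {  // exact solution reached (zero residual)
      converged = arma::accu(arma::square(r)) == 0.0;
      it -= 1;  // this iteration performed no update
      break;
    }
    double alpha = rz / pAp;
    x += alpha * p;
    r -= alpha * Ap;
    double xn = arma::accu(arma::square(x));
    double dn = alpha * alpha * arma::accu(arma::square(p));
    cr = (xn > 0.0) ? std::sqrt(dn / xn) : 0.0;
    if (!std::isfinite(cr)) {
      return List::create(_["solution"] = x, _["iterations"] = it,
                          _["criterion"] = cr, _["converged"] = false,
                          _["finite"] = false);
    }
    if (cr < tol) { converged = true; break; }
    z = apply_M(r);
    double rz_new = arma::dot(r, z);
    p = z + (rz_new / rz) * p;
    rz = rz_new;
  }
  if (it > maxit) it = maxit;
  return List::create(_["solution"] = x, _["iterations"] = it,
                      _["criterion"] = cr, _["converged"] = converged,
                      _["finite"] = true);
}

// PCG where the coefficient matrix is Adata + embed(Ginv (x) Ainv) at
// offset g0, applied without materializing the Kronecker product:
// the genetic part of the product is vec(Ginv * X * Ainv) with X the
// bs x n_animals reshape of the genetic solution segment.
// diag_pre holds the inverted diagonal for the first g0 equations; Binv
// the inverted per-animal preconditioner blocks.
// [[Rcpp::export]]
List pcg_kron_cpp(const arma::sp_mat& Adata, const arma::sp_mat& Ainv,
                  const arma::mat& Ginv, int g0, const arma::vec& b,
                  const arma::vec& x0, double tol, int maxit,
                  const arma::vec& diag_pre, const arma::mat& Binv) {
  const int bs = Ginv.n_rows;
  const int n_anim = Ainv.n_rows;
  const arma::uword n = g0 + (arma::uword)bs * n_anim;
  auto matvec = [&](const arma::vec& x) {
    arma::vec v = Adata * x;
    arma::mat X(const_cast<double*>(x.memptr()) + g0, bs, n_anim, false);
    arma::mat Y = Ginv * X;
    Y = arma::trans(Ainv * arma::trans(Y));  // = Ginv X Ainv (Ainv symmetric)
    v.subvec(g0, n - 1) += arma::vectorise(Y);
    return v;
  };
  auto apply_M = [&](const arma::vec& r) {
    arma::vec z(n);
    for (int k = 0; k < g0; ++k) z[k] = diag_pre[k] * r[k];
    for (int a = 0; a < n_anim; ++a) {
      const arma::mat Ba(const_cast<double*>(Binv.colptr(a)), bs, bs, false);
      z.subvec(g0 + a * bs, g0 + (a + 1) * bs - 1) =
        Ba * r.subvec(g0 + a * bs, g0 + (a + 1) * bs - 1);
    }
    return z;
  };
  arma::vec x = x0;
  arma::vec r = b - matvec(x);
  arma::vec z = apply_M(r);
  arma::vec p = z;
  double rz = arma::dot(r, z);
  double cr = NA_REAL;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= maxit; ++it) {
    arma::vec Ap = matvec(p);
    double pAp = arma::dot(p, Ap);
    if (!std::isfinite(pAp)) {
      return List::create(_["solution"] = x, _["iterations"] = it,
                          _["criterion"] = cr, _["converged"] = false,
                          _["finite"] = false);
    }
    if (pAp == 0.0) {  // exact solution reached (zero residual)
      converged = arma::accu(arma::square(r)) == 0.0;
      it -= 1;  // this iteration performed no update
      break;
    }
    double alpha = rz / pAp;
    x += alpha * p;
    r -= alpha * Ap;
    double xn = arma::accu(arma::square(x));
    double dn = alpha * alpha * arma::accu(arma::square(p));
    cr = (xn > 0.0) ? std::sqrt(dn / xn) : 0.0;
    if (!std::isfinite(cr)) {
      return List::create(_["solution"] = x, _["iterations"] = it,
                          _["criterion"] = cr, _["converged"] = false,
                          _["finite"] = false);
    }
    if (cr < tol) { converged = true; break; }
    z = apply_M(r);
    double rz_new = arma::dot(r, z);
    p = z + (rz_new / rz) * p;
    rz = rz_new;
  }
  if (it > maxit) it = maxit;
  return List::create(_["solution"] = x, _["iterations"] = it,
                      _["criterion"] = cr, _["converged"] = converged,
                      _["finite"] = true);
}
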