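// Profiled ML deviance for Gaussian random-intercept mixed models.
//
// The model is y = X beta + sum_k Z_k u_k + e with u_k ~ N(0, s2_k I) and
// e ~ N(0, s2_e I).  Writing gamma_k = s2_k / s2_e and theta_k = sqrt(gamma_k),
// the marginal covariance is s2_e * V0 with V0 = I + sum_k theta_k^2 Z_k Z_k'.
// beta and s2_e profile out analytically, leaving a deviance in theta alone:
//   dev(theta) = n log(2 pi rss/n) + n + log|V0|.
//
// Two algebraically equivalent evaluation paths are kept, chosen once per
// design by whichever dimension is smaller:
//   - observation side (n x n): V0 assembled from cached 0/1 similarity
//     matrices S_k = Z_k Z_k', one Cholesky of order n;
//   - level side (q x q): Woodbury identity through A = I + W Z'Z W with
//     W = diag(theta over columns of Z), one Cholesky of order q.
// Design-side matrices never change across optimizer iterations or bootstrap
// replicates, so they are cached behind an external pointer; only theta and
// the response vector cross the R/C++ boundary per evaluation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct VcData {
  bool nside;
  int n, K, p, q;
  mat X;        // n x p
  imat gidx;    // n x K, 1-based level index per factor
  ivec qvec;    // levels per factor
  ivec off;     // column offset of each factor's block in Z
  cube S;       // n x n x K similarity matrices (nside only)
  mat ZtZ, ZtX, XtX;  // qside only
  ivec kmap;    // column of Z -> factor, 1-based (qside only)
};

// [[Rcpp::export(name = ".vc_cache_cpp")]]
SEXP vc_cache_cpp(const arma::mat& X, const arma::imat& gidx,
                  const arma::ivec& qvec) {
  VcData* d = new VcData;
  d->n = X.n_rows; d->p = X.n_cols; d->K = gidx.n_cols;
  d->X = X; d->gidx = gidx; d->qvec = qvec;
  d->q = accu(qvec);
  d->off.set_size(d->K);
  int o = 0;
  for (int k = 0; k < d->K; ++k) { d->off[k] = o; o += qvec[k]; }
  d->nside = (d->n <= d->q);
  if (d->nside) {
    d->S.zeros(d->n, d->n, d->K);
    for (int k = 0; k < d->K; ++k)
      for (int i = 0; i < d->n; ++i)
        for (int j = 0; j < d->n; ++j)
          if (gidx(i, k) == gidx(j, k)) d->S(i, j, k) = 1.0;
  } else {
    mat Z(d->n, d->q, fill::zeros);
    d->kmap.set_size(d->q);
    for (int k = 0; k < d->K; ++k)
      for (int i = 0; i < d->n; ++i)
        Z(i, d->off[k] + gidx(i, k) - 1) = 1.0;
    for (int k = 0; k < d->K; ++k)
      for (int j = 0; j < qvec[k]; ++j) d->kmap[d->off[k] + j] = k + 1;
    d->ZtZ = Z.t() * Z;
    d->ZtX = Z.t() * X;
    d->XtX = X.t() * X;
  }
  Rcpp::XPtr<VcData> p(d, true);
  return p;
}

// [[Rcpp::export(name = ".vc_cache_ok_cpp")]]
bool vc_cache_ok_cpp(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != nullptr;
}

// group sums of v by factor levels -> length-q vector (Z'v)
static vec group_sums(const VcData& d, const vec& v) {
  vec out(d.q, fill::zeros);
  for (int k = 0; k < d.K; ++k)
    for (int i = 0; i < d.n; ++i)
      out[d.off[k] + d.gidx(i, k) - 1] += v[i];
  return out;
}

// Core computation; fills rss, logdet, beta (and L, needed by extraction).
// Returns false on numerical failure.
static bool prof_core(const VcData& d, const vec& theta, const vec& y,
                      mat& L, vec& beta, double& rss, double& logdet) {
  if (d.nside) {
    mat V(d.n, d.n, fill::eye);
    for (int k = 0; k < d.K; ++k) V += (theta[k] * theta[k]) * d.S.slice(k);
    if (!chol(L, V, "lower")) return false;
    mat Xy(d.n, d.p + 1);
    Xy.head_cols(d.p) = d.X;
    Xy.col(d.p) = y;
    mat M = solve(trimatl(L), Xy);
    mat G = M.t() * M;
    mat XtVX = G.submat(0, 0, d.p - 1, d.p - 1);
    vec XtVy = G.submat(0, d.p, d.p - 1, d.p);
    double ytVy = G(d.p, d.p);
    if (!solve(beta, XtVX, XtVy, solve_opts::no_approx)) return false;
    rss = ytVy - dot(beta, XtVy);
  } else {
    vec w(d.q);
    for (int j = 0; j < d.q; ++j) w[j] = theta[d.kmap[j] - 1];
    mat A = d.ZtZ;
    A.each_col() %= w;
    A.each_row() %= w.t();
    A.diag() += 1.0;
    if (!chol(L, A, "lower")) return false;
    vec Zty = group_sums(d, y);
    vec Xty = d.X.t() * y;
    double yty = dot(y, y);
    vec cu = solve(trimatl(L), w % Zty);
    mat CX = solve(trimatl(L), d.ZtX.each_col() % w);
    mat XtVX = d.XtX - CX.t() * CX;
    vec XtVy = Xty - CX.t() * cu;
    double ytVy = yty - dot(cu, cu);
    if (!solve(beta, XtVX, XtVy, solve_opts::no_approx)) return false;
    rss = ytVy - dot(beta, XtVy);
  }
  logdet = 2.0 * accu(log(L.diag()));
  return rss > 0 && std::isfinite(rss) && std::isfinite(logdet);
}

// [[Rcpp::export(name = ".vc_profdev_cpp")]]
double vc_profdev_cpp(SEXP ptr, const arma::vec& theta, const arma::vec& y) {
  const double BIG = 1e10;
  if (!vc_cache_ok_cpp(ptr)) Rcpp::stop("stale vcmm design cache");
  Rcpp::XPtr<VcData> d(ptr);
  mat L; vec beta; double rss, logdet;
  if (!prof_core(*d, theta, y, L, beta, rss, logdet)) return BIG;
  double sigma2 = rss / d->n;
  double dev = d->n * std::log(2.0 * M_PI * sigma2) + d->n + logdet;
  return std::isfinite(dev) ? dev : BIG;
}

// Deviance together with its analytic gradient in theta.  Uses the envelope
// theorem: at the profiled beta, d rss/d theta_k = -2 theta_k |Z_k'V0^{-1}r|^2,
// and d log|V0|/d theta_k = 2 theta_k tr(V0^{-1} Z_k Z_k').
// [[Rcpp::export(name = ".vc_devgrad_cpp")]]
Rcpp::List vc_devgrad_cpp(SEXP ptr, const arma::vec& theta,
                          const arma::vec& y) {
  const double BIG = 1e10;
  if (!vc_cache_ok_cpp(ptr)) Rcpp::stop("stale vcmm design cache");
  Rcpp::XPtr<VcData> d(ptr);
  mat L; vec beta; double rss, logdet;
  if (!prof_core(*d, theta, y, L, beta, rss, logdet))
    return Rcpp::List::create(Rcpp::Named("deviance") = BIG,
                              Rcpp::Named("gradient") = vec(d->K, fill::zeros));
  double dev = d->n * std::log(2.0 * M_PI * rss / d->n) + d->n + logdet;
  vec r = y - d->X * beta;
  vec grad(d->K);

  if (d->nside) {
    mat Linv = inv(trimatl(L));
    mat Vinv = Linv.t() * Linv;
    vec v = Vinv * r;
    vec Ztv = group_sums(*d, v);
    for (int k = 0; k < d->K; ++k) {
      double tr_k = accu(Vinv % d->S.slice(k));
      double quad = dot(Ztv.subvec(d->off[k], d->off[k] + d->qvec[k] - 1),
                        Ztv.subvec(d->off[k], d->off[k] + d->qvec[k] - 1));
      grad[k] = 2.0 * theta[k] * (tr_k - (d->n / rss) * quad);
    }
  } else {
    vec w(d->q);
    for (int j = 0; j < d->q; ++j) w[j] = theta[d->kmap[j] - 1];
    mat Linv = inv(trimatl(L));
    mat Ainv = Linv.t() * Linv;
    // B = W Ainv W
    mat B = Ainv;
    B.each_col() %= w;
    B.each_row() %= w.t();
    mat T = d->ZtZ * B;          // q x q
    // diag of Z'V0^{-1}Z = diag(ZtZ) - diag(T * ZtZ)
    vec dZVZ(d->q);
    for (int j = 0; j < d->q; ++j)
      dZVZ[j] = d->ZtZ(j, j) - dot(T.row(j), d->ZtZ.col(j));
    vec Ztr = group_sums(*d, r);
    vec ZVr = Ztr - d->ZtZ * (w % (Ainv * (w % Ztr)));
    for (int k = 0; k < d->K; ++k) {
      double tr_k = 0.0, quad = 0.0;
      for (int j = d->off[k]; j < d->off[k] + d->qvec[k]; ++j) {
        tr_k += dZVZ[j];
        quad += ZVr[j] * ZVr[j];
      }
      grad[k] = 2.0 * theta[k] * (tr_k - (d->n / rss) * quad);
    }
  }
  return Rcpp::List::create(Rcpp::Named("deviance") = dev,
                            Rcpp::Named("gradient") = grad);
}

// Full extraction at the optimum: beta, residual variance, deviance,
// unscaled covariance of beta, and the scaled random-effect modes
// u_hat = theta_k^2 Z_k' V0^{-1} (y - X beta), concatenated over factors.
// [[Rcpp::export(name = ".vc_extract_cpp")]]
Rcpp::List vc_extract_cpp(SEXP ptr, const arma::vec& theta,
                          const arma::vec& y) {
  if (!vc_cache_ok_cpp(ptr)) Rcpp::stop("stale vcmm design cache");
  Rcpp::XPtr<VcData> d(ptr);
  mat L; vec beta; double rss, logdet;
  if (!prof_core(*d, theta, y, L, beta, rss, logdet))
    Rcpp::stop("covariance factorization failed at the optimum");
  double sigma2 = rss / d->n;
  double dev = d->n * std::log(2.0 * M_PI * sigma2) + d->n + logdet;

  vec r = y - d->X * beta;
  vec u(d->q, fill::zeros);
  mat XtVX(d->p, d->p);
  if (d->nside) {
    vec v = solve(trimatu(L.t()), solve(trimatl(L), r));
    vec Ztv = group_sums(*d, v);
    for (int k = 0; k < d->K; ++k)
      u.subvec(d->off[k], d->off[k] + d->qvec[k] - 1) =
        (theta[k] * theta[k]) *
        Ztv.subvec(d->off[k], d->off[k] + d->qvec[k] - 1);
    mat MX = solve(trimatl(L), d->X);
    XtVX = MX.t() * MX;
  } else {
    vec w(d->q);
    for (int j = 0; j < d->q; ++j) w[j] = theta[d->kmap[j] - 1];
    vec Ztr = group_sums(*d, r);
    vec t1 = solve(trimatu(L.t()), solve(trimatl(L), w % Ztr));
    u = square(w) % (Ztr - d->ZtZ * (w % t1));
    mat CX = solve(trimatl(L), d->ZtX.each_col() % w);
    XtVX = d->XtX - CX.t() * CX;
  }
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("sigma2") = sigma2,
    Rcpp::Named("deviance") = dev,
    Rcpp::Named("u") = u,
    Rcpp::Named("cov_unscaled") = inv_sympd(symmatu(XtVX)));
}
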