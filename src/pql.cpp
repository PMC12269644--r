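// Penalized quasi-likelihood fitter for the overdispersed binomial mixed
// model used in ASM-aware meQTL mapping.
//
// Model (one pair): row t belongs to sample i(t) and carries counts
// y_t ~ Binomial(r_t, pi_t), logit(pi_t) = beta * a_t + x_{i(t)}' alpha + u_i,
// u ~ MVN(0, sg2 * K + se2 * I) shared across rows of a sample.
//
// Fitting: PQL working-variable updates; at each outer iteration the
// variance components are re-estimated by REML on the working linear mixed
// model via a 2-d Nelder-Mead on (log sg2, log se2). All m x m algebra is
// carried out in the eigenbasis of K = U diag(d) U' (decomposed once by the
// caller): the per-sample weight totals are rotated once per outer
// iteration (one syrk), after which each REML evaluation costs one m x m
// Cholesky, one triangular solve and one cross-product (Woodbury
// identity). Workspace matrices are allocated once per batch; Armadillo
// reuses them when shapes repeat.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// fitter state shared across the pairs of one batch
struct BmmBatch {
  const mat& U;          // m x m eigenvectors of K
  const vec& d;          // m eigenvalues
  uword m, p;            // samples, fixed effects (incl. genotype column)
  bool use_ml = false;   // ML working criterion (drop the REML projection term)

  // working-model sufficient statistics (rotated where m-dimensional)
  mat Ttil;              // m x m : U' diag(T) U
  mat B;                 // m x (p+1) : U' Z' W [X_row, z]
  mat Sxx;               // p x p
  vec Sxy;               // p
  double Syy = 0.0, sum_log_w = 0.0;

  // reusable buffers
  mat Us, M, L, Y, G, XVX, XVX_chol, XtViX_inv;
  vec lam, XVz, beta, q, util;

  BmmBatch(const mat& U_, const vec& d_, uword p_)
    : U(U_), d(d_), m(U_.n_rows), p(p_),
      Ttil(m, m), B(m, p_ + 1), Sxx(p_, p_), Sxy(p_),
      Us(m, m), M(m, m), L(m, m), Y(m, p_ + 1), G(p_ + 1, p_ + 1),
      XVX(p_, p_), XVX_chol(p_, p_), XtViX_inv(p_, p_),
      lam(m), XVz(p_), beta(p_), q(m), util(m) {}

  // REML -2 log-likelihood (up to a constant) of the working model at
  // (sg2, se2); V = W^{-1} + Z Sigma Z', M = diag(1/lam) + Ttil with
  // lam = sg2 d + se2 (Woodbury). Returns +inf on failure.
  double reml_nll(double sg2, double se2, bool want_blup) {
    lam = sg2 * d + se2;
    if (lam.min() <= 0) return datum::inf;
    M = Ttil;
    M.diag() += 1.0 / lam;
    if (!chol(L, M, "lower")) return datum::inf;
    double log_det_M = 2.0 * accu(log(L.diag()));
    double log_det_Sig = accu(log(lam));

    Y = solve(trimatl(L), B);
    G = Y.t() * Y;                      // B' M^{-1} B

    double zVz = Syy - G(p, p);
    XVz = Sxy - G.submat(0, p, p - 1, p);
    XVX = symmatu(Sxx - G.submat(0, 0, p - 1, p - 1));
    if (!chol(XVX_chol, XVX)) return datum::inf;
    double log_det_XVX = 2.0 * accu(log(XVX_chol.diag()));
    beta = solve(trimatu(XVX_chol), solve(trimatl(XVX_chol.t()), XVz));
    double zPz = zVz - dot(XVz, beta);

    if (want_blup) {
      q = B.col(p) - B.cols(0, p - 1) * beta;
      util = solve(trimatu(L.t()), solve(trimatl(L), q));
      XtViX_inv = solve(trimatu(XVX_chol),
                        solve(trimatl(XVX_chol.t()), eye<mat>(p, p)));
    }
    double crit = (-sum_log_w + log_det_Sig + log_det_M) + zPz;
    if (!use_ml) crit += log_det_XVX;
    return crit;
  }

  // 2-d Nelder-Mead on theta = (log sg2, log se2), clamped to [-20, 8];
  // a vanishing penalty on theta[0] breaks ties toward smaller sg2.
  void nelder_mead(vec& theta, int maxit, double step) {
    auto f = [&](const vec& th) {
      vec t = clamp(th, -20.0, 8.0);
      double v = reml_nll(std::exp(t(0)), std::exp(t(1)), false);
      return std::isfinite(v) ? v + 1e-8 * t(0) : 1e30;
    };
    mat V(2, 3); V.col(0) = theta;
    V.col(1) = theta + vec({step, 0.0});
    V.col(2) = theta + vec({0.0, step});
    vec fv(3);
    for (int j = 0; j < 3; ++j) fv(j) = f(V.col(j));
    for (int it = 0; it < maxit; ++it) {
      uvec ord = sort_index(fv);
      V = V.cols(ord); fv = fv(ord);
      if (fv(2) - fv(0) < 1e-8) break;
      vec centroid = (V.col(0) + V.col(1)) / 2.0;
      vec xr = centroid + (centroid - V.col(2));
      double fr = f(xr);
      if (fr < fv(0)) {
        vec xe = centroid + 2.0 * (centroid - V.col(2));
        double fe = f(xe);
        if (fe < fr) { V.col(2) = xe; fv(2) = fe; }
        else { V.col(2) = xr; fv(2) = fr; }
      } else if (fr < fv(1)) {
        V.col(2) = xr; fv(2) = fr;
      } else {
        vec xc = centroid + 0.5 * (V.col(2) - centroid);
        double fc = f(xc);
        if (fc < fv(2)) { V.col(2) = xc; fv(2) = fc; }
        else {
          V.col(1) = V.col(0) + 0.5 * (V.col(1) - V.col(0));
          V.col(2) = V.col(0) + 0.5 * (V.col(2) - V.col(0));
          fv(1) = f(V.col(1)); fv(2) = f(V.col(2));
        }
      }
    }
    uvec ord = sort_index(fv);
    theta = clamp(V.col(ord(0)), -20.0, 8.0);
  }
};

} // namespace

// Batch PQL fit. Rows of all pairs are concatenated; offsets (length
// n_pairs + 1, 0-based) delimit each pair's rows. X is the m x p
// sample-level fixed design (intercept + covariates); the genotype
// regressor a is row-level and becomes the first fixed effect. U, d hold
// the eigenvectors/eigenvalues of the (ridged) relatedness matrix.
// fix_sg2/fix_se2 >= 0 pin the variance components (0 is replaced by a
// negligible 1e-10 so the working covariance stays invertible);
// theta_init optionally warm-starts (sg2, se2) per pair, in which case a
// reduced Nelder-Mead step is used.
// Returns one row per pair:
// beta, se, sg2, se2, converged, n_rows, iter, alpha_1..alpha_p
// [[Rcpp::export]]
Rcpp::NumericMatrix bmm_pql_batch(Rcpp::NumericVector y_in,
                                  Rcpp::NumericVector r_in,
                                  Rcpp::NumericVector a_in,
                                  Rcpp::IntegerVector sample_in,
                                  Rcpp::IntegerVector offsets_in,
                                  Rcpp::NumericMatrix X_in,
                                  Rcpp::NumericMatrix U_in,
                                  Rcpp::NumericVector d_in,
                                  double tol = 1e-5,
                                  int max_iter = 100,
                                  int nm_iter_first = 30,
                                  int nm_iter_later = 10,
                                  double fix_sg2 = -1.0,
                                  double fix_se2 = -1.0,
                                  Rcpp::Nullable<Rcpp::NumericMatrix> theta_init = R_NilValue,
                                  bool use_ml = false) {
  const bool fixed = (fix_sg2 >= 0 && fix_se2 >= 0);
  const double sg2_pin = std::max(fix_sg2, 1e-10);
  const double se2_pin = std::max(fix_se2, 1e-10);

  vec y(y_in.begin(), y_in.size(), false);
  vec r(r_in.begin(), r_in.size(), false);
  vec a(a_in.begin(), a_in.size(), false);
  ivec smp(sample_in.begin(), sample_in.size(), false);
  ivec off(offsets_in.begin(), offsets_in.size(), false);
  mat X(X_in.begin(), X_in.nrow(), X_in.ncol(), false);
  mat U(U_in.begin(), U_in.nrow(), U_in.ncol(), false);
  vec d(d_in.begin(), d_in.size(), false);

  mat th_init;
  bool warm = theta_init.isNotNull();
  if (warm) {
    Rcpp::NumericMatrix ti(theta_init);
    th_init = mat(ti.begin(), ti.nrow(), ti.ncol());
  }

  const uword m = X.n_rows, p_cov = X.n_cols, p = p_cov + 1;
  const int n_pairs = off.n_elem - 1;
  Rcpp::NumericMatrix res(n_pairs, 7 + p_cov);
  BmmBatch W(U, d, p);
  W.use_ml = use_ml;
  vec T(m), sqT(m);
  mat Bc(m, p + 1);

  for (int pi = 0; pi < n_pairs; ++pi) {
    if (pi % 256 == 0) Rcpp::checkUserInterrupt();
    const int lo = off(pi), hi = off(pi + 1);
    const int n_rows = hi - lo;
    bool failed = (n_rows < 3);
    bool got_fit = false;
    bool warm_ok = warm && std::isfinite(th_init(pi, 0)) &&
                   std::isfinite(th_init(pi, 1));
    vec theta = fixed ? vec({std::log(sg2_pin), std::log(se2_pin)})
              : warm_ok ? vec({std::log(std::max(th_init(pi, 0), 1e-10)),
                               std::log(std::max(th_init(pi, 1), 1e-10))})
                        : vec({std::log(0.1), std::log(0.1)});
    const double nm_step = warm_ok ? 0.35 : 0.7;
    bool converged = false;
    int it = 0;

    if (!failed) {
      vec yy = y.subvec(lo, hi - 1), rr = r.subvec(lo, hi - 1),
          aa = a.subvec(lo, hi - 1);
      ivec ss = smp.subvec(lo, hi - 1);

      mat Xr(n_rows, p);                    // [a, X[sample,]]
      for (int t = 0; t < n_rows; ++t) {
        Xr(t, 0) = aa(t);
        for (uword j = 0; j < p_cov; ++j) Xr(t, j + 1) = X(ss(t), j);
      }

      vec eta = log((yy + 0.5) / (rr - yy + 0.5));
      vec beta_old(p, fill::zeros), sig_old = {0.1, 0.1};

      for (it = 0; it < max_iter; ++it) {
        vec mu = 1.0 / (1.0 + exp(-eta));
        vec w = rr % mu % (1.0 - mu);
        w = clamp(w, 1e-6, datum::inf);
        vec z = eta + (yy - rr % mu) / w;

        T.zeros(); Bc.zeros();
        for (int t = 0; t < n_rows; ++t) {
          const int s = ss(t);
          const double wt = w(t);
          T(s) += wt;
          for (uword j = 0; j < p; ++j) Bc(s, j) += wt * Xr(t, j);
          Bc(s, p) += wt * z(t);
        }
        // Ttil = U' diag(T) U computed as a symmetric cross-product
        sqT = sqrt(T);
        W.Us = U.each_col() % sqT;
        W.Ttil = W.Us.t() * W.Us;
        W.B = U.t() * Bc;
        W.Syy = accu(w % z % z);
        W.Sxy = Xr.t() * (w % z);
        W.Sxx = Xr.t() * (Xr.each_col() % w);
        W.sum_log_w = accu(log(w));

        // nm_iter_later == 0 freezes the variance components after the
        // first iteration's estimate (used for warm-started refits)
        if (!fixed && (it == 0 || nm_iter_later > 0)) {
          W.nelder_mead(theta, it == 0 ? nm_iter_first : nm_iter_later,
                        nm_step);
        }
        double sg2 = std::exp(theta(0)), se2 = std::exp(theta(1));
        double nll = W.reml_nll(sg2, se2, true);
        if (!std::isfinite(nll)) { failed = true; break; }
        got_fit = true;

        vec u = U * W.util;
        vec eta_new(n_rows);
        for (int t = 0; t < n_rows; ++t) {
          eta_new(t) = dot(Xr.row(t), W.beta) + u(ss(t));
        }
        double db = abs(W.beta - beta_old).max();
        double ds = std::max(std::fabs(sg2 - sig_old(0)),
                             std::fabs(se2 - sig_old(1)));
        beta_old = W.beta; sig_old = {sg2, se2};
        eta = eta_new;
        if (it > 0 && db < tol && ds < tol) { converged = true; ++it; break; }
      }
    }

    if (!failed && got_fit) {
      res(pi, 0) = W.beta(0);
      res(pi, 1) = std::sqrt(W.XtViX_inv(0, 0));
      res(pi, 2) = std::exp(theta(0));
      res(pi, 3) = std::exp(theta(1));
      res(pi, 4) = converged ? 1 : 0;
      res(pi, 5) = n_rows;
      res(pi, 6) = it;
      for (uword j = 0; j < p_cov; ++j) res(pi, 7 + j) = W.beta(j + 1);
    } else {
      for (int j = 0; j < 7 + (int)p_cov; ++j) res(pi, j) = NA_REAL;
      res(pi, 4) = 0; res(pi, 5) = n_rows; res(pi, 6) = it;
    }
  }
  return res;
}
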