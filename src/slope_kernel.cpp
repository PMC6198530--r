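// Blockwise profile likelihood for the per-probe longitudinal mixed model
//
//   y_i = X_i u + Z_i g_i + e_i,   g_i ~ N(0, s2e * Gamma),  e_i ~ N(0, s2e I)
//
// Individuals are independent blocks; Z_i holds a per-individual intercept
// column and/or a slope column on standardized age. Gamma is the random-effect
// covariance expressed as a ratio to the residual variance, so u and s2e can
// be profiled out and the optimizer only sees the 1-3 free entries of Gamma.
//
// Writing V_i = s2e * (I + Z_i Gamma Z_i'), the Woodbury identity
//   (I + Z G Z')^{-1} = I - Z G (I + Z'Z G)^{-1} Z'
// holds for any PSD G (including singular ones, which occur on the
// boundary of the parameter space), and det(I + Z G Z') = det(I + Z'Z G).
// Every quantity reduces to q x q algebra with q <= 2; the optimizer calls
// this thousands of times per probe scan, so the inner loop uses fixed-size
// stack arrays rather than general matrix objects.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int PMAX = 8;  // max fixed-effect columns handled

// Invert (I_q + C * Gamma) in place; returns log|I + C Gamma| or NaN.
// q <= 2; C and Gamma symmetric q x q in row-major 2x2 storage.
static inline double inv_iplus(const double C[4], const double G[4], int q,
                               double Minv[4]) {
  if (q == 1) {
    double m = 1.0 + C[0] * G[0];
    if (m <= 0) return NA_REAL;
    Minv[0] = 1.0 / m;
    return std::log(m);
  }
  double m11 = 1.0 + C[0] * G[0] + C[1] * G[2];
  double m12 = C[0] * G[1] + C[1] * G[3];
  double m21 = C[2] * G[0] + C[3] * G[2];
  double m22 = 1.0 + C[2] * G[1] + C[3] * G[3];
  double det = m11 * m22 - m12 * m21;
  if (det <= 0) return NA_REAL;
  Minv[0] = m22 / det; Minv[1] = -m12 / det;
  Minv[2] = -m21 / det; Minv[3] = m11 / det;
  return std::log(det);
}

// K = Gamma * Minv (q x q)
static inline void gamma_times(const double G[4], const double Minv[4], int q,
                               double K[4]) {
  if (q == 1) { K[0] = G[0] * Minv[0]; return; }
  K[0] = G[0] * Minv[0] + G[1] * Minv[2];
  K[1] = G[0] * Minv[1] + G[1] * Minv[3];
  K[2] = G[2] * Minv[0] + G[3] * Minv[2];
  K[3] = G[2] * Minv[1] + G[3] * Minv[3];
}

// Accumulate A = X'V*^-1 X, b = X'V*^-1 y, qyy = y'V*^-1 y, ldet.
// Returns false if a block determinant is non-positive.
static bool accumulate(const vec& y, const mat& X, const mat& Z,
                       const ivec& grp_start, const ivec& grp_size,
                       const double G[4], int q,
                       double* A, double* b, double& qyy, double& ldet) {
  const int p = (int)X.n_cols;
  const int nblk = (int)grp_start.n_elem;
  for (int j = 0; j < p * p; ++j) A[j] = 0.0;
  for (int j = 0; j < p; ++j) b[j] = 0.0;
  qyy = 0.0; ldet = 0.0;
  const double* xp = X.memptr();
  const double* zp = Z.memptr();
  const double* yp = y.memptr();
  const int N = (int)y.n_elem;

  for (int i = 0; i < nblk; ++i) {
    const int r0 = grp_start[i], m = grp_size[i];
    double C[4] = {0, 0, 0, 0};        // Z'Z
    double ZtX[2 * PMAX];              // q x p, row-major
    double Zty[2] = {0, 0};
    for (int j = 0; j < q * p; ++j) ZtX[j] = 0.0;
    for (int r = r0; r < r0 + m; ++r) {
      double z0 = zp[r], z1 = (q == 2) ? zp[N + r] : 0.0;
      C[0] += z0 * z0;
      if (q == 2) { C[1] += z0 * z1; C[3] += z1 * z1; }
      double yr = yp[r];
      Zty[0] += z0 * yr;
      if (q == 2) Zty[1] += z1 * yr;
      for (int c = 0; c < p; ++c) {
        double xv = xp[c * N + r];
        ZtX[c] += z0 * xv;
        if (q == 2) ZtX[p + c] += z1 * xv;
      }
      // global crossproducts (accumulated once per row)
      for (int c = 0; c < p; ++c) {
        double xv = xp[c * N + r];
        b[c] += xv * yr;
        for (int c2 = c; c2 < p; ++c2) A[c * p + c2] += xv * xp[c2 * N + r];
      }
      qyy += yr * yr;
    }
    C[2] = C[1];
    double Minv[4], K[4];
    double ld = inv_iplus(C, G, q, Minv);
    if (!std::isfinite(ld)) return false;
    ldet += ld;
    gamma_times(G, Minv, q, K);
    // w = K * Zty ; qyy -= Zty' w ; b -= ZtX' w ; A -= ZtX' K ZtX
    double w[2];
    w[0] = K[0] * Zty[0] + ((q == 2) ? K[1] * Zty[1] : 0.0);
    if (q == 2) w[1] = K[2] * Zty[0] + K[3] * Zty[1];
    qyy -= Zty[0] * w[0] + ((q == 2) ? Zty[1] * w[1] : 0.0);
    for (int c = 0; c < p; ++c) {
      b[c] -= ZtX[c] * w[0] + ((q == 2) ? ZtX[p + c] * w[1] : 0.0);
      // KZtX column c
      double k0 = K[0] * ZtX[c] + ((q == 2) ? K[1] * ZtX[p + c] : 0.0);
      double k1 = (q == 2) ? K[2] * ZtX[c] + K[3] * ZtX[p + c] : 0.0;
      for (int c2 = c; c2 < p; ++c2)
        A[c * p + c2] -= ZtX[c2] * k0 + ((q == 2) ? ZtX[p + c2] * k1 : 0.0);
    }
  }
  // symmetrize
  for (int c = 0; c < p; ++c)
    for (int c2 = 0; c2 < c; ++c2) A[c * p + c2] = A[c2 * p + c];
  return true;
}

static void unpack_gamma(const mat& Gamma, double G[4], int q) {
  G[0] = Gamma(0, 0);
  if (q == 2) { G[1] = Gamma(0, 1); G[2] = Gamma(1, 0); G[3] = Gamma(1, 1); }
  else G[1] = G[2] = G[3] = 0.0;
}

// Gradient of the profile negative log-likelihood with respect to Gamma.
//
// With r = y - X u(Gamma) and u the GLS minimizer of the V*-weighted RSS,
// the envelope theorem gives, for a symmetric perturbation of Gamma_kl,
//   d ldet / dGamma_kl = [Z' V*^-1 Z]_kl      (W below, blockwise)
//   d RSS  / dGamma_kl = -[Z' V*^-1 r]_k [Z' V*^-1 r]_l   (h below)
// so d nll / dGamma_kl = 0.5 * (W_kl - h_k h_l / s2e), summed over blocks.
// [[Rcpp::export(name = ".profile_nll_grad_cpp")]]
Rcpp::List profile_nll_grad_cpp(const arma::vec& y, const arma::mat& X,
                                const arma::mat& Z,
                                const arma::ivec& grp_start,
                                const arma::ivec& grp_size,
                                const arma::mat& Gamma) {
  const int N = (int)y.n_elem;
  const int p = (int)X.n_cols;
  const int q = (int)Z.n_cols;
  if (p > PMAX) Rcpp::stop("too many fixed-effect columns");
  if (q < 1 || q > 2) Rcpp::stop("random-effect design must have 1 or 2 columns");
  double G[4];
  unpack_gamma(Gamma, G, q);
  double Abuf[PMAX * PMAX], bbuf[PMAX], qyy, ldet;
  if (!accumulate(y, X, Z, grp_start, grp_size, G, q, Abuf, bbuf, qyy, ldet))
    Rcpp::stop("non-positive block determinant (Gamma outside the feasible region)");
  mat A(Abuf, p, p);
  vec b(bbuf, p);
  vec u;
  if (!solve(u, A, b, solve_opts::likely_sympd + solve_opts::no_approx))
    Rcpp::stop("singular fixed-effect design");
  double rss = qyy - dot(b, u);
  if (rss < 0) rss = 0;
  const double s2e = std::max(rss / (double)N, 1e-300);
  const double nll = 0.5 * (N * std::log(2.0 * M_PI * s2e) + (double)N + ldet);

  // second pass for the gradient terms
  const int nblk = (int)grp_start.n_elem;
  const double* zp = Z.memptr();
  double Wsum[4] = {0, 0, 0, 0};
  double hh[4] = {0, 0, 0, 0};   // sum over blocks of h h'
  for (int i = 0; i < nblk; ++i) {
    const int r0 = grp_start[i], m = grp_size[i];
    double C[4] = {0, 0, 0, 0}, Ztr[2] = {0, 0};
    for (int r = r0; r < r0 + m; ++r) {
      double z0 = zp[r], z1 = (q == 2) ? zp[N + r] : 0.0;
      double rr = y[r];
      for (int c = 0; c < p; ++c) rr -= X(r, c) * u[c];
      C[0] += z0 * z0;
      if (q == 2) { C[1] += z0 * z1; C[3] += z1 * z1; }
      Ztr[0] += z0 * rr;
      if (q == 2) Ztr[1] += z1 * rr;
    }
    C[2] = C[1];
    double Minv[4], K[4];
    inv_iplus(C, G, q, Minv);
    gamma_times(G, Minv, q, K);
    // KC = K * C ; W = C - C K C ; h = Ztr - C K Ztr
    double KC[4], h0, h1 = 0.0;
    if (q == 1) {
      KC[0] = K[0] * C[0];
      Wsum[0] += C[0] - C[0] * KC[0];
      h0 = Ztr[0] - C[0] * (K[0] * Ztr[0]);
      hh[0] += h0 * h0;
    } else {
      KC[0] = K[0] * C[0] + K[1] * C[2];
      KC[1] = K[0] * C[1] + K[1] * C[3];
      KC[2] = K[2] * C[0] + K[3] * C[2];
      KC[3] = K[2] * C[1] + K[3] * C[3];
      Wsum[0] += C[0] - (C[0] * KC[0] + C[1] * KC[2]);
      Wsum[1] += C[1] - (C[0] * KC[1] + C[1] * KC[3]);
      Wsum[3] += C[3] - (C[2] * KC[1] + C[3] * KC[3]);
      double w0 = K[0] * Ztr[0] + K[1] * Ztr[1];
      double w1 = K[2] * Ztr[0] + K[3] * Ztr[1];
      h0 = Ztr[0] - (C[0] * w0 + C[1] * w1);
      h1 = Ztr[1] - (C[2] * w0 + C[3] * w1);
      hh[0] += h0 * h0; hh[1] += h0 * h1; hh[3] += h1 * h1;
    }
  }
  Rcpp::NumericMatrix grad(q, q);
  grad(0, 0) = 0.5 * (Wsum[0] - hh[0] / s2e);
  if (q == 2) {
    grad(1, 1) = 0.5 * (Wsum[3] - hh[3] / s2e);
    grad(0, 1) = grad(1, 0) = 0.5 * (Wsum[1] - hh[1] / s2e);
  }
  return Rcpp::List::create(Rcpp::Named("nll") = nll,
                            Rcpp::Named("grad") = grad);
}

// Profile negative log-likelihood at Gamma; optionally also return the
// profiled fixed effects, residual variance, fixed-effect covariance and
// per-individual BLUPs.
// [[Rcpp::export(name = ".profile_nll_cpp")]]
Rcpp::List profile_nll_cpp(const arma::vec& y, const arma::mat& X,
                           const arma::mat& Z,
                           const arma::ivec& grp_start,
                           const arma::ivec& grp_size,
                           const arma::mat& Gamma,
                           const bool details) {
  const int N = (int)y.n_elem;
  const int p = (int)X.n_cols;
  const int q = (int)Z.n_cols;
  if (p > PMAX) Rcpp::stop("too many fixed-effect columns");
  if (q < 1 || q > 2) Rcpp::stop("random-effect design must have 1 or 2 columns");
  double G[4];
  unpack_gamma(Gamma, G, q);

  double Abuf[PMAX * PMAX], bbuf[PMAX], qyy, ldet;
  if (!accumulate(y, X, Z, grp_start, grp_size, G, q, Abuf, bbuf, qyy, ldet))
    Rcpp::stop("non-positive block determinant (Gamma outside the feasible region)");
  mat A(Abuf, p, p);   // row-major == col-major for symmetric A
  vec b(bbuf, p);
  vec u;
  if (!solve(u, A, b, solve_opts::likely_sympd + solve_opts::no_approx))
    Rcpp::stop("singular fixed-effect design");
  double rss = qyy - dot(b, u);
  if (rss < 0) rss = 0;                        // guard against rounding
  const double s2e = rss / (double)N;
  const double nll = 0.5 * (N * std::log(2.0 * M_PI * s2e) + (double)N + ldet);
  if (!details)
    return Rcpp::List::create(Rcpp::Named("nll") = nll);

  // BLUPs: g_i = Gamma (Z_i'r_i - C_i K_i Z_i'r_i), r = y - X u
  const int nblk = (int)grp_start.n_elem;
  mat blup(nblk, q);
  const double* zp = Z.memptr();
  for (int i = 0; i < nblk; ++i) {
    const int r0 = grp_start[i], m = grp_size[i];
    double C[4] = {0, 0, 0, 0}, Ztr[2] = {0, 0};
    for (int r = r0; r < r0 + m; ++r) {
      double z0 = zp[r], z1 = (q == 2) ? zp[N + r] : 0.0;
      double rr = y[r];
      for (int c = 0; c < p; ++c) rr -= X(r, c) * u[c];
      C[0] += z0 * z0;
      if (q == 2) { C[1] += z0 * z1; C[3] += z1 * z1; }
      Ztr[0] += z0 * rr;
      if (q == 2) Ztr[1] += z1 * rr;
    }
    C[2] = C[1];
    double Minv[4], K[4];
    inv_iplus(C, G, q, Minv);
    gamma_times(G, Minv, q, K);
    double w0 = K[0] * Ztr[0] + ((q == 2) ? K[1] * Ztr[1] : 0.0);
    double w1 = (q == 2) ? K[2] * Ztr[0] + K[3] * Ztr[1] : 0.0;
    double h0 = Ztr[0] - (C[0] * w0 + ((q == 2) ? C[1] * w1 : 0.0));
    double h1 = (q == 2) ? Ztr[1] - (C[2] * w0 + C[3] * w1) : 0.0;
    blup(i, 0) = G[0] * h0 + ((q == 2) ? G[1] * h1 : 0.0);
    if (q == 2) blup(i, 1) = G[2] * h0 + G[3] * h1;
  }
  mat Ainv = inv_sympd(symmatu(A));
  return Rcpp::List::create(
      Rcpp::Named("nll") = nll,
      Rcpp::Named("u") = u,
      Rcpp::Named("s2e") = s2e,
      Rcpp::Named("vcov_u") = Ainv * s2e,
      Rcpp::Named("blup") = blup);
}
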