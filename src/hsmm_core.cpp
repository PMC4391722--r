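// Forward-backward recursions for the explicit-duration HSMM.
//
// The recursions use the self-normalising rho/r formulation: every forward
// quantity is a proper conditional probability, so no log-space arithmetic
// is needed.  States are 0-based here; the R wrappers use 1-based indexing.
//
// Array layout: cubes are (M, d_max, T) with one slice per trial; the R side
// permutes to (T, M, d_max).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double PROB_FLOOR = 1e-300;

// Forward pass.
// B: T x M matrix of emission densities b_m(y_t, z_t).
// pi: length-M initial probabilities; A: M x M transition matrix (rows =
// "from" state at sojourn end); P: M x d_max duration probabilities.
// [[Rcpp::export]]
List hsmmForwardCpp(const arma::mat& B, const arma::vec& pi,
                    const arma::mat& A, const arma::mat& P) {
  const int T = B.n_rows, M = B.n_cols, D = P.n_cols;

  arma::cube alpha(M, D, T);          // alpha_{t|t-1}(m,d)
  arma::mat rho(T, M), E(T, M), F(T, M);
  arma::vec rinv(T);

  // alpha_{1|0}(m,d) = pi_m p_m(d)
  arma::mat ap = P;
  ap.each_col() %= pi;

  for (int t = 0; t < T; ++t) {
    alpha.slice(t) = ap;
    // predictive density r_t^{-1} = sum_m gamma_{t|t-1}(m) b_m(y_t,z_t)
    double r = 0.0;
    for (int m = 0; m < M; ++m)
      r += arma::accu(ap.row(m)) * B(t, m);
    if (!std::isfinite(r) || r < PROB_FLOOR)
      stop("predictive density underflow at trial %d", t + 1);
    rinv(t) = r;
    for (int m = 0; m < M; ++m) {
      rho(t, m) = B(t, m) / r;
      E(t, m) = ap(m, 0) * rho(t, m);  // E_t(m) = alpha(m,1) rho_m
    }
    for (int m = 0; m < M; ++m) {      // F_t(m) = sum_n a_nm E_t(n)
      double f = 0.0;
      for (int n = 0; n < M; ++n) f += A(n, m) * E(t, n);
      F(t, m) = f;
    }
    // alpha_{t+1|t}(m,d) = F_t(m) p_m(d) + rho_t(m) alpha_{t|t-1}(m,d+1)
    arma::mat nxt(M, D);
    for (int m = 0; m < M; ++m)
      for (int d = 0; d < D; ++d)
        nxt(m, d) = F(t, m) * P(m, d) +
          rho(t, m) * (d + 1 < D ? ap(m, d + 1) : 0.0);
    ap = nxt;
  }

  double loglik = arma::accu(arma::log(rinv));
  return List::create(_["alphaPred"] = alpha, _["rho"] = rho,
                      _["rInv"] = rinv, _["E"] = E, _["F"] = F,
                      _["logLik"] = loglik);
}

// Backward pass: beta_t(m,d) = alpha_{t|T}/alpha_{t|t-1}, with
// beta_T(m,d) = rho_m(y_T, z_T) for every d.
// [[Rcpp::export]]
List hsmmBackwardCpp(const arma::mat& rho, const arma::mat& A,
                     const arma::mat& P) {
  const int T = rho.n_rows, M = rho.n_cols, D = P.n_cols;

  arma::cube beta(M, D, T);
  arma::mat Estar(T, M), Fstar(T, M);

  for (int m = 0; m < M; ++m)
    beta.slice(T - 1).row(m).fill(rho(T - 1, m));

  for (int t = T - 1; t >= 0; --t) {
    if (t < T - 1) {
      arma::mat b(M, D);
      for (int m = 0; m < M; ++m) {
        b(m, 0) = Fstar(t + 1, m) * rho(t, m);
        for (int d = 1; d < D; ++d)
          b(m, d) = beta(m, d - 1, t + 1) * rho(t, m);
      }
      beta.slice(t) = b;
    }
    for (int m = 0; m < M; ++m)        // E*_t(m) = sum_d p_m(d) beta_t(m,d)
      Estar(t, m) = arma::dot(P.row(m), beta.slice(t).row(m));
    for (int m = 0; m < M; ++m) {      // F*_t(m) = sum_n a_mn E*_t(n)
      double f = 0.0;
      for (int n = 0; n < M; ++n) f += A(m, n) * Estar(t, n);
      Fstar(t, m) = f;
    }
  }
  return List::create(_["beta"] = beta, _["EStar"] = Estar,
                      _["FStar"] = Fstar);
}

// Fused E-step for the EM inner loop: runs both passes and accumulates only
// the sufficient statistics the M-step needs.  Returns:
//   logLik, gamma (T x M),
//   Asum(m,n)  = sum_{t>=2} T_{t|T}(m,n),
//   Psum(m,d)  = sum_{t>=2} D_{t|T}(m,d),
//   DdurSum(m) = sum_{t>=2} sum_d d * D_{t|T}(m,d)   (geometric update).
// [[Rcpp::export]]
List hsmmEStepStatsCpp(const arma::mat& B, const arma::vec& pi,
                       const arma::mat& A, const arma::mat& P) {
  const int T = B.n_rows, M = B.n_cols, D = P.n_cols;

  arma::cube alpha(M, D, T);
  arma::mat rho(T, M), E(T, M), F(T, M);
  arma::vec rinv(T);

  arma::mat ap = P;
  ap.each_col() %= pi;
  for (int t = 0; t < T; ++t) {
    alpha.slice(t) = ap;
    double r = 0.0;
    for (int m = 0; m < M; ++m)
      r += arma::accu(ap.row(m)) * B(t, m);
    if (!std::isfinite(r) || r < PROB_FLOOR)
      stop("predictive density underflow at trial %d", t + 1);
    rinv(t) = r;
    for (int m = 0; m < M; ++m) {
      rho(t, m) = B(t, m) / r;
      E(t, m) = ap(m, 0) * rho(t, m);
    }
    for (int m = 0; m < M; ++m) {
      double f = 0.0;
      for (int n = 0; n < M; ++n) f += A(n, m) * E(t, n);
      F(t, m) = f;
    }
    arma::mat nxt(M, D);
    for (int m = 0; m < M; ++m)
      for (int d = 0; d < D; ++d)
        nxt(m, d) = F(t, m) * P(m, d) +
          rho(t, m) * (d + 1 < D ? ap(m, d + 1) : 0.0);
    ap = nxt;
  }

  arma::mat gamma(T, M);
  arma::mat Asum(M, M, arma::fill::zeros), Psum(M, D, arma::fill::zeros);
  arma::vec DdurSum(M, arma::fill::zeros);

  arma::mat beta(M, D), Estar(M, 1), Fstar(M, 1);
  arma::mat betaNext(M, D);
  // backward sweep, accumulating as we go
  for (int t = T - 1; t >= 0; --t) {
    if (t == T - 1) {
      for (int m = 0; m < M; ++m) beta.row(m).fill(rho(t, m));
    } else {
      for (int m = 0; m < M; ++m) {
        beta(m, 0) = Fstar(m, 0) * rho(t, m);   // Fstar holds F*_{t+1}
        for (int d = 1; d < D; ++d)
          beta(m, d) = betaNext(m, d - 1) * rho(t, m);
      }
    }
    for (int m = 0; m < M; ++m)
      Estar(m, 0) = arma::dot(P.row(m), beta.row(m));
    for (int m = 0; m < M; ++m)
      gamma(t, m) = arma::dot(alpha.slice(t).row(m), beta.row(m));
    if (t >= 1) {
      for (int m = 0; m < M; ++m)
        for (int d = 0; d < D; ++d) {
          double Dtd = F(t - 1, m) * P(m, d) * beta(m, d);
          Psum(m, d) += Dtd;
          DdurSum(m) += (d + 1) * Dtd;
        }
      for (int m = 0; m < M; ++m)
        for (int n = 0; n < M; ++n)
          Asum(m, n) += E(t - 1, m) * A(m, n) * Estar(n, 0);
    }
    arma::mat FsNew(M, 1);
    for (int m = 0; m < M; ++m) {
      double f = 0.0;
      for (int n = 0; n < M; ++n) f += A(m, n) * Estar(n, 0);
      FsNew(m, 0) = f;
    }
    Fstar = FsNew;
    betaNext = beta;
  }

  return List::create(_["logLik"] = arma::accu(arma::log(rinv)),
                      _["gamma"] = gamma, _["Asum"] = Asum,
                      _["Psum"] = Psum, _["DdurSum"] = DdurSum);
}

// Smoothed quantities: alpha_{t|T} = alpha_{t|t-1} . beta_t,
// gamma_{t|T}(m) = sum_d alpha_{t|T}(m,d),
// D_{t|T}(m,d)   = F_{t-1}(m) p_m(d) beta_t(m,d)   (pi_m p_m(d) beta at t=1),
// T_{t|T}(m,n)   = E_{t-1}(m) a_mn E*_t(n).
// [[Rcpp::export]]
List hsmmSmoothCpp(const arma::cube& alpha, const arma::cube& beta,
                   const arma::mat& E, const arma::mat& F,
                   const arma::mat& Estar, const arma::vec& pi,
                   const arma::mat& A, const arma::mat& P) {
  const int M = alpha.n_rows, D = alpha.n_cols, T = alpha.n_slices;

  arma::cube alphaSmooth = alpha % beta;
  arma::mat gamma(T, M);
  arma::cube Dsm(M, D, T), Tsm(M, M, T, arma::fill::zeros);

  for (int t = 0; t < T; ++t)
    for (int m = 0; m < M; ++m)
      gamma(t, m) = arma::accu(alphaSmooth.slice(t).row(m));

  for (int m = 0; m < M; ++m)
    for (int d = 0; d < D; ++d)
      Dsm(m, d, 0) = pi(m) * P(m, d) * beta(m, d, 0);
  for (int t = 1; t < T; ++t)
    for (int m = 0; m < M; ++m) {
      for (int d = 0; d < D; ++d)
        Dsm(m, d, t) = F(t - 1, m) * P(m, d) * beta(m, d, t);
      for (int n = 0; n < M; ++n)
        Tsm(m, n, t) = E(t - 1, m) * A(m, n) * Estar(t, n);
    }

  return List::create(_["alphaSmooth"] = alphaSmooth, _["gammaSmooth"] = gamma,
                      _["DSmooth"] = Dsm, _["TSmooth"] = Tsm);
}
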