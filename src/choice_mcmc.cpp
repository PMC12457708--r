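// Gibbs sampler for the joint multi-context hierarchical Bernoulli-logit
// model. Male-strain effects are K-variate normal across contexts with
// SD vector sigma and correlation matrix R (half-t and LKJ(1) priors);
// female-strain effects are independent per noncompetitive context;
// intercepts carry Student-t priors via a scale-mixture augmentation and
// color contrasts are flat. Bernoulli likelihood handled by Polya-Gamma
// augmentation (Polson, Scott & Windle), with the exact PG(1,z) sampler
// of Devroye. All randomness flows through R's RNG so set.seed() governs
// reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TRUNC = 0.64;

// piecewise coefficients of the alternating series for the J*(1,z) density
static double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x <= TRUNC)
    return M_PI * np5 * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * np5 * np5 / x);
  return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * x / 2.0);
}

// CDF of inverse-Gaussian(mu = 1/z, lambda = 1) at x; z may be 0
static double pigauss(double x, double z) {
  double rx = std::sqrt(1.0 / x);
  double b = rx * (x * z - 1.0);
  double a = -rx * (x * z + 1.0);
  return R::pnorm(b, 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(a, 0.0, 1.0, 1, 0);
}

// inverse-Gaussian(mu = 1/z, 1) truncated to (0, TRUNC)
static double rtinvgauss(double z) {
  double t = TRUNC, X;
  double mu = (z > 0.0) ? 1.0 / z : R_PosInf;
  if (mu > t) {
    while (true) {
      double E1 = R::exp_rand(), E2 = R::exp_rand();
      while (E1 * E1 > 2.0 * E2 / t) {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      }
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * X)) break;
    }
  } else {
    while (true) {
      double Y = R::norm_rand();
      Y = Y * Y;
      double muY = mu * Y;
      X = mu + 0.5 * mu * (muY - std::sqrt(4.0 * muY + muY * muY));
      if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
      if (X < t) break;
    }
  }
  return X;
}

// exact PG(1, z) draw
// [[Rcpp::export]]
double rpg1(double z) {
  z = std::fabs(z) * 0.5;
  double K = M_PI * M_PI / 8.0 + z * z / 2.0;
  double p = (M_PI / (2.0 * K)) * std::exp(-K * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  while (true) {
    double X;
    if (R::unif_rand() < p / (p + q)) {
      X = TRUNC + R::exp_rand() / K;
    } else {
      X = rtinvgauss(z);
    }
    double S = a_coef(0, X);
    double Y = R::unif_rand() * S;
    int n = 0;
    bool accept = false;
    while (true) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) { accept = true; break; }
      } else {
        S += a_coef(n, X);
        if (Y > S) break;
      }
    }
    if (accept) return X / 4.0;
  }
}

// [[Rcpp::export]]
NumericVector rpg1_vec(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}

// Cholesky factor of a correlation matrix from canonical partial
// correlations (tanh of the unconstrained vector), Stan-style ordering
// (2,1),(3,1),(3,2),(4,1),(4,2),(4,3)...
static arma::mat cpc_to_chol(const arma::vec& zcpc, int K) {
  arma::mat L(K, K, arma::fill::zeros);
  L(0, 0) = 1.0;
  int idx = 0;
  for (int i = 1; i < K; ++i) {
    double rem = 1.0;
    for (int j = 0; j < i; ++j) {
      double p = std::tanh(zcpc(idx++));
      L(i, j) = p * rem;
      rem *= std::sqrt(1.0 - p * p);
    }
    L(i, i) = rem;
  }
  return L;
}

// log prior of the unconstrained CPC vector inducing LKJ(1) (uniform over
// correlation matrices) on R, including the tanh Jacobian. The canonical
// partial correlation in column j (1-based tree level l = j + 1) is
// Beta(a_l, a_l) on (-1, 1) with a_l = 1 + (K - 1 - l) / 2, so in the
// unconstrained scale each pair contributes b * log(1 - p^2) with
// b = a_l - 1 + 1 (verified by Monte Carlo against the Beta(2,2) marginal
// of a 4x4 uniform correlation matrix).
static double cpc_log_prior(const arma::vec& zcpc, int K) {
  double lp = 0.0;
  int idx = 0;
  for (int i = 1; i < K; ++i) {
    for (int j = 0; j < i; ++j) {
      double b = 1.0 + 0.5 * (K - 2 - j);
      double p = std::tanh(zcpc(idx++));
      lp += b * std::log1p(-p * p);
    }
  }
  return lp;
}

// half-Student-t(nu, 0, s) log density (unnormalized in s is fine for MH)
static double log_half_t(double x, double nu, double s) {
  return -0.5 * (nu + 1.0) * std::log1p((x * x) / (nu * s * s));
}

// log MVN(a_s; 0, Sigma) summed over rows, Sigma = D L L' D
static double mvn_loglik(const arma::mat& A, const arma::vec& sig,
                         const arma::mat& Lr) {
  int S = A.n_rows, K = A.n_cols;
  double ldet = 0.0;
  for (int k = 0; k < K; ++k) ldet += std::log(sig(k)) + std::log(Lr(k, k));
  double ll = -S * (ldet + 0.5 * K * std::log(2.0 * M_PI));
  // solve L_Sigma v = a_s for each row; L_Sigma = diag(sig) * Lr
  arma::mat Ls = arma::diagmat(sig) * Lr;
  arma::mat V = arma::solve(arma::trimatl(Ls), A.t());
  ll -= 0.5 * arma::accu(V % V);
  return ll;
}

// main Gibbs kernel; one chain
// [[Rcpp::export]]
List run_choice_chain(const arma::ivec& y, const arma::ivec& ctx,
                      const arma::ivec& male, const arma::ivec& fem,
                      const arma::ivec& fctx, const arma::mat& X,
                      const arma::ivec& tprior, int S, int F, int K, int KF,
                      int iter, int warmup, int thin, double int_nu,
                      double int_scale, double sd_nu, double sd_scale,
                      List init) {
  const int n = y.n_elem, p = X.n_cols;
  const int ncpc = K * (K - 1) / 2;

  arma::vec beta = as<arma::vec>(init["beta"]);
  arma::mat A = as<arma::mat>(init["a"]);          // S x K
  arma::mat B(std::max(F, 1), std::max(KF, 1), arma::fill::zeros);
  if (KF > 0) B = as<arma::mat>(init["b"]);
  arma::vec logsig = as<arma::vec>(init["logsig"]); // K
  arma::vec zcpc(std::max(ncpc, 1), arma::fill::zeros);
  if (ncpc > 0) zcpc = as<arma::vec>(init["zcpc"]);
  arma::vec logtau(std::max(KF, 1), arma::fill::zeros);
  if (KF > 0) logtau = as<arma::vec>(init["logtau"]);
  arma::vec lambda(p, arma::fill::ones); // t-prior scale mixture

  arma::vec kappa(n);
  for (int i = 0; i < n; ++i) kappa(i) = y(i) - 0.5;

  // adaptive RW scales
  const int n_cov_sweeps = 5;
  arma::vec step_sig_k(K, arma::fill::value(0.4));
  arma::vec step_cpc_j(std::max(ncpc, 1), arma::fill::value(0.4));
  arma::vec step_tau(std::max(KF, 1), arma::fill::value(0.4));
  double acc_sig = 0.0, acc_cpc = 0.0;
  int try_sig = 0, try_cpc = 0;

  arma::vec sig = arma::exp(logsig);
  arma::mat Lr = cpc_to_chol(zcpc, K);

  const int n_keep = (iter - warmup) / thin;
  const int npar = p + K + ncpc + KF + S * K + F * KF;
  arma::mat draws(n_keep, npar);
  int keep = 0;

  arma::vec eta(n), omega(n), other(n);

  for (int it = 0; it < iter; ++it) {
    // ---- linear predictor & PG draws ----
    eta = X * beta;
    for (int i = 0; i < n; ++i) {
      eta(i) += A(male(i), ctx(i));
      if (fem(i) >= 0) eta(i) += B(fem(i), fctx(i));
    }
    for (int i = 0; i < n; ++i) omega(i) = rpg1(eta(i));

    // ---- fixed effects beta ----
    other = eta - X * beta;
    arma::mat Q = X.t() * (X.each_col() % omega);
    for (int j = 0; j < p; ++j)
      if (tprior(j)) Q(j, j) += 1.0 / lambda(j);
    arma::vec m = X.t() * (kappa - omega % other);
    arma::mat Lq = arma::chol(Q, "lower");
    arma::vec mu_b = arma::solve(arma::trimatu(Lq.t()),
                                 arma::solve(arma::trimatl(Lq), m));
    arma::vec zdraw(p);
    for (int j = 0; j < p; ++j) zdraw(j) = R::norm_rand();
    beta = mu_b + arma::solve(arma::trimatu(Lq.t()), zdraw);

    // ---- t-prior scale mixture for intercepts ----
    for (int j = 0; j < p; ++j)
      if (tprior(j)) {
        double shape = 0.5 * (int_nu + 1.0);
        double rate = 0.5 * (int_nu * int_scale * int_scale + beta(j) * beta(j));
        lambda(j) = rate / R::rgamma(shape, 1.0);
      }

    // ---- male-strain effects a_s ----
    eta = X * beta;
    for (int i = 0; i < n; ++i)
      if (fem(i) >= 0) eta(i) += B(fem(i), fctx(i));
    arma::mat W(S, K, arma::fill::zeros), M(S, K, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      W(male(i), ctx(i)) += omega(i);
      M(male(i), ctx(i)) += kappa(i) - omega(i) * eta(i);
    }
    sig = arma::exp(logsig);
    Lr = cpc_to_chol(zcpc, K);
    arma::mat Sigma = arma::diagmat(sig) * (Lr * Lr.t()) * arma::diagmat(sig);
    Sigma.diag() += 1e-12; // keep the solve well-posed near the boundary
    arma::mat Sigi = arma::inv_sympd(Sigma);
    for (int s = 0; s < S; ++s) {
      arma::mat Qs = Sigi;
      Qs.diag() += W.row(s).t();
      arma::mat Lqs = arma::chol(Qs, "lower");
      arma::vec ms = arma::solve(arma::trimatu(Lqs.t()),
                                 arma::solve(arma::trimatl(Lqs), M.row(s).t()));
      arma::vec zs(K);
      for (int k = 0; k < K; ++k) zs(k) = R::norm_rand();
      A.row(s) = (ms + arma::solve(arma::trimatu(Lqs.t()), zs)).t();
    }

    // ---- female-strain effects b_f per noncompetitive context ----
    if (KF > 0) {
      for (int i = 0; i < n; ++i) eta(i) += A(male(i), ctx(i));
      arma::mat Wb(F, KF, arma::fill::zeros), Mb(F, KF, arma::fill::zeros);
      for (int i = 0; i < n; ++i)
        if (fem(i) >= 0) {
          Wb(fem(i), fctx(i)) += omega(i);
          Mb(fem(i), fctx(i)) += kappa(i) - omega(i) * eta(i);
        }
      for (int k = 0; k < KF; ++k) {
        double tau2 = std::exp(2.0 * logtau(k));
        for (int f = 0; f < F; ++f) {
          double prec = 1.0 / tau2 + Wb(f, k);
          double mean = Mb(f, k) / prec;
          B(f, k) = mean + R::norm_rand() / std::sqrt(prec);
        }
      }

      // ---- tau_k random-walk MH ----
      for (int k = 0; k < KF; ++k) {
        double cur = logtau(k);
        double tau = std::exp(cur);
        double ll_cur = log_half_t(tau, sd_nu, sd_scale) + cur;
        for (int f = 0; f < F; ++f)
          ll_cur += R::dnorm(B(f, k), 0.0, tau, 1);
        double prop = cur + step_tau(k) * R::norm_rand();
        double taup = std::exp(prop);
        double ll_prop = log_half_t(taup, sd_nu, sd_scale) + prop;
        for (int f = 0; f < F; ++f)
          ll_prop += R::dnorm(B(f, k), 0.0, taup, 1);
        double acc = (std::log(R::unif_rand()) < ll_prop - ll_cur) ? 1.0 : 0.0;
        if (acc > 0.5) logtau(k) = prop;
        if (it < warmup)
          step_tau(k) *= std::exp((acc - 0.3) / std::sqrt(it / 10.0 + 1.0));
      }
    }

    // ---- (sigma, R) given A: per-coordinate adaptive MH, several sweeps
    // (the conditional is cheap relative to the PG step, and repeated
    // sweeps make this conditional mix essentially freely) ----
    sig = arma::exp(logsig);
    Lr = cpc_to_chol(zcpc, K);
    double base = mvn_loglik(A, sig, Lr);
    double pr_sig = 0.0;
    for (int k = 0; k < K; ++k)
      pr_sig += log_half_t(sig(k), sd_nu, sd_scale) + logsig(k);
    double pr_cpc = cpc_log_prior(zcpc, K);
    double adapt = std::exp(1.0 / std::sqrt(it / 10.0 + 1.0));

    for (int sweep = 0; sweep < n_cov_sweeps; ++sweep) {
      for (int k = 0; k < K; ++k) { // sigma coordinates
        arma::vec prop = logsig;
        prop(k) += step_sig_k(k) * R::norm_rand();
        if (prop(k) < -12.0) continue; // numerically singular; reject
        arma::vec sigp = arma::exp(prop);
        double prp = 0.0;
        for (int kk = 0; kk < K; ++kk)
          prp += log_half_t(sigp(kk), sd_nu, sd_scale) + prop(kk);
        double llp = mvn_loglik(A, sigp, Lr);
        ++try_sig;
        if (std::log(R::unif_rand()) < llp + prp - base - pr_sig) {
          logsig = prop;
          sig = sigp;
          base = llp;
          pr_sig = prp;
          acc_sig += 1.0;
          if (it < warmup) step_sig_k(k) *= std::pow(adapt, 0.7);
        } else if (it < warmup) {
          step_sig_k(k) *= std::pow(adapt, -0.3);
        }
      }
      for (int j = 0; j < ncpc; ++j) { // correlation coordinates
        arma::vec prop = zcpc;
        prop(j) += step_cpc_j(j) * R::norm_rand();
        if (std::fabs(prop(j)) > 8.0) continue; // tanh saturates; reject
        arma::mat Lrp = cpc_to_chol(prop, K);
        double llp = mvn_loglik(A, sig, Lrp);
        double prp = cpc_log_prior(prop, K);
        ++try_cpc;
        if (std::log(R::unif_rand()) < llp + prp - base - pr_cpc) {
          zcpc = prop;
          Lr = Lrp;
          base = llp;
          pr_cpc = prp;
          acc_cpc += 1.0;
          if (it < warmup) step_cpc_j(j) *= std::pow(adapt, 0.7);
        } else if (it < warmup) {
          step_cpc_j(j) *= std::pow(adapt, -0.3);
        }
      }
    }

    // ---- store ----
    if (it >= warmup && ((it - warmup) % thin == (thin - 1))) {
      int c = 0;
      for (int j = 0; j < p; ++j) draws(keep, c++) = beta(j);
      for (int k = 0; k < K; ++k) draws(keep, c++) = std::exp(logsig(k));
      if (ncpc > 0) {
        arma::mat Rm = Lr * Lr.t();
        for (int i = 1; i < K; ++i)
          for (int j = 0; j < i; ++j) draws(keep, c++) = Rm(i, j);
      }
      for (int k = 0; k < KF; ++k) draws(keep, c++) = std::exp(logtau(k));
      for (int k = 0; k < K; ++k)
        for (int s = 0; s < S; ++s) draws(keep, c++) = A(s, k);
      for (int k = 0; k < KF; ++k)
        for (int f = 0; f < F; ++f) draws(keep, c++) = B(f, k);
      ++keep;
    }
  }

  return List::create(
      _["draws"] = draws,
      _["accept_sigma"] = try_sig ? acc_sig / try_sig : NA_REAL,
      _["accept_corr"] = try_cpc ? acc_cpc / try_cpc : NA_REAL);
}
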