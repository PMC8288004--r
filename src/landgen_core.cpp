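// Compiled cores: (1) Metropolis-within-Gibbs sampler for the hierarchical
// population allele-frequency covariance model (core/auxiliary runs), and
// (2) the non-negative least squares IRLS fitter for generalized
// dissimilarity models. Both use R's RNG so set.seed() on the R side gives
// full reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Wishart draw via Bartlett decomposition using R's RNG.
// Returns W ~ Wishart(df, S) with S the scale matrix.
static arma::mat rwishart(double df, const arma::mat &S) {
  const int p = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// Hierarchical model: y_ij ~ Bin(n_ij, alpha_ij); alpha_j ~ N(pi_j 1,
// pi_j (1-pi_j) Omega) truncated to [0,1]; pi_j ~ Beta(1,1); Omega ~
// inverse-Wishart(P+2, I). alpha and pi move by random-walk Metropolis with
// pilot-adapted step sizes; Omega by the conjugate inverse-Wishart step on
// standardized residuals (truncation ignored in that step).
//
// If update_omega is false, Omega stays at omega_init (auxiliary /
// calibration runs). If Z (P x C standardized covariates) is non-empty,
// importance-sampling Bayes factors for a linear covariate effect on the
// standardized frequencies are accumulated over a uniform grid of effect
// sizes beta_grid.
// [[Rcpp::export]]
List bp_mcmc_cpp(const arma::imat &Yc, const arma::imat &Nc,
                 int n_iter, int burnin, int npilot, int pilotlength,
                 int thin, bool update_omega, const arma::mat &omega_init,
                 const arma::mat &Z, const arma::vec &beta_grid) {
  const int P = Yc.n_rows, L = Yc.n_cols;
  const int C = Z.n_cols;
  const bool do_bf = C > 0 && beta_grid.n_elem > 0;
  arma::mat Yd = arma::conv_to<arma::mat>::from(Yc);
  arma::mat Nd = arma::conv_to<arma::mat>::from(Nc);

  // initial values from empirical frequencies
  arma::mat A(P, L);
  arma::vec pi(L);
  for (int j = 0; j < L; ++j) {
    double sy = 0, sn = 0;
    for (int i = 0; i < P; ++i) { sy += Yd(i, j); sn += Nd(i, j); }
    pi(j) = std::min(0.98, std::max(0.02, (sy + 0.5) / (sn + 1.0)));
    for (int i = 0; i < P; ++i)
      A(i, j) = std::min(0.99, std::max(0.01, (Yd(i, j) + 0.5) / (Nd(i, j) + 1.0)));
  }
  arma::mat Omega = omega_init;
  arma::mat Q = arma::inv_sympd(Omega);
  arma::vec q1 = Q * arma::ones(P);
  double qsum = arma::accu(Q);

  arma::mat R = A;  R.each_row() -= pi.t();   // residuals alpha - pi
  arma::mat W = Q * R;                         // Q (alpha - pi)
  arma::mat LA = arma::log(A);                 // cached log(alpha)
  arma::mat L1A = arma::log(1.0 - A);          // cached log(1 - alpha)

  arma::mat step_a(P, L, arma::fill::value(0.2));
  arma::vec step_p(L, arma::fill::value(0.1));
  arma::mat acc_a(P, L, arma::fill::zeros);
  arma::vec acc_p(L, arma::fill::zeros);

  const double prior_df = P + 2.0;
  arma::mat S0 = arma::eye(P, P);

  // accumulators
  arma::mat sum_omega(P, P, arma::fill::zeros);
  arma::vec sum_pi(L, arma::fill::zeros);
  arma::mat sum_alpha(P, L, arma::fill::zeros);
  arma::vec sum_xtx(L, arma::fill::zeros);
  arma::mat sum_bf(L, std::max(C, 1), arma::fill::zeros);
  int n_saved = 0;

  arma::mat MZ;          // C x P, Z' Q
  arma::vec czz(std::max(C, 1));
  if (do_bf) {
    MZ = Z.t() * Q;
    for (int k = 0; k < C; ++k)
      czz(k) = arma::as_scalar(Z.col(k).t() * Q * Z.col(k));
  }

  const int total_main = n_iter;               // burnin + kept sweeps
  const int pilot_total = npilot * pilotlength;
  int pilot_done = 0;

  for (int sweep = 0; sweep < pilot_total + total_main; ++sweep) {
    const bool in_pilot = sweep < pilot_total;
    // ---- alpha updates (vectorised proposals, sequential accept) ----
    NumericVector eps = runif(P * L, -1.0, 1.0);
    NumericVector us = runif(P * L);
    int t = 0;
    for (int j = 0; j < L; ++j) {
      const double s2 = pi(j) * (1.0 - pi(j));
      for (int i = 0; i < P; ++i, ++t) {
        const double a = A(i, j);
        const double ap = a + step_a(i, j) * eps[t];
        if (ap <= 0.0 || ap >= 1.0) continue;
        const double d = ap - a;
        const double lap = std::log(ap), l1ap = std::log1p(-ap);
        double dll = 0.0;
        if (Nd(i, j) > 0.0)
          dll = Yd(i, j) * (lap - LA(i, j)) +
                (Nd(i, j) - Yd(i, j)) * (l1ap - L1A(i, j));
        const double dquad = (2.0 * d * W(i, j) + d * d * Q(i, i)) / (2.0 * s2);
        if (std::log(us[t]) < dll - dquad) {
          A(i, j) = ap;
          LA(i, j) = lap;
          L1A(i, j) = l1ap;
          R(i, j) += d;
          W.col(j) += Q.col(i) * d;
          acc_a(i, j) += 1.0;
        }
      }
    }
    // ---- pi updates ----
    NumericVector epp = runif(L, -1.0, 1.0);
    NumericVector upp = runif(L);
    for (int j = 0; j < L; ++j) {
      const double p0 = pi(j);
      const double p1 = p0 + step_p(j) * epp[j];
      if (p1 <= 0.001 || p1 >= 0.999) continue;
      const double quad0 = arma::dot(R.col(j), W.col(j));
      const double sW = arma::accu(W.col(j));
      const double dp = p1 - p0;
      const double quad1 = quad0 - 2.0 * dp * sW + dp * dp * qsum;
      const double s2_0 = p0 * (1.0 - p0), s2_1 = p1 * (1.0 - p1);
      const double lp0 = -0.5 * P * std::log(s2_0) - quad0 / (2.0 * s2_0);
      const double lp1 = -0.5 * P * std::log(s2_1) - quad1 / (2.0 * s2_1);
      if (std::log(upp[j]) < lp1 - lp0) {
        pi(j) = p1;
        R.col(j) -= dp;
        W.col(j) -= dp * q1;
        acc_p(j) += 1.0;
      }
    }
    // ---- Omega update (conjugate inverse-Wishart on standardized residuals) ----
    if (update_omega) {
      arma::rowvec inv_sd = 1.0 / arma::sqrt(pi.t() % (1.0 - pi.t()));
      arma::mat Rs = R;  Rs.each_row() %= inv_sd;
      arma::mat Spost = S0 + Rs * Rs.t();
      arma::mat Wdraw = rwishart(prior_df + L, arma::inv_sympd(Spost));
      arma::mat Om = arma::inv_sympd(Wdraw);
      if (Om.is_sympd()) {
        Omega = Om;
        Q = arma::inv_sympd(Omega);
        q1 = Q * arma::ones(P);
        qsum = arma::accu(Q);
        W = Q * R;
        if (do_bf) {
          MZ = Z.t() * Q;
          for (int k = 0; k < C; ++k)
            czz(k) = arma::as_scalar(Z.col(k).t() * Q * Z.col(k));
        }
      }
    }
    // ---- pilot adaptation ----
    if (in_pilot && ((sweep + 1) % pilotlength == 0)) {
      ++pilot_done;
      const double denom = pilotlength;
      for (int j = 0; j < L; ++j) {
        for (int i = 0; i < P; ++i) {
          const double r = acc_a(i, j) / denom;
          if (r > 0.4) step_a(i, j) = std::min(1.0, step_a(i, j) * 1.3);
          else if (r < 0.2) step_a(i, j) = std::max(0.005, step_a(i, j) / 1.3);
          acc_a(i, j) = 0.0;
        }
        const double rp = acc_p(j) / denom;
        if (rp > 0.4) step_p(j) = std::min(1.0, step_p(j) * 1.3);
        else if (rp < 0.2) step_p(j) = std::max(0.005, step_p(j) / 1.3);
        acc_p(j) = 0.0;
      }
    }
    // ---- sample accumulation ----
    const int main_sweep = sweep - pilot_total;
    if (main_sweep >= burnin && ((main_sweep - burnin) % thin == 0)) {
      ++n_saved;
      sum_omega += Omega;
      sum_pi += pi;
      sum_alpha += A;
      arma::rowvec inv_s2 = 1.0 / (pi.t() % (1.0 - pi.t()));
      sum_xtx += (arma::sum(R % W, 0) % inv_s2).t();
      if (do_bf) {
        arma::rowvec inv_sd = arma::sqrt(inv_s2);
        arma::mat Ystd = R;  Ystd.each_row() %= inv_sd;
        arma::mat U = MZ * Ystd;  // C x L: z_k' Q y_j
        for (int k = 0; k < C; ++k) {
          const double ck = czz(k);
          for (int j = 0; j < L; ++j) {
            double m1 = 0.0;
            const double u = U(k, j);
            for (arma::uword gI = 0; gI < beta_grid.n_elem; ++gI) {
              const double b = beta_grid(gI);
              m1 += std::exp(b * u - 0.5 * b * b * ck);
            }
            sum_bf(j, k) += m1 / beta_grid.n_elem;
          }
        }
      }
    }
  }

  const double ns = std::max(n_saved, 1);
  List out = List::create(
      _["omega"] = sum_omega / ns,
      _["pi"] = sum_pi / ns,
      _["alpha"] = sum_alpha / ns,
      _["xtx"] = sum_xtx / ns,
      _["n_saved"] = n_saved);
  if (do_bf) out["bf"] = sum_bf / ns;
  return out;
}

// ---------------------------------------------------------------------------
// Lawson-Hanson style non-negative least squares: min ||Ax - b||, x >= 0.
static arma::vec nnls(const arma::mat &A, const arma::vec &b) {
  const int p = A.n_cols;
  arma::vec x(p, arma::fill::zeros);
  std::vector<bool> passive(p, false);
  arma::vec w = A.t() * (b - A * x);
  const double tol = 1e-10 * arma::norm(A, "fro");
  int outer = 0;
  while (outer++ < 30 * p) {
    int t = -1; double wmax = tol;
    for (int j = 0; j < p; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = j; }
    if (t < 0) break;
    passive[t] = true;
    while (true) {
      arma::uvec idx(p); int np = 0;
      for (int j = 0; j < p; ++j) if (passive[j]) idx(np++) = j;
      idx.resize(np);
      arma::vec z;
      bool ok = arma::solve(z, A.cols(idx), b);
      if (!ok) z = arma::pinv(A.cols(idx)) * b;
      if (z.min() > 0) {
        x.zeros();
        for (int k = 0; k < np; ++k) x(idx(k)) = z(k);
        break;
      }
      double alpha = 1.0;
      for (int k = 0; k < np; ++k)
        if (z(k) <= 0) {
          double a = x(idx(k)) / (x(idx(k)) - z(k));
          if (a < alpha) alpha = a;
        }
      for (int k = 0; k < np; ++k)
        x(idx(k)) += alpha * (z(k) - x(idx(k)));
      for (int j = 0; j < p; ++j)
        if (passive[j] && x(j) <= 1e-12) { passive[j] = false; x(j) = 0; }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

// [[Rcpp::export]]
arma::vec nnls_cpp(const arma::mat &A, const arma::vec &b) { return nnls(A, b); }

static double gdm_deviance(const arma::vec &d, const arma::vec &mu) {
  double D = 0.0;
  for (arma::uword i = 0; i < d.n_elem; ++i) {
    double m = std::min(1.0 - 1e-9, std::max(1e-9, mu(i)));
    double di = d(i);
    double t1 = (di > 0) ? di * std::log(di / m) : 0.0;
    double t2 = (di < 1) ? (1.0 - di) * std::log((1.0 - di) / (1.0 - m)) : 0.0;
    D += 2.0 * (t1 + t2);
  }
  return D;
}

// IRLS with non-negative coefficients for the GDM link mu = 1 - exp(-eta),
// binomial-type deviance. X includes the intercept column.
// [[Rcpp::export]]
List gdm_irls_cpp(const arma::mat &X, const arma::vec &d, int maxit,
                  double tol) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  // start from a small positive intercept
  double dbar = std::min(0.98, std::max(0.02, arma::mean(d)));
  beta(0) = -std::log(1.0 - dbar);
  arma::vec eta = X * beta;
  arma::vec mu = 1.0 - arma::exp(-eta);
  double dev = gdm_deviance(d, mu);
  bool converged = false;
  for (int it = 0; it < maxit; ++it) {
    arma::vec dmu = arma::exp(-eta);                   // d mu / d eta
    arma::vec muc = arma::clamp(mu, 1e-6, 1.0 - 1e-6);
    arma::vec V = muc % (1.0 - muc);
    arma::vec wv = arma::clamp(dmu % dmu / V, 1e-10, 1e10);
    arma::vec z = eta + (d - mu) / arma::clamp(dmu, 1e-8, 1.0);
    arma::vec sw = arma::sqrt(wv);
    arma::mat Xw = X.each_col() % sw;
    arma::vec zw = z % sw;
    arma::vec bnew = nnls(Xw, zw);
    // step-halving line search on deviance
    double step = 1.0;
    arma::vec btry, etat, mut;
    double devt = dev + 1.0;
    for (int h = 0; h < 12; ++h) {
      btry = beta + step * (bnew - beta);
      etat = X * btry;
      mut = 1.0 - arma::exp(-etat);
      devt = gdm_deviance(d, mut);
      if (devt <= dev + 1e-12) break;
      step *= 0.5;
    }
    if (devt > dev) { converged = true; break; }  // at a stationary point
    double delta = dev - devt;
    beta = btry; eta = etat; mu = mut; dev = devt;
    if (delta < tol) { converged = true; break; }
  }
  return List::create(_["beta"] = beta, _["deviance"] = dev,
                      _["fitted"] = mu, _["converged"] = converged);
}
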