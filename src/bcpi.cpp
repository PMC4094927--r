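// Gibbs / Metropolis-Hastings kernels for Bayes C-pi whole-genome regression.
//
// All randomness goes through R's RNG (RNGScope is installed by the Rcpp
// attribute wrappers), so chains are reproducible with set.seed() and a
// single stream is shared with R-level code.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Draw from N(mu, 1) truncated to the open-closed interval (lo, hi] by
// inverse-CDF; the draw is clamped strictly inside the interval so category
// membership of a sampled liability is never ambiguous.
static double rtnorm1(double mu, double lo, double hi) {
  double plo = std::isfinite(lo) ? R::pnorm(lo - mu, 0.0, 1.0, 1, 0) : 0.0;
  double phi = std::isfinite(hi) ? R::pnorm(hi - mu, 0.0, 1.0, 1, 0) : 1.0;
  if (phi <= plo) { // vanishing interval mass: fall back to nearest bound
    double mid = std::isfinite(lo) ? (std::isfinite(hi) ? 0.5 * (lo + hi)
                                                        : lo + 1e-8)
                                   : hi - 1e-8;
    return mid;
  }
  double u = R::runif(plo, phi);
  if (u <= 1e-300) u = 1e-300;
  if (u >= 1.0 - 1e-16) u = 1.0 - 1e-16;
  double x = mu + R::qnorm(u, 0.0, 1.0, 1, 0);
  if (std::isfinite(lo) && x <= lo) x = lo + 1e-10;
  if (std::isfinite(hi) && x > hi) x = hi - 1e-10 < lo ? hi : hi - 1e-10;
  return x;
}

// Truncated-normal proposal with scale `step` on (lo, hi).
static double rtnorm_scaled(double mu, double lo, double hi, double step) {
  double plo = std::isfinite(lo) ? R::pnorm((lo - mu) / step, 0.0, 1.0, 1, 0)
                                 : 0.0;
  double phi = std::isfinite(hi) ? R::pnorm((hi - mu) / step, 0.0, 1.0, 1, 0)
                                 : 1.0;
  if (phi <= plo) return mu;
  double u = R::runif(plo, phi);
  if (u <= 1e-300) u = 1e-300;
  if (u >= 1.0 - 1e-16) u = 1.0 - 1e-16;
  return mu + step * R::qnorm(u, 0.0, 1.0, 1, 0);
}

static inline double ncdf(double x) {
  if (x == R_PosInf) return 1.0;
  if (x == R_NegInf) return 0.0;
  return R::pnorm(x, 0.0, 1.0, 1, 0);
}

// -- full-conditional updates (shared by the kernel wrappers and the chain) --

static void upd_beta(arma::vec& r, const arma::mat& X, const arma::vec& xtx,
                     arma::vec& beta, double sigma_e2) {
  for (arma::uword m = 0; m < X.n_cols; ++m) {
    if (xtx[m] <= 0.0) stop("degenerate design: empty fixed-effect level");
    r += X.col(m) * beta[m];
    double bhat = arma::dot(X.col(m), r) / xtx[m];
    beta[m] = R::rnorm(bhat, std::sqrt(sigma_e2 / xtx[m]));
    r -= X.col(m) * beta[m];
  }
}

// Joint update of (inclusion indicator, effect) for every locus, ascending
// index order. Inclusion odds are prior odds times the Bayes factor of
// z_k'r_k under a_k ~ N(0, sigma_a2) versus a_k = 0; a monomorphic column
// (z'z = 0) carries no information so its indicator follows the prior.
static void upd_loci(arma::vec& r, const arma::mat& Z, const arma::vec& zz,
                     arma::vec& a, arma::ivec& delta,
                     double sigma_a2, double sigma_e2, double pi_excl) {
  if (sigma_a2 <= 0.0) stop("invalid state: sigma_a2 must be positive");
  const int K = Z.n_cols;
  for (int k = 0; k < K; ++k) {
    if (delta[k]) r += Z.col(k) * a[k];
    double zzk = zz[k];
    double rhs = arma::dot(Z.col(k), r);
    double logBF = 0.0;
    if (zzk > 0.0) {
      double v0 = zzk * sigma_e2;
      double v1 = v0 + zzk * zzk * sigma_a2;
      logBF = 0.5 * std::log(v0 / v1) + 0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
    }
    double pincl;
    if (pi_excl <= 0.0) pincl = 1.0;
    else if (pi_excl >= 1.0) pincl = 0.0;
    else {
      double logodds = std::log1p(-pi_excl) - std::log(pi_excl) + logBF;
      pincl = 1.0 / (1.0 + std::exp(-logodds));
    }
    if (R::runif(0.0, 1.0) < pincl) {
      double Ck = zzk + sigma_e2 / sigma_a2;
      a[k] = R::rnorm(rhs / Ck, std::sqrt(sigma_e2 / Ck));
      delta[k] = 1;
      r -= Z.col(k) * a[k];
    } else {
      a[k] = 0.0;
      delta[k] = 0;
    }
  }
}

// Scaled-inverse-chi-square draw: nu_tilde * S2_tilde / chisq(nu_tilde).
static double rsinvchisq(double df, double sum_sq_times_scale) {
  return sum_sq_times_scale / R::rchisq(df);
}

static double upd_sigma_a2(const arma::vec& a, const arma::ivec& delta,
                           double nu_a, double scale_a) {
  double ssq = 0.0;
  int M = 0;
  for (arma::uword k = 0; k < a.n_elem; ++k) {
    if (delta[k]) { ssq += a[k] * a[k]; ++M; }
  }
  return rsinvchisq(nu_a + M, nu_a * scale_a + ssq);
}

static void upd_liab(arma::vec& r, arma::vec& l, const arma::ivec& y,
                     const arma::vec& tau_ext) {
  for (arma::uword i = 0; i < l.n_elem; ++i) {
    double mu = l[i] - r[i];
    double lo = tau_ext[y[i] - 1];
    double hi = tau_ext[y[i]];
    double lnew = rtnorm1(mu, lo, hi);
    l[i] = lnew;
    r[i] = lnew - mu;
  }
}

// Cowles-style joint Metropolis-Hastings update of the free thresholds
// (tau_1 fixed at 0). Each free tau_j is proposed from a normal with scale
// `step` centred at the current value, truncated to (tau_{j-1}^new,
// tau_{j+1}^old); the whole vector is accepted or rejected together using
// the marginal likelihood of the scores (liabilities integrated out) plus
// the truncation correction of the proposal densities.
static bool upd_tau(arma::vec& tau, const arma::ivec& y, const arma::vec& mu,
                    double step, int ncat) {
  const int c1 = ncat - 1;        // number of thresholds; tau[0] = 0 fixed
  if (c1 < 2) return false;       // binary trait: nothing to update
  arma::vec prop = tau;
  double logq = 0.0;
  for (int j = 1; j < c1; ++j) {
    double lo_f = prop[j - 1];                       // new lower neighbour
    double hi_f = (j + 1 < c1) ? tau[j + 1] : R_PosInf;  // old upper neighbour
    prop[j] = rtnorm_scaled(tau[j], lo_f, hi_f, step);
    double zf = ncdf(std::isfinite(hi_f) ? (hi_f - tau[j]) / step : R_PosInf) -
                ncdf((lo_f - tau[j]) / step);
    double lo_r = tau[j - 1];                        // old lower neighbour
    double hi_r = (j + 1 < c1) ? prop[j + 1] : R_PosInf; // new upper neighbour
    double zr = ncdf(std::isfinite(hi_r) ? (hi_r - prop[j]) / step : R_PosInf) -
                ncdf((lo_r - prop[j]) / step);
    if (zf <= 0.0 || zr <= 0.0) return false;
    logq += std::log(zf) - std::log(zr);
  }
  // marginal likelihood of the observed categories under current vs proposed
  double loglik = 0.0;
  arma::vec cur_ext(ncat + 1), prop_ext(ncat + 1);
  cur_ext[0] = R_NegInf; prop_ext[0] = R_NegInf;
  for (int j = 0; j < c1; ++j) { cur_ext[j + 1] = tau[j]; prop_ext[j + 1] = prop[j]; }
  cur_ext[ncat] = R_PosInf; prop_ext[ncat] = R_PosInf;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double m = mu[i];
    double pp = ncdf(prop_ext[y[i]] - m) - ncdf(prop_ext[y[i] - 1] - m);
    double pc = ncdf(cur_ext[y[i]] - m) - ncdf(cur_ext[y[i] - 1] - m);
    if (pp <= 0.0) return false;       // proposed interval carries no mass
    if (pc <= 0.0) { loglik = R_PosInf; break; } // escape a degenerate state
    loglik += std::log(pp) - std::log(pc);
  }
  if (std::log(R::runif(0.0, 1.0)) < loglik + logq) {
    tau = prop;
    return true;
  }
  return false;
}

static arma::vec make_tau_ext(const arma::vec& tau, int ncat) {
  arma::vec ext(ncat + 1);
  ext[0] = R_NegInf;
  for (int j = 0; j < ncat - 1; ++j) ext[j + 1] = tau[j];
  ext[ncat] = R_PosInf;
  return ext;
}

// ---------------------------------------------------------------- kernels --

// [[Rcpp::export]]
List cpp_sample_beta(arma::vec r, const arma::mat& X, arma::vec beta,
                     double sigma_e2) {
  arma::vec xtx = arma::sum(arma::square(X), 0).t();
  upd_beta(r, X, xtx, beta, sigma_e2);
  return List::create(_["beta"] = beta, _["r"] = r);
}

// [[Rcpp::export]]
List cpp_sample_loci(arma::vec r, const arma::mat& Z, arma::vec a,
                     arma::ivec delta, double sigma_a2, double sigma_e2,
                     double pi) {
  arma::vec zz = arma::sum(arma::square(Z), 0).t();
  upd_loci(r, Z, zz, a, delta, sigma_a2, sigma_e2, pi);
  return List::create(_["a"] = a, _["delta"] = delta, _["r"] = r);
}

// [[Rcpp::export]]
double cpp_sample_sigma_a2(const arma::vec& a, const arma::ivec& delta,
                           double nu_a, double scale_a) {
  return upd_sigma_a2(a, delta, nu_a, scale_a);
}

// [[Rcpp::export]]
double cpp_sample_sigma_e2(const arma::vec& r, double nu_e, double scale_e) {
  return rsinvchisq(nu_e + r.n_elem, nu_e * scale_e + arma::dot(r, r));
}

// [[Rcpp::export]]
double cpp_sample_pi(int K, int M) {
  return R::rbeta(K - M + 1.0, M + 1.0);
}

// [[Rcpp::export]]
List cpp_sample_liabilities(arma::vec r, arma::vec l, const arma::ivec& y,
                            const arma::vec& tau, int ncat) {
  arma::vec ext = make_tau_ext(tau, ncat);
  upd_liab(r, l, y, ext);
  return List::create(_["l"] = l, _["r"] = r);
}

// [[Rcpp::export]]
List cpp_sample_thresholds(arma::vec tau, const arma::ivec& y,
                           const arma::vec& mu, double step, int ncat) {
  bool acc = upd_tau(tau, y, mu, step, ncat);
  return List::create(_["tau"] = tau, _["accepted"] = acc);
}

// [[Rcpp::export]]
arma::vec cpp_rtnorm(int n, double mu, double lo, double hi) {
  arma::vec out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm1(mu, lo, hi);
  return out;
}

// ------------------------------------------------------------- full chain --

// model: 0 = linear (response observed, sigma_e2 sampled),
//        1 = threshold (liability latent, sigma_e2 = 1, tau_1 = 0).
// [[Rcpp::export]]
List cpp_bcpi_chain(const arma::vec& y, const arma::mat& X, const arma::mat& Z,
                    int model, int ncat,
                    double nu_a, double scale_a,
                    double nu_e, double scale_e,
                    int n_iter, int burn_in, int thin,
                    double mh_step, bool adapt_mh,
                    const arma::vec& tau_init, const arma::vec& l_init,
                    int refresh_every) {
  const int n = y.n_elem, K = Z.n_cols, p = X.n_cols;
  arma::vec xtx = arma::sum(arma::square(X), 0).t();
  arma::vec zz = arma::sum(arma::square(Z), 0).t();

  arma::vec beta(p, arma::fill::zeros);
  arma::vec a(K, arma::fill::zeros);
  arma::ivec delta(K, arma::fill::zeros);
  double sigma_a2 = nu_a * scale_a / (nu_a + 2.0);  // prior mode
  double sigma_e2 = (model == 1) ? 1.0
                                 : nu_e * scale_e / (nu_e + 2.0);
  double pi_excl = 0.5;
  arma::vec tau = tau_init;
  arma::vec l = (model == 1) ? l_init : y;
  arma::vec r = l;                    // beta = 0, a = 0 at start
  arma::ivec yi(n);
  for (int i = 0; i < n; ++i) yi[i] = (int) y[i];

  const int n_kept = (n_iter > 0) ? (n_iter - 1) / thin + 1 : 0;
  arma::vec tr_pi(n_kept), tr_sa2(n_kept), tr_se2(n_kept), tr_h2(n_kept);
  arma::ivec tr_m(n_kept);
  arma::mat tr_tau(n_kept, tau.n_elem);
  arma::vec sum_a(K, arma::fill::zeros);
  arma::vec sum_delta(K, arma::fill::zeros);
  arma::vec sum_beta(p, arma::fill::zeros);
  arma::vec sum_tau(tau.n_elem, arma::fill::zeros);

  int mh_att = 0, mh_acc = 0;            // post-burn-in acceptance statistics
  int adapt_att = 0, adapt_acc = 0;
  double step = mh_step;
  int kept = 0;
  const int total = burn_in + n_iter;

  for (int it = 0; it < total; ++it) {
    if (model == 1) {
      if (ncat >= 3) {
        arma::vec mu = l - r;
        bool acc = upd_tau(tau, yi, mu, step, ncat);
        if (it < burn_in) {
          ++adapt_att; if (acc) ++adapt_acc;
          if (adapt_mh && adapt_att == 50) {   // tune toward 20-50% acceptance
            double rate = (double) adapt_acc / adapt_att;
            if (rate > 0.5) step *= 1.25;
            else if (rate < 0.2) step *= 0.8;
            adapt_att = 0; adapt_acc = 0;
          }
        } else {
          ++mh_att; if (acc) ++mh_acc;
        }
      }
      arma::vec ext = make_tau_ext(tau, ncat);
      upd_liab(r, l, yi, ext);
    }
    upd_beta(r, X, xtx, beta, sigma_e2);
    upd_loci(r, Z, zz, a, delta, sigma_a2, sigma_e2, pi_excl);
    sigma_a2 = upd_sigma_a2(a, delta, nu_a, scale_a);
    int M = arma::accu(delta);
    pi_excl = cpp_sample_pi(K, M);
    if (model == 0) {
      sigma_e2 = rsinvchisq(nu_e + n, nu_e * scale_e + arma::dot(r, r));
    }
    if (refresh_every > 0 && (it + 1) % refresh_every == 0) {
      r = l - X * beta;
      for (int k = 0; k < K; ++k) if (delta[k]) r -= Z.col(k) * a[k];
    }
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      arma::vec g = l - r - X * beta;     // current fitted genetic values
      double vg = arma::var(g);
      tr_pi[kept] = pi_excl;
      tr_sa2[kept] = sigma_a2;
      tr_se2[kept] = sigma_e2;
      tr_m[kept] = M;
      tr_h2[kept] = vg / (vg + sigma_e2);
      tr_tau.row(kept) = tau.t();
      sum_a += a;
      sum_delta += arma::conv_to<arma::vec>::from(delta);
      sum_beta += beta;
      sum_tau += tau;
      ++kept;
    }
  }

  return List::create(
    _["effect_sum"] = sum_a,
    _["incl_sum"] = sum_delta,
    _["beta_sum"] = sum_beta,
    _["tau_sum"] = sum_tau,
    _["n_kept"] = kept,
    _["pi"] = tr_pi, _["sigma_a2"] = tr_sa2, _["sigma_e2"] = tr_se2,
    _["m"] = tr_m, _["h2"] = tr_h2, _["tau_trace"] = tr_tau,
    _["mh_acceptance"] = mh_att > 0 ? (double) mh_acc / mh_att : NA_REAL,
    _["mh_step_final"] = step);
}
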