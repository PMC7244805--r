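// Blockwise adaptive Metropolis-Hastings sampler for the isolation-by-
// environment model: latent per-locus allele frequencies f_l with a
// truncated multivariate normal prior N(mu_l * 1, mu_l (1 - mu_l) Omega)
// (truncation handled by bound-rejection of proposals), a binomial
// likelihood for the observed allele counts, and a distance-decay
// covariance Omega = (1/a0) exp(-(aD D + aE E)^a2) + delta I on
// standardized distances.
//
// The Mahalanobis forms are maintained through cached whitened matrices:
// with Omega = R'R and WF = R'^-1 F, w1 = R'^-1 1, the quadratic form of
// locus l at mean mu_l is q_l = qF_l - 2 mu_l cross_l + mu_l^2 c11, so the
// per-locus mean block costs no triangular solve, and the covariance and
// frequency blocks cost one solve each. Covariance parameters are updated
// one per iteration in rotation. All randomness flows from a generator
// seeded off R's RNG, so set.seed() makes runs reproducible.
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

struct Rng {
  std::mt19937_64 gen;
  std::normal_distribution<double> norm;
  std::uniform_real_distribution<double> unif;
  explicit Rng(uint64_t seed) : gen(seed), norm(0.0, 1.0), unif(0.0, 1.0) {}
  double rnorm() { return norm(gen); }
  double runif() { return unif(gen); }
  arma::vec rnorm_vec(int n) {
    arma::vec v(n);
    for (int i = 0; i < n; ++i) v(i) = norm(gen);
    return v;
  }
  arma::mat rnorm_mat(int r, int c) {
    arma::mat m(r, c);
    for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = norm(gen);
    return m;
  }
};

// upper-triangular Cholesky of Omega(params); false when not PD
static bool build_chol(arma::mat &R, double &logdet, double a0, double aD,
                       double aE, double a2, const arma::mat &D,
                       const arma::mat &E, double delta) {
  arma::mat S = aD * D + aE * E;
  arma::mat Om = (1.0 / a0) * arma::exp(-arma::pow(S, a2));
  Om.diag() += delta;
  if (!Om.is_finite()) return false;
  if (!arma::chol(R, Om)) return false;
  logdet = 2.0 * arma::accu(arma::log(R.diag()));
  return true;
}

static double lp_params(double a0, double aD, double aE, double a2,
                        double a0_scale, double exp_rate) {
  // half-normal(a0_scale) for a0; Exponential(exp_rate) for aD, aE;
  // Uniform(0,1] for a2
  double lp = -0.5 * (a0 / a0_scale) * (a0 / a0_scale) + std::log(2.0) -
              std::log(a0_scale) - 0.5 * LOG2PI;
  lp += std::log(exp_rate) - exp_rate * aD;
  lp += std::log(exp_rate) - exp_rate * aE;
  return lp;
}

static bool in_support(double a0, double aD, double aE, double a2) {
  return a0 > 0.0 && aD >= 0.0 && aE >= 0.0 && a2 > 0.0 && a2 <= 1.0;
}

// [[Rcpp::export]]
List ibe_mcmc_cpp(const arma::mat &X, const arma::mat &N, const arma::mat &D,
                  const arma::mat &E, int iterations, int thin, int adapt_end,
                  bool use_lik, double delta, double a0_scale,
                  double exp_rate, arma::vec init_params, arma::mat F,
                  arma::vec mu_in, arma::vec step_init) {
  const int K = D.n_rows;
  const int L = use_lik ? X.n_cols : 0;
  double a0 = init_params(0), aD = init_params(1), aE = init_params(2),
         a2 = init_params(3);
  Rng rng((uint64_t)(R::unif_rand() * 4294967295.0) + 1u);

  arma::mat R;                 // chol of Omega (upper)
  double logdet = 0.0;
  arma::mat WF;                // R'^-1 F
  arma::vec w1;                // R'^-1 1
  arma::rowvec qF, cross;      // colsums WF^2, w1' WF
  double c11 = 0.0;            // w1' w1
  arma::rowvec mu, s, bl;      // locus means, mu(1-mu), binomial loglik
  double Cbin = 0.0;
  arma::colvec onesK = arma::ones<arma::colvec>(K);

  auto refresh_freq_cache = [&]() {
    WF = arma::solve(arma::trimatl(R.t()), F);
    w1 = arma::solve(arma::trimatl(R.t()), onesK);
    qF = arma::sum(WF % WF, 0);
    cross = w1.t() * WF;
    c11 = arma::dot(w1, w1);
  };
  auto qvec = [&](const arma::rowvec &m, const arma::rowvec &qF_,
                  const arma::rowvec &cross_, double c11_) -> arma::rowvec {
    return qF_ - 2.0 * (m % cross_) + (m % m) * c11_;
  };

  if (use_lik) {
    mu = mu_in.t();
    if (!build_chol(R, logdet, a0, aD, aE, a2, D, E, delta))
      stop("initial covariance not positive definite");
    refresh_freq_cache();
    s = mu % (1.0 - mu);
    bl = arma::sum(X % arma::log(F) + (N - X) % arma::log(1.0 - F), 0);
    for (arma::uword i = 0; i < X.n_elem; ++i)
      Cbin += R::lchoose(N(i), X(i));
  }

  auto mvn_total = [&]() {
    if (!use_lik) return 0.0;
    arma::rowvec q = qvec(mu, qF, cross, c11);
    return -0.5 * arma::accu(q / s) - 0.5 * K * arma::accu(arma::log(s)) -
           0.5 * L * logdet - 0.5 * K * L * LOG2PI;
  };

  double lp_cur = lp_params(a0, aD, aE, a2, a0_scale, exp_rate);
  double init_post =
      lp_cur + mvn_total() + (use_lik ? arma::accu(bl) + Cbin : 0.0);
  if (!std::isfinite(init_post))
    stop("initial log posterior is not finite; check counts and initial values");

  const int n_keep = iterations / thin;
  arma::mat trace(n_keep, 5);
  arma::vec steps = step_init;  // a0 aD aE a2 mu f
  arma::vec acc_tot = arma::zeros(6), att_tot = arma::zeros(6);
  arma::vec acc_win = arma::zeros(6), att_win = arma::zeros(6);
  int kept = 0;

  for (int iter = 1; iter <= iterations; ++iter) {
    // ---- covariance-parameter block: one parameter per iteration
    {
      int p = use_lik ? (iter % 4) : 0;
      int pmax = use_lik ? p + 1 : 4;  // prior-only mode: all four, cheap
      for (; p < pmax; ++p) {
        double pa0 = a0, paD = aD, paE = aE, pa2 = a2;
        double prop = rng.rnorm() * steps(p);
        if (p == 0) pa0 += prop;
        else if (p == 1) paD += prop;
        else if (p == 2) paE += prop;
        else pa2 += prop;
        att_win(p) += 1; att_tot(p) += 1;
        if (!in_support(pa0, paD, paE, pa2)) continue;
        double lp_new = lp_params(pa0, paD, paE, pa2, a0_scale, exp_rate);
        if (!use_lik) {
          if (std::log(rng.runif()) < lp_new - lp_cur) {
            a0 = pa0; aD = paD; aE = paE; a2 = pa2;
            lp_cur = lp_new;
            acc_win(p) += 1; acc_tot(p) += 1;
          }
          continue;
        }
        arma::mat Rp;
        double logdetp = 0.0;
        if (!build_chol(Rp, logdetp, pa0, paD, paE, pa2, D, E, delta))
          continue;  // non-PD proposal rejected, never an exception
        arma::mat WFp = arma::solve(arma::trimatl(Rp.t()), F);
        arma::vec w1p = arma::solve(arma::trimatl(Rp.t()), onesK);
        arma::rowvec qFp = arma::sum(WFp % WFp, 0);
        arma::rowvec crossp = w1p.t() * WFp;
        double c11p = arma::dot(w1p, w1p);
        arma::rowvec qp = qvec(mu, qFp, crossp, c11p);
        arma::rowvec qc = qvec(mu, qF, cross, c11);
        double mvn_new = -0.5 * arma::accu(qp / s) - 0.5 * L * logdetp;
        double mvn_old = -0.5 * arma::accu(qc / s) - 0.5 * L * logdet;
        if (std::log(rng.runif()) < (lp_new + mvn_new) - (lp_cur + mvn_old)) {
          a0 = pa0; aD = paD; aE = paE; a2 = pa2;
          lp_cur = lp_new;
          R = Rp; logdet = logdetp; WF = WFp; w1 = w1p;
          qF = qFp; cross = crossp; c11 = c11p;
          acc_win(p) += 1; acc_tot(p) += 1;
        }
      }
    }

    if (use_lik) {
      {
        // ---- mu block: per-locus random walk; no solve needed
        att_win(4) += L; att_tot(4) += L;
        for (int l = 0; l < L; ++l) {
          double mp = mu(l) + steps(4) * rng.rnorm();
          if (mp <= 0.0 || mp >= 1.0) continue;
          double sp = mp * (1.0 - mp);
          double q_old = qF(l) - 2.0 * mu(l) * cross(l) + mu(l) * mu(l) * c11;
          double q_new = qF(l) - 2.0 * mp * cross(l) + mp * mp * c11;
          double dl = (-0.5 * q_new / sp - 0.5 * K * std::log(sp)) -
                      (-0.5 * q_old / s(l) - 0.5 * K * std::log(s(l)));
          if (std::log(rng.runif()) < dl) {
            mu(l) = mp; s(l) = sp;
            acc_win(4) += 1; acc_tot(4) += 1;
          }
        }
      }

      {
        // ---- f block: joint per-locus random walk, one solve
        arma::mat Fp = F + steps(5) * rng.rnorm_mat(K, L);
        arma::umat inb = (Fp > 0.0) % (Fp < 1.0);
        arma::urowvec valid = arma::all(inb, 0);
        arma::mat Fp_safe = arma::clamp(Fp, 1e-12, 1.0 - 1e-12);
        arma::mat WFp = arma::solve(arma::trimatl(R.t()), Fp);
        arma::rowvec qFp = arma::sum(WFp % WFp, 0);
        arma::rowvec crossp = w1.t() * WFp;
        arma::rowvec bl_p = arma::sum(
            X % arma::log(Fp_safe) + (N - X) % arma::log(1.0 - Fp_safe), 0);
        att_win(5) += L; att_tot(5) += L;
        for (int l = 0; l < L; ++l) {
          if (!valid(l)) continue;
          double q_old = qF(l) - 2.0 * mu(l) * cross(l) + mu(l) * mu(l) * c11;
          double q_new =
              qFp(l) - 2.0 * mu(l) * crossp(l) + mu(l) * mu(l) * c11;
          double dl = -0.5 * (q_new - q_old) / s(l) + (bl_p(l) - bl(l));
          if (std::log(rng.runif()) < dl) {
            F.col(l) = Fp.col(l); WF.col(l) = WFp.col(l);
            qF(l) = qFp(l); cross(l) = crossp(l); bl(l) = bl_p(l);
            acc_win(5) += 1; acc_tot(5) += 1;
          }
        }
      }
    }

    // ---- step-size adaptation, frozen after adapt_end
    if (iter <= adapt_end && iter % 200 == 0) {
      for (int b = 0; b < 6; ++b) {
        if (att_win(b) == 0) continue;
        double acc = acc_win(b) / att_win(b);
        if (acc < 0.20) steps(b) *= 0.7;
        else if (acc > 0.70) steps(b) *= 1.4;
        steps(b) = std::min(std::max(steps(b), 1e-6), 10.0);
      }
      acc_win.zeros(); att_win.zeros();
    }

    if (iter % thin == 0 && kept < n_keep) {
      double lpost = lp_cur + mvn_total() +
                     (use_lik ? arma::accu(bl) + Cbin : 0.0);
      trace(kept, 0) = a0; trace(kept, 1) = aD; trace(kept, 2) = aE;
      trace(kept, 3) = a2; trace(kept, 4) = lpost;
      ++kept;
    }
    if (iter % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  arma::vec acc_rate(6);
  for (int b = 0; b < 6; ++b)
    acc_rate(b) = att_tot(b) > 0 ? acc_tot(b) / att_tot(b) : NA_REAL;

  double final_post =
      lp_cur + mvn_total() + (use_lik ? arma::accu(bl) + Cbin : 0.0);
  return List::create(
      _["trace"] = trace.rows(0, kept - 1), _["acceptance"] = acc_rate,
      _["steps"] = steps, _["f"] = F,
      _["mu"] = use_lik ? arma::vec(mu.t()) : arma::vec(),
      _["log_posterior"] = final_post);
}
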