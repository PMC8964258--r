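#include <Rcpp.h>
#include <functional>
#include "models.h"
using namespace Rcpp;

// Hierarchical slice-within-Gibbs chain for the RL / BI choice models.
//
// Subject-level parameters are updated with random-direction slice moves in
// transformed coordinates (logit for rates/probabilities, log for the inverse
// temperature, atanh for stickiness) so that correlated subject posteriors
// mix well. Group-level hyperparameters get componentwise slice updates plus
// reparameterized joint moves that carry the subject parameters along
// (translation in the stickiness mean, scale in the stickiness spread and in
// the gamma-law mean); for those moves the group densities and the transform
// Jacobian cancel exactly, leaving only the likelihood, the hyperprior, and
// (for truncated normals) the truncation normalizer. All randomness comes
// from R's RNG, so chain seeds give bit-reproducible draws.
//
// Group-law types: 0 = beta (mean mu, concentration kappa), 1 = gamma
// (mean m, shape k), 2 = normal truncated to [-1, 1] (mu, sigma).

static inline double logspace_sub_(double x, double y) {
  return x + log1p(-exp(y - x));
}

// log of P(lo < N(mean, sd) < hi) for the [-1, 1] truncation, stable when the
// location sits far outside the interval
static double tnorm_logz(double mean, double sd) {
  double a = (-1.0 - mean) / sd, b = (1.0 - mean) / sd;
  if (a > 0.0)
    return logspace_sub_(R::pnorm(a, 0, 1, 0, 1), R::pnorm(b, 0, 1, 0, 1));
  if (b < 0.0)
    return logspace_sub_(R::pnorm(b, 0, 1, 1, 1), R::pnorm(a, 0, 1, 1, 1));
  return std::log(R::pnorm(b, 0, 1, 1, 0) - R::pnorm(a, 0, 1, 1, 0));
}

// Univariate slice sampler (stepping out + shrinkage, Neal 2003).
static double slice1(double x0, const std::function<double(double)>& logf,
                     double w, double lower, double upper, int max_step = 30) {
  double f0 = logf(x0);
  if (!R_finite(f0)) stop("slice sampler started at a zero-density point");
  double y = f0 - exp_rand();
  double L = x0 - unif_rand() * w, Rr = L + w;
  int j = (int)std::floor(unif_rand() * max_step);
  int k = max_step - 1 - j;
  while (j > 0 && L > lower && logf(L) > y) { L -= w; --j; }
  while (k > 0 && Rr < upper && logf(Rr) > y) { Rr += w; --k; }
  if (L < lower) L = lower;
  if (Rr > upper) Rr = upper;
  for (;;) {
    if (Rr - L < 1e-14) return x0;
    double x1 = L + unif_rand() * (Rr - L);
    if (logf(x1) >= y) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
}

struct ChainSpec {
  std::vector<SubjData> dat;
  int model;            // 0 = rl, 1 = bi
  bool counterfactual;
  int P;                // number of active subject-level parameters
  std::vector<int> type;   // per active param
  std::vector<int> pmap;   // full param slot -> active column (or -1)
  double bh_shape, bh_rate, gh_shape, gh_rate, st_mu_sd, st_sigma_sd;

  double subj_ll(int j, const double* th) const {
    double p[4];
    for (int k = 0; k < 4; ++k) {
      if (pmap[k] >= 0) p[k] = th[pmap[k]];
      else p[k] = (k == 1) ? p[0] : 0.0;  // shared alpha / stickiness fixed 0
    }
    if (model == 0)
      return rl_loglik_subj(dat[j], p[0], p[1], p[2], p[3], counterfactual);
    return bi_loglik_subj(dat[j], p[0], p[1], p[2], p[3], 1e-4);
  }

  // subject-level prior of one parameter value under its group law
  double prior1(int p, double x, const double* hyper) const {
    double h1 = hyper[2 * p], h2 = hyper[2 * p + 1];
    switch (type[p]) {
      case 0: return R::dbeta(x, h1 * h2, (1.0 - h1) * h2, 1);
      case 1: return R::dgamma(x, h2, h1 / h2, 1);
      default:
        if (x <= -1.0 || x >= 1.0) return R_NegInf;
        return R::dnorm(x, h1, h2, 1) - tnorm_logz(h1, h2);
    }
  }

  double logprior_beta_hyper(double mu, double kap) const {
    return R::dgamma(mu * kap, bh_shape, 1.0 / bh_rate, 1) +
           R::dgamma((1.0 - mu) * kap, bh_shape, 1.0 / bh_rate, 1) +
           std::log(kap);
  }
  double logprior_gamma_hyper(double m, double k) const {
    return R::dgamma(k, gh_shape, 1.0 / gh_rate, 1) +
           R::dgamma(k / m, gh_shape, 1.0 / gh_rate, 1) +
           std::log(k) - 2.0 * std::log(m);
  }
  double logprior_st_hyper(double mu, double sig) const {
    return R::dnorm(mu, 0.0, st_mu_sd, 1) + R::dnorm(sig, 0.0, st_sigma_sd, 1);
  }
};

static inline double x_of_z(int type, double z) {
  switch (type) {
    case 0: return 1.0 / (1.0 + std::exp(-z));
    case 1: return std::exp(z);
    default: return std::tanh(z);
  }
}
static inline double z_of_x(int type, double x) {
  switch (type) {
    case 0: return std::log(x / (1.0 - x));
    case 1: return std::log(x);
    default: return std::atanh(x);
  }
}
static inline double logjac(int type, double x) {
  switch (type) {
    case 0: return std::log(x) + log1p(-x);
    case 1: return std::log(x);
    default: return log1p(-x * x);
  }
}

// [[Rcpp::export(name = ".hier_chain_cpp")]]
NumericMatrix hier_chain_cpp(List subjects, int model_code,
                             bool counterfactual, IntegerVector types,
                             IntegerVector param_map,
                             NumericVector prior_consts,
                             NumericMatrix init_theta,
                             NumericVector init_hyper,
                             NumericVector dir_scale,
                             int n_iter, int n_warmup, int n_dir_moves,
                             int n_thin) {
  ChainSpec cs;
  cs.model = model_code;
  cs.counterfactual = counterfactual;
  cs.P = types.size();
  cs.type = as<std::vector<int> >(types);
  cs.pmap = as<std::vector<int> >(param_map);
  cs.bh_shape = prior_consts[0]; cs.bh_rate = prior_consts[1];
  cs.gh_shape = prior_consts[2]; cs.gh_rate = prior_consts[3];
  cs.st_mu_sd = prior_consts[4]; cs.st_sigma_sd = prior_consts[5];

  int n = subjects.size();
  cs.dat.resize(n);
  for (int j = 0; j < n; ++j) {
    List s = subjects[j];
    cs.dat[j].choice = as<std::vector<int> >(s["choice"]);
    cs.dat[j].reward = as<std::vector<int> >(s["reward"]);
    cs.dat[j].block_start = as<std::vector<int> >(s["block_start"]);
  }

  int P = cs.P;
  // theta[p * n + j]; hyper[2p], hyper[2p + 1]
  std::vector<double> theta(P * n), hyper(2 * P);
  for (int p = 0; p < P; ++p) {
    for (int j = 0; j < n; ++j) theta[p * n + j] = init_theta(j, p);
    hyper[2 * p] = init_hyper[2 * p];
    hyper[2 * p + 1] = init_hyper[2 * p + 1];
  }

  int n_keep = n_iter - n_warmup;
  NumericMatrix draws(n_keep, P * n + 2 * P);

  std::vector<double> z(P), d(P), zc(P), xc(P), row(P);

  // log posterior of one subject in z coordinates (prior + Jacobian + ll)
  auto subj_logpost_z = [&](int j, const std::vector<double>& zz,
                            std::vector<double>& xbuf) -> double {
    double lp = 0.0;
    for (int p = 0; p < P; ++p) {
      double x = x_of_z(cs.type[p], zz[p]);
      switch (cs.type[p]) {
        case 0: if (x <= 1e-12 || x >= 1.0 - 1e-12) return R_NegInf; break;
        case 1: if (x <= 1e-12 || x >= 1e6) return R_NegInf; break;
        default: if (std::fabs(x) >= 1.0 - 1e-12) return R_NegInf;
      }
      xbuf[p] = x;
      lp += cs.prior1(p, x, hyper.data()) + logjac(cs.type[p], x);
      if (!R_finite(lp)) return R_NegInf;
    }
    return lp + cs.subj_ll(j, xbuf.data());
  };


  for (int it = 1; it <= n_iter; ++it) {
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
    // n_thin full sweeps per recorded iteration
    for (int sweep = 0; sweep < n_thin; ++sweep) {

    // ---- subject-level updates: one componentwise sweep in transformed
    // coordinates (covers wide marginals), then random-direction moves
    // (covers correlated directions) ----
    for (int j = 0; j < n; ++j) {
      for (int p = 0; p < P; ++p) {
        z[p] = z_of_x(cs.type[p], theta[p * n + j]);
      }
      for (int p = 0; p < P; ++p) {
        double w_comp = (cs.type[p] == 0) ? 1.5 : 0.8;
        auto logf = [&](double zp) -> double {
          zc = z; zc[p] = zp;
          return subj_logpost_z(j, zc, xc);
        };
        z[p] = slice1(z[p], logf, w_comp, R_NegInf, R_PosInf);
        theta[p * n + j] = x_of_z(cs.type[p], z[p]);
      }
      for (int rep = 0; rep < n_dir_moves; ++rep) {
        for (int p = 0; p < P; ++p) {
          z[p] = z_of_x(cs.type[p], theta[p * n + j]);
          d[p] = dir_scale[p] * norm_rand();
        }
        auto logf = [&](double t) -> double {
          for (int p = 0; p < P; ++p) zc[p] = z[p] + t * d[p];
          return subj_logpost_z(j, zc, xc);
        };
        double t1 = slice1(0.0, logf, 1.0, R_NegInf, R_PosInf);
        for (int p = 0; p < P; ++p) {
          theta[p * n + j] = x_of_z(cs.type[p], z[p] + t1 * d[p]);
        }
      }
    }

    // ---- componentwise hyper updates ----
    for (int p = 0; p < P; ++p) {
      double* v = &theta[p * n];
      double h1 = hyper[2 * p], h2 = hyper[2 * p + 1];
      if (cs.type[p] == 0) {
        auto f_mu = [&](double mu) -> double {
          double a = mu * h2, b = (1.0 - mu) * h2, s = 0.0;
          for (int j = 0; j < n; ++j) s += R::dbeta(v[j], a, b, 1);
          return s + cs.logprior_beta_hyper(mu, h2);
        };
        h1 = slice1(h1, f_mu, 0.08, 1e-6, 1.0 - 1e-6);
        auto f_kap = [&](double kap) -> double {
          double a = h1 * kap, b = (1.0 - h1) * kap, s = 0.0;
          for (int j = 0; j < n; ++j) s += R::dbeta(v[j], a, b, 1);
          return s + cs.logprior_beta_hyper(h1, kap);
        };
        h2 = slice1(h2, f_kap, 3.0, 1e-6, R_PosInf);
      } else if (cs.type[p] == 1) {
        auto f_m = [&](double m) -> double {
          double s = 0.0;
          for (int j = 0; j < n; ++j) s += R::dgamma(v[j], h2, m / h2, 1);
          return s + cs.logprior_gamma_hyper(m, h2);
        };
        h1 = slice1(h1, f_m, 1.5, 1e-6, R_PosInf);
        auto f_k = [&](double k) -> double {
          double s = 0.0;
          for (int j = 0; j < n; ++j) s += R::dgamma(v[j], k, h1 / k, 1);
          return s + cs.logprior_gamma_hyper(h1, k);
        };
        h2 = slice1(h2, f_k, 1.0, 1e-6, R_PosInf);
      } else {
        auto f_mu = [&](double mu) -> double {
          double s = -n * tnorm_logz(mu, h2);
          for (int j = 0; j < n; ++j) s += R::dnorm(v[j], mu, h2, 1);
          return s + cs.logprior_st_hyper(mu, h2);
        };
        h1 = slice1(h1, f_mu, 0.2, R_NegInf, R_PosInf);
        auto f_sig = [&](double sig) -> double {
          double s = -n * tnorm_logz(h1, sig);
          for (int j = 0; j < n; ++j) s += R::dnorm(v[j], h1, sig, 1);
          return s + cs.logprior_st_hyper(h1, sig);
        };
        h2 = slice1(h2, f_sig, 0.2, 1e-6, R_PosInf);
      }
      hyper[2 * p] = h1;
      hyper[2 * p + 1] = h2;
    }

    // ---- reparameterized joint moves (funnel breakers) ----
    // Shared scratch: evaluate the total likelihood with one param column
    // replaced by candidate values.
    std::vector<double> cand(n), th_row(P);
    auto total_ll_with = [&](int p, const std::vector<double>& vals) -> double {
      double s = 0.0;
      for (int j = 0; j < n; ++j) {
        for (int q = 0; q < P; ++q) th_row[q] = theta[q * n + j];
        th_row[p] = vals[j];
        s += cs.subj_ll(j, th_row.data());
      }
      return s;
    };

    for (int p = 0; p < P; ++p) {
      double* v = &theta[p * n];
      double h1 = hyper[2 * p], h2 = hyper[2 * p + 1];
      if (cs.type[p] == 0) {
        // Beta-law funnel breakers, exactly computed in logit space (no
        // cancellation: group densities, hyperprior, Jacobians and the
        // likelihood are all re-evaluated at the mapped state).
        std::vector<double> zv(n);
        for (int j = 0; j < n; ++j) zv[j] = std::log(v[j] / (1.0 - v[j]));
        double zmu = std::log(h1 / (1.0 - h1));
        // translation: shift all subjects and the group mean by delta
        auto f_d = [&](double d_) -> double {
          double mu2 = 1.0 / (1.0 + std::exp(-(zmu + d_)));
          if (mu2 <= 1e-6 || mu2 >= 1.0 - 1e-6) return R_NegInf;
          double a = mu2 * h2, b = (1.0 - mu2) * h2, s = 0.0;
          for (int j = 0; j < n; ++j) {
            double x = 1.0 / (1.0 + std::exp(-(zv[j] + d_)));
            if (x <= 1e-12 || x >= 1.0 - 1e-12) return R_NegInf;
            cand[j] = x;
            s += R::dbeta(x, a, b, 1) + std::log(x) + log1p(-x);
          }
          return s + total_ll_with(p, cand) + cs.logprior_beta_hyper(mu2, h2) +
                 std::log(mu2) + log1p(-mu2);
        };
        double d_new = slice1(0.0, f_d, 0.3, R_NegInf, R_PosInf);
        zmu += d_new;
        h1 = 1.0 / (1.0 + std::exp(-zmu));
        for (int j = 0; j < n; ++j) {
          zv[j] += d_new;
          v[j] = 1.0 / (1.0 + std::exp(-zv[j]));
        }
        // scale: expand logit residuals around the group mean by e^t and
        // move the concentration by e^{-2t} (beta spread ~ 1/sqrt(kappa));
        // log-Jacobian of (z_j, kappa) -> (zmu + e^t (z_j - zmu), kappa
        // e^{-2t}) is (n - 2) t
        auto f_t = [&](double t_) -> double {
          double c = std::exp(t_);
          double kap2 = h2 * std::exp(-2.0 * t_);
          if (kap2 <= 1e-6 || kap2 >= 1e8) return R_NegInf;
          double a = h1 * kap2, b = (1.0 - h1) * kap2, s = 0.0;
          for (int j = 0; j < n; ++j) {
            double x = 1.0 / (1.0 + std::exp(-(zmu + c * (zv[j] - zmu))));
            if (x <= 1e-12 || x >= 1.0 - 1e-12) return R_NegInf;
            cand[j] = x;
            s += R::dbeta(x, a, b, 1) + std::log(x) + log1p(-x);
          }
          return s + total_ll_with(p, cand) + cs.logprior_beta_hyper(h1, kap2) +
                 (n - 2.0) * t_;
        };
        double t_new = slice1(0.0, f_t, 0.3, R_NegInf, R_PosInf);
        double c = std::exp(t_new);
        h2 *= std::exp(-2.0 * t_new);
        for (int j = 0; j < n; ++j) {
          zv[j] = zmu + c * (zv[j] - zmu);
          v[j] = 1.0 / (1.0 + std::exp(-zv[j]));
        }
      } else if (cs.type[p] == 1) {
        // scale move in the gamma-law mean, slicing log(m'): group densities
        // and the (m'/m)^n Jacobian cancel; +s is the log-scale measure term
        std::vector<double> rat(n);
        for (int j = 0; j < n; ++j) rat[j] = v[j] / h1;
        auto f_s = [&](double s_) -> double {
          double m2 = std::exp(s_);
          for (int j = 0; j < n; ++j) {
            cand[j] = m2 * rat[j];
            // keep every subject inside the support the subject moves assume
            if (cand[j] <= 1e-12 || cand[j] >= 1e6) return R_NegInf;
          }
          return total_ll_with(p, cand) + cs.logprior_gamma_hyper(m2, h2) + s_;
        };
        double s_new = slice1(std::log(h1), f_s, 0.3, R_NegInf, 15.0);
        h1 = std::exp(s_new);
        for (int j = 0; j < n; ++j) v[j] = h1 * rat[j];
      } else if (cs.type[p] == 2) {
        // translation move in mu: residuals u_j fixed, their group densities
        // constant; only the truncation normalizer, hyperprior and the
        // likelihood vary
        std::vector<double> u(n);
        double u_min = R_PosInf, u_max = R_NegInf;
        for (int j = 0; j < n; ++j) {
          u[j] = v[j] - h1;
          if (u[j] < u_min) u_min = u[j];
          if (u[j] > u_max) u_max = u[j];
        }
        double lo = -1.0 + 1e-9 - u_min, hi = 1.0 - 1e-9 - u_max;
        if (lo < hi) {
          auto f_mu = [&](double mu2) -> double {
            for (int j = 0; j < n; ++j) {
              cand[j] = mu2 + u[j];
              // cancellation of the group densities only holds on-support
              if (std::fabs(cand[j]) >= 1.0 - 1e-12) return R_NegInf;
            }
            return total_ll_with(p, cand) - n * tnorm_logz(mu2, h2) +
                   R::dnorm(mu2, 0.0, cs.st_mu_sd, 1);
          };
          double mu_new = slice1(h1, f_mu, 0.15, lo, hi);
          for (int j = 0; j < n; ++j) v[j] = mu_new + u[j];
          h1 = mu_new;
        }
        // scale move in sigma, slicing log(sigma'): standardized residuals
        // fixed; group densities cancel against the Jacobian, leaving the
        // normalizer, hyperprior, likelihood and the log-scale measure term
        for (int j = 0; j < n; ++j) u[j] = (v[j] - h1) / h2;
        {
          // feasibility in sigma can be two-sided (when mu sits outside the
          // truncation interval), so the support check lives in the density
          auto f_t = [&](double t_) -> double {
            double sig2 = std::exp(t_);
            for (int j = 0; j < n; ++j) {
              cand[j] = h1 + sig2 * u[j];
              if (std::fabs(cand[j]) >= 1.0 - 1e-12) return R_NegInf;
            }
            return total_ll_with(p, cand) - n * tnorm_logz(h1, sig2) +
                   R::dnorm(sig2, 0.0, cs.st_sigma_sd, 1) + t_;
          };
          double t_new = slice1(std::log(h2), f_t, 0.3, R_NegInf, 15.0);
          h2 = std::exp(t_new);
          for (int j = 0; j < n; ++j) v[j] = h1 + h2 * u[j];
        }
        // ridge-traversal hyper moves: given the subject values, the
        // conditional posterior of (mu, sigma) has a low-mass large-sigma
        // ridge (any far-off mu is admissible once sigma is huge) that the
        // componentwise updates traverse only diffusively. Slice along two
        // rays in hyper space with the subjects held fixed, so only the
        // group densities, normalizer and hyperprior vary; in coordinates
        // (mu / sigma^k, log sigma) the Jacobian contributes (k + 1) s:
        //   k = 1: proportional ray (mu, sigma) -> (mu e^s, sigma e^s)
        //   k = 2: curvature ray    (mu, sigma) -> (mu e^{2s}, sigma e^s)
        // Either connects a ridge point to the concentrated mode in one move.
        for (int k_ray = 1; k_ray <= 2; ++k_ray) {
          double pow_mu = (double)k_ray;
          double eta = h1 / std::pow(h2, pow_mu);
          auto f_s = [&](double s_) -> double {
            double sig2 = std::exp(s_);
            if (sig2 <= 1e-6 || sig2 >= 1e6) return R_NegInf;
            double mu2 = eta * std::pow(sig2, pow_mu);
            if (!R_finite(mu2) || std::fabs(mu2) >= 1e6) return R_NegInf;
            double acc = -n * tnorm_logz(mu2, sig2);
            for (int j = 0; j < n; ++j) acc += R::dnorm(v[j], mu2, sig2, 1);
            return acc + cs.logprior_st_hyper(mu2, sig2) +
                   (1.0 + pow_mu) * s_;
          };
          double s_new = slice1(std::log(h2), f_s, 0.5, R_NegInf, R_PosInf);
          h2 = std::exp(s_new);
          h1 = eta * std::pow(h2, pow_mu);
        }
      }
      hyper[2 * p] = h1;
      hyper[2 * p + 1] = h2;
    }

    }  // end thinning sweeps

    if (it > n_warmup) {
      int r = it - n_warmup - 1;
      for (int c = 0; c < P * n; ++c) draws(r, c) = theta[c];
      for (int c = 0; c < 2 * P; ++c) draws(r, P * n + c) = hyper[c];
    }
  }
  return draws;
}
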