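// Polya-Gamma data augmentation for the Bernoulli-logit random-intercept
// model.  PG(1,z) is sampled with the alternating-series rejection method of
// Devroye / Polson-Scott-Windle; all randomness comes from R's RNG so that
// set.seed() governs the chain.

#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64; // series switch point for the Jacobi density

// piecewise coefficients a_n(x) of the alternating series for the J*(1,z) density
static double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x <= TRUNC)
    return M_PI * np5 * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * np5 * np5 / x);
  return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * x / 2.0);
}

// CDF at TRUNC of an inverse-Gaussian(mu = 1/z, lambda = 1); z may be 0 (Levy limit)
static double pigauss_trunc(double z) {
  double rt = std::sqrt(1.0 / TRUNC);
  double b = rt * (TRUNC * z - 1.0);
  double a = -rt * (TRUNC * z + 1.0);
  return R::pnorm(b, 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(a, 0.0, 1.0, 1, 0);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) restricted to (0, TRUNC]
static double rtigauss(double z) {
  z = std::fabs(z);
  double x = TRUNC + 1.0;
  if (z < 1.0 / TRUNC) { // large mean: inverse-chi-square proposal on the tail
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / TRUNC);
      x = TRUNC / ((1.0 + TRUNC * e1) * (1.0 + TRUNC * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > TRUNC) {
      double y = norm_rand();
      y *= y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// one draw from PG(1, z)
static double rpg1(double z) {
  z = 0.5 * std::fabs(z);
  double k = M_PI * M_PI / 8.0 + 0.5 * z * z;
  double p = (M_PI / (2.0 * k)) * std::exp(-k * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss_trunc(z);
  for (;;) {
    double x;
    if (unif_rand() < p / (p + q))
      x = TRUNC + exp_rand() / k; // exponential tail
    else
      x = rtigauss(z);
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    for (int n = 1;; ++n) {
      if (n & 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

//' @keywords internal
// [[Rcpp::export(rng = true)]]
NumericVector rpg_cpp(int n, NumericVector z) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i % z.size()]);
  return out;
}

// Gibbs sampler for logit(p_i) = b0 + b1 x_i + u_{cl(i)}, u_j ~ N(0, s2u),
// priors b ~ N(0, prior_var I), s2u ~ InvGamma(prior_shape, prior_rate).
// cl is 0-based. Saved iterations are burn_in + thin * (1..n_save).
// fix_u0: freeze all u at 0 and skip the s2u update (plain Bayesian logistic
// regression target, used for validation against numerical integration).
// [[Rcpp::export(rng = true)]]
List pg_gibbs_chain(IntegerVector y, NumericVector x, IntegerVector cl,
                    int n_cluster, double beta0_init, double beta1_init,
                    double prior_var, double prior_shape, double prior_rate,
                    int burn_in, int thin, int n_save, bool fix_u0 = false) {
  int n = y.size();
  double b0 = beta0_init, b1 = beta1_init, s2u = 1.0;
  std::vector<double> u(n_cluster, 0.0);
  std::vector<double> omega(n);

  int total = burn_in + thin * n_save;
  NumericMatrix draws(n_save, 3);
  colnames(draws) = CharacterVector::create("beta0", "beta1", "sigma_u2");
  int kept = 0;
  double prior_prec = 1.0 / prior_var;

  for (int it = 1; it <= total; ++it) {
    // 1. augmentation: omega_i | . ~ PG(1, lp_i)
    for (int i = 0; i < n; ++i) {
      double lp = b0 + b1 * x[i] + u[cl[i]];
      omega[i] = rpg1(lp);
    }

    // 2. beta | omega, u : bivariate normal via 2x2 Cholesky
    double s11 = prior_prec, s12 = 0.0, s22 = prior_prec, t1 = 0.0, t2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double w = omega[i], kap = y[i] - 0.5, r = kap - w * u[cl[i]];
      s11 += w;
      s12 += w * x[i];
      s22 += w * x[i] * x[i];
      t1 += r;
      t2 += r * x[i];
    }
    double det = s11 * s22 - s12 * s12;
    double m0 = (s22 * t1 - s12 * t2) / det;
    double m1 = (s11 * t2 - s12 * t1) / det;
    // Cholesky of the covariance (inverse of the 2x2 precision)
    double c11 = s22 / det, c12 = -s12 / det, c22 = s11 / det;
    double l11 = std::sqrt(c11), l21 = c12 / l11;
    double l22 = std::sqrt(c22 - l21 * l21);
    double z0 = norm_rand(), z1 = norm_rand();
    b0 = m0 + l11 * z0;
    b1 = m1 + l21 * z0 + l22 * z1;

    if (!fix_u0) {
      // 3. u_j | beta, omega, s2u : independent scalar normals
      std::vector<double> prec(n_cluster, 1.0 / s2u), mnum(n_cluster, 0.0);
      for (int i = 0; i < n; ++i) {
        double w = omega[i], kap = y[i] - 0.5;
        prec[cl[i]] += w;
        mnum[cl[i]] += kap - w * (b0 + b1 * x[i]);
      }
      double ssu = 0.0;
      for (int j = 0; j < n_cluster; ++j) {
        u[j] = mnum[j] / prec[j] + norm_rand() / std::sqrt(prec[j]);
        ssu += u[j] * u[j];
      }
      // 4. s2u | u ~ InvGamma(shape + J/2, rate + sum u^2 / 2)
      s2u = 1.0 / R::rgamma(prior_shape + 0.5 * n_cluster,
                            1.0 / (prior_rate + 0.5 * ssu));
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      draws(kept, 0) = b0;
      draws(kept, 1) = b1;
      draws(kept, 2) = s2u;
      ++kept;
    }
  }

  return List::create(_["draws"] = draws, _["u_last"] = NumericVector(u.begin(), u.end()));
}
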