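// Polya-Gamma random variates for logistic data augmentation.
//
// PG(1, z) is drawn exactly with Devroye's alternating-series rejection
// sampler on J*(1, z/2) (PG(1, z) = J*(1, z/2) / 4). Integer shapes up to
// PG_EXACT_MAX are sums of PG(1, z) draws; larger shapes use a moment-
// matched normal approximation, whose relative error is negligible at the
// aggregated-cell counts where it is used. All randomness comes from R's
// RNG, so draws are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;
static const int PG_EXACT_MAX = 30;

// Piecewise coefficients of the alternating series for the J*(1,z) density.
static double a_coef(int n, double x) {
  double np = n + 0.5;
  if (x > TRUNC)
    return M_PI * np * std::exp(-np * np * M_PI * M_PI * x / 2.0);
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * np *
         std::exp(-2.0 * np * np / x);
}

// P(IG(mu = 1/z, lambda = 1) <= x), written to stay finite for large z.
static double pigauss(double x, double z) {
  double rx = 1.0 / std::sqrt(x);
  double b = rx * (x * z - 1.0);
  double a = -rx * (x * z + 1.0);
  double term1 = R::pnorm(b, 0.0, 1.0, 1, 0);
  double lterm2 = 2.0 * z + R::pnorm(a, 0.0, 1.0, 1, 1);
  return term1 + std::exp(lterm2);
}

// Inverse-Gaussian(1/z, 1) truncated to (0, t).
static double rtigauss(double z, double t) {
  double x;
  if (z < 1.0 / t) {  // mu > t: one-sided rejection from the Levy tail
    while (true) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  }
  double mu = 1.0 / z;
  while (true) {
    double y = R::norm_rand();
    y = y * y;
    double muy = mu * y;
    x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
    if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    if (x <= t) return x;
  }
}

// One exact PG(1, z) draw.
static double rpg1(double z) {
  z = std::fabs(z) * 0.5;
  double K = M_PI * M_PI * 0.125 + 0.5 * z * z;
  double p = (M_PI / (2.0 * K)) * std::exp(-K * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  while (true) {
    double x;
    if (R::unif_rand() * (p + q) < p)
      x = TRUNC + R::exp_rand() / K;
    else
      x = rtigauss(z, TRUNC);
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    while (true) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

static double pg_mean(double b, double z) {
  double az = std::fabs(z);
  if (az < 1e-8) return 0.25 * b;
  return 0.5 * b * std::tanh(0.5 * az) / az;
}

static double pg_var(double b, double z) {
  double az = std::fabs(z);
  if (az < 1e-4) return b / 24.0;
  double th = std::tanh(0.5 * az);
  double sech2 = 1.0 - th * th;
  return 0.25 * b * (2.0 * th - az * sech2) / (az * az * az);
}

//' @keywords internal
// [[Rcpp::export(name = ".rpg_cpp")]]
NumericVector rpg_cpp(IntegerVector shape, NumericVector z) {
  int n = shape.size();
  if (z.size() != n) stop("shape and z must have the same length");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int b = shape[i];
    if (b < 0) stop("shape must be non-negative");
    if (b == 0) { out[i] = 0.0; continue; }
    if (b <= PG_EXACT_MAX) {
      double s = 0.0;
      for (int r = 0; r < b; ++r) s += rpg1(z[i]);
      out[i] = s;
    } else {
      double m = pg_mean((double)b, z[i]);
      double v = pg_var((double)b, z[i]);
      double d = m + std::sqrt(v) * R::norm_rand();
      out[i] = d > 1e-12 ? d : 1e-12;
    }
  }
  return out;
}
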