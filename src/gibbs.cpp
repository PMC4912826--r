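#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-site Gibbs sampler for the two-component normal mixture GWAS model
//
//   y = 1*mu + X g + Z u + e,   e_i ~ N(0, sigma2_e / w_i)
//   g_j ~ N(0, sigma2_g0)              with probability pi0
//   g_j ~ N(0, ratio * sigma2_g0)      with probability 1 - pi0
//   pi0 ~ Beta(pi_a, pi_b),  u ~ N(0, A sigma2_u)
//   flat priors on mu, sigma2_g0 (bounded support), sigma2_u, sigma2_e
//
// The indicator delta_j is drawn with g_j integrated out, then g_j from its
// normal full conditional.  u is updated element-wise through the sparse
// inverse of A (CSC arrays Ai_p / Ai_i / Ai_x).  rec_of maps each pedigree
// position to its phenotype record (-1 when unphenotyped); obs maps records
// to pedigree positions.  All randomness comes from R's RNG, so set.seed()
// in R makes chains bit-reproducible.

static double draw_inv_gamma_bounded(double shape, double scale, double upper) {
  // density prop to x^-(shape+1) exp(-scale/x) on (0, upper]
  if (shape > 0.5) {
    for (int k = 0; k < 100; ++k) {
      double x = scale / R::rgamma(shape, 1.0);
      if (x <= upper) return x;
    }
    return upper;
  }
  // shape <= 0.5 (flat prior with very few effects): the inverse-gamma form is
  // improper or heavy-tailed, but the conditional is proper on (0, upper].
  // Slice sample t = log x with log f(t) = -shape * t - scale * exp(-t).
  double t = std::log(std::min(std::max(scale / std::max(shape, 0.5), 1e-12), upper));
  const double tmax = std::log(upper);
  for (int it = 0; it < 10; ++it) { // a few passes to decorrelate
    double lf0 = -shape * t - scale * std::exp(-t);
    double ls = lf0 - R::exp_rand();
    double lo = t - 2.0, hi = std::min(t + 2.0, tmax);
    while ((-shape * lo - scale * std::exp(-lo)) > ls) lo -= 2.0;
    while (hi < tmax && (-shape * hi - scale * std::exp(-hi)) > ls) hi = std::min(hi + 2.0, tmax);
    for (;;) {
      double prop = R::runif(lo, hi);
      if ((-shape * prop - scale * std::exp(-prop)) > ls) { t = prop; break; }
      if (prop < t) lo = prop; else hi = prop;
    }
  }
  return std::exp(t);
}

// [[Rcpp::export]]
List gibbs_mixture_cpp(NumericVector y, NumericVector w, NumericMatrix X,
                       IntegerVector obs,
                       IntegerVector Ai_p, IntegerVector Ai_i, NumericVector Ai_x,
                       int n_cycles, int burn_in, int thin,
                       double pi_a, double pi_b, double ratio,
                       double sigma2_g0_max, int check_every, bool prior_only,
                       double init_sigma2_g0, double init_sigma2_u,
                       double init_sigma2_e) {
  const int n = y.size();        // records
  const int m = X.ncol();        // markers
  const int np = Ai_p.size() - 1; // pedigree individuals
  if (X.nrow() != n) stop("genotype matrix rows must match phenotype records");

  std::vector<int> rec_of(np, -1);
  for (int i = 0; i < n; ++i) {
    if (obs[i] < 0 || obs[i] >= np) stop("obs index out of pedigree range");
    rec_of[obs[i]] = i;
  }

  const int n_saved = (n_cycles - burn_in) / thin;
  if (n_saved < 1) stop("chain settings leave no saved cycles");

  NumericMatrix g_s(n_saved, m), u_s(n_saved, np);
  IntegerMatrix d_s(n_saved, m);
  NumericVector mu_s(n_saved), s2g_s(n_saved), pi0_s(n_saved),
                s2u_s(n_saved), s2e_s(n_saved);

  std::vector<double> g(m, 0.0), u(np, 0.0), r(n), xwx(m);
  std::vector<int> delta(m, 0);
  double mu = 0.0, sw = 0.0;
  for (int i = 0; i < n; ++i) sw += w[i];
  {
    double num = 0.0;
    for (int i = 0; i < n; ++i) num += w[i] * y[i];
    mu = num / sw;
  }
  std::vector<double> WX((size_t)n * m); // w_i * x_ij, speeds the dot products
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double *xj = &X(0, j);
    double *wxj = &WX[(size_t)j * n];
    for (int i = 0; i < n; ++i) {
      wxj[i] = w[i] * xj[i];
      s += wxj[i] * xj[i];
    }
    xwx[j] = s;
  }
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  double s2g = init_sigma2_g0, s2u = init_sigma2_u, s2e = init_sigma2_e;
  double pi0 = pi_a / (pi_a + pi_b);
  double max_drift = 0.0;

  RNGScope scope;
  int isave = 0;
  for (int cyc = 1; cyc <= n_cycles; ++cyc) {
    if (!prior_only) {
      // --- mu (flat prior) ---
      double num = 0.0;
      for (int i = 0; i < n; ++i) num += w[i] * r[i];
      double mu_new = R::rnorm(mu + num / sw, std::sqrt(s2e / sw));
      double dmu = mu - mu_new;
      for (int i = 0; i < n; ++i) r[i] += dmu;
      mu = mu_new;
    }

    // --- (delta_j, g_j) jointly, g integrated out of the indicator draw ---
    const double log_pi0 = std::log(pi0), log_pi1 = std::log1p(-pi0);
    for (int j = 0; j < m; ++j) {
      if (prior_only) {
        delta[j] = (unif_rand() < (1.0 - pi0)) ? 1 : 0;
        g[j] = norm_rand() * std::sqrt(delta[j] ? ratio * s2g : s2g);
        continue;
      }
      const double *xj = &X(0, j);
      const double *wxj = &WX[(size_t)j * n];
      const double c = xwx[j];
      double q = c * g[j];
      for (int i = 0; i < n; ++i) q += wxj[i] * r[i];
      const double v0 = s2g, v1 = ratio * s2g;
      // log marginal of the residual under each component (up to shared const)
      double l0 = -0.5 * std::log1p(c * v0 / s2e) +
                  0.5 * v0 * q * q / (s2e * (s2e + c * v0));
      double l1 = -0.5 * std::log1p(c * v1 / s2e) +
                  0.5 * v1 * q * q / (s2e * (s2e + c * v1));
      double lo1 = (log_pi1 + l1) - (log_pi0 + l0);
      int dj = (unif_rand() < 1.0 / (1.0 + std::exp(-lo1))) ? 1 : 0;
      double v = dj ? v1 : v0;
      double prec = c / s2e + 1.0 / v;
      double gnew = R::rnorm(q / (s2e * prec), std::sqrt(1.0 / prec));
      double dg = g[j] - gnew;
      if (dg != 0.0) for (int i = 0; i < n; ++i) r[i] += xj[i] * dg;
      delta[j] = dj;
      g[j] = gnew;
    }

    // --- sigma2_g0 (flat prior, bounded support) ---
    if (!prior_only) {
      double S = 0.0;
      int m1 = 0;
      for (int j = 0; j < m; ++j) {
        S += delta[j] ? g[j] * g[j] / ratio : g[j] * g[j];
        m1 += delta[j];
      }
      // conditional prop to (s2g)^{-m/2} exp(-S/(2 s2g)): inv-gamma shape m/2 - 1
      s2g = draw_inv_gamma_bounded(0.5 * m - 1.0, 0.5 * S, sigma2_g0_max);
      if (!R_finite(s2g) || s2g <= 0.0)
        stop("sigma2_g0 draw degenerate at cycle %d", cyc);
    }

    // --- pi0 ~ Beta(pi_a + m0, pi_b + m1) ---
    {
      int m1 = 0;
      for (int j = 0; j < m; ++j) m1 += delta[j];
      pi0 = R::rbeta(pi_a + (m - m1), pi_b + m1);
    }

    if (!prior_only) {
      // --- u, element-wise via sparse A-inverse ---
      for (int i = 0; i < np; ++i) {
        double aii = 0.0, off = 0.0;
        for (int k = Ai_p[i]; k < Ai_p[i + 1]; ++k) {
          int row = Ai_i[k];
          if (row == i) aii = Ai_x[k];
          else off += Ai_x[k] * u[row];
        }
        double prec = aii / s2u, rhs = -off / s2u;
        int ri = rec_of[i];
        if (ri >= 0) {
          prec += w[ri] / s2e;
          rhs += w[ri] * (r[ri] + u[i]) / s2e;
        }
        double unew = R::rnorm(rhs / prec, std::sqrt(1.0 / prec));
        if (ri >= 0) r[ri] += u[i] - unew;
        u[i] = unew;
      }

      // --- sigma2_u: u' Ainv u over nonzeros ---
      double Su = 0.0;
      for (int i = 0; i < np; ++i)
        for (int k = Ai_p[i]; k < Ai_p[i + 1]; ++k)
          Su += u[i] * Ai_x[k] * u[Ai_i[k]];
      s2u = draw_inv_gamma_bounded(0.5 * np - 1.0, 0.5 * Su, 1e12);

      // --- sigma2_e ---
      double Se = 0.0;
      for (int i = 0; i < n; ++i) Se += w[i] * r[i] * r[i];
      s2e = draw_inv_gamma_bounded(0.5 * n - 1.0, 0.5 * Se, 1e12);
      if (!R_finite(s2e) || !R_finite(s2u))
        stop("variance draw overflow at cycle %d (sigma2_u=%g, sigma2_e=%g)",
             cyc, s2u, s2e);

      // --- periodic residual consistency check & refresh ---
      if (check_every > 0 && cyc % check_every == 0) {
        for (int i = 0; i < n; ++i) {
          double fit = mu + u[obs[i]];
          for (int j = 0; j < m; ++j) fit += X(i, j) * g[j];
          double fresh = y[i] - fit;
          double dr = std::fabs(fresh - r[i]);
          if (dr > max_drift) max_drift = dr;
          r[i] = fresh;
        }
      }
    }

    if (cyc > burn_in && (cyc - burn_in) % thin == 0 && isave < n_saved) {
      for (int j = 0; j < m; ++j) { g_s(isave, j) = g[j]; d_s(isave, j) = delta[j]; }
      for (int i = 0; i < np; ++i) u_s(isave, i) = u[i];
      mu_s[isave] = mu; s2g_s[isave] = s2g; pi0_s[isave] = pi0;
      s2u_s[isave] = s2u; s2e_s[isave] = s2e;
      ++isave;
    }
    if (cyc % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["g"] = g_s, _["delta"] = d_s, _["u"] = u_s, _["mu"] = mu_s,
    _["sigma2_g0"] = s2g_s, _["pi0"] = pi0_s, _["sigma2_u"] = s2u_s,
    _["sigma2_e"] = s2e_s, _["n_saved"] = isave,
    _["max_residual_drift"] = max_drift);
}
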