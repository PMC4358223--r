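#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the spike-and-slab SNP model
//   y = 1*mu + Z alpha + e,  alpha_j = 0 with prob 1-pi,
//   alpha_j ~ N(0, sigma2_snp) with prob pi,
//   pi ~ Beta(a, b), sigma2_snp ~ flat on (s2_lo, s2_hi), sigma2_e ~ flat.
// Z is the centred (not scaled) dose matrix of the training animals.
// Uses R's RNG so results are reproducible under set.seed().

// sample sigma2_snp from its full conditional
//   p(s2) ∝ s2^{-k/2} exp(-S/(2 s2)) on (lo, hi)
// scaled-inverse-chi-square draw for k >= 3, grid sampler otherwise
static double sample_s2_snp(int k, double S, double lo, double hi) {
  lo = std::max(lo, 1e-12);
  if (k >= 3) {
    for (int t = 0; t < 100; ++t) {
      double cand = S / R::rchisq((double)(k - 2));
      if (cand > lo && cand < hi) return cand;
    }
  }
  // grid fallback (also covers k < 3, where the density is proper only
  // because the prior is bounded)
  const int ng = 201;
  std::vector<double> g(ng), lw(ng);
  double lmax = -1e300;
  for (int t = 0; t < ng; ++t) {
    double s2 = lo + (hi - lo) * (t + 0.5) / ng;
    g[t] = s2;
    lw[t] = -0.5 * k * std::log(s2) - S / (2.0 * s2);
    if (lw[t] > lmax) lmax = lw[t];
  }
  double tot = 0.0;
  for (int t = 0; t < ng; ++t) { lw[t] = std::exp(lw[t] - lmax); tot += lw[t]; }
  double u = unif_rand() * tot, acc = 0.0;
  for (int t = 0; t < ng; ++t) { acc += lw[t]; if (u <= acc) return g[t]; }
  return g[ng - 1];
}

// [[Rcpp::export]]
List bayesc_gibbs(NumericMatrix Z, NumericVector y,
                  int burn_in, int n_samples, int thin,
                  double pi_a, double pi_b,
                  double s2_lo, double s2_hi,
                  double pi_fixed, double s2s_fixed) {
  const int n = Z.nrow(), m = Z.ncol();
  if (n != y.size()) stop("Z and y dimensions disagree");
  const int total = burn_in + n_samples * thin;
  if (burn_in >= total) stop("burn-in must be shorter than the total chain");

  std::vector<double> cj(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    cj[j] = s;
  }

  double vy = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) my += y[i];
  my /= n;
  for (int i = 0; i < n; ++i) vy += (y[i] - my) * (y[i] - my);
  vy /= (n - 1);

  // state
  std::vector<double> alpha(m, 0.0);
  std::vector<int> delta(m, 0);
  double mu = my, s2e = vy / 2.0, s2s = std::min(vy / (0.01 * m) + 1e-8,
                                                 0.5 * (s2_lo + s2_hi));
  double pi = (pi_fixed > 0) ? pi_fixed : 0.5;
  if (s2s_fixed > 0) s2s = s2s_fixed;
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  // accumulators
  std::vector<double> alpha_sum(m, 0.0), incl_sum(m, 0.0);
  double pi_sum = 0, s2s_sum = 0, s2e_sum = 0, mu_sum = 0;
  NumericVector genvar_trace(n_samples);
  int rec = 0;

  for (int cyc = 1; cyc <= total; ++cyc) {
    // mu
    double rs = 0.0;
    for (int i = 0; i < n; ++i) rs += r[i] + mu;
    double mu_new = R::rnorm(rs / n, std::sqrt(s2e / n));
    for (int i = 0; i < n; ++i) r[i] += mu - mu_new;
    mu = mu_new;

    // SNP effects: joint (indicator, effect) update
    int k = 0;
    double S = 0.0;
    double log_odds_prior = (pi >= 1.0) ? 1e300
      : std::log(pi) - std::log1p(-pi);
    for (int j = 0; j < m; ++j) {
      if (cj[j] <= 0.0) { alpha[j] = 0.0; delta[j] = 0; continue; }
      double aj = alpha[j];
      double rhs = 0.0;
      if (aj != 0.0) {
        for (int i = 0; i < n; ++i) { r[i] += Z(i, j) * aj; rhs += Z(i, j) * r[i]; }
      } else {
        for (int i = 0; i < n; ++i) rhs += Z(i, j) * r[i];
      }
      double v1 = s2e + cj[j] * s2s;
      double logBF = 0.5 * (std::log(s2e / v1) + rhs * rhs * s2s / (s2e * v1));
      double p1 = 1.0 / (1.0 + std::exp(-(log_odds_prior + logBF)));
      if (unif_rand() < p1) {
        double prec = cj[j] + s2e / s2s;
        double mean_post = rhs / prec;
        double a_new = R::rnorm(mean_post, std::sqrt(s2e / prec));
        for (int i = 0; i < n; ++i) r[i] -= Z(i, j) * a_new;
        alpha[j] = a_new;
        delta[j] = 1;
        ++k;
        S += a_new * a_new;
      } else {
        alpha[j] = 0.0;
        delta[j] = 0;
      }
    }

    // sigma2_snp | alpha, delta (bounded flat prior)
    if (s2s_fixed <= 0) {
      if (k > 0) s2s = sample_s2_snp(k, S, s2_lo, s2_hi);
      else s2s = s2_lo + unif_rand() * (s2_hi - std::max(s2_lo, 1e-12));
    }

    // pi | delta ~ Beta(a + k, b + m - k)
    if (pi_fixed <= 0) {
      pi = R::rbeta(pi_a + k, pi_b + (m - k));
      if (pi <= 1e-12) pi = 1e-12;
      if (pi >= 1.0 - 1e-12) pi = 1.0 - 1e-12;
    }

    // sigma2_e | r (flat prior)
    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    s2e = rss / R::rchisq((double)(n - 2));

    if (cyc > burn_in && (cyc - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j) {
        alpha_sum[j] += alpha[j];
        incl_sum[j] += delta[j];
      }
      pi_sum += pi; s2s_sum += s2s; s2e_sum += s2e; mu_sum += mu;
      // genetic values g = y - mu - r; record their variance
      double gm = 0.0;
      for (int i = 0; i < n; ++i) gm += y[i] - mu - r[i];
      gm /= n;
      double gv = 0.0;
      for (int i = 0; i < n; ++i) {
        double gi = y[i] - mu - r[i] - gm;
        gv += gi * gi;
      }
      genvar_trace[rec] = gv / (n - 1);
      ++rec;
    }
  }

  NumericVector am(m), ip(m);
  for (int j = 0; j < m; ++j) {
    am[j] = alpha_sum[j] / rec;
    ip[j] = incl_sum[j] / rec;
  }
  return List::create(
    _["alpha_mean"] = am,
    _["inclusion_prob"] = ip,
    _["pi_mean"] = pi_sum / rec,
    _["sigma2_snp_mean"] = s2s_sum / rec,
    _["sigma2_e_mean"] = s2e_sum / rec,
    _["mu_mean"] = mu_sum / rec,
    _["genvar_trace"] = genvar_trace,
    _["n_recorded"] = rec);
}
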