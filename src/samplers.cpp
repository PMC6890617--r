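#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs samplers for whole-genome regression
// (BayesA / BayesB / BayesCpi / two-component normal mixture "MMixp").
//
// Model: y = X alpha + W beta + e, e ~ N(0, I sigma_e2).
// Fixed effects: flat priors. Residual variance: scaled-inv-chisq(ve_df,
// ve_scale). Marker effect variances per model, scaled-inv-chisq(v, s2).
// Uses R's RNG so set.seed() on the R side fixes the chain.

static inline double rinvchisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export]]
List bayes_gibbs_cpp(NumericVector y, NumericMatrix X, NumericMatrix W,
                     int model, double pi0, double v, double s2,
                     double ve_df, double ve_scale,
                     int n_iter, int burn_in, int thin, double ratio) {
  const int n = y.size();
  const int p = X.ncol();
  const int m = W.ncol();

  std::vector<double> xtx(p), wtw(m);
  for (int k = 0; k < p; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, k) * X(i, k);
    xtx[k] = s;
  }
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    wtw[j] = s;
  }

  std::vector<double> alpha(p, 0.0), beta(m, 0.0);
  std::vector<double> sb2(m, v * s2 / std::max(v - 2.0, 0.1)); // per-marker variances (BayesA/B)
  std::vector<int> delta(m, 1), zlarge(m, 1);
  double sigma_b2 = v * s2 / std::max(v - 2.0, 0.1); // common slab (BayesCpi)
  double tau2 = sigma_b2;                            // large-class variance (MMixp)
  double pi_cur = (model == 2) ? 0.5 : pi0;          // inclusion prob
  double p_large = 0.5;                              // MMixp large-class prob
  double ymean = 0.0, yvar = 0.0;
  for (int i = 0; i < n; ++i) ymean += y[i];
  ymean /= n;
  for (int i = 0; i < n; ++i) yvar += (y[i] - ymean) * (y[i] - ymean);
  yvar /= (n - 1);
  double sigma_e2 = yvar / 2.0;

  if (model == 1 || model == 2) { // sparse start for spike-and-slab models
    for (int j = 0; j < m; ++j) delta[j] = (R::unif_rand() < pi_cur) ? 1 : 0;
  }

  // start at alpha = 0, beta = 0, so e = y; the first alpha sweep absorbs the mean
  std::vector<double> e(y.begin(), y.end());

  std::vector<double> beta_sum(m, 0.0), delta_sum(m, 0.0), alpha_sum(p, 0.0);
  int n_keep = 0;
  const int keep_cap = (n_iter - burn_in + thin - 1) / thin;
  NumericVector pi_samples(keep_cap), se2_samples(keep_cap), sb2_samples(keep_cap);

  for (int it = 0; it < n_iter; ++it) {
    // --- fixed effects, flat prior ---
    for (int k = 0; k < p; ++k) {
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, k) * e[i];
      rhs += xtx[k] * alpha[k];
      double mean = rhs / xtx[k];
      double anew = R::norm_rand() * std::sqrt(sigma_e2 / xtx[k]) + mean;
      double diff = anew - alpha[k];
      for (int i = 0; i < n; ++i) e[i] -= X(i, k) * diff;
      alpha[k] = anew;
    }

    // --- marker effects ---
    int m_in = 0;
    double ss_beta = 0.0;    // BayesCpi: sum beta^2 over included
    double ss_scaled = 0.0;  // MMixp: sum beta^2 / c_j
    int n_large = 0;
    for (int j = 0; j < m; ++j) {
      if (wtw[j] <= 0.0) { beta[j] = 0.0; continue; } // monomorphic-in-training guard
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += W(i, j) * e[i];
      r += wtw[j] * beta[j]; // = w_j' e_{-j}

      double varj; // slab / effect variance for this marker
      if (model == 0) varj = sb2[j];
      else if (model == 1) varj = sb2[j];
      else if (model == 2) varj = sigma_b2;
      else { // MMixp: sample the variance class given current beta
        double v_l = tau2, v_s = tau2 / ratio;
        double ll_l = std::log(p_large) - 0.5 * (std::log(v_l) + beta[j] * beta[j] / v_l);
        double ll_s = std::log(1.0 - p_large) - 0.5 * (std::log(v_s) + beta[j] * beta[j] / v_s);
        double pl = 1.0 / (1.0 + std::exp(ll_s - ll_l));
        zlarge[j] = (R::unif_rand() < pl) ? 1 : 0;
        if (zlarge[j]) ++n_large;
        varj = zlarge[j] ? v_l : v_s;
      }

      int inc = 1;
      if (model == 1 || model == 2) {
        if (pi_cur >= 1.0) {
          inc = 1;
        } else {
          // indicator with the effect integrated out given the variances:
          // r ~ N(0, sigma_e2 wtw) under out, N(0, sigma_e2 wtw + varj wtw^2) under in
          double v0 = sigma_e2 * wtw[j];
          double v1 = v0 + varj * wtw[j] * wtw[j];
          double log_bf = -0.5 * (std::log(v1 / v0) + r * r * (1.0 / v1 - 1.0 / v0));
          double log_odds = std::log(pi_cur / (1.0 - pi_cur)) + log_bf;
          double p1 = 1.0 / (1.0 + std::exp(-log_odds));
          inc = (R::unif_rand() < p1) ? 1 : 0;
        }
        delta[j] = inc;
      }

      double bnew = 0.0;
      if (inc) {
        double lhs = wtw[j] + sigma_e2 / varj;
        double mean = r / lhs;
        bnew = R::norm_rand() * std::sqrt(sigma_e2 / lhs) + mean;
      }
      double diff = bnew - beta[j];
      if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] -= W(i, j) * diff;
      beta[j] = bnew;

      // variance updates per marker
      if (model == 0) {
        sb2[j] = rinvchisq(v + 1.0, (v * s2 + beta[j] * beta[j]) / (v + 1.0));
      } else if (model == 1) {
        if (inc) sb2[j] = rinvchisq(v + 1.0, (v * s2 + beta[j] * beta[j]) / (v + 1.0));
        else sb2[j] = rinvchisq(v, s2); // refresh from the prior
      } else if (model == 2) {
        if (inc) { ++m_in; ss_beta += beta[j] * beta[j]; }
      } else {
        ss_scaled += beta[j] * beta[j] * (zlarge[j] ? 1.0 : ratio);
      }
    }

    if (model == 2) {
      sigma_b2 = rinvchisq(v + m_in, (v * s2 + ss_beta) / (v + m_in));
      pi_cur = R::rbeta(1.0 + m_in, 1.0 + (m - m_in));
    } else if (model == 3) {
      tau2 = rinvchisq(v + m, (v * s2 + ss_scaled) / (v + m));
      p_large = R::rbeta(1.0 + n_large, 1.0 + (m - n_large));
    }

    // --- residual variance ---
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma_e2 = (ve_df * ve_scale + sse) / R::rchisq(ve_df + n);
    if (!std::isfinite(sigma_e2) || sigma_e2 <= 0.0) {
      stop("residual variance diverged at iteration %d (sse = %g)", it + 1, sse);
    }

    // --- accumulate post burn-in, thinned ---
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j) {
        beta_sum[j] += beta[j];
        delta_sum[j] += (model == 1 || model == 2) ? delta[j]
                        : (model == 3 ? zlarge[j] : 1.0);
      }
      for (int k = 0; k < p; ++k) alpha_sum[k] += alpha[k];
      pi_samples[n_keep] = (model == 3) ? p_large : pi_cur;
      se2_samples[n_keep] = sigma_e2;
      sb2_samples[n_keep] = (model == 2) ? sigma_b2
                            : (model == 3 ? tau2 : s2);
      ++n_keep;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector effect_mean(m), incl(m), alpha_mean(p);
  for (int j = 0; j < m; ++j) {
    effect_mean[j] = beta_sum[j] / n_keep;
    incl[j] = delta_sum[j] / n_keep;
  }
  for (int k = 0; k < p; ++k) alpha_mean[k] = alpha_sum[k] / n_keep;

  return List::create(
    _["effect_mean"] = effect_mean,
    _["inclusion_prob"] = incl,
    _["alpha_mean"] = alpha_mean,
    _["pi_samples"] = pi_samples[Range(0, n_keep - 1)],
    _["sigma_e2_samples"] = se2_samples[Range(0, n_keep - 1)],
    _["sigma_b2_samples"] = sb2_samples[Range(0, n_keep - 1)]
  );
}
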