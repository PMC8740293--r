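#include <Rcpp.h>
using namespace Rcpp;

// Fill missing genotype entries by majority vote among the k nearest
// accessions observing the marker. ord is n x n: row i holds neighbour
// indices of accession i in increasing distance (1-based, self excluded
// upstream via infinite self-distance). freq_pref is 3 x p: genotypes at
// each marker ranked by observed frequency (ties already broken toward 1).
// [[Rcpp::export]]
NumericMatrix knn_impute_cpp(NumericMatrix X, LogicalMatrix obs,
                             IntegerMatrix ord, int k,
                             NumericMatrix freq_pref) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix out = clone(X);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) {
      if (obs(i, j)) continue;
      int votes[3] = {0, 0, 0};  // counts for -1, 0, 1
      int got = 0;
      for (int t = 0; t < n && got < k; ++t) {
        int nb = ord(i, t) - 1;
        if (nb == i || !obs(nb, j)) continue;
        double v = X(nb, j);
        votes[(int)v + 1]++;
        got++;
      }
      if (got == 0) { out(i, j) = freq_pref(0, j); continue; }
      int best = votes[0];
      for (int c = 1; c < 3; ++c) if (votes[c] > best) best = votes[c];
      // resolve ties by the marker's frequency-ranked preference
      double pick = NA_REAL;
      for (int r = 0; r < 3; ++r) {
        int g = (int)freq_pref(r, j) + 1;
        if (votes[g] == best) { pick = freq_pref(r, j); break; }
      }
      out(i, j) = pick;
    }
  }
  return out;
}

static double rscinvchisq(double df, double scale_times_df) {
  // draw from scaled-inverse-chi-square: scale_times_df / chisq(df)
  return scale_times_df / R::rchisq(df);
}

// BayesC-pi Gibbs sampler. Z is the centred marker matrix; each marker
// effect is null with probability pi (sampled each iteration under a
// uniform prior via its beta full conditional) or drawn from N(0, s2g).
// Both variances carry scaled-inverse-chi-square priors with nu0 degrees
// of freedom and scales Sg, Se. When pi_fixed >= 0 the inclusion
// probability is held at that value (pi_fixed = 0 keeps every marker in
// the model, the ridge limit). Uses R's RNG, so set.seed() upstream makes
// chains reproducible.
// [[Rcpp::export]]
List bayescpi_gibbs(NumericMatrix Z, NumericVector y, int n_iter,
                    int burn_in, int thin, double nu0, double Sg, double Se,
                    double pi_fixed) {
  int n = Z.nrow(), p = Z.ncol();
  std::vector<double> u(p, 0.0);
  std::vector<int> delta(p, 0);
  std::vector<double> zz(p);
  for (int j = 0; j < p; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    zz[j] = s;
  }
  double mu = mean(y);
  double s2g = Sg, s2e = Se;
  double pi = (pi_fixed >= 0) ? pi_fixed : 0.5;
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  std::vector<double> u_sum(p, 0.0), incl_sum(p, 0.0);
  double pi_sum = 0, s2g_sum = 0, s2e_sum = 0, mu_sum = 0;
  std::vector<double> s2e_chain, pi_chain;
  int n_kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double rbar = 0;
    for (int i = 0; i < n; ++i) rbar += r[i];
    rbar /= n;
    double mu_new = rbar + mu + R::rnorm(0.0, std::sqrt(s2e / n));
    double shift = mu_new - mu;
    for (int i = 0; i < n; ++i) r[i] -= shift;
    mu = mu_new;

    int m = 0;
    double uss = 0;
    for (int j = 0; j < p; ++j) {
      if (zz[j] <= 0) continue;
      double rhs = 0;
      if (delta[j]) {
        for (int i = 0; i < n; ++i) { r[i] += Z(i, j) * u[j]; }
      }
      for (int i = 0; i < n; ++i) rhs += Z(i, j) * r[i];
      double v = 1.0 / (zz[j] / s2e + 1.0 / s2g);
      double mean_inc = v * rhs / s2e;
      double logbf = 0.5 * (std::log(v) - std::log(s2g)) +
                     0.5 * mean_inc * mean_inc / v;
      double logit = std::log1p(-pi) - std::log(pi > 0 ? pi : 1e-300) + logbf;
      double p_inc = (pi <= 0) ? 1.0 :
                     (pi >= 1) ? 0.0 : 1.0 / (1.0 + std::exp(-logit));
      if (R::unif_rand() < p_inc) {
        u[j] = mean_inc + R::norm_rand() * std::sqrt(v);
        delta[j] = 1;
        for (int i = 0; i < n; ++i) r[i] -= Z(i, j) * u[j];
        m++;
        uss += u[j] * u[j];
      } else {
        u[j] = 0.0;
        delta[j] = 0;
      }
    }
    if (pi_fixed < 0) {
      pi = R::rbeta(p - m + 1.0, m + 1.0);   // pi = null probability
    }
    // per-marker scale spreads the genetic-variance budget over the
    // included fraction (1 - pi), the usual BayesC-pi elicitation
    double frac_in = std::max(1.0 - pi, 1.0 / p);
    s2g = rscinvchisq(nu0 + m, nu0 * Sg / frac_in + uss);
    double rss = 0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    s2e = rscinvchisq(nu0 + n, nu0 * Se + rss);
    if (!R_finite(s2e) || !R_finite(s2g)) {
      stop("BayesC-pi chain diverged (non-finite variance) at iteration %d",
           it + 1);
    }

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      for (int j = 0; j < p; ++j) {
        u_sum[j] += u[j];
        incl_sum[j] += delta[j];
      }
      pi_sum += pi; s2g_sum += s2g; s2e_sum += s2e; mu_sum += mu;
      s2e_chain.push_back(s2e);
      pi_chain.push_back(pi);
      n_kept++;
    }
  }
  NumericVector u_mean(p), incl(p);
  for (int j = 0; j < p; ++j) {
    u_mean[j] = u_sum[j] / n_kept;
    incl[j] = incl_sum[j] / n_kept;
  }
  return List::create(_["u_mean"] = u_mean, _["incl_prob"] = incl,
                      _["pi_mean"] = pi_sum / n_kept,
                      _["s2g_mean"] = s2g_sum / n_kept,
                      _["s2e_mean"] = s2e_sum / n_kept,
                      _["mu_mean"] = mu_sum / n_kept,
                      _["s2e_chain"] = wrap(s2e_chain),
                      _["pi_chain"] = wrap(pi_chain),
                      _["n_kept"] = n_kept);
}
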