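// MCMC sampler for the presence-only joint SDM.
//
// Model: y_i(k) ~ Bern(Q_i(k)), Q_i = alpha_i * P_i + (1 - alpha_i) * S,
//        logit P_i = D_e beta_pi + G, logit S = D_a beta_s + G,
//        G ~ N(0, [tau (D - lambda W)]^{-1})  (proper CAR),
//        y_c(k) ~ Bern(S(k)); missing responses are marginalised (they
//        contribute a factor of 1, so they simply drop out of every
//        likelihood term).
//
// Updates per iteration:
//   - G: single-site adaptive random-walk Metropolis. The CAR full
//     conditional of G_k has mean lambda * sum_nb(G)/d_k and precision
//     tau*d_k; the Bernoulli terms of cell k complete the target.
//   - joint shift move G -> G - c, all intercepts -> + c. Every linear
//     predictor is invariant, so the move resolves the weak identifiability
//     between the field level and the intercepts; the MH ratio involves
//     only the CAR prior and the intercept priors.
//   - beta_p, beta_s: component-wise adaptive random walk.
//   - alpha_i: random walk on the logit scale (Beta prior + Jacobian).
//   - lambda: random walk on the logit scale. log det(D - lambda W) =
//     sum(log d) + sum(log(1 - lambda * e_j)) with e_j the eigenvalues of
//     D^{-1/2} W D^{-1/2} (precomputed once), so each proposal is O(n).
//   - tau: Gibbs. With a Gamma(shape, rate) prior on the precision
//     multiplier (= inverse-gamma on the CAR variance), the full
//     conditional is Gamma(shape + n/2, rate + G'(D - lambda W)G / 2).
//
// Proposal scales adapt toward 0.44 acceptance during burn-in only.
// All randomness comes from R's RNG, so set.seed() on the R side gives
// bit-reproducible chains.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double ilogit(double x) {
  if (x >= 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

static inline double bern_ll(int y, double p) {
  if (y == 1) return (p <= 0.0) ? R_NegInf : std::log(p);
  return (p >= 1.0) ? R_NegInf : std::log1p(-p);
}

// [[Rcpp::export(name = ".run_mcmc_chain")]]
List run_mcmc_chain(IntegerMatrix y, IntegerVector yc, List De,
                    const arma::mat& Da, List nb_list,
                    const arma::vec& deg, const arma::vec& evals,
                    List priors, List init, LogicalVector alpha_fixed,
                    int n_iter, int burn_in, int thin, int field_sweeps,
                    int param_sweeps) {
  const int n = y.nrow(), T = y.ncol();
  const int pa = Da.n_cols;

  std::vector<arma::mat> Xe(T);
  std::vector<arma::vec> bp(T);
  for (int i = 0; i < T; ++i) {
    Xe[i] = as<arma::mat>(De[i]);
    bp[i] = as<arma::vec>(as<List>(init["beta_p"])[i]);
  }
  arma::vec bs = as<arma::vec>(init["beta_s"]);
  arma::vec alpha = as<arma::vec>(init["alpha"]);
  double lambda = as<double>(init["lambda"]);
  double tau = as<double>(init["tau"]);
  arma::vec G = as<arma::vec>(init["G"]);

  const double beta_var = as<double>(priors["beta_var"]);
  const double aa = as<double>(priors["alpha_a"]), ab = as<double>(priors["alpha_b"]);
  const double la = as<double>(priors["lambda_a"]), lb = as<double>(priors["lambda_b"]);
  const double tau_shape = as<double>(priors["tau_shape"]);
  const double tau_rate = as<double>(priors["tau_rate"]);

  std::vector<std::vector<int>> nb(n);
  for (int k = 0; k < n; ++k) {
    IntegerVector v = nb_list[k];
    nb[k].assign(v.begin(), v.end());
  }
  const double sum_deg = arma::accu(deg);

  // caches
  arma::mat etaP(n, T);
  for (int i = 0; i < T; ++i) etaP.col(i) = Xe[i] * bp[i];
  arma::vec etaA = Da * bs;

  auto cell_ll = [&](int k, double gk) -> double {
    double ll = 0.0;
    double s = ilogit(etaA[k] + gk);
    if (yc[k] != NA_INTEGER) ll += bern_ll(yc[k], s);
    for (int i = 0; i < T; ++i) {
      int yk = y(k, i);
      if (yk == NA_INTEGER) continue;
      double p = ilogit(etaP(k, i) + gk);
      ll += bern_ll(yk, alpha[i] * p + (1.0 - alpha[i]) * s);
    }
    return ll;
  };
  // full log-likelihood of taxon i with a trial etaP column
  auto taxon_ll = [&](int i, const arma::vec& ep) -> double {
    double ll = 0.0;
    for (int k = 0; k < n; ++k) {
      int yk = y(k, i);
      if (yk == NA_INTEGER) continue;
      double p = ilogit(ep[k] + G[k]);
      double s = ilogit(etaA[k] + G[k]);
      ll += bern_ll(yk, alpha[i] * p + (1.0 - alpha[i]) * s);
    }
    return ll;
  };
  // log-lik terms touched by the sampling process (y_c and every taxon)
  auto effort_ll = [&](const arma::vec& ea) -> double {
    double ll = 0.0;
    for (int k = 0; k < n; ++k) {
      double s = ilogit(ea[k] + G[k]);
      if (yc[k] != NA_INTEGER) ll += bern_ll(yc[k], s);
      for (int i = 0; i < T; ++i) {
        int yk = y(k, i);
        if (yk == NA_INTEGER) continue;
        double p = ilogit(etaP(k, i) + G[k]);
        ll += bern_ll(yk, alpha[i] * p + (1.0 - alpha[i]) * s);
      }
    }
    return ll;
  };

  // ---- adaptive-covariance (AM) block proposals --------------------------
  // One block per taxon over (beta_pi, logit alpha_i) — these are the
  // strongly correlated directions — and one block for beta_s. Empirical
  // covariance accumulated during burn-in (Welford), proposal
  // scale * chol(2.38^2/d * Sigma + eps I), global scale adapted to 0.234.
  struct AMBlock {
    arma::vec mean, last;
    arma::mat scat, L;
    double lscale = 0.0;
    long cnt = 0;
    void init(int d) {
      mean.zeros(d); scat.zeros(d, d); last.zeros(d);
      L.eye(d, d); L *= 0.1;
    }
    void record(const arma::vec& v) {
      ++cnt;
      arma::vec d1 = v - mean;
      mean += d1 / cnt;
      scat += d1 * (v - mean).t();
    }
    void refresh() {
      if (cnt < 20) return;
      int d = mean.n_elem;
      arma::mat S = scat / (cnt - 1) * (5.6644 / d);  // 2.38^2 / d
      S.diag() += 1e-8;
      arma::mat Lt;
      if (arma::chol(Lt, S, "lower")) L = Lt;
    }
  };
  std::vector<AMBlock> amP(T);
  for (int i = 0; i < T; ++i)
    amP[i].init(Xe[i].n_cols + (alpha_fixed[i] ? 0 : 1));
  AMBlock amS; amS.init(pa);

  // adaptive proposal log-scales
  arma::vec lsG(n, arma::fill::zeros); lsG.fill(std::log(1.0));
  std::vector<arma::vec> lsBp(T);
  for (int i = 0; i < T; ++i) lsBp[i] = arma::vec(Xe[i].n_cols, arma::fill::value(std::log(0.1)));
  arma::vec lsBs(pa, arma::fill::value(std::log(0.1)));
  arma::vec lsA(T, arma::fill::value(std::log(0.5)));
  double lsL = std::log(0.5), lsC = std::log(0.2), lsS = std::log(0.2);
  double lsR = std::log(0.3);
  const double target = 0.44;

  const int n_keep = (n_iter - burn_in) / thin;
  int P = 0;
  for (int i = 0; i < T; ++i) P += Xe[i].n_cols;
  P += pa + T + 2 + n;
  arma::mat out(n_keep, P);
  int stored = 0;

  RNGScope scope;
  for (int it = 1; it <= n_iter; ++it) {
    const bool adapting = it <= burn_in;
    const double gam = std::min(0.25, 3.0 / std::sqrt((double) it));

    for (int sweep = 0; sweep < field_sweeps; ++sweep) {
    // ---- G single-site sweep ----
    for (int k = 0; k < n; ++k) {
      double nbsum = 0.0;
      for (int j : nb[k]) nbsum += G[j];
      const double m = lambda * nbsum / deg[k];
      const double prec = tau * deg[k];
      const double g0 = G[k];
      const double g1 = g0 + std::exp(lsG[k]) * norm_rand();
      double lr = cell_ll(k, g1) - cell_ll(k, g0)
        - 0.5 * prec * ((g1 - m) * (g1 - m) - (g0 - m) * (g0 - m));
      double ap = (lr >= 0) ? 1.0 : std::exp(lr);
      if (unif_rand() < ap) G[k] = g1;
      if (adapting) lsG[k] += gam * (ap - target);
    }

    // ---- joint level-shift move: G -> G - c, intercepts -> + c ----
    {
      const double c = std::exp(lsC) * norm_rand();
      double dWG = 0.0;  // sum_k d_k G_k  (since (D - lW)1 = (1-l)d)
      for (int k = 0; k < n; ++k) dWG += deg[k] * G[k];
      double lr = -0.5 * tau * (1.0 - lambda) * (c * c * sum_deg - 2.0 * c * dWG);
      for (int i = 0; i < T; ++i)
        lr += (-0.5 * ((bp[i][0] + c) * (bp[i][0] + c) - bp[i][0] * bp[i][0]) / beta_var);
      lr += (-0.5 * ((bs[0] + c) * (bs[0] + c) - bs[0] * bs[0]) / beta_var);
      double ap = (lr >= 0) ? 1.0 : std::exp(lr);
      if (unif_rand() < ap) {
        G -= c;
        for (int i = 0; i < T; ++i) { bp[i][0] += c; etaP.col(i) += c; }
        bs[0] += c; etaA += c;
      }
      if (adapting) lsC += gam * (ap - target);
    }

    // ---- field amplitude move: G -> s G (log-scale random walk) ----
    // Single-site updates explore the field's shape but random-walk its
    // overall amplitude very slowly; this global move (with the tau Gibbs
    // step) mixes the amplitude direction directly.
    {
      const double eps = std::exp(lsS) * norm_rand();
      const double s = std::exp(eps);
      double qD = 0.0, qW = 0.0, ll0 = 0.0, ll1 = 0.0;
      for (int k = 0; k < n; ++k) {
        qD += deg[k] * G[k] * G[k];
        double sm = 0.0;
        for (int j : nb[k]) sm += G[j];
        qW += G[k] * sm;
        ll0 += cell_ll(k, G[k]);
        ll1 += cell_ll(k, s * G[k]);
      }
      double lr = ll1 - ll0
        - 0.5 * tau * (s * s - 1.0) * (qD - lambda * qW)
        + n * eps;  // Jacobian of G -> sG
      double ap = (lr >= 0) ? 1.0 : std::exp(lr);
      if (unif_rand() < ap) G *= s;
      if (adapting) lsS += gam * (ap - 0.234);
    }

    // ---- interweaved rescale (G, tau) -> (sG, tau / s^2) ----
    // The centred parameterisation has a funnel: a small-amplitude field
    // sends the tau Gibbs step to huge values, which in turn clamps the
    // site-wise field moves. This joint move keeps tau * G'(D - lW)G
    // invariant, so it walks along the funnel's axis; the MH ratio is the
    // likelihood change plus the tau prior and Jacobian terms only.
    {
      const double eps = std::exp(lsR) * norm_rand();
      const double s = std::exp(eps);
      double ll0 = 0.0, ll1 = 0.0;
      for (int k = 0; k < n; ++k) {
        ll0 += cell_ll(k, G[k]);
        ll1 += cell_ll(k, s * G[k]);
      }
      double lr = ll1 - ll0 - 2.0 * tau_shape * eps
        - tau_rate * tau * (1.0 / (s * s) - 1.0);
      double ap = (lr >= 0) ? 1.0 : std::exp(lr);
      if (unif_rand() < ap) { G *= s; tau /= s * s; }
      if (adapting) lsR += gam * (ap - 0.234);
    }
    }  // field sweeps

    for (int psweep = 0; psweep < param_sweeps; ++psweep) {
    // ---- ecological coefficients, component-wise ----
    for (int i = 0; i < T; ++i) {
      const int p = Xe[i].n_cols;
      double ll0 = taxon_ll(i, etaP.col(i));
      for (int j = 0; j < p; ++j) {
        const double d = std::exp(lsBp[i][j]) * norm_rand();
        arma::vec ep = etaP.col(i) + d * Xe[i].col(j);
        const double b1 = bp[i][j] + d;
        const double ll1 = taxon_ll(i, ep);
        double lr = ll1 - ll0
          - 0.5 * (b1 * b1 - bp[i][j] * bp[i][j]) / beta_var;
        double ap = (lr >= 0) ? 1.0 : std::exp(lr);
        if (unif_rand() < ap) { bp[i][j] = b1; etaP.col(i) = ep; ll0 = ll1; }
        if (adapting) lsBp[i][j] += gam * (ap - target);
      }
    }

    // ---- sampling-effort coefficients, component-wise ----
    {
      double ll0 = effort_ll(etaA);
      for (int j = 0; j < pa; ++j) {
        const double d = std::exp(lsBs[j]) * norm_rand();
        arma::vec ea = etaA + d * Da.col(j);
        const double b1 = bs[j] + d;
        const double ll1 = effort_ll(ea);
        double lr = ll1 - ll0
          - 0.5 * (b1 * b1 - bs[j] * bs[j]) / beta_var;
        double ap = (lr >= 0) ? 1.0 : std::exp(lr);
        if (unif_rand() < ap) { bs[j] = b1; etaA = ea; ll0 = ll1; }
        if (adapting) lsBs[j] += gam * (ap - target);
      }
    }

    // ---- mixing weights on the logit scale ----
    for (int i = 0; i < T; ++i) {
      if (alpha_fixed[i]) continue;
      const double a0 = alpha[i];
      const double z0 = std::log(a0) - std::log1p(-a0);
      const double z1 = z0 + std::exp(lsA[i]) * norm_rand();
      const double a1 = ilogit(z1);
      double ll0 = 0.0, ll1 = 0.0;
      for (int k = 0; k < n; ++k) {
        int yk = y(k, i);
        if (yk == NA_INTEGER) continue;
        double p = ilogit(etaP(k, i) + G[k]);
        double s = ilogit(etaA[k] + G[k]);
        ll0 += bern_ll(yk, a0 * p + (1.0 - a0) * s);
        ll1 += bern_ll(yk, a1 * p + (1.0 - a1) * s);
      }
      double lr = ll1 - ll0
        + (aa * (std::log(a1) - std::log(a0))
           + ab * (std::log1p(-a1) - std::log1p(-a0)));  // Beta + Jacobian
      double ap = (lr >= 0) ? 1.0 : std::exp(lr);
      if (unif_rand() < ap) alpha[i] = a1;
      if (adapting) lsA[i] += gam * (ap - target);
    }

    // ---- CAR quadratic forms ----
    double qD = 0.0, qW = 0.0;
    for (int k = 0; k < n; ++k) {
      qD += deg[k] * G[k] * G[k];
      double s = 0.0;
      for (int j : nb[k]) s += G[j];
      qW += G[k] * s;
    }

    // ---- lambda on the logit scale ----
    {
      const double z0 = std::log(lambda) - std::log1p(-lambda);
      const double z1 = z0 + std::exp(lsL) * norm_rand();
      const double l1 = ilogit(z1);
      double lr = 0.0;
      for (arma::uword j = 0; j < evals.n_elem; ++j)
        lr += 0.5 * (std::log1p(-l1 * evals[j]) - std::log1p(-lambda * evals[j]));
      lr += 0.5 * tau * (l1 - lambda) * qW;
      lr += (la * (std::log(l1) - std::log(lambda))
             + lb * (std::log1p(-l1) - std::log1p(-lambda)));
      double ap = (lr >= 0) ? 1.0 : std::exp(lr);
      if (unif_rand() < ap) lambda = l1;
      if (adapting) lsL += gam * (ap - target);
    }

    // ---- tau by Gibbs ----
    {
      const double shape = tau_shape + 0.5 * n;
      const double rate = tau_rate + 0.5 * (qD - lambda * qW);
      tau = R::rgamma(shape, 1.0 / rate);
    }
    }  // parameter sweeps

    // ---- joint AM block updates: (beta_pi, logit alpha_i) per taxon ----
    for (int i = 0; i < T; ++i) {
      const int p = Xe[i].n_cols;
      const bool with_a = !alpha_fixed[i];
      const int d = p + (with_a ? 1 : 0);
      arma::vec cur(d);
      for (int j = 0; j < p; ++j) cur[j] = bp[i][j];
      if (with_a) cur[p] = std::log(alpha[i]) - std::log1p(-alpha[i]);
      arma::vec z(d);
      for (int j = 0; j < d; ++j) z[j] = norm_rand();
      arma::vec prop = cur + std::exp(amP[i].lscale) * (amP[i].L * z);
      arma::vec bnew(p);
      for (int j = 0; j < p; ++j) bnew[j] = prop[j];
      const double anew = with_a ? ilogit(prop[p]) : alpha[i];
      arma::vec ep = Xe[i] * bnew;
      // likelihood of taxon i at (bnew, anew)
      double ll0 = 0.0, ll1 = 0.0;
      for (int k = 0; k < n; ++k) {
        int yk = y(k, i);
        if (yk == NA_INTEGER) continue;
        double s = ilogit(etaA[k] + G[k]);
        ll0 += bern_ll(yk, alpha[i] * ilogit(etaP(k, i) + G[k])
                             + (1.0 - alpha[i]) * s);
        ll1 += bern_ll(yk, anew * ilogit(ep[k] + G[k]) + (1.0 - anew) * s);
      }
      double lr = ll1 - ll0;
      for (int j = 0; j < p; ++j)
        lr += -0.5 * (bnew[j] * bnew[j] - bp[i][j] * bp[i][j]) / beta_var;
      if (with_a)
        lr += (aa * (std::log(anew) - std::log(alpha[i]))
               + ab * (std::log1p(-anew) - std::log1p(-alpha[i])));
      double ap = (lr >= 0) ? 1.0 : std::exp(lr);
      if (unif_rand() < ap) {
        bp[i] = bnew; etaP.col(i) = ep;
        if (with_a) alpha[i] = anew;
      }
      if (adapting) {
        amP[i].lscale += gam * (ap - 0.234);
        arma::vec now(d);
        for (int j = 0; j < p; ++j) now[j] = bp[i][j];
        if (with_a) now[p] = std::log(alpha[i]) - std::log1p(-alpha[i]);
        amP[i].record(now);
        if (it % 25 == 0) amP[i].refresh();
      }
    }

    // ---- joint AM block update: beta_s ----
    {
      arma::vec z(pa);
      for (int j = 0; j < pa; ++j) z[j] = norm_rand();
      arma::vec bnew = bs + std::exp(amS.lscale) * (amS.L * z);
      arma::vec ea = Da * bnew;
      double lr = effort_ll(ea) - effort_ll(etaA);
      for (int j = 0; j < pa; ++j)
        lr += -0.5 * (bnew[j] * bnew[j] - bs[j] * bs[j]) / beta_var;
      double ap = (lr >= 0) ? 1.0 : std::exp(lr);
      if (unif_rand() < ap) { bs = bnew; etaA = ea; }
      if (adapting) {
        amS.lscale += gam * (ap - 0.234);
        amS.record(bs);
        if (it % 25 == 0) amS.refresh();
      }
    }

    // ---- store ----
    if (it > burn_in && (it - burn_in) % thin == 0 && stored < n_keep) {
      int c = 0;
      for (int i = 0; i < T; ++i)
        for (arma::uword j = 0; j < bp[i].n_elem; ++j) out(stored, c++) = bp[i][j];
      for (int j = 0; j < pa; ++j) out(stored, c++) = bs[j];
      for (int i = 0; i < T; ++i) out(stored, c++) = alpha[i];
      out(stored, c++) = lambda;
      out(stored, c++) = tau;
      for (int k = 0; k < n; ++k) out(stored, c++) = G[k];
      ++stored;
    }
  }

  return List::create(_["samples"] = out, _["n_kept"] = stored);
}
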