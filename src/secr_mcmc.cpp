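// Data-augmented spatially-explicit robust-design capture-recapture
// sampler. Individuals (observed + augmented) carry an activity-center
// chain over water cells and an alive-interval [entry, death]; detection is
// half-normal in distance from the center to the nearest effort line, with
// per-primary mean sighting locations Gaussian around the center. Survival
// phi and entry gamma get conjugate Beta updates; p0, sigma and the
// stratum log-intensity coefficients get random-walk Metropolis; centers
// get neighborhood Metropolis; alive intervals get exact categorical Gibbs
// by enumerating all T(T+1)/2 + 1 monotone trajectories.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logit(double p) { return std::log(p / (1.0 - p)); }
static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Model {
  int M, T, K, ncell;
  std::vector<double> cx, cy, effd;   // per water cell
  std::vector<int> strat;             // 0 inshore, 1 island, 2 offshore
  std::vector<int> nbr_start, nbr_idx;
  double sig_move;
  // movement-kernel normalizer components per origin cell, by destination
  // stratum: Z_beta(s) = Zs0[s] + e^bI Zs1[s] + e^bO Zs2[s]
  std::vector<double> Zs0, Zs1, Zs2;
  // data (M x T), row-major i*T + t
  std::vector<int> ndet;
  std::vector<double> obsx, obsy;     // NaN when no detection
  std::vector<double> ssq;            // within-primary location scatter
  std::vector<double> D2w;            // squared distances between cells
};

// log normalizer of the water-truncated location density per center cell:
// logS[s] = log sum_c exp(-d^2(s, c) / 2 sigma^2) over water cells.
// (The 2 pi sigma^2 factor cancels against the cell-sum approximation of
// the truncation integral, so this is the whole sigma-dependent constant.)
static void location_logS(const Model& m, double sigma,
                          std::vector<double>& logS) {
  logS.resize(m.ncell);
  double inv = 1.0 / (2.0 * sigma * sigma);
  for (int s = 0; s < m.ncell; ++s) {
    double acc = 0.0;
    const double* row = &m.D2w[(size_t)s * m.ncell];
    for (int c = 0; c < m.ncell; ++c) acc += std::exp(-row[c] * inv);
    logS[s] = std::log(acc);
  }
}

// log-likelihood of primary t for individual i when alive with center cell s
static double ll_alive(const Model& m, int i, int t, int s,
                       double p0, double sigma,
                       const std::vector<double>& logS) {
  double d = m.effd[s];
  double p = p0 * std::exp(-d * d / (2.0 * sigma * sigma));
  if (p <= 1e-300) p = 1e-300;
  if (p >= 1.0 - 1e-12) p = 1.0 - 1e-12;
  int n = m.ndet[i * m.T + t];
  double ll = n * std::log(p) + (m.K - n) * std::log1p(-p);
  if (n > 0) {
    double dx = m.obsx[i * m.T + t] - m.cx[s];
    double dy = m.obsy[i * m.T + t] - m.cy[s];
    ll += -(n * (dx * dx + dy * dy) + m.ssq[i * m.T + t])
            / (2.0 * sigma * sigma)
          - n * logS[s];
  }
  return ll;
}

// intensity-weighted dispersal kernel:
// k(to | from) = exp(beta x(to)) exp(-d^2 / 2 sig^2) / Z_beta(from)
static double move_ld(const Model& m, int from, int to,
                      double bI, double bO) {
  double dx = m.cx[to] - m.cx[from], dy = m.cy[to] - m.cy[from];
  double bx = (m.strat[to] == 1) ? bI : (m.strat[to] == 2) ? bO : 0.0;
  double Z = m.Zs0[from] + std::exp(bI) * m.Zs1[from]
           + std::exp(bO) * m.Zs2[from];
  return bx - (dx * dx + dy * dy) / (2.0 * m.sig_move * m.sig_move)
         - std::log(Z);
}

// [[Rcpp::export]]
List secr_chain(List data, List init, List ctrl) {
  Model m;
  m.M = as<int>(data["M"]); m.T = as<int>(data["T"]);
  m.K = as<int>(data["K"]);
  NumericVector cx = data["cell_x"], cy = data["cell_y"],
                effd = data["eff_dist"], z0 = data["Zs0"], z1 = data["Zs1"],
                z2 = data["Zs2"];
  IntegerVector strat = data["stratum"], nbs = data["nbr_start"],
                nbi = data["nbr_idx"];
  m.ncell = cx.size();
  m.cx.assign(cx.begin(), cx.end()); m.cy.assign(cy.begin(), cy.end());
  m.effd.assign(effd.begin(), effd.end());
  m.Zs0.assign(z0.begin(), z0.end()); m.Zs1.assign(z1.begin(), z1.end());
  m.Zs2.assign(z2.begin(), z2.end());
  m.strat.assign(strat.begin(), strat.end());
  m.nbr_start.assign(nbs.begin(), nbs.end());
  m.nbr_idx.assign(nbi.begin(), nbi.end());
  m.sig_move = as<double>(data["sigma_move"]);
  IntegerMatrix ndet = data["n_det"];          // M x T
  NumericMatrix ox = data["obs_x"], oy = data["obs_y"], ssq = data["ss"];
  m.ndet.resize(m.M * m.T); m.obsx.resize(m.M * m.T);
  m.obsy.resize(m.M * m.T); m.ssq.resize(m.M * m.T);
  for (int i = 0; i < m.M; ++i)
    for (int t = 0; t < m.T; ++t) {
      m.ndet[i * m.T + t] = ndet(i, t);
      m.obsx[i * m.T + t] = ox(i, t);
      m.obsy[i * m.T + t] = oy(i, t);
      m.ssq[i * m.T + t] = ssq(i, t);
    }

  int n_iter = as<int>(ctrl["n_iter"]), burn = as<int>(ctrl["burn"]),
      thin = as<int>(ctrl["thin"]);
  double prior_sigma_sd = as<double>(ctrl["prior_sigma_sd"]);
  double prior_beta_sd = as<double>(ctrl["prior_beta_sd"]);
  double prop_p0 = as<double>(ctrl["prop_p0"]);
  double prop_sigma = as<double>(ctrl["prop_sigma"]);
  double prop_beta = as<double>(ctrl["prop_beta"]);
  bool fix_p0 = as<bool>(ctrl["fix_p0"]);
  bool fix_sigma = as<bool>(ctrl["fix_sigma"]);

  // state
  std::vector<int> s(m.M * m.T);                 // center cell per (i, t)
  IntegerMatrix s0 = init["s"];
  for (int i = 0; i < m.M; ++i)
    for (int t = 0; t < m.T; ++t) s[i * m.T + t] = s0(i, t);
  std::vector<int> ent(m.M), dth(m.M);           // 1-based; 0 = never
  IntegerVector e0 = init["entry"], d0 = init["death"];
  for (int i = 0; i < m.M; ++i) { ent[i] = e0[i]; dth[i] = d0[i]; }
  double p0 = as<double>(init["p0"]), sigma = as<double>(init["sigma"]);
  double betaI = as<double>(init["beta_island"]);
  double betaO = as<double>(init["beta_offshore"]);
  std::vector<double> phi(m.T - 1, 0.7), gam(m.T, 0.3);

  int n_keep = (n_iter - burn) / thin;
  NumericMatrix out_par(n_keep, 4 + (m.T - 1));  // p0 sigma bI bO phi...
  IntegerMatrix out_N(n_keep, m.T * 3);          // alive per t x stratum
  IntegerVector out_entered(n_keep);
  int keep = 0;

  std::vector<double> lp(m.T * (m.T + 1) / 2 + 1);
  std::vector<int> pe(lp.size()), pd(lp.size());

  // stratum counts of cells (for beta normalizer)
  int cells_per_strat[3] = {0, 0, 0};
  for (int c = 0; c < m.ncell; ++c) cells_per_strat[m.strat[c]]++;

  NumericMatrix D2w = data["D2w"];
  m.D2w.resize((size_t)m.ncell * m.ncell);
  for (int a = 0; a < m.ncell; ++a)
    for (int b = 0; b < m.ncell; ++b)
      m.D2w[(size_t)a * m.ncell + b] = D2w(a, b);
  std::vector<double> logS, logS_prop;
  location_logS(m, sigma, logS);

  RNGScope scope;

  for (int iter = 0; iter < n_iter; ++iter) {
    // --- alive-interval Gibbs per individual ----------------------------
    std::vector<double> lg(m.T), l1mg(m.T), lph(m.T - 1), l1mph(m.T - 1);
    for (int t = 0; t < m.T; ++t) {
      lg[t] = std::log(gam[t]); l1mg[t] = std::log1p(-gam[t]);
    }
    for (int t = 0; t < m.T - 1; ++t) {
      lph[t] = std::log(phi[t]); l1mph[t] = std::log1p(-phi[t]);
    }
    for (int i = 0; i < m.M; ++i) {
      // cache per-primary lls
      std::vector<double> la(m.T), cum1mg(m.T + 1, 0.0);
      bool any_det = false;
      for (int t = 0; t < m.T; ++t) {
        la[t] = ll_alive(m, i, t, s[i * m.T + t], p0, sigma, logS);
        if (m.ndet[i * m.T + t] > 0) any_det = true;
        cum1mg[t + 1] = cum1mg[t] + l1mg[t];
      }
      int np = 0;
      if (!any_det) { lp[np] = cum1mg[m.T]; pe[np] = 0; pd[np] = 0; ++np; }
      for (int e = 1; e <= m.T; ++e) {
        bool ok_pre = true;
        for (int t = 0; t < e - 1; ++t)
          if (m.ndet[i * m.T + t] > 0) { ok_pre = false; break; }
        if (!ok_pre) break;  // larger e only worse
        double base = cum1mg[e - 1] + lg[e - 1];
        double run = 0.0;
        for (int d = e; d <= m.T; ++d) {
          run += la[d - 1];
          if (d > e) run += lph[d - 2];
          bool ok_post = true;
          for (int t = d; t < m.T; ++t)
            if (m.ndet[i * m.T + t] > 0) { ok_post = false; break; }
          if (ok_post) {
            double tail = (d < m.T) ? l1mph[d - 1] : 0.0;
            lp[np] = base + run + tail; pe[np] = e; pd[np] = d; ++np;
          }
        }
      }
      // categorical sample via Gumbel-max
      double best = -INFINITY; int arg = 0;
      for (int k = 0; k < np; ++k) {
        double g = lp[k] - std::log(-std::log(unif_rand()));
        if (g > best) { best = g; arg = k; }
      }
      ent[i] = pe[arg]; dth[i] = pd[arg];
    }

    // --- phi, gamma Gibbs ----------------------------------------------
    for (int t = 0; t < m.T - 1; ++t) {
      int surv = 0, died = 0;
      for (int i = 0; i < m.M; ++i) {
        if (ent[i] >= 1 && ent[i] <= t + 1 && dth[i] >= t + 1) {
          if (dth[i] >= t + 2) ++surv; else ++died;
        }
      }
      phi[t] = R::rbeta(1.0 + surv, 1.0 + died);
    }
    for (int t = 0; t < m.T; ++t) {
      int entered = 0, avail = 0;
      for (int i = 0; i < m.M; ++i) {
        bool not_yet = (ent[i] == 0) || (ent[i] > t);
        if (not_yet || ent[i] == t + 1) {
          ++avail;
          if (ent[i] == t + 1) ++entered;
        }
      }
      gam[t] = R::rbeta(1.0 + entered, 1.0 + (avail - entered));
    }

    // --- center updates -------------------------------------------------
    for (int i = 0; i < m.M; ++i) {
      for (int t = 0; t < m.T; ++t) {
        int cur = s[i * m.T + t];
        int off = m.nbr_start[cur], len = m.nbr_start[cur + 1] - off;
        int prop = m.nbr_idx[off + (int)(unif_rand() * len)];
        if (prop == cur) continue;
        int plen = m.nbr_start[prop + 1] - m.nbr_start[prop];
        double lacc = std::log((double)len) - std::log((double)plen);
        bool alive = ent[i] >= 1 && ent[i] <= t + 1 && dth[i] >= t + 1;
        if (alive)
          lacc += ll_alive(m, i, t, prop, p0, sigma, logS)
                - ll_alive(m, i, t, cur, p0, sigma, logS);
        if (t == 0) {
          double bp = (m.strat[prop] == 1) ? betaI :
                      (m.strat[prop] == 2) ? betaO : 0.0;
          double bc = (m.strat[cur] == 1) ? betaI :
                      (m.strat[cur] == 2) ? betaO : 0.0;
          lacc += bp - bc;
        } else {
          lacc += move_ld(m, s[i * m.T + t - 1], prop, betaI, betaO)
                - move_ld(m, s[i * m.T + t - 1], cur, betaI, betaO);
        }
        if (t < m.T - 1) {
          lacc += move_ld(m, prop, s[i * m.T + t + 1], betaI, betaO)
                - move_ld(m, cur, s[i * m.T + t + 1], betaI, betaO);
        }
        if (std::log(unif_rand()) < lacc) s[i * m.T + t] = prop;
      }
    }

    // --- p0, sigma Metropolis -------------------------------------------
    auto total_ll = [&](double p0_, double sig_,
                        const std::vector<double>& lS) {
      double ll = 0.0;
      for (int i = 0; i < m.M; ++i) {
        if (ent[i] < 1) continue;
        for (int t = ent[i] - 1; t < dth[i]; ++t)
          ll += ll_alive(m, i, t, s[i * m.T + t], p0_, sig_, lS);
      }
      return ll;
    };
    double cur_ll = total_ll(p0, sigma, logS);
    if (!fix_p0) {
      double lp0 = logit(p0) + norm_rand() * prop_p0;
      double p0n = inv_logit(lp0);
      double prop_ll = total_ll(p0n, sigma, logS);
      double lacc = prop_ll - cur_ll
        + std::log(p0n * (1 - p0n)) - std::log(p0 * (1 - p0));
      if (std::log(unif_rand()) < lacc) { p0 = p0n; cur_ll = prop_ll; }
    }
    if (!fix_sigma) {
      double lsn = std::log(sigma) + norm_rand() * prop_sigma;
      double sn = std::exp(lsn);
      location_logS(m, sn, logS_prop);
      double lacc = total_ll(p0, sn, logS_prop) - cur_ll
        + R::dnorm(sn, 0.0, prior_sigma_sd, 1)
        - R::dnorm(sigma, 0.0, prior_sigma_sd, 1)
        + lsn - std::log(sigma);
      if (std::log(unif_rand()) < lacc) { sigma = sn; logS.swap(logS_prop); }
    }

    // --- stratum intensity coefficients ---------------------------------
    // beta enters the t = 1 center prior and every dispersal transition
    {
      int n_strat1 = 0, n_strat2 = 0;          // first-primary centers
      int mv_strat1 = 0, mv_strat2 = 0;        // transition destinations
      std::vector<int> cnt_from(m.ncell, 0);   // transition origins
      for (int i = 0; i < m.M; ++i) {
        int st = m.strat[s[i * m.T + 0]];
        if (st == 1) ++n_strat1; else if (st == 2) ++n_strat2;
        for (int t = 1; t < m.T; ++t) {
          int st2 = m.strat[s[i * m.T + t]];
          if (st2 == 1) ++mv_strat1; else if (st2 == 2) ++mv_strat2;
          cnt_from[s[i * m.T + t - 1]]++;
        }
      }
      auto beta_ll = [&](double bI, double bO) {
        double Z = cells_per_strat[0] + cells_per_strat[1] * std::exp(bI)
                 + cells_per_strat[2] * std::exp(bO);
        double ll = n_strat1 * bI + n_strat2 * bO - m.M * std::log(Z)
             + (mv_strat1 * bI + mv_strat2 * bO)
             + R::dnorm(bI, 0.0, prior_beta_sd, 1)
             + R::dnorm(bO, 0.0, prior_beta_sd, 1);
        double eI = std::exp(bI), eO = std::exp(bO);
        for (int c = 0; c < m.ncell; ++c)
          if (cnt_from[c])
            ll -= cnt_from[c] * std::log(m.Zs0[c] + eI * m.Zs1[c]
                                         + eO * m.Zs2[c]);
        return ll;
      };
      // several sub-updates per sweep: the conditional is tight and the
      // coefficient decorrelates slowly against the center configuration
      for (int rep = 0; rep < 3; ++rep) {
        double bIn = betaI + norm_rand() * prop_beta;
        if (std::log(unif_rand()) <
            beta_ll(bIn, betaO) - beta_ll(betaI, betaO))
          betaI = bIn;
        if (cells_per_strat[2] > 0) {
          double bOn = betaO + norm_rand() * prop_beta;
          if (std::log(unif_rand()) <
              beta_ll(betaI, bOn) - beta_ll(betaI, betaO))
            betaO = bOn;
        }
      }
    }

    // --- record ----------------------------------------------------------
    if (iter >= burn && (iter - burn) % thin == 0) {
      out_par(keep, 0) = p0; out_par(keep, 1) = sigma;
      out_par(keep, 2) = betaI; out_par(keep, 3) = betaO;
      for (int t = 0; t < m.T - 1; ++t) out_par(keep, 4 + t) = phi[t];
      int entered_tot = 0;
      for (int i = 0; i < m.M; ++i) if (ent[i] >= 1) ++entered_tot;
      out_entered[keep] = entered_tot;
      for (int t = 0; t < m.T; ++t) {
        int cnt[3] = {0, 0, 0};
        for (int i = 0; i < m.M; ++i) {
          if (ent[i] >= 1 && ent[i] <= t + 1 && dth[i] >= t + 1)
            cnt[m.strat[s[i * m.T + t]]]++;
        }
        for (int st = 0; st < 3; ++st) out_N(keep, t * 3 + st) = cnt[st];
      }
      ++keep;
    }
  }

  return List::create(_["par"] = out_par, _["N"] = out_N,
                      _["entered"] = out_entered);
}
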