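#include <Rcpp.h>
using namespace Rcpp;

// Exact Gillespie simulation of a growing, self-restricting population.
//
// Cells are classified by their site configuration (n_U, n_H, n_D) with
// n_U + n_H + n_D = N_S; cells of equal configuration are exchangeable, so
// the simulation tracks counts per configuration ("type") and remains an
// exact realization of the agent-level process.
//
// Per-cell event channels (analytic-consistent mode):
//   U -> H   at m * n_U        (methylation)
//   H -> D   at m * n_H        (methylation)
//   D -> H   at lambda * n_D   (demethylation by replication)
//   H -> U   at lambda/2 * n_H (demethylation; one daughter copy is bare)
//   death    at r * n_U        (self-restriction, cell removed)
//   division at lambda         (daughter copies the mother's configuration)
//
// Mechanistic mode replaces the two continuous demethylation channels by
// coupling demethylation to division: each D site becomes H in both
// daughters; each H site stays H in one daughter and is U in the other
// (fair coin per site).
//
// Population control: when the population exceeds pop_cap it is thinned by
// uniform binomial subsampling to about pop_cap / 2 and the log dilution
// factor is accumulated so dilution-corrected log population remains an
// unbiased growth record.

struct TypeTable {
  int NS, ntypes;
  std::vector<int> u, h, d;
  std::vector<std::vector<int>> idx; // idx[u][h] -> type index

  explicit TypeTable(int NS_) : NS(NS_) {
    idx.assign(NS + 1, std::vector<int>(NS + 1, -1));
    int t = 0;
    for (int uu = 0; uu <= NS; ++uu)
      for (int hh = 0; hh + uu <= NS; ++hh) {
        u.push_back(uu);
        h.push_back(hh);
        d.push_back(NS - uu - hh);
        idx[uu][hh] = t++;
      }
    ntypes = t;
  }
};

// [[Rcpp::export]]
List sim_population_cpp(double r, double m, double lambda, int NS,
                        IntegerVector init_counts, double t_max,
                        int pop_cap, int n_grid, bool mechanistic) {
  TypeTable tt(NS);
  if (init_counts.size() != tt.ntypes)
    stop("init_counts has wrong length");

  std::vector<double> cnt(tt.ntypes);
  for (int j = 0; j < tt.ntypes; ++j) cnt[j] = init_counts[j];

  // per-cell channel rates by type
  std::vector<double> q_mU(tt.ntypes), q_mH(tt.ntypes), q_dD(tt.ntypes),
      q_dH(tt.ntypes), q_death(tt.ntypes), q_div(tt.ntypes), q_tot(tt.ntypes);
  for (int j = 0; j < tt.ntypes; ++j) {
    q_mU[j] = m * tt.u[j];
    q_mH[j] = m * tt.h[j];
    q_dD[j] = mechanistic ? 0.0 : lambda * tt.d[j];
    q_dH[j] = mechanistic ? 0.0 : 0.5 * lambda * tt.h[j];
    q_death[j] = r * tt.u[j];
    q_div[j] = lambda;
    q_tot[j] = q_mU[j] + q_mH[j] + q_dD[j] + q_dH[j] + q_death[j] + q_div[j];
  }

  double pop = 0, Utot = 0, Htot = 0, Dtot = 0, Rtot = 0;
  for (int j = 0; j < tt.ntypes; ++j) {
    pop += cnt[j];
    Utot += cnt[j] * tt.u[j];
    Htot += cnt[j] * tt.h[j];
    Dtot += cnt[j] * tt.d[j];
    Rtot += cnt[j] * q_tot[j];
  }

  NumericVector grid_t(n_grid), log_pop(n_grid);
  NumericVector deaths_iv(n_grid), celltime_iv(n_grid),
      Ut_iv(n_grid), Ht_iv(n_grid), Dt_iv(n_grid);
  for (int g = 0; g < n_grid; ++g) grid_t[g] = t_max * (g + 1) / n_grid;

  double t = 0, log_dilution = 0;
  long long deaths_cum = 0;
  int g = 0; // next grid boundary to fill
  double acc_ct = 0, acc_U = 0, acc_H = 0, acc_D = 0;
  long long acc_deaths = 0;
  bool extinct = false;

  RNGScope scope;

  auto advance_to = [&](double t_new) {
    // accumulate time integrals across any grid boundaries in (t, t_new]
    while (g < n_grid && grid_t[g] <= t_new) {
      double dt = grid_t[g] - t;
      acc_ct += pop * dt;
      acc_U += Utot * dt;
      acc_H += Htot * dt;
      acc_D += Dtot * dt;
      celltime_iv[g] = acc_ct;
      Ut_iv[g] = acc_U;
      Ht_iv[g] = acc_H;
      Dt_iv[g] = acc_D;
      deaths_iv[g] = (double)acc_deaths;
      log_pop[g] = (pop > 0 ? std::log(pop) : R_NegInf) + log_dilution;
      acc_ct = acc_U = acc_H = acc_D = 0;
      acc_deaths = 0;
      t = grid_t[g];
      ++g;
    }
    double dt = t_new - t;
    acc_ct += pop * dt;
    acc_U += Utot * dt;
    acc_H += Htot * dt;
    acc_D += Dtot * dt;
    t = t_new;
  };

  auto add_cell = [&](int j, double n) {
    cnt[j] += n;
    pop += n;
    Utot += n * tt.u[j];
    Htot += n * tt.h[j];
    Dtot += n * tt.d[j];
    Rtot += n * q_tot[j];
  };

  long long max_events = 400000000LL; // hard safety stop
  long long ev = 0;

  while (t < t_max && pop > 0 && ev < max_events) {
    ++ev;
    if (Rtot <= 0) { advance_to(t_max); break; }
    double dt = R::rexp(1.0) / Rtot;
    double t_new = t + dt;
    if (t_new >= t_max) { advance_to(t_max); break; }
    advance_to(t_new);

    // pick type proportional to cnt[j] * q_tot[j]
    double x = unif_rand() * Rtot;
    int j = -1;
    double csum = 0;
    for (int jj = 0; jj < tt.ntypes; ++jj) {
      csum += cnt[jj] * q_tot[jj];
      if (x <= csum) { j = jj; break; }
    }
    if (j < 0) j = tt.ntypes - 1;

    // pick channel within type
    double y = unif_rand() * q_tot[j];
    int uu = tt.u[j], hh = tt.h[j];
    if (y < q_mU[j]) {
      add_cell(j, -1); add_cell(tt.idx[uu - 1][hh + 1], 1);
    } else if (y < q_mU[j] + q_mH[j]) {
      add_cell(j, -1); add_cell(tt.idx[uu][hh - 1], 1);
    } else if (y < q_mU[j] + q_mH[j] + q_dD[j]) {
      add_cell(j, -1); add_cell(tt.idx[uu][hh + 1], 1);
    } else if (y < q_mU[j] + q_mH[j] + q_dD[j] + q_dH[j]) {
      add_cell(j, -1); add_cell(tt.idx[uu + 1][hh - 1], 1);
    } else if (y < q_mU[j] + q_mH[j] + q_dD[j] + q_dH[j] + q_death[j]) {
      add_cell(j, -1);
      ++deaths_cum;
      ++acc_deaths;
    } else {
      // division
      if (mechanistic) {
        int X = (int)R::rbinom(hh, 0.5);
        add_cell(j, -1);
        add_cell(tt.idx[uu + (hh - X)][X + tt.d[j]], 1);   // daughter 1
        add_cell(tt.idx[uu + X][(hh - X) + tt.d[j]], 1);   // daughter 2
      } else {
        add_cell(j, 1);
      }
    }

    if (pop > pop_cap) {
      double keep_p = 0.5 * pop_cap / pop;
      double pop_before = pop;
      for (int jj = 0; jj < tt.ntypes; ++jj) {
        if (cnt[jj] > 0) {
          double kept = R::rbinom(cnt[jj], keep_p);
          if (kept != cnt[jj]) add_cell(jj, kept - cnt[jj]);
        }
      }
      if (pop <= 0) { extinct = true; break; }
      log_dilution += std::log(pop_before / pop);
    }
  }
  if (pop <= 0) extinct = true;
  if (g < n_grid && !extinct) advance_to(t_max);
  // if extinct before the end, remaining grid cells stay at their defaults
  int filled = g;

  return List::create(
      _["time"] = grid_t, _["log_pop"] = log_pop,
      _["deaths"] = deaths_iv, _["celltime"] = celltime_iv,
      _["site_U_time"] = Ut_iv, _["site_H_time"] = Ht_iv,
      _["site_D_time"] = Dt_iv,
      _["filled"] = filled, _["extinct"] = extinct,
      _["final_time"] = t, _["final_pop"] = pop,
      _["total_deaths"] = (double)deaths_cum,
      _["log_dilution"] = log_dilution);
}
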