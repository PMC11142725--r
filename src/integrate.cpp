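#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Column layout (must match SPECIES in R):
// 0 I_a, 1 I_i, 2 C_a, 3 C_i, 4 R_a, 5 R_i, 6 rho_a, 7 rho_i,
// 8 P_C, 9 P_un, 10 S_C, 11 S_un

// Parameter vector layout (must match params_as_vector in R):
// 0 I_tot, 1 I_I, 2 delta_I, 3 alpha_I, 4 D_Ii,
// 5 C_tot, 6 I_C, 7 delta_C, 8 alpha_rho,
// 9 R_tot, 10 I_R, 11 delta_R, 12 beta_rho, 13 beta_PR,
// 14 rho_tot, 15 I_rho, 16 delta_rho, 17 beta_R,
// 18 n_hill,
// 19 D_act, 20 D_inact,
// 21 P_tot, 22 k_on_P, 23 k_off_P, 24 alpha_C, 25 beta_SP,
// 26 S_tot, 27 k_on_S, 28 k_off_S, 29 beta_PS,
// 30 D_PC, 31 D_SC, 32 D_Pun, 33 D_Sun

static inline double hilln(double v, double beta, int n) {
  if (v < 0.0) v = 0.0;
  double r = v / beta, p = 1.0;
  for (int k = 0; k < n; ++k) p *= r;
  return p;
}

static const char *SPECIES_NAMES[12] = {
  "I_a", "I_i", "C_a", "C_i", "R_a", "R_i",
  "rho_a", "rho_i", "P_C", "P_un", "S_C", "S_un"
};

// Explicit-Euler integration of the 12-field reaction-diffusion system with
// conservative no-flux boundaries.
//
// perturb_species: 0 none, 1 Cdc42, 2 Rac, 3 Rho (active/inactive column
// pairs 2/3, 4/5, 6/7). perturb_mode: 0 free dynamics, 1 ramp (after each
// step the targeted active field is rescaled so its node sum follows
// 100 + a (1 - exp(-rate (t - t_ramp_start))) percent of active_ref_sum, and
// the targeted species' rate law uses its current spatial-mean total),
// 2 freeze (targeted pair not updated at all).
//
// [[Rcpp::export]]
List rd_integrate(NumericMatrix state0, NumericVector par, double dx, double dt,
                  int n_steps, LogicalVector mask, int snap_stride, double t0,
                  int perturb_species, int perturb_mode, double a, double rate,
                  double t_ramp_start, double active_ref_sum) {
  const int n = state0.nrow();
  if (state0.ncol() != 12) stop("state must have 12 species columns");
  if (mask.size() != n) stop("mask length must equal the number of nodes");
  if (n < 3) stop("grid must have at least 3 nodes");

  const double I_tot = par[0], I_I = par[1], delta_I = par[2], alpha_I = par[3],
               D_Ii = par[4], C_tot = par[5], I_C = par[6], delta_C = par[7],
               alpha_rho = par[8], R_tot = par[9], I_R = par[10],
               delta_R = par[11], beta_rho = par[12], beta_PR = par[13],
               rho_tot = par[14], I_rho = par[15], delta_rho = par[16],
               beta_R = par[17];
  const int nh = (int)par[18];
  const double D_act = par[19], D_inact = par[20], P_tot = par[21],
               k_on_P = par[22], k_off_P = par[23], alpha_C = par[24],
               beta_SP = par[25], S_tot = par[26], k_on_S = par[27],
               k_off_S = par[28], beta_PS = par[29], D_PC = par[30],
               D_SC = par[31], D_Pun = par[32], D_Sun = par[33];

  const double D[12] = {0.0, D_Ii, D_act, D_inact, D_act, D_inact,
                        D_act, D_inact, D_PC, D_Pun, D_SC, D_Sun};
  const double idx2 = 1.0 / (dx * dx);

  // working copy
  std::vector< std::vector<double> > f(12, std::vector<double>(n));
  for (int s = 0; s < 12; ++s)
    for (int i = 0; i < n; ++i) f[s][i] = state0(i, s);

  std::vector< std::vector<double> > fn(12, std::vector<double>(n));
  std::vector<double> lap(n);

  const int pa = (perturb_species == 1) ? 2 : (perturb_species == 2) ? 4 :
                 (perturb_species == 3) ? 6 : -1;  // active column of target
  const int pi_ = pa + 1;

  double max_clip = 0.0;
  List snaps;
  std::vector<double> snap_times;

  for (int step = 0; step < n_steps; ++step) {
    const double t_new = t0 + (step + 1) * dt;

    // During the ramp the targeted species' conservation is intentionally
    // broken: its rate law uses the current (spatial-mean) total instead of
    // the fixed parameter. Equals the parameter exactly while no mass has
    // been added or removed.
    double tot_eff = 0.0;
    if (perturb_mode == 1 && pa >= 0) {
      for (int i = 0; i < n; ++i) tot_eff += f[pa][i] + f[pi_][i];
      tot_eff /= n;
    }

    // reaction + diffusion update of every field
    for (int s = 0; s < 12; ++s) {
      if (perturb_mode == 2 && (s == pa || s == pi_)) {
        for (int i = 0; i < n; ++i) fn[s][i] = f[s][i];  // frozen
        continue;
      }
      // Laplacian with zero-flux closure at both ends (conservative form)
      if (D[s] > 0.0) {
        lap[0] = (f[s][1] - f[s][0]) * idx2;
        lap[n - 1] = (f[s][n - 2] - f[s][n - 1]) * idx2;
        for (int i = 1; i < n - 1; ++i)
          lap[i] = (f[s][i - 1] - 2.0 * f[s][i] + f[s][i + 1]) * idx2;
      } else {
        std::fill(lap.begin(), lap.end(), 0.0);
      }

      for (int i = 0; i < n; ++i) {
        double react;
        switch (s) {
        case 0: case 1: {  // integrins
          double act = (mask[i] ? I_I * f[1][i] / I_tot : 0.0) -
                       delta_I * f[0][i];
          react = (s == 0) ? act : -act;
          break;
        }
        case 2: case 3: {  // Cdc42
          double ct = (perturb_mode == 1 && pa == 2) ? tot_eff : C_tot;
          double act = (alpha_rho * f[6][i] + I_C) * (f[3][i] / ct) -
                       delta_C * f[2][i];
          react = (s == 2) ? act : -act;
          break;
        }
        case 4: case 5: {  // Rac
          double rt = (perturb_mode == 1 && pa == 4) ? tot_eff : R_tot;
          double inhib = 1.0 + hilln(f[6][i], beta_rho, nh) +
                         hilln(f[8][i], beta_PR, nh);
          double act = (alpha_I * f[0][i] + I_R) / inhib * (f[5][i] / rt) -
                       delta_R * f[4][i];
          react = (s == 4) ? act : -act;
          break;
        }
        case 6: case 7: {  // Rho
          double rt = (perturb_mode == 1 && pa == 6) ? tot_eff : rho_tot;
          double act = I_rho / (1.0 + hilln(f[4][i], beta_R, nh)) *
                       (f[7][i] / rt) - delta_rho * f[6][i];
          react = (s == 6) ? act : -act;
          break;
        }
        case 8: case 9: {  // Par complex
          double act = (alpha_C * f[2][i] + k_on_P) /
                       (1.0 + hilln(f[10][i], beta_SP, nh)) *
                       (f[9][i] / P_tot) - k_off_P * f[8][i];
          react = (s == 8) ? act : -act;
          break;
        }
        default: {  // 10, 11: Scribble complex
          double act = k_on_S / (1.0 + hilln(f[8][i], beta_PS, nh)) *
                       (f[11][i] / S_tot) - k_off_S * f[10][i];
          react = (s == 10) ? act : -act;
          break;
        }
        }
        double v = f[s][i] + dt * (react + D[s] * lap[i]);
        if (!std::isfinite(v)) {
          stop("integration failure: non-finite %s at node %d, t = %.4f s",
               SPECIES_NAMES[s], i + 1, t_new);
        }
        if (v < 0.0) {
          if (-v > max_clip) max_clip = -v;
          v = 0.0;
        }
        fn[s][i] = v;
      }
    }
    for (int s = 0; s < 12; ++s) f[s].swap(fn[s]);

    // degradation/upregulation ramp: pin the targeted active node-sum to the
    // prescribed temporal profile (shape preserved)
    if (perturb_mode == 1 && pa >= 0) {
      double pct = 100.0 + a * (1.0 - std::exp(-rate * (t_new - t_ramp_start)));
      double target = pct / 100.0 * active_ref_sum;
      double cur = 0.0;
      for (int i = 0; i < n; ++i) cur += f[pa][i];
      if (cur > 0.0 && target >= 0.0) {
        double fac = target / cur;
        for (int i = 0; i < n; ++i) f[pa][i] *= fac;
      }
    }

    if (snap_stride > 0 && ((step + 1) % snap_stride == 0)) {
      NumericMatrix snap(n, 12);
      for (int s = 0; s < 12; ++s)
        for (int i = 0; i < n; ++i) snap(i, s) = f[s][i];
      snaps.push_back(snap);
      snap_times.push_back(t_new);
    }
  }

  NumericMatrix final_state(n, 12);
  for (int s = 0; s < 12; ++s)
    for (int i = 0; i < n; ++i) final_state(i, s) = f[s][i];

  return List::create(_["final_state"] = final_state,
                      _["snapshots"] = snaps,
                      _["snap_times"] = NumericVector(snap_times.begin(),
                                                      snap_times.end()),
                      _["max_clip"] = max_clip);
}
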