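#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Reservoir indices (order shared with the R layer's RESERVOIRS constant)
enum { ATM = 0, OCEAN = 1, CC = 2, OC = 3, MS = 4, UM = 5, LM = 6, CORE = 7 };

// Fast fixed-step integration of the phosphorus reservoir network.
// The flux arithmetic mirrors the reference R implementation in
// R/fluxes.R (flux_rates) and R/simulate.R (step_state) operation for
// operation; a test asserts their agreement. Change both together.
//
// `pars` is the flat list built by R's .pack_sim_pars():
// scalars of the model parameters plus structure constants and mode flags.
// [[Rcpp::export]]
List simulate_cpp(NumericVector init, List pars, double t0, int n_steps,
                  int stride, double init_cum_et) {
  // parameters
  const double dt = pars["dt"];
  const double t_end = pars["t_end"];
  const double et_F0 = pars["et_F0"], et_F1 = pars["et_F1"], et_tau = pars["et_tau"];
  const double alpha = pars["alpha"], beta = pars["beta"];
  const double aeolian_rate = pars["aeolian_p_rate"];
  const int aeolian_beta = pars["aeolian_beta"]; // 0: rate mode, 1: beta mode
  const double atm_cap = pars["atm_cap"];
  const double ocean_sat_mass = pars["ocean_sat_mass"];
  const double rainout_land_frac = pars["rainout_land_frac"];
  const double riverine_ms_frac = pars["riverine_ms_frac"];
  const double epsilon = pars["epsilon"];
  const double tau_sub = pars["tau_sub"];
  const double mix_F0 = pars["mix_F0"], mix_F1 = pars["mix_F1"], mix_tau = pars["mix_tau"];
  const double V_arc = pars["V_arc"], V_mor = pars["V_mor"], V_hot = pars["V_hotspot"];
  const double E_arc = pars["E_arc"], E_mor = pars["E_mor"], E_hot = pars["E_hotspot"];
  const double f_volc = pars["f_volc"], tau_volc = pars["tau_volc"];
  const double H0 = pars["H0"], tau_hydro = pars["tau_hydro"];
  const double seaspray_rate = pars["seaspray_rate"];
  const int growth_exp = pars["growth_exp"]; // 0: piecewise linear, 1: exponential
  const double A0_frac = pars["A0_frac"], t_knee = pars["t_knee"], frac_knee = pars["frac_knee"];
  const int cc_rock_growth = pars["cc_rock_growth"];
  // structure
  const double area_earth = pars["area_earth"];
  const double A_modern = pars["area_land_modern"];
  const double rho_cc = pars["rho_cc"], rho_mantle = pars["rho_mantle"];
  const double ocean_volume = pars["ocean_volume"];
  const double rock_cc = pars["rock_cc"], rock_um = pars["rock_um"], rock_lm = pars["rock_lm"];
  const double conc_cc_modern = pars["conc_cc_modern"];

  // exponential growth-curve rescaling constant
  const double raw_end = 1.0 - (1.0 - A0_frac) * std::exp(-t_end / t_knee);

  double M[8];
  for (int r = 0; r < 8; ++r) M[r] = init[r];
  double cum_et = init_cum_et;

  const int n_snap = n_steps / stride + 1 + (n_steps % stride != 0 ? 1 : 0);
  NumericVector times(n_snap), cum_et_out(n_snap);
  NumericMatrix masses(n_snap, 8);
  int snap = 0;
  auto record = [&](double t) {
    times[snap] = t;
    cum_et_out[snap] = cum_et;
    for (int r = 0; r < 8; ++r) {
      if (!std::isfinite(M[r]) || M[r] < 0)
        stop("simulate: non-finite or negative mass in reservoir %d at t = %g yr", r, t);
      masses(snap, r) = M[r];
    }
    ++snap;
  };
  record(t0);

  for (int i = 0; i < n_steps; ++i) {
    const double t = t0 + i * dt;

    // --- time-dependent drivers, evaluated once per step
    double frac;
    if (growth_exp) {
      const double raw = 1.0 - (1.0 - A0_frac) * std::exp(-t / t_knee);
      frac = A0_frac + (1.0 - A0_frac) * (raw - A0_frac) / (raw_end - A0_frac);
    } else {
      frac = (t <= t_knee)
        ? A0_frac + (frac_knee - A0_frac) * t / t_knee
        : frac_knee + (1.0 - frac_knee) * (t - t_knee) / (t_end - t_knee);
    }
    const double area = A_modern * frac;            // km^2
    const double f_land = area / area_earth;
    const double F_et = et_F0 + (et_F1 - et_F0) * std::exp(-t / et_tau);
    const double s_volc = 1.0 + (f_volc - 1.0) * std::exp(-t / tau_volc);
    const double r_mix = mix_F0 + (mix_F1 - mix_F0) * std::exp(-t / mix_tau);

    // --- continuous fluxes (kg P / yr)
    const double et_land = F_et * f_land;
    const double et_ocean = F_et - et_land;

    const double rock_cc_t = cc_rock_growth ? rock_cc * frac : rock_cc;
    const double conc_cc = rock_cc_t > 0 ? M[CC] / rock_cc_t : 0.0;
    const double ero = alpha * (area * 1e6) * rho_cc * conc_cc;
    const double aeol = aeolian_beta
      ? beta * (area * 1e6) * rho_cc * conc_cc
      : aeolian_rate * area * conc_cc / conc_cc_modern;
    const double spray = M[OCEAN] * seaspray_rate / ocean_volume;
    const double accretion = epsilon * M[MS] / tau_sub;
    const double sub_ms = (1.0 - epsilon) * M[MS] / tau_sub;
    const double sub_oc = M[OC] / tau_sub;
    const double conc_um = M[UM] / rock_um;
    const double conc_lm = M[LM] / rock_lm;
    const double arc = s_volc * V_arc * 1e9 * rho_mantle * conc_um * E_arc;
    const double mor = s_volc * V_mor * 1e9 * rho_mantle * conc_um * E_mor;
    const double hotspot = s_volc * V_hot * 1e9 * rho_mantle * conc_lm * E_hot;
    const double hot_cc = hotspot * f_land;
    const double hot_oc = hotspot - hot_cc;
    double hydro = H0 * std::exp(-t / tau_hydro);
    if (hydro > M[OCEAN] / dt) hydro = M[OCEAN] / dt;
    const double mix_up = r_mix * M[LM];
    const double mix_down = r_mix * rock_lm * conc_um;

    // --- proportional outflow limiter: no reservoir may be overdrawn
    auto clamp = [&](double mass, double out) {
      return (out > 0.0 && out * dt > mass) ? mass / (out * dt) : 1.0;
    };
    const double c_cc = clamp(M[CC], ero + aeol);
    const double c_ocean = clamp(M[OCEAN], spray + hydro);
    const double c_ms = clamp(M[MS], accretion + sub_ms);
    const double c_oc = clamp(M[OC], sub_oc);
    const double c_um = clamp(M[UM], arc + mor + mix_down);
    const double c_lm = clamp(M[LM], hotspot + mix_up);

    const double ero_c = ero * c_cc, aeol_c = aeol * c_cc;
    const double spray_c = spray * c_ocean, hydro_c = hydro * c_ocean;
    const double accr_c = accretion * c_ms, sub_ms_c = sub_ms * c_ms;
    const double sub_oc_c = sub_oc * c_oc;
    const double arc_c = arc * c_um, mor_c = mor * c_um, mixd_c = mix_down * c_um;
    const double hot_cc_c = hot_cc * c_lm, hot_oc_c = hot_oc * c_lm, mixu_c = mix_up * c_lm;

    // --- explicit Euler update
    M[ATM]   += dt * (aeol_c + spray_c);
    M[OCEAN] += dt * (et_ocean + ero_c - spray_c - hydro_c);
    M[CC]    += dt * (et_land + accr_c + arc_c + hot_cc_c - ero_c - aeol_c);
    M[OC]    += dt * (mor_c + hot_oc_c + hydro_c - sub_oc_c);
    M[MS]    += dt * (-accr_c - sub_ms_c);
    M[UM]    += dt * (sub_ms_c + sub_oc_c + mixu_c - arc_c - mor_c - mixd_c);
    M[LM]    += dt * (mixd_c - mixu_c - hot_cc_c - hot_oc_c);
    cum_et += dt * F_et;

    // round-off guard: the limiter can leave -1 ulp behind
    for (int r = 0; r < 8; ++r) {
      if (M[r] < 0) {
        if (M[r] > -1e-3) M[r] = 0.0;
        else stop("simulate: reservoir %d driven negative (%g kg) at t = %g yr", r, M[r], t);
      }
    }

    // --- saturation switchboard: atmosphere first (its rain-out feeds the
    // ocean), then the ocean
    if (M[ATM] > atm_cap) {
      const double excess = M[ATM] - atm_cap;
      M[ATM] = atm_cap;
      M[CC] += excess * rainout_land_frac;
      M[OCEAN] += excess * (1.0 - rainout_land_frac);
    }
    if (M[OCEAN] > ocean_sat_mass) {
      const double excess = M[OCEAN] - ocean_sat_mass;
      M[OCEAN] = ocean_sat_mass;
      M[MS] += excess * riverine_ms_frac;
      M[OC] += excess * (1.0 - riverine_ms_frac);
    }

    if ((i + 1) % stride == 0 || i + 1 == n_steps) record(t0 + (i + 1) * dt);
  }

  return List::create(
    _["times"] = times, _["masses"] = masses, _["cumulative_et"] = cum_et_out
  );
}
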