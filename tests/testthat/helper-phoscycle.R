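# Shared fixtures, built in code.

# Main configuration with a shortened run (for tests that only need a few
# thousand steps of dynamics).
quick_params <- function(n_steps = 2000, dt = 5000, ...) {
  p_params(n_steps = n_steps, dt = dt, ...)
}

# A configuration in which every flux vanishes: the integrator must be the
# identity on any admissible state.
zero_flux_params <- function(n_steps = 100) {
  p_params(
    et = list(F0 = 0, F1 = 0, tau = 1.5e8),
    alpha = 0, beta = 0, aeolian_p_rate = 0,
    seaspray_rate = 0,
    tau_sub = Inf,
    mixing = list(F0 = 0, F1 = 0, tau = 1.5e9),
    volcanism = list(
      V_arc = 0, V_mor = 0, V_hotspot = 0,
      E_arc = 5, E_mor = 4.6, E_hotspot = 4.6, f = 1, tau = 5e8
    ),
    hydrothermal = list(H0 = 0, tau = 1.5e9),
    n_steps = n_steps
  )
}

# A mid-run state with every reservoir populated at plausible magnitudes.
generic_state <- function(t = 2e9) {
  planet_state(
    c(
      ATM = 2.8e7, OCEAN = 9.0e13, CC = 5e18, OC = 6e18, MS = 2e18,
      UM = 2.4e20, LM = 6.2e20, CORE = 0
    ),
    t = t
  )
}
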