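# Flatten params + structure into the scalar list consumed by the C++ loop.
pack_sim_pars <- function(params, structure) {
  list(
    dt = params$dt,
    t_end = run_span(params),
    et_F0 = params$et$F0, et_F1 = params$et$F1, et_tau = params$et$tau,
    alpha = params$alpha, beta = params$beta,
    aeolian_p_rate = params$aeolian_p_rate,
    aeolian_beta = as.integer(identical(params$aeolian_mode, "beta")),
    atm_cap = params$atm_cap,
    ocean_sat_mass = ocean_saturation_mass(params, structure),
    rainout_land_frac = params$rainout_land_frac,
    riverine_ms_frac = params$riverine_ms_frac,
    epsilon = params$epsilon, tau_sub = params$tau_sub,
    mix_F0 = params$mixing$F0, mix_F1 = params$mixing$F1,
    mix_tau = params$mixing$tau,
    V_arc = params$volcanism$V_arc, V_mor = params$volcanism$V_mor,
    V_hotspot = params$volcanism$V_hotspot,
    E_arc = params$volcanism$E_arc, E_mor = params$volcanism$E_mor,
    E_hotspot = params$volcanism$E_hotspot,
    f_volc = params$volcanism$f, tau_volc = params$volcanism$tau,
    H0 = params$hydrothermal$H0, tau_hydro = params$hydrothermal$tau,
    seaspray_rate = params$seaspray_rate,
    growth_exp = as.integer(identical(params$growth$model, "exponential")),
    A0_frac = params$growth$A0_frac, t_knee = params$growth$t_knee,
    frac_knee = params$growth$frac_knee,
    cc_rock_growth = as.integer(isTRUE(params$cc_rock_growth)),
    area_earth = structure$area_earth,
    area_land_modern = structure$area_land_modern,
    rho_cc = structure$rho_cc, rho_mantle = structure$rho_mantle,
    ocean_volume = structure$ocean_volume,
    rock_cc = structure$rock_masses[["CC"]],
    rock_um = structure$rock_masses[["UM"]],
    rock_lm = structure$rock_masses[["LM"]],
    conc_cc_modern = structure$modern_p[["CC"]] / structure$rock_masses[["CC"]]
  )
}

#' Advance the planet state by one Euler step (reference implementation)
#'
#' Forward-Euler update of every reservoir from the instantaneous fluxes,
#' followed by the saturation "switchboard": atmospheric P above `atm_cap`
#' rains out (split `rainout_land_frac` to CC, remainder to the ocean), then
#' oceanic P above the saturation mass is transferred (split
#' `riverine_ms_frac` to MS, remainder to OC). Outflows of any reservoir
#' that would be overdrawn within the step are scaled down proportionally,
#' preserving flux ratios and non-negativity.
#'
#' This is the reference R implementation; [run_simulation()] uses a compiled
#' loop with the identical arithmetic (the two are cross-checked by the test
#' suite).
#'
#' @param state A [planet_state()].
#' @param params A [p_params()] object.
#' @param structure A [p_structure()] object.
#' @param dt Timestep in years (defaults to `params$dt`).
#' @return The updated `p_state`, with the realized per-channel rates
#'   (including the overflow channels, as kg yr^-1 equivalents) attached as
#'   attribute `"fluxes"`.
#' @export
step_state <- function(state, params, structure, dt = params$dt) {
  stopifnot(dt > 0)
  m <- state$masses
  t <- state$t
  f <- flux_rates(t, m, params, structure, dt = dt)

  clamp <- function(mass, out) if (out > 0 && out * dt > mass) mass / (out * dt) else 1
  c_cc <- clamp(m[["CC"]], f[["surface_erosion"]] + f[["aeolian"]])
  c_ocean <- clamp(m[["OCEAN"]], f[["seaspray"]] + f[["hydrothermal"]])
  c_ms <- clamp(m[["MS"]], f[["accretion"]] + f[["subduction_ms"]])
  c_oc <- clamp(m[["OC"]], f[["subduction_oc"]])
  c_um <- clamp(m[["UM"]], f[["arc"]] + f[["mor"]] + f[["mix_down"]])
  c_lm <- clamp(m[["LM"]], f[["hotspot_cc"]] + f[["hotspot_oc"]] + f[["mix_up"]])
  fc <- f * c(
    et_land = 1, et_ocean = 1,
    surface_erosion = c_cc, aeolian = c_cc,
    seaspray = c_ocean,
    accretion = c_ms, subduction_ms = c_ms, subduction_oc = c_oc,
    arc = c_um, mor = c_um, hotspot_cc = c_lm, hotspot_oc = c_lm,
    mix_up = c_lm, mix_down = c_um, hydrothermal = c_ocean
  )[names(f)]

  m[["ATM"]] <- m[["ATM"]] + dt * (fc[["aeolian"]] + fc[["seaspray"]])
  m[["OCEAN"]] <- m[["OCEAN"]] + dt * (fc[["et_ocean"]] + fc[["surface_erosion"]] -
    fc[["seaspray"]] - fc[["hydrothermal"]])
  m[["CC"]] <- m[["CC"]] + dt * (fc[["et_land"]] + fc[["accretion"]] + fc[["arc"]] +
    fc[["hotspot_cc"]] - fc[["surface_erosion"]] - fc[["aeolian"]])
  m[["OC"]] <- m[["OC"]] + dt * (fc[["mor"]] + fc[["hotspot_oc"]] +
    fc[["hydrothermal"]] - fc[["subduction_oc"]])
  m[["MS"]] <- m[["MS"]] - dt * (fc[["accretion"]] + fc[["subduction_ms"]])
  m[["UM"]] <- m[["UM"]] + dt * (fc[["subduction_ms"]] + fc[["subduction_oc"]] +
    fc[["mix_up"]] - fc[["arc"]] - fc[["mor"]] - fc[["mix_down"]])
  m[["LM"]] <- m[["LM"]] + dt * (fc[["mix_down"]] - fc[["mix_up"]] -
    fc[["hotspot_cc"]] - fc[["hotspot_oc"]])

  neg <- m < 0
  if (any(neg)) {
    if (any(m[neg] < -1e-3)) {
      stop("step_state: reservoir driven negative at t = ", t, call. = FALSE)
    }
    m[neg] <- 0
  }

  rainout_land <- rainout_ocean <- overflow_ms <- overflow_oc <- 0
  if (m[["ATM"]] > params$atm_cap) {
    excess <- m[["ATM"]] - params$atm_cap
    m[["ATM"]] <- params$atm_cap
    rainout_land <- excess * params$rainout_land_frac / dt
    rainout_ocean <- excess * (1 - params$rainout_land_frac) / dt
    m[["CC"]] <- m[["CC"]] + excess * params$rainout_land_frac
    m[["OCEAN"]] <- m[["OCEAN"]] + excess * (1 - params$rainout_land_frac)
  }
  sat <- ocean_saturation_mass(params, structure)
  if (m[["OCEAN"]] > sat) {
    excess <- m[["OCEAN"]] - sat
    m[["OCEAN"]] <- sat
    overflow_ms <- excess * params$riverine_ms_frac / dt
    overflow_oc <- excess * (1 - params$riverine_ms_frac) / dt
    m[["MS"]] <- m[["MS"]] + excess * params$riverine_ms_frac
    m[["OC"]] <- m[["OC"]] + excess * (1 - params$riverine_ms_frac)
  }
  if (any(!is.finite(m))) {
    stop("step_state: non-finite mass at t = ", t, call. = FALSE)
  }

  out <- planet_state(m,
    t = t + dt,
    cumulative_et = state$cumulative_et + dt * et_flux(t, params)
  )
  attr(out, "fluxes") <- c(fc,
    rainout_land = rainout_land, rainout_ocean = rainout_ocean,
    overflow_ms = overflow_ms, overflow_oc = overflow_oc
  )
  out
}

#' Run the box model over the full time span
#'
#' Integrates the reservoir network with `n_steps` explicit Euler steps of
#' `dt` years (9e5 steps of 5,000 yr in the main configuration, 4.5 Ga
#' total), enforcing the atmosphere and ocean saturation caps after every
#' step, and returns a decimated trajectory of reservoir P masses together
#' with a per-snapshot conservation audit.
#'
#' @param initial A [planet_state()] (typically from [seed_initial()]).
#' @param params A [p_params()] object.
#' @param structure A [p_structure()] object.
#' @param stride Snapshot decimation: store every `stride`-th step (the
#'   initial and final states are always stored). Default 100 (0.5 Ma in the
#'   main configuration).
#' @return A `p_trajectory`: a tibble with columns `time_yr`, `atm_kg`,
#'   `ocean_kg`, `cc_kg`, `oc_kg`, `ms_kg`, `um_kg`, `lm_kg`, `cum_et_kg`
#'   and `residual` (the relative mass-closure error), carrying the run
#'   configuration as attributes.
#' @examples
#' \donttest{
#' traj <- run_simulation(seed_initial(seed_spec(rng_seed = 1)), p_params(), p_structure())
#' conservation_residual(traj)
#' }
#' @export
run_simulation <- function(initial, params, structure = p_structure(),
                           stride = 100) {
  validate_params(params, structure)
  sat <- ocean_saturation_mass(params, structure)
  res <- simulate_cpp(
    unname(initial$masses[RESERVOIRS]),
    pack_sim_pars(params, structure),
    initial$t, as.integer(params$n_steps), as.integer(stride),
    initial$cumulative_et
  )
  colnames(res$masses) <- RESERVOIRS
  seed_total <- sum(initial$masses[setdiff(RESERVOIRS, "CORE")]) -
    initial$cumulative_et
  noncore <- rowSums(res$masses[, setdiff(RESERVOIRS, "CORE"), drop = FALSE])
  residual <- abs(noncore - seed_total - res$cumulative_et) / seed_total

  out <- tibble::tibble(
    time_yr = res$times,
    atm_kg = res$masses[, "ATM"],
    ocean_kg = res$masses[, "OCEAN"],
    cc_kg = res$masses[, "CC"],
    oc_kg = res$masses[, "OC"],
    ms_kg = res$masses[, "MS"],
    um_kg = res$masses[, "UM"],
    lm_kg = res$masses[, "LM"],
    cum_et_kg = res$cumulative_et,
    residual = residual
  )
  attr(out, "params") <- params
  attr(out, "structure") <- structure
  attr(out, "seed_total") <- seed_total
  attr(out, "core_kg") <- unname(initial$masses[["CORE"]])
  class(out) <- c("p_trajectory", class(out))
  out
}

#' Final planet state of a trajectory
#' @param traj A `p_trajectory` from [run_simulation()].
#' @return A [planet_state()].
#' @export
final_state <- function(traj) {
  n <- nrow(traj)
  planet_state(
    c(
      ATM = traj$atm_kg[n], OCEAN = traj$ocean_kg[n], CC = traj$cc_kg[n],
      OC = traj$oc_kg[n], MS = traj$ms_kg[n], UM = traj$um_kg[n],
      LM = traj$lm_kg[n], CORE = attr(traj, "core_kg") %||% 0
    ),
    t = traj$time_yr[n], cumulative_et = traj$cum_et_kg[n]
  )
}

#' Maximum conservation residual of a trajectory
#'
#' The mass-closure audit: at every stored snapshot the non-core reservoir
#' total must equal the initial BSE seed plus the cumulative extraterrestrial
#' input. Returns the maximum relative deviation over the trajectory
#' (<= 1e-6 on any well-formed run).
#'
#' @param traj A `p_trajectory` from [run_simulation()].
#' @return Dimensionless maximum relative closure error.
#' @export
conservation_residual <- function(traj) {
  if (nrow(traj) == 0) stop("conservation_residual: empty trajectory", call. = FALSE)
  seed_total <- attr(traj, "seed_total")
  if (is.null(seed_total)) {
    return(max(traj$residual))
  }
  # recompute from the stored masses so tampered snapshots are caught
  noncore <- traj$atm_kg + traj$ocean_kg + traj$cc_kg + traj$oc_kg +
    traj$ms_kg + traj$um_kg + traj$lm_kg
  max(abs(noncore - seed_total - traj$cum_et_kg) / seed_total)
}

#' Write / read a trajectory as CSV
#'
#' One row per stored snapshot with the header
#' `time_yr,atm_kg,ocean_kg,cc_kg,oc_kg,ms_kg,um_kg,lm_kg,cum_et_kg`.
#'
#' @param traj A `p_trajectory`.
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a tibble.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c(
    "time_yr", "atm_kg", "ocean_kg", "cc_kg", "oc_kg", "ms_kg",
    "um_kg", "lm_kg", "cum_et_kg"
  )
  utils::write.csv(as.data.frame(traj)[, cols], path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @export
print.p_trajectory <- function(x, ...) {
  cat(sprintf(
    "<p_trajectory> %d snapshots over %.3g Ga; max conservation residual %.2e\n",
    nrow(x), (x$time_yr[nrow(x)] - x$time_yr[1]) / 1e9, max(x$residual)
  ))
  NextMethod()
}
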