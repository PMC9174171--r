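#' Flux channels of the reservoir network
#'
#' Directed edges of the box model. The four overflow channels
#' (`rainout_land`, `rainout_ocean`, `overflow_ms`, `overflow_oc`) are
#' resolved inside the integration step when a capped reservoir exceeds its
#' saturation value; the remainder are continuous functions of the state.
#'
#' @format A data frame with columns `channel`, `from`, `to`.
#' @export
FLUX_EDGES <- data.frame(
  channel = c(
    "et_land", "et_ocean", "surface_erosion", "aeolian", "seaspray",
    "rainout_land", "rainout_ocean", "overflow_ms", "overflow_oc",
    "accretion", "subduction_ms", "subduction_oc",
    "arc", "mor", "hotspot_cc", "hotspot_oc",
    "mix_up", "mix_down", "hydrothermal"
  ),
  from = c(
    "ET", "ET", "CC", "CC", "OCEAN",
    "ATM", "ATM", "OCEAN", "OCEAN",
    "MS", "MS", "OC",
    "UM", "UM", "LM", "LM",
    "LM", "UM", "OCEAN"
  ),
  to = c(
    "CC", "OCEAN", "OCEAN", "ATM", "ATM",
    "CC", "OCEAN", "MS", "OC",
    "CC", "UM", "UM",
    "CC", "OC", "CC", "OC",
    "UM", "LM", "OC"
  ),
  stringsAsFactors = FALSE
)

# CC P concentration entering the erosion/aeolian laws. By default referenced
# to the constant modern CC rock mass (concentration then grows with CC P
# content, and erosional flux grows with emergent area); optionally to the
# growth-scaled rock mass.
cc_concentration <- function(t, m_cc, params, structure) {
  rock <- if (isTRUE(params$cc_rock_growth)) {
    cc_rock_mass(t, params, structure)
  } else {
    structure$rock_masses[["CC"]]
  }
  if (rock <= 0) return(0)
  m_cc / rock
}

# Canonical computation of the 15 continuous flux channels (kg P / yr) from
# time and masses. The C++ integrator mirrors this arithmetic operation for
# operation; change both together.
flux_rates <- function(t, masses, params, structure, dt = params$dt) {
  area <- emergent_land_area(t, params, structure)
  f_land <- area / structure$area_earth
  F_et <- et_flux(t, params)
  et_land <- F_et * f_land
  et_ocean <- F_et - et_land

  conc_cc <- cc_concentration(t, masses[["CC"]], params, structure)
  conc_cc_modern <- structure$modern_p[["CC"]] / structure$rock_masses[["CC"]]
  surface_erosion <- params$alpha * (area * 1e6) * structure$rho_cc * conc_cc
  aeolian <- if (identical(params$aeolian_mode, "rate")) {
    params$aeolian_p_rate * area * conc_cc / conc_cc_modern
  } else {
    params$beta * (area * 1e6) * structure$rho_cc * conc_cc
  }

  seaspray <- masses[["OCEAN"]] * params$seaspray_rate / structure$ocean_volume

  accretion <- params$epsilon * masses[["MS"]] / params$tau_sub
  subduction_ms <- (1 - params$epsilon) * masses[["MS"]] / params$tau_sub
  subduction_oc <- masses[["OC"]] / params$tau_sub

  s <- volcanic_scale(t, params)
  v <- params$volcanism
  conc_um <- masses[["UM"]] / structure$rock_masses[["UM"]]
  conc_lm <- masses[["LM"]] / structure$rock_masses[["LM"]]
  arc <- s * v$V_arc * 1e9 * structure$rho_mantle * conc_um * v$E_arc
  mor <- s * v$V_mor * 1e9 * structure$rho_mantle * conc_um * v$E_mor
  hotspot <- s * v$V_hotspot * 1e9 * structure$rho_mantle * conc_lm * v$E_hotspot
  hotspot_cc <- hotspot * f_land
  hotspot_oc <- hotspot - hotspot_cc

  hydrothermal <- min(
    params$hydrothermal$H0 * exp(-t / params$hydrothermal$tau),
    masses[["OCEAN"]] / dt
  )

  r <- mixing_rate(t, params)
  # Balanced rock exchange between the mantle layers: a mass r(t) * rock_LM
  # of rock crosses the boundary each way per year, carrying P at the source
  # concentration. Equal concentrations (not equal P masses) give zero net
  # exchange, so the steady state preserves the rock-mass ratio.
  mix_up <- r * masses[["LM"]]
  mix_down <- r * structure$rock_masses[["LM"]] * conc_um

  c(
    et_land = et_land, et_ocean = et_ocean,
    surface_erosion = surface_erosion, aeolian = aeolian,
    seaspray = seaspray,
    accretion = accretion, subduction_ms = subduction_ms,
    subduction_oc = subduction_oc,
    arc = arc, mor = mor, hotspot_cc = hotspot_cc, hotspot_oc = hotspot_oc,
    mix_up = mix_up, mix_down = mix_down, hydrothermal = hydrothermal
  )
}

#' Riverine (surface-erosion) phosphorus flux, CC to ocean pool
#'
#' Physical-erosion law `alpha * land_area * rho_cc * concentration`, where
#' the concentration is the CC P mass over the CC rock mass. At the modern
#' state this evaluates to ~7.7e10 kg P yr^-1.
#'
#' @param state A [planet_state()].
#' @param params A [p_params()] object.
#' @param structure A [p_structure()] object.
#' @return Flux, kg P yr^-1.
#' @export
surface_erosion_flux <- function(state, params, structure) {
  flux_rates(state$t, state$masses, params, structure)[["surface_erosion"]]
}

#' Aeolian phosphorus flux, CC to atmosphere
#'
#' Wind-driven dust export of crustal P. In the default `"rate"` mode the
#' modern calibration of 27 kg P km^-2 yr^-1 is scaled by land area and by
#' the CC P concentration relative to modern (4.0e9 kg yr^-1 at the modern
#' state); in `"beta"` mode the wind rock-erosion rate `beta` is used.
#'
#' @inheritParams surface_erosion_flux
#' @return Flux, kg P yr^-1.
#' @export
aeolian_flux <- function(state, params, structure) {
  flux_rates(state$t, state$masses, params, structure)[["aeolian"]]
}

#' Sea-spray phosphorus flux, ocean to atmosphere
#'
#' Product of the dissolved P molarity and a constant mobilized-seawater
#' volume, calibrated so a saturated modern ocean (2.2 uM) ejects
#' 3.3e8 kg P yr^-1.
#'
#' @inheritParams surface_erosion_flux
#' @return Flux, kg P yr^-1.
#' @export
seaspray_flux <- function(state, params, structure) {
  flux_rates(state$t, state$masses, params, structure)[["seaspray"]]
}

#' Subduction and accretion fluxes
#'
#' First-order turnover of the marine-sediment and oceanic-crust P
#' inventories over the subduction time `tau_sub`, with the accretion
#' efficiency `epsilon` splitting the sediment flux between continental
#' accretion and delivery to the upper mantle:
#' `F_ms_um = (1 - epsilon) * M_MS / tau`, `F_ms_cc = epsilon * M_MS / tau`,
#' `F_oc_um = M_OC / tau`.
#'
#' @inheritParams surface_erosion_flux
#' @return Named numeric vector `c(F_ms_um, F_ms_cc, F_oc_um)`, kg P yr^-1.
#' @export
subduction_fluxes <- function(state, params, structure) {
  if (!is.infinite(params$tau_sub) && params$tau_sub <= 0) {
    stop("tau_sub: must be > 0", call. = FALSE)
  }
  f <- flux_rates(state$t, state$masses, params, structure)
  c(
    F_ms_um = f[["subduction_ms"]],
    F_ms_cc = f[["accretion"]],
    F_oc_um = f[["subduction_oc"]]
  )
}

#' Volcanic phosphorus fluxes
#'
#' Arc (UM to CC), mid-ocean-ridge (UM to OC) and hotspot (LM to crust)
#' volcanism: `scale(t) * V * rho_mantle * concentration * E` for each
#' channel, with the hotspot total split between CC and OC by the
#' emergent-area fraction.
#'
#' @inheritParams surface_erosion_flux
#' @return Named numeric vector `c(arc, mor, hotspot_cc, hotspot_oc)`.
#' @export
volcanism_fluxes <- function(state, params, structure) {
  f <- flux_rates(state$t, state$masses, params, structure)
  c(
    arc = f[["arc"]], mor = f[["mor"]],
    hotspot_cc = f[["hotspot_cc"]], hotspot_oc = f[["hotspot_oc"]]
  )
}

#' Hydrothermal phosphorus drawdown, ocean to oceanic crust
#'
#' Removal of dissolved P by hydrothermal circulation, decaying exponentially
#' over geological time: `min(H0 * exp(-t/tau), ocean P / dt)` — the clamp
#' guarantees the ocean is never drained below zero within a step.
#'
#' @inheritParams surface_erosion_flux
#' @param dt Timestep used for the clamp (defaults to `params$dt`).
#' @return Flux, kg P yr^-1.
#' @export
hydrothermal_flux <- function(state, params, structure, dt = params$dt) {
  flux_rates(state$t, state$masses, params, structure, dt = dt)[["hydrothermal"]]
}

#' Mantle mixing fluxes
#'
#' Convective P exchange between lower and upper mantle as balanced rock
#' exchange: a rock mass `r(t) * rock_LM` crosses the boundary each way per
#' year carrying P at the source concentration, so `mix_up = r(t) * M_LM`
#' and `mix_down = r(t) * rock_LM * M_UM / rock_UM`. Net exchange vanishes
#' when the two layers share the same P concentration.
#'
#' @inheritParams surface_erosion_flux
#' @return Named numeric vector `c(mix_up, mix_down)`, kg P yr^-1.
#' @export
mixing_fluxes <- function(state, params, structure) {
  f <- flux_rates(state$t, state$masses, params, structure)
  c(mix_up = f[["mix_up"]], mix_down = f[["mix_down"]])
}

#' Assemble the full instantaneous flux vector
#'
#' Evaluates every continuous channel of the network at the given state and
#' returns one row per directed edge. The four overflow channels are present
#' with value 0: they are resolved inside the integration step when the
#' atmosphere or ocean exceeds its saturation cap.
#'
#' @inheritParams surface_erosion_flux
#' @return A tibble with columns `channel`, `from`, `to`, `flux_kg_yr`.
#' @examples
#' assemble_fluxes(modern_state(), p_params(), p_structure())
#' @export
assemble_fluxes <- function(state, params, structure) {
  f <- flux_rates(state$t, state$masses, params, structure)
  if (any(f < 0) || any(!is.finite(f))) {
    stop("assemble_fluxes: negative or non-finite flux computed (internal invariant violation)",
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(FLUX_EDGES)
  out$flux_kg_yr <- 0
  out$flux_kg_yr[match(names(f), out$channel)] <- unname(f)
  out
}
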