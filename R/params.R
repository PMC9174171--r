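#' Reservoir identifiers
#'
#' The eight boxes of the model. `CORE` holds the sequestered metallic-core
#' phosphorus and participates in no flux; the other seven make up the bulk
#' silicate Earth (BSE).
#'
#' @format Character vector of length 8.
#' @export
RESERVOIRS <- c("ATM", "OCEAN", "CC", "OC", "MS", "UM", "LM", "CORE")

#' Reservoirs compared against modern estimates
#'
#' Solid-Earth reservoirs plus marine sediments. The atmosphere and ocean are
#' pinned at their saturation caps by construction, so percent deviations from
#' modern values are only meaningful for these five boxes.
#'
#' @format Character vector of length 5.
#' @export
SOLID_RESERVOIRS <- c("CC", "OC", "MS", "UM", "LM")

#' Molar mass of phosphorus (kg mol^-1)
#' @export
P_MOLAR_MASS <- 0.0309738

#' Planetary structure: rock masses, modern P inventories and geometry
#'
#' Static (non-integrated) properties of the planet: reservoir rock masses,
#' the modern phosphorus content of each reservoir used as comparison
#' targets, ocean volume, surface areas, and rock densities. Defaults
#' describe the modern Earth.
#'
#' Rock masses and modern P contents are in kg; the continental-crust P
#' content default (1.4e19 kg) is the upper end of the 1.2-1.4e19 kg range
#' estimated from average crustal P2O5. The upper-mantle values imply a
#' 200 ppm P concentration.
#'
#' @param rock_masses Named numeric vector over [RESERVOIRS], reservoir rock
#'   mass in kg.
#' @param modern_p Named numeric vector over [RESERVOIRS], estimated modern
#'   reservoir P content in kg.
#' @param ocean_volume Ocean volume in liters.
#' @param area_earth,area_ocean,area_land_modern Surface areas in km^2;
#'   `area_land_modern` is the modern subaerially exposed land area
#'   (~29% of the globe).
#' @param rho_cc,rho_mantle Continental-crust and mantle-melt rock densities,
#'   kg m^-3.
#'
#' @return An object of class `p_structure` (a named list).
#' @examples
#' s <- p_structure()
#' s$modern_p[["UM"]] / s$rock_masses[["UM"]] # ~200 ppm
#' @export
p_structure <- function(rock_masses = c(
                          ATM = 5.1e18, OCEAN = 1.4e21, CC = 1.6e22,
                          OC = 9.0e21, MS = 2.6e20, UM = 1.1e24,
                          LM = 3.0e24, CORE = 2.0e24
                        ),
                        modern_p = c(
                          ATM = 2.8e7, OCEAN = 9.3e13, CC = 1.4e19,
                          OC = 7.2e18, MS = 4.0e18, UM = 2.2e20,
                          LM = 6.0e20, CORE = 5.8e21
                        ),
                        ocean_volume = 1.4e21,
                        area_earth = 5.1e8,
                        area_ocean = 3.6e8,
                        area_land_modern = 1.48e8,
                        rho_cc = 2700,
                        rho_mantle = 3300) {
  structure(
    list(
      rock_masses = rock_masses[RESERVOIRS],
      modern_p = modern_p[RESERVOIRS],
      ocean_volume = ocean_volume,
      area_earth = area_earth,
      area_ocean = area_ocean,
      area_land_modern = area_land_modern,
      rho_cc = rho_cc,
      rho_mantle = rho_mantle
    ),
    class = "p_structure"
  )
}

#' Model parameters for the phosphorus-cycle simulation
#'
#' All tunable constants of the flux network and integrator, with defaults
#' transcribing the model's main configuration. Values are grouped the way
#' the processes are: extraterrestrial delivery, erosion, ocean/atmosphere
#' saturation caps, subduction and accretion, mantle mixing, volcanism,
#' hydrothermal drawdown, continental growth, and the integration grid.
#'
#' @param et List with `F0`, `F1` (kg P yr^-1, modern and initial
#'   extraterrestrial fluxes) and `tau` (yr, decay constant): the delivery law
#'   is `F0 + (F1 - F0) * exp(-t/tau)`.
#' @param alpha Surface (riverine) erosion rate, m yr^-1.
#' @param beta Wind erosion rate, m yr^-1 (used when
#'   `aeolian_mode = "beta"`).
#' @param aeolian_p_rate Modern area-averaged aeolian P erosion rate,
#'   kg P km^-2 yr^-1.
#' @param aeolian_mode `"rate"` (default) scales `aeolian_p_rate` by land area
#'   and relative CC P concentration; `"beta"` uses the rock-erosion route
#'   `beta * area * rho_cc * concentration`.
#' @param atm_cap Atmospheric saturation P mass, kg.
#' @param ocean_sat_conc Oceanic saturation P concentration, mol L^-1.
#' @param rainout_land_frac Fraction of atmospheric overflow rained out to the
#'   continents (default 3.2/4.6, the modern continental share of rain-out).
#' @param riverine_ms_frac Fraction of ocean overflow routed to marine
#'   sediments; the remainder reaches the oceanic crust.
#' @param epsilon Continental accretion efficiency in `[0, 1]`: the fraction of
#'   subducting marine-sediment P scraped back onto the continental crust.
#' @param tau_sub Subduction turnover time, yr.
#' @param mixing List with `F0`, `F1` (yr^-1, modern and initial mantle mixing
#'   rates) and `tau` (yr): `r(t) = F0 + (F1 - F0) * exp(-t/tau)`.
#' @param volcanism List with modern eruption volumes `V_arc`, `V_mor`,
#'   `V_hotspot` (km^3 yr^-1), P enrichment factors `E_arc`, `E_mor`,
#'   `E_hotspot`, the initial volcanic multiplying factor `f` (the scale is
#'   `1 + (f - 1) * exp(-t/tau)`) and its decay constant `tau` (yr).
#' @param hydrothermal List with `H0` (kg P yr^-1, initial ocean-to-OC removal
#'   flux) and `tau` (yr, decay constant of hydrothermal circulation).
#' @param seaspray_rate Mobilized-seawater constant, L yr^-1. The default is
#'   calibrated so that a saturated modern ocean ejects 3.3e8 kg P yr^-1.
#' @param growth List describing emergent land growth: `model`
#'   (`"piecewise_linear"` or `"exponential"`), `A0_frac` (initial emergent
#'   fraction of the modern land area), `t_knee` (yr) and `frac_knee`
#'   (fraction of modern area at the knee).
#' @param cc_rock_growth If `TRUE`, the CC P concentration entering the
#'   erosion and aeolian laws uses the growth-scaled CC rock mass
#'   ([cc_rock_mass]); the default `FALSE` references the constant modern CC
#'   rock mass, so that erosional output grows with emergent area.
#' @param core_fraction Fraction of the total planetary P inventory
#'   sequestered in the core (0.85, 0.90, 0.95 or 0.97 in the scenarios
#'   explored; default 0.90).
#' @param dt Timestep, yr.
#' @param n_steps Number of timesteps; `dt * n_steps` is the run span
#'   (4.5 Ga for the main configuration).
#' @param p_molar_mass Molar mass of P, kg mol^-1.
#'
#' @return An object of class `p_params` (a nested named list).
#' @seealso [validate_params()], [set_param()], [p_structure()]
#' @examples
#' p <- p_params()
#' p$epsilon
#' p2 <- set_param(p, "volcanism.E_mor", 10)
#' @export
p_params <- function(et = list(F0 = 2.0e5, F1 = 2.0e8, tau = 1.5e8),
                     alpha = 2.2e-4,
                     beta = 2.7e-5,
                     aeolian_p_rate = 27,
                     aeolian_mode = c("rate", "beta"),
                     atm_cap = 2.8e7,
                     ocean_sat_conc = 2.2e-6,
                     rainout_land_frac = 3.2 / 4.6,
                     riverine_ms_frac = 0.90,
                     epsilon = 0.30,
                     tau_sub = 1.0e8,
                     mixing = list(F0 = 1.0e-8, F1 = 3.0e-8, tau = 1.5e9),
                     volcanism = list(
                       V_arc = 2.75, V_mor = 20, V_hotspot = 2.25,
                       E_arc = 5, E_mor = 4.6, E_hotspot = 4.6,
                       f = 3, tau = 5.0e8
                     ),
                     hydrothermal = list(H0 = 1.0e9, tau = 1.5e9),
                     seaspray_rate = 3.3e8 / (2.2e-6 * P_MOLAR_MASS),
                     growth = list(
                       model = "piecewise_linear", A0_frac = 0.01,
                       t_knee = 1.5e9, frac_knee = 2 / 3
                     ),
                     cc_rock_growth = FALSE,
                     core_fraction = 0.90,
                     dt = 5000,
                     n_steps = 9e5,
                     p_molar_mass = P_MOLAR_MASS) {
  aeolian_mode <- match.arg(aeolian_mode)
  # store every numeric scalar as double (JSON round-trips can yield
  # integers, and e.g. dt * n_steps overflows integer arithmetic)
  num <- function(x) if (is.list(x)) lapply(x, num) else if (is.numeric(x)) as.numeric(x) else x
  et <- num(et); mixing <- num(mixing); volcanism <- num(volcanism)
  hydrothermal <- num(hydrothermal); growth <- num(growth)
  alpha <- num(alpha); beta <- num(beta); aeolian_p_rate <- num(aeolian_p_rate)
  atm_cap <- num(atm_cap); ocean_sat_conc <- num(ocean_sat_conc)
  rainout_land_frac <- num(rainout_land_frac)
  riverine_ms_frac <- num(riverine_ms_frac)
  epsilon <- num(epsilon); tau_sub <- num(tau_sub)
  seaspray_rate <- num(seaspray_rate); core_fraction <- num(core_fraction)
  dt <- num(dt); n_steps <- num(n_steps); p_molar_mass <- num(p_molar_mass)
  structure(
    list(
      et = et, alpha = alpha, beta = beta,
      aeolian_p_rate = aeolian_p_rate, aeolian_mode = aeolian_mode,
      atm_cap = atm_cap, ocean_sat_conc = ocean_sat_conc,
      rainout_land_frac = rainout_land_frac,
      riverine_ms_frac = riverine_ms_frac,
      epsilon = epsilon, tau_sub = tau_sub,
      mixing = mixing, volcanism = volcanism,
      hydrothermal = hydrothermal, seaspray_rate = seaspray_rate,
      growth = growth, cc_rock_growth = cc_rock_growth,
      core_fraction = core_fraction,
      dt = dt, n_steps = n_steps, p_molar_mass = p_molar_mass
    ),
    class = "p_params"
  )
}

#' Total run span of a configuration, years
#' @param params A [p_params()] object.
#' @return `dt * n_steps` in years.
#' @export
run_span <- function(params) params$dt * params$n_steps

#' Ocean phosphorus saturation mass
#'
#' The dissolved-P mass at which the ocean saturates:
#' `ocean_sat_conc * ocean_volume * p_molar_mass`. Incoming P beyond this
#' value is routed to the marine sediments and oceanic crust within the step.
#'
#' @param params A [p_params()] object.
#' @param structure A [p_structure()] object.
#' @return Saturation mass in kg.
#' @examples
#' ocean_saturation_mass(p_params(), p_structure()) # ~9.5e13 kg
#' @export
ocean_saturation_mass <- function(params, structure) {
  params$ocean_sat_conc * structure$ocean_volume * params$p_molar_mass
}

#' Instantaneous planet state
#'
#' The integrated state vector: model time, P mass per reservoir, and the
#' cumulative extraterrestrial P delivered since t = 0 (tracked for
#' conservation audits).
#'
#' @param masses Named numeric vector of P masses (kg) over [RESERVOIRS];
#'   missing reservoirs default to 0.
#' @param t Model time since start, years.
#' @param cumulative_et Cumulative extraterrestrial P input since t = 0, kg.
#' @return An object of class `p_state`.
#' @export
planet_state <- function(masses, t = 0, cumulative_et = 0) {
  m <- stats::setNames(numeric(length(RESERVOIRS)), RESERVOIRS)
  m[names(masses)] <- masses
  if (any(m < 0) || any(!is.finite(m))) {
    stop("planet_state: masses must be finite and non-negative", call. = FALSE)
  }
  structure(list(t = t, masses = m, cumulative_et = cumulative_et),
    class = "p_state"
  )
}

#' The modern planet as a state
#'
#' Convenience constructor: a [planet_state()] holding the Table-of-modern
#' P inventories from a [p_structure()], at the end of the run span.
#'
#' @param structure A [p_structure()] object.
#' @param t Model time to stamp on the state (default 4.5 Ga).
#' @return A `p_state`.
#' @export
modern_state <- function(structure = p_structure(), t = 4.5e9) {
  planet_state(structure$modern_p, t = t)
}

check_that <- function(errors, ok, msg) {
  if (!isTRUE(ok)) c(errors, msg) else errors
}

#' Validate a parameter set
#'
#' Checks every admissibility constraint on a [p_params()] object and, if any
#' fails, throws a single error itemizing the offending keys.
#'
#' @param params A [p_params()] object.
#' @param structure Optionally, a [p_structure()] validated alongside.
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params, structure = NULL) {
  e <- character()
  p <- params
  e <- check_that(e, is.finite(p$epsilon) && p$epsilon >= 0 && p$epsilon <= 1,
    "epsilon: must be in [0, 1]")
  nonneg <- c(
    alpha = p$alpha, beta = p$beta, aeolian_p_rate = p$aeolian_p_rate,
    atm_cap = p$atm_cap, ocean_sat_conc = p$ocean_sat_conc,
    seaspray_rate = p$seaspray_rate, "et.F0" = p$et$F0, "et.F1" = p$et$F1,
    "et.tau" = p$et$tau, "mixing.F0" = p$mixing$F0,
    "mixing.F1" = p$mixing$F1, "mixing.tau" = p$mixing$tau,
    "volcanism.V_arc" = p$volcanism$V_arc,
    "volcanism.V_mor" = p$volcanism$V_mor,
    "volcanism.V_hotspot" = p$volcanism$V_hotspot,
    "volcanism.E_arc" = p$volcanism$E_arc,
    "volcanism.E_mor" = p$volcanism$E_mor,
    "volcanism.E_hotspot" = p$volcanism$E_hotspot,
    "volcanism.tau" = p$volcanism$tau,
    "hydrothermal.H0" = p$hydrothermal$H0,
    "hydrothermal.tau" = p$hydrothermal$tau
  )
  bad <- names(nonneg)[is.na(nonneg) | nonneg < 0]
  for (k in bad) e <- c(e, paste0(k, ": must be >= 0"))
  e <- check_that(e, p$et$F1 >= p$et$F0, "et.F1: must be >= et.F0")
  e <- check_that(e, p$mixing$F1 >= p$mixing$F0,
    "mixing.F1: must be >= mixing.F0")
  e <- check_that(e, p$volcanism$f >= 1, "volcanism.f: must be >= 1")
  e <- check_that(e, is.finite(p$tau_sub) && p$tau_sub > 0 || is.infinite(p$tau_sub),
    "tau_sub: must be > 0")
  e <- check_that(e, p$dt > 0, "dt: must be > 0")
  e <- check_that(e, p$n_steps >= 1, "n_steps: must be >= 1")
  e <- check_that(e, p$rainout_land_frac >= 0 && p$rainout_land_frac <= 1,
    "rainout_land_frac: must be in [0, 1]")
  e <- check_that(e, p$riverine_ms_frac >= 0 && p$riverine_ms_frac <= 1,
    "riverine_ms_frac: must be in [0, 1]")
  e <- check_that(e, p$core_fraction > 0 && p$core_fraction < 1,
    "core_fraction: must be in (0, 1)")
  e <- check_that(e, p$growth$model %in% c("piecewise_linear", "exponential"),
    "growth.model: must be 'piecewise_linear' or 'exponential'")
  e <- check_that(e, p$growth$A0_frac > 0 && p$growth$A0_frac <= 1,
    "growth.A0_frac: must be in (0, 1]")
  e <- check_that(e, p$growth$frac_knee > 0 && p$growth$frac_knee <= 1,
    "growth.frac_knee: must be in (0, 1]")
  e <- check_that(e, p$growth$t_knee > 0, "growth.t_knee: must be > 0")
  if (!is.null(structure)) {
    e <- check_that(e, all(structure$rock_masses > 0),
      "structure.rock_masses: all entries must be > 0")
    e <- check_that(e, all(structure$modern_p > 0),
      "structure.modern_p: all entries must be > 0")
  }
  if (length(e)) {
    stop("invalid configuration:\n  - ", paste(e, collapse = "\n  - "),
      call. = FALSE
    )
  }
  invisible(params)
}

#' Set a (possibly nested) parameter by dotted path
#'
#' Sensitivity sweeps address parameters by dotted paths such as
#' `"epsilon"`, `"volcanism.E_mor"` or `"mixing.F1"`. The path must resolve
#' to an existing scalar field.
#'
#' @param params A [p_params()] object.
#' @param path Dotted path string.
#' @param value Replacement scalar.
#' @return The modified `p_params` object.
#' @export
set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]])) {
      stop(
        "unknown parameter path '", path, "'; valid paths include: ",
        paste(utils::head(param_paths(params), 12), collapse = ", "), ", ...",
        call. = FALSE
      )
    }
    node <- node[[k]]
  }
  if (length(node) != 1) {
    stop("parameter path '", path, "' does not resolve to a scalar",
      call. = FALSE
    )
  }
  params[[keys]] <- value
  params
}

#' Get a parameter by dotted path
#' @inheritParams set_param
#' @return The scalar value at `path`; unknown paths are an error.
#' @export
get_param <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]])) {
      stop("unknown parameter path '", path, "'", call. = FALSE)
    }
    node <- node[[k]]
  }
  node
}

#' All sweepable parameter paths
#' @param params A [p_params()] object.
#' @return Character vector of dotted paths to scalar fields.
#' @export
param_paths <- function(params = p_params()) {
  paths <- character()
  walk <- function(node, prefix) {
    for (nm in names(node)) {
      val <- node[[nm]]
      key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      if (is.list(val)) {
        walk(val, key)
      } else if (length(val) == 1 && is.numeric(val)) {
        paths <<- c(paths, key)
      }
    }
  }
  walk(unclass(params), "")
  paths
}

#' @export
print.p_params <- function(x, ...) {
  cat("<p_params> phosphorus-cycle model parameters\n")
  cat(sprintf(
    "  run: %d steps x %g yr = %.3g Ga; epsilon = %.2f, tau_sub = %.3g yr\n",
    as.integer(x$n_steps), x$dt, run_span(x) / 1e9, x$epsilon, x$tau_sub
  ))
  cat(sprintf(
    "  ET: F0 = %.3g, F1 = %.3g kg/yr (tau = %.3g yr); volcanic f = %g\n",
    x$et$F0, x$et$F1, x$et$tau, x$volcanism$f
  ))
  invisible(x)
}

#' @export
print.p_state <- function(x, ...) {
  cat(sprintf("<p_state> t = %.4g yr, cumulative ET = %.4g kg\n", x$t, x$cumulative_et))
  print(format(x$masses, digits = 4, scientific = TRUE), quote = FALSE)
  invisible(x)
}
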