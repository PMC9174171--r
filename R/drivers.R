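#' Emergent land area through time
#'
#' Continental growth curve. The default (`"piecewise_linear"`) starts from a
#' small non-zero emergent fraction, grows linearly to `frac_knee` of the
#' modern area at `t_knee` (2/3 at 1.5 Ga), then continues linearly at a
#' slower pace to the modern subaerial land area at the end of the run.
#' The `"exponential"` alternative relaxes as
#' `1 - (1 - A0_frac) * exp(-t/t_knee)`, rescaled so both models agree at
#' t = 0 and at 4.5 Ga.
#'
#' @param t Time since start of run, years (vectorized). Must lie within
#'   `[0, dt * n_steps]`.
#' @param params A [p_params()] object.
#' @param structure A [p_structure()] object.
#' @return Emergent land area, km^2.
#' @examples
#' emergent_land_area(4.5e9, p_params(), p_structure()) # 1.48e8 km^2
#' @export
emergent_land_area <- function(t, params, structure) {
  t_end <- run_span(params)
  if (any(t < 0 | t > t_end)) {
    stop("emergent_land_area: t must lie in [0, ", t_end, "]", call. = FALSE)
  }
  structure$area_land_modern * land_fraction(t, params, t_end)
}

# Emergent fraction of the modern land area (shared by R and config writers;
# the C++ integrator mirrors this arithmetic).
land_fraction <- function(t, params, t_end = run_span(params)) {
  g <- params$growth
  if (identical(g$model, "piecewise_linear")) {
    ifelse(t <= g$t_knee,
      g$A0_frac + (g$frac_knee - g$A0_frac) * t / g$t_knee,
      g$frac_knee + (1 - g$frac_knee) * (t - g$t_knee) / (t_end - g$t_knee)
    )
  } else {
    raw <- function(x) 1 - (1 - g$A0_frac) * exp(-x / g$t_knee)
    g$A0_frac + (1 - g$A0_frac) * (raw(t) - g$A0_frac) / (raw(t_end) - g$A0_frac)
  }
}

#' Continental-crust rock mass through time
#'
#' CC rock inventory scaled with the emergent-area growth curve at constant
#' average thickness and density: `modern CC rock mass * A(t)/A_modern`.
#' This is the growth-scaled rock-mass model; by default the flux laws
#' reference CC P concentration to the constant modern rock mass instead
#' (see `cc_rock_growth` in [p_params()]), so that erosional output grows
#' with emergent area.
#'
#' @inheritParams emergent_land_area
#' @return CC rock mass, kg.
#' @examples
#' cc_rock_mass(4.5e9, p_params(), p_structure()) # 1.6e22 kg
#' @export
cc_rock_mass <- function(t, params, structure) {
  structure$rock_masses[["CC"]] *
    emergent_land_area(t, params, structure) / structure$area_land_modern
}

#' Mantle mixing rate through time
#'
#' Exponential relaxation from the vigorous early-Earth convection rate `F1`
#' to the modern rate `F0`: `F0 + (F1 - F0) * exp(-t/tau)`. Defaults span
#' 3e-8 yr^-1 (early) to 1e-8 yr^-1 (modern).
#'
#' @param t Time, years (vectorized, must be >= 0).
#' @param params A [p_params()] object.
#' @return Mixing rate, yr^-1.
#' @export
mixing_rate <- function(t, params) {
  m <- params$mixing
  m$F0 + (m$F1 - m$F0) * exp(-t / m$tau)
}

#' Volcanic activity scale through time
#'
#' Dimensionless multiplier on all three modern volcanic volume rates:
#' `1 + (f - 1) * exp(-t/tau)`, equal to the initial volcanic multiplying
#' factor `f` (default 3) at t = 0 and relaxing to the modern value 1.
#'
#' @inheritParams mixing_rate
#' @return Dimensionless scale >= 1.
#' @export
volcanic_scale <- function(t, params) {
  v <- params$volcanism
  1 + (v$f - 1) * exp(-t / v$tau)
}

#' Extraterrestrial phosphorus delivery flux
#'
#' Exponentially decaying delivery of P by comets, asteroids, meteorites and
#' interplanetary dust: `F(t) = F0 + (F1 - F0) * exp(-t/tau)`, with defaults
#' F1 = 2e8 kg/yr at accretion, F0 = 2e5 kg/yr today, tau = 150 Ma.
#' Downstream, the flux is split between emergent land (to CC) and the ocean
#' pool in proportion to surface area.
#'
#' @param t Time, years (vectorized; negative times are a domain error).
#' @param params A [p_params()] object (only the `et` element is used).
#' @return Flux, kg P yr^-1.
#' @examples
#' et_flux(0, p_params()) # 2e8
#' @export
et_flux <- function(t, params) {
  if (any(t < 0)) stop("et_flux: t must be >= 0", call. = FALSE)
  e <- params$et
  e$F0 + (e$F1 - e$F0) * exp(-t / e$tau)
}

#' Closed-form integral of the extraterrestrial flux
#'
#' Cumulative delivered mass from 0 to `T`:
#' `F0*T + (F1 - F0) * tau * (1 - exp(-T/tau))`. Used by the conservation
#' audit and to cross-check the numerical integration.
#'
#' @param T Upper time limit, years.
#' @param params A [p_params()] object.
#' @return Cumulative mass, kg.
#' @export
et_cumulative <- function(T, params) {
  e <- params$et
  e$F0 * T + (e$F1 - e$F0) * e$tau * (1 - exp(-T / e$tau))
}
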