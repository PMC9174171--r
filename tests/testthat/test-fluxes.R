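test_that("extraterrestrial flux follows the exponential delivery law", {
  p <- p_params()
  expect_equal(et_flux(0, p), 2.0e8)
  expect_equal(et_flux(1e12, p), 2.0e5, tolerance = 1e-6)
  expect_equal(et_flux(1.5e8, p), 2e5 + (2e8 - 2e5) / exp(1), tolerance = 1e-12)
  expect_equal(et_flux(1.5e8, p), 7.371e7, tolerance = 1e-3)
  expect_error(et_flux(-1, p), "t must be >= 0")
})

test_that("trapezoid integration of the ET flux matches the closed form within 0.1%", {
  p <- p_params()
  tt <- seq(0, 4.5e9, by = p$dt)
  f <- et_flux(tt, p)
  trap <- sum((f[-1] + f[-length(f)]) / 2 * diff(tt))
  expect_equal(trap, et_cumulative(4.5e9, p), tolerance = 1e-3)
})

test_that("surface erosion reproduces the modern riverine oracle and is linear", {
  p <- p_params()
  s <- p_structure()
  st <- modern_state(s)
  # direct arithmetic: alpha * land m^2 * rho * (1.4e19 / 1.6e22)
  oracle <- 2.2e-4 * 1.48e14 * 2700 * (1.4e19 / 1.6e22)
  expect_equal(surface_erosion_flux(st, p, s), oracle, tolerance = 1e-12)
  expect_equal(oracle, 7.69e10, tolerance = 1e-3)
  # zero CC P -> zero flux
  st0 <- st
  st0$masses[["CC"]] <- 0
  expect_equal(surface_erosion_flux(st0, p, s), 0)
  # doubling alpha doubles the flux
  expect_equal(
    surface_erosion_flux(st, set_param(p, "alpha", 4.4e-4), s),
    2 * oracle,
    tolerance = 1e-12
  )
})

test_that("aeolian flux matches its modern calibration and scales with concentration", {
  p <- p_params()
  s <- p_structure()
  st <- modern_state(s)
  expect_equal(aeolian_flux(st, p, s), 27 * 1.48e8, tolerance = 1e-12)
  expect_equal(aeolian_flux(st, p, s), 4.0e9, tolerance = 2e-3)
  # half-modern CC concentration -> half flux
  st2 <- st
  st2$masses[["CC"]] <- st$masses[["CC"]] / 2
  expect_equal(aeolian_flux(st2, p, s), 2.0e9, tolerance = 2e-3)
  # no emergent land -> no flux
  st0 <- st
  st0$t <- 0
  p0 <- p_params(growth = list(
    model = "piecewise_linear", A0_frac = 1e-12, t_knee = 1.5e9, frac_knee = 2 / 3
  ))
  expect_lt(aeolian_flux(st0, p0, s), 1e-2)
  # beta mode is the rock-erosion route
  pb <- p_params(aeolian_mode = "beta")
  expect_equal(
    aeolian_flux(st, pb, s),
    2.7e-5 * 1.48e14 * 2700 * (1.4e19 / 1.6e22),
    tolerance = 1e-12
  )
})

test_that("sea spray is proportional to dissolved concentration, 3.3e8 kg/yr at saturation", {
  p <- p_params()
  s <- p_structure()
  st <- modern_state(s)
  st$masses[["OCEAN"]] <- ocean_saturation_mass(p, s)
  expect_equal(seaspray_flux(st, p, s), 3.3e8, tolerance = 1e-9)
  st$masses[["OCEAN"]] <- ocean_saturation_mass(p, s) / 2
  expect_equal(seaspray_flux(st, p, s), 1.65e8, tolerance = 1e-9)
  st$masses[["OCEAN"]] <- 0
  expect_equal(seaspray_flux(st, p, s), 0)
})

test_that("subduction and accretion split the sediment turnover by epsilon", {
  p <- p_params()
  s <- p_structure()
  st <- modern_state(s) # MS = 4e18, OC = 7.2e18, tau = 1e8, eps = 0.3
  f <- subduction_fluxes(st, p, s)
  expect_equal(f[["F_ms_cc"]], 1.2e10)
  expect_equal(f[["F_ms_um"]], 2.8e10)
  expect_equal(f[["F_oc_um"]], 7.2e10)
  # identity F_ms_um + F_ms_cc = M_sed / tau, to round-off
  expect_equal(f[["F_ms_um"]] + f[["F_ms_cc"]], st$masses[["MS"]] / p$tau_sub,
    tolerance = 1e-15
  )
  f0 <- subduction_fluxes(st, set_param(p, "epsilon", 0), s)
  expect_equal(f0[["F_ms_cc"]], 0)
  expect_equal(f0[["F_ms_um"]], 4.0e10)
})

test_that("volcanic fluxes follow volume x density x concentration x enrichment", {
  s <- p_structure()
  st <- modern_state(s)
  # late time: volcanic scale ~ 1
  p <- p_params(volcanism = list(
    V_arc = 2.75, V_mor = 20, V_hotspot = 2.25,
    E_arc = 5, E_mor = 4.6, E_hotspot = 4.6, f = 1, tau = 5e8
  ))
  f <- volcanism_fluxes(st, p, s)
  expect_equal(f[["mor"]], 20e9 * 3300 * 2.0e-4 * 4.6, tolerance = 1e-12)
  expect_equal(f[["mor"]], 6.07e10, tolerance = 1e-3)
  # hotspot split by emergent-area fraction
  f_land <- 1.48e8 / 5.1e8
  hot <- 2.25e9 * 3300 * 2.0e-4 * 4.6
  expect_equal(f[["hotspot_cc"]], hot * f_land, tolerance = 1e-12)
  expect_equal(f[["hotspot_oc"]], hot * (1 - f_land), tolerance = 1e-12)
  # f = 3 at t = 0 triples every channel
  p3 <- p_params(volcanism = list(
    V_arc = 2.75, V_mor = 20, V_hotspot = 2.25,
    E_arc = 5, E_mor = 4.6, E_hotspot = 4.6, f = 3, tau = 5e8
  ))
  st0 <- st
  st0$t <- 0
  f3 <- volcanism_fluxes(st0, p3, s)
  f1 <- volcanism_fluxes(st0, p, s)
  expect_equal(unname(f3 / f1), rep(3, 4), tolerance = 1e-12)
  # zero volume -> zero flux
  p0 <- p_params(volcanism = list(
    V_arc = 0, V_mor = 0, V_hotspot = 0,
    E_arc = 1, E_mor = 1, E_hotspot = 1, f = 1, tau = 5e8
  ))
  expect_equal(unname(volcanism_fluxes(st, p0, s)), rep(0, 4))
})

test_that("hydrothermal drawdown decays and never drains the ocean below zero", {
  p <- p_params()
  s <- p_structure()
  st <- modern_state(s)
  st$t <- 0
  st$masses[["OCEAN"]] <- 1e20 # not limiting
  expect_equal(hydrothermal_flux(st, p, s), 1e9)
  st$t <- p$hydrothermal$tau
  expect_equal(hydrothermal_flux(st, p, s), 1e9 / exp(1), tolerance = 1e-12)
  st$masses[["OCEAN"]] <- 0
  expect_equal(hydrothermal_flux(st, p, s), 0)
  # clamp: a nearly empty ocean limits the flux to M/dt
  st$masses[["OCEAN"]] <- 5e9
  st$t <- 0
  expect_equal(hydrothermal_flux(st, p, s), 5e9 / p$dt)
})

test_that("mantle mixing is balanced rock exchange with zero net flux at equal concentration", {
  p <- p_params()
  s <- p_structure()
  st <- generic_state(t = 0)
  st$masses[["LM"]] <- 6.0e20
  f <- mixing_fluxes(st, p, s)
  expect_equal(f[["mix_up"]], 3e-8 * 6.0e20) # 1.8e13 kg/yr
  # equal P concentrations in UM and LM -> no net exchange
  conc <- 2e-4
  st$masses[["UM"]] <- conc * s$rock_masses[["UM"]]
  st$masses[["LM"]] <- conc * s$rock_masses[["LM"]]
  f <- mixing_fluxes(st, p, s)
  expect_equal(f[["mix_up"]], f[["mix_down"]], tolerance = 1e-12)
  # zero mixing rate -> both zero
  p0 <- p_params(mixing = list(F0 = 0, F1 = 0, tau = 1.5e9))
  expect_equal(unname(mixing_fluxes(st, p0, s)), c(0, 0))
})

test_that("assemble_fluxes covers every network edge exactly once, non-negatively", {
  p <- p_params()
  s <- p_structure()
  fx <- assemble_fluxes(modern_state(s), p, s)
  expect_setequal(fx$channel, FLUX_EDGES$channel)
  expect_equal(nrow(fx), nrow(FLUX_EDGES))
  expect_true(all(fx$flux_kg_yr >= 0))
  # componentwise agreement with the single-channel operations
  st <- modern_state(s)
  expect_equal(
    fx$flux_kg_yr[fx$channel == "surface_erosion"],
    surface_erosion_flux(st, p, s)
  )
  expect_equal(fx$flux_kg_yr[fx$channel == "aeolian"], aeolian_flux(st, p, s))
  expect_equal(
    fx$flux_kg_yr[fx$channel == "mor"],
    unname(volcanism_fluxes(st, p, s)[["mor"]])
  )
  # an empty (core-only) planet produces no flux except the ET source
  st0 <- planet_state(c(CORE = 5.8e21), t = 1e9)
  fx0 <- assemble_fluxes(st0, p, s)
  et <- fx0$channel %in% c("et_land", "et_ocean")
  expect_true(all(fx0$flux_kg_yr[!et] == 0))
  expect_equal(sum(fx0$flux_kg_yr[et]), et_flux(1e9, p))
})

test_that("every flux is non-negative and degree-1 in its source P mass (property)", {
  set.seed(7)
  p <- p_params()
  s <- p_structure()
  mass_channels <- c(
    "surface_erosion", "aeolian", "seaspray", "accretion", "subduction_ms",
    "subduction_oc", "arc", "mor", "hotspot_cc", "hotspot_oc",
    "mix_up", "mix_down"
  )
  source_of <- c(
    surface_erosion = "CC", aeolian = "CC", seaspray = "OCEAN",
    accretion = "MS", subduction_ms = "MS", subduction_oc = "OC",
    arc = "UM", mor = "UM", hotspot_cc = "LM", hotspot_oc = "LM",
    mix_up = "LM", mix_down = "UM"
  )
  for (i in 1:30) {
    masses <- 10^stats::runif(7, 5, 20)
    names(masses) <- setdiff(RESERVOIRS, "CORE")
    st <- planet_state(masses, t = stats::runif(1, 0, 4.5e9))
    fx <- assemble_fluxes(st, p, s)
    expect_true(all(fx$flux_kg_yr >= 0))
    # doubling one source reservoir doubles exactly its outgoing fluxes
    res <- sample(names(source_of), 1)
    src <- source_of[[res]]
    st2 <- st
    st2$masses[[src]] <- 2 * st$masses[[src]]
    fx2 <- assemble_fluxes(st2, p, s)
    ratio <- fx2$flux_kg_yr[fx2$channel == res] / fx$flux_kg_yr[fx$channel == res]
    expect_equal(ratio, 2, tolerance = 1e-9)
  }
})
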