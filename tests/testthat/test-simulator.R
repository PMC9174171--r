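test_that("the integrator is the identity when every flux vanishes", {
  p <- zero_flux_params(n_steps = 50)
  s <- p_structure()
  st <- generic_state(t = 0)
  # single reference step
  st1 <- step_state(st, p, s)
  expect_equal(st1$masses, st$masses)
  expect_equal(st1$cumulative_et, 0)
  # full compiled run
  traj <- run_simulation(st, p, s, stride = 10)
  expect_equal(unname(as.numeric(traj[nrow(traj), c(
    "atm_kg", "ocean_kg", "cc_kg", "oc_kg", "ms_kg", "um_kg", "lm_kg"
  )])), unname(st$masses[c("ATM", "OCEAN", "CC", "OC", "MS", "UM", "LM")]))
  expect_equal(conservation_residual(traj), 0)
})

test_that("atmospheric overflow splits 3.2/4.6 to land and 1.4/4.6 to the ocean", {
  p <- zero_flux_params()
  s <- p_structure()
  # reservoirs kept small enough that the overflow deltas are exactly
  # representable alongside the standing masses
  st <- planet_state(
    c(ATM = 2 * 2.8e7, OCEAN = 1e10, CC = 1e9, UM = 2e20, LM = 6e20),
    t = 0
  )
  st1 <- step_state(st, p, s)
  excess <- 2.8e7
  expect_equal(unname(st1$masses[["ATM"]]), 2.8e7)
  expect_equal(unname(st1$masses[["CC"]] - st$masses[["CC"]]),
    excess * 3.2 / 4.6,
    tolerance = 1e-12
  )
  expect_equal(unname(st1$masses[["OCEAN"]] - st$masses[["OCEAN"]]),
    excess * 1.4 / 4.6,
    tolerance = 1e-12
  )
})

test_that("ocean overflow routes 90% to sediments and 10% to oceanic crust", {
  p <- zero_flux_params()
  s <- p_structure()
  sat <- ocean_saturation_mass(p, s)
  st <- planet_state(
    c(OCEAN = sat + 1e10, CC = 1e18, MS = 1e18, OC = 1e18, UM = 2e20, LM = 6e20),
    t = 0
  )
  st1 <- step_state(st, p, s)
  expect_equal(unname(st1$masses[["OCEAN"]]), sat)
  expect_equal(unname(st1$masses[["MS"]] - st$masses[["MS"]]), 9e9, tolerance = 1e-9)
  expect_equal(unname(st1$masses[["OC"]] - st$masses[["OC"]]), 1e9, tolerance = 1e-9)
})

test_that("the compiled loop agrees with the reference R step", {
  p <- quick_params(n_steps = 300)
  s <- p_structure()
  st <- seed_initial(seed_spec(rng_seed = 3))
  traj <- run_simulation(st, p, s, stride = 300)
  for (i in 1:300) st <- step_state(st, p, s)
  got <- as.numeric(traj[nrow(traj), c(
    "atm_kg", "ocean_kg", "cc_kg", "oc_kg", "ms_kg", "um_kg", "lm_kg"
  )])
  ref <- unname(st$masses[c("ATM", "OCEAN", "CC", "OC", "MS", "UM", "LM")])
  expect_equal(got, ref, tolerance = 1e-12)
  expect_equal(traj$cum_et_kg[nrow(traj)], st$cumulative_et, tolerance = 1e-12)
})

test_that("mass is conserved and caps are respected on a shortened main run", {
  p <- quick_params(n_steps = 2e4)
  s <- p_structure()
  init <- seed_initial(seed_spec(rng_seed = 5))
  traj <- run_simulation(init, p, s, stride = 100)
  expect_lte(conservation_residual(traj), 1e-6)
  expect_true(all(traj$atm_kg <= p$atm_cap * (1 + 1e-12)))
  expect_true(all(traj$ocean_kg <= ocean_saturation_mass(p, s) * (1 + 1e-12)))
  expect_true(all(diff(traj$time_yr) > 0))
  expect_equal(traj$time_yr[1], 0)
  expect_equal(traj$time_yr[nrow(traj)], run_span(p))
  # the audited total tracks the delivered ET mass (left-Riemann sum, so
  # agreement with the closed form is first-order in dt)
  expect_equal(traj$cum_et_kg[nrow(traj)], et_cumulative(run_span(p), p),
    tolerance = 1e-4
  )
})

test_that("a corrupted snapshot is caught by the conservation audit", {
  p <- quick_params(n_steps = 1000)
  s <- p_structure()
  traj <- run_simulation(seed_initial(seed_spec(rng_seed = 6)), p, s, stride = 100)
  expect_lte(conservation_residual(traj), 1e-6)
  bad <- traj
  bad$cc_kg[5] <- bad$cc_kg[5] + 0.01 * attr(traj, "seed_total")
  expect_gt(conservation_residual(bad), 1e-6)
})

test_that("the CC P inventory rises to an interior peak and then declines", {
  p <- p_params()
  s <- p_structure()
  traj <- run_simulation(seed_initial(seed_spec(rng_seed = 1)), p, s, stride = 900)
  cc <- traj$cc_kg
  ipk <- which.max(cc)
  expect_gt(ipk, 1) # not at the start
  expect_lt(ipk, length(cc)) # not at the end: a true interior maximum
  expect_lt(cc[length(cc)], max(cc))
  # mantle reservoirs settle before the crustal ones
  conv <- vapply(
    c(um_kg = "um_kg", lm_kg = "lm_kg", cc_kg = "cc_kg", oc_kg = "oc_kg", ms_kg = "ms_kg"),
    function(cl) convergence_time(traj$time_yr, traj[[cl]]), numeric(1)
  )
  expect_lt(
    stats::median(conv[c("um_kg", "lm_kg")]),
    stats::median(conv[c("cc_kg", "oc_kg", "ms_kg")])
  )
})

test_that("trajectories round-trip through the CSV writer", {
  p <- quick_params(n_steps = 500)
  s <- p_structure()
  traj <- run_simulation(seed_initial(seed_spec(rng_seed = 2)), p, s, stride = 100)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  hdr <- readLines(f, n = 1)
  expect_identical(
    hdr,
    "time_yr,atm_kg,ocean_kg,cc_kg,oc_kg,ms_kg,um_kg,lm_kg,cum_et_kg"
  )
  back <- read_trajectory(f)
  expect_equal(nrow(back), nrow(traj))
  expect_equal(back$cc_kg, traj$cc_kg, tolerance = 1e-12)
})

test_that("aborting inputs are rejected with diagnostics", {
  p <- quick_params(n_steps = 10)
  s <- p_structure()
  expect_error(
    run_simulation(generic_state(0), p_params(dt = -1), s),
    "dt"
  )
  expect_error(step_state(generic_state(0), p, s, dt = 0), "dt > 0")
})
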