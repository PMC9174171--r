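test_that("random seeding honors the caps and sums exactly to the BSE total", {
  for (seed in c(1, 7, 123)) {
    st <- seed_initial(seed_spec(rng_seed = seed))
    expect_equal(sum(st$masses), 8.4e20)
    expect_equal(unname(st$masses[["ATM"]]), 2.8e7)
    expect_equal(unname(st$masses[["OCEAN"]]), 9.3e13)
    expect_equal(unname(st$masses[["CC"]]), 100)
    expect_equal(unname(st$masses[["MS"]]), 100)
    expect_equal(unname(st$masses[["CORE"]]), 0)
    expect_true(all(st$masses[c("LM", "UM", "OC")] >= 0))
  }
  # degenerate weights: all residual mass lands in the lower mantle
  st <- seed_initial(seed_spec(rng_seed = 1), weights = c(1, 0, 0))
  residual <- 8.4e20 - (2.8e7 + 9.3e13 + 200)
  expect_equal(unname(st$masses[["LM"]]), residual)
  expect_equal(unname(st$masses[["UM"]]), 0)
  expect_equal(unname(st$masses[["OC"]]), 0)
  # an inconsistent spec is rejected
  expect_error(seed_spec(bse_total = 1e13), "must exceed")
})

test_that("residual-mass allocation is uniform on the simplex (mean 1/3 per share)", {
  residual <- 8.4e20 - (2.8e7 + 9.3e13 + 200)
  shares <- vapply(seq_len(1e4), function(seed) {
    st <- seed_initial(seed_spec(rng_seed = seed))
    unname(st$masses[c("LM", "UM", "OC")]) / residual
  }, numeric(3))
  means <- rowMeans(shares)
  expect_true(all(abs(means - 1 / 3) < 0.01))
})

test_that("the BSE seed rescales with the core sequestration fraction", {
  expect_equal(bse_seed_for_core_fraction(0.90), 8.4e20)
  expect_equal(bse_seed_for_core_fraction(0.97), 2.52e20)
  expect_equal(bse_seed_for_core_fraction(0.85), 1.26e21)
  expect_error(bse_seed_for_core_fraction(1.1), "core_fraction")
})

test_that("percent deviation from modern follows its definition", {
  expect_equal(deviation_from_modern(5, 5), 0)
  expect_equal(deviation_from_modern(1.42 * 7e18, 7e18), 42)
  expect_equal(deviation_from_modern(0.97 * 7e18, 7e18), -3)
  expect_error(deviation_from_modern(1, 0), "modern_mass")
})

test_that("convergence time matches the closed-form crossing of a relaxation", {
  # constant series converges immediately
  t <- seq(0, 4.5e9, by = 1e7)
  expect_equal(convergence_time(t, rep(3, length(t))), 0)
  # exponential relaxation to a plateau: analytic crossing at tau*log(amp/(tol*final))
  plateau <- 5
  tau <- 2e8
  x <- plateau + exp(-t / tau)
  analytic <- tau * log(1 / (0.02 * plateau))
  expect_lt(abs(convergence_time(t, x) - analytic), 1e7 + 1e-6)
  # a monotone drift settles only at the very end of the run
  expect_gte(convergence_time(t, seq_along(t) * 1e18), 0.97 * max(t))
  expect_error(convergence_time(numeric(0), numeric(0)), "empty")
})

test_that("cumulative constant-flux arithmetic supports the back-of-envelope estimates", {
  expect_equal(cumulative_constant_flux(1e8, 2e8), 2e16)
  expect_equal(cumulative_constant_flux(2e8, 1e8), 2e16)
  expect_equal(cumulative_constant_flux(0, 1e9), 0)
  expect_error(cumulative_constant_flux(-1, 1), "rate")
})

test_that("ensembles are deterministic given the master seed", {
  p <- quick_params(n_steps = 2000)
  s <- p_structure()
  e1 <- run_ensemble(3, p, s, master_seed = 99, stride = 500)
  e2 <- run_ensemble(3, p, s, master_seed = 99, stride = 500)
  expect_identical(e1$summary, e2$summary)
  expect_identical(e1$finals, e2$finals)
  expect_identical(e1$seeds, e2$seeds)
  e3 <- run_ensemble(3, p, s, master_seed = 100, stride = 500)
  expect_false(identical(e3$seeds, e1$seeds))
})

test_that("a zero-flux single-run ensemble reduces to seeding-vs-modern arithmetic", {
  p <- zero_flux_params(n_steps = 200)
  s <- p_structure()
  ens <- run_ensemble(1, p, s, master_seed = 4, stride = 100)
  init <- seed_initial(seed_spec(
    bse_total = 8.4e20,
    caps = list(
      ATM = min(2.8e7, p$atm_cap),
      OCEAN = min(9.3e13, ocean_saturation_mass(p, s)), CC = 100, MS = 100
    ),
    rng_seed = ens$seeds[1]
  ))
  for (r in SOLID_RESERVOIRS) {
    expect_equal(
      ensemble_deviation(ens, r),
      deviation_from_modern(unname(init$masses[[r]]), unname(s$modern_p[[r]]))
    )
  }
})

test_that("tidiers and summary accessors expose the ensemble results", {
  p <- quick_params(n_steps = 1000)
  s <- p_structure()
  ens <- run_ensemble(2, p, s, master_seed = 12, stride = 250)
  td <- tidy(ens)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$reservoir, setdiff(RESERVOIRS, "CORE"))
  gl <- glance(ens)
  expect_equal(gl$n_runs, 2)
  expect_true(is.finite(gl$mantle_convergence_yr))
  expect_error(ensemble_deviation(ens, "XX"), "unknown reservoir")
  # summary JSON writer stamps version, seed and config hash
  f <- withr::local_tempfile(fileext = ".json")
  write_ensemble_summary(ens, f)
  js <- jsonlite::read_json(f)
  expect_equal(js$master_seed, 12)
  expect_match(js$config_hash, "^[0-9a-f]+$")
  expect_equal(length(js$summary), 7)
})
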