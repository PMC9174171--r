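#' Random initial-seeding specification
#'
#' The initial bulk-silicate-Earth (BSE) P mass and the caps constraining its
#' random distribution: atmosphere and ocean start at their saturation caps,
#' continental crust and marine sediments at ~100 kg (to avoid numerical
#' problems while integrating), and the remainder is split randomly among
#' lower mantle, upper mantle and oceanic crust.
#'
#' @param bse_total Initial BSE P mass, kg (default 8.4e20, the 90%-core
#'   scenario).
#' @param caps Named list of fixed initial masses for ATM, OCEAN, CC, MS.
#' @param rng_seed Integer seed for the random allocation.
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(bse_total = 8.4e20,
                      caps = list(ATM = 2.8e7, OCEAN = 9.3e13, CC = 100, MS = 100),
                      rng_seed = 1L) {
  if (bse_total <= sum(unlist(caps))) {
    stop("seed_spec: bse_total must exceed the sum of the caps", call. = FALSE)
  }
  structure(list(bse_total = bse_total, caps = caps, rng_seed = as.integer(rng_seed)),
    class = "seed_spec"
  )
}

# Symmetric Dirichlet(1, ..., 1) draw (uniform on the simplex).
rdirichlet1 <- function(k) {
  w <- -log(stats::runif(k))
  w / sum(w)
}

#' Randomly seeded initial planet state
#'
#' Sets ATM and OCEAN to their caps, CC and MS to ~100 kg, and distributes
#' the remaining BSE P mass over LM, UM and OC with symmetric-Dirichlet
#' (uniform simplex) weights drawn from the seeded RNG. Masses sum exactly
#' to `bse_total`.
#'
#' @param spec A [seed_spec()].
#' @param weights Optional fixed allocation weights over (LM, UM, OC),
#'   bypassing the RNG (used for degenerate-seeding tests).
#' @return A [planet_state()] at t = 0.
#' @examples
#' s <- seed_initial(seed_spec(rng_seed = 42))
#' sum(s$masses) # 8.4e20
#' @export
seed_initial <- function(spec, weights = NULL) {
  caps <- spec$caps
  residual <- spec$bse_total - sum(unlist(caps))
  if (is.null(weights)) {
    set.seed(spec$rng_seed)
    weights <- rdirichlet1(3)
  } else {
    stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0)
    weights <- weights / sum(weights)
  }
  alloc <- residual * weights
  planet_state(c(
    ATM = caps$ATM, OCEAN = caps$OCEAN, CC = caps$CC, MS = caps$MS,
    LM = alloc[1], UM = alloc[2], OC = alloc[3], CORE = 0
  ))
}

#' BSE seed mass implied by a core sequestration fraction
#'
#' The total planetary P inventory is fixed by the reference point that a
#' 90% core share leaves 8.4e20 kg in the BSE (so the total is 8.4e21 kg);
#' alternative core fractions (0.85, 0.95, 0.97) rescale the starting BSE
#' seed as `(1 - core_fraction) * 8.4e21`.
#'
#' @param core_fraction Fraction of planetary P sequestered in the core,
#'   strictly between 0 and 1.
#' @return Initial BSE P seed mass, kg.
#' @examples
#' bse_seed_for_core_fraction(0.97) # 2.52e20
#' @export
bse_seed_for_core_fraction <- function(core_fraction) {
  if (any(core_fraction <= 0 | core_fraction >= 1)) {
    stop("core_fraction must be in (0, 1)", call. = FALSE)
  }
  (1 - core_fraction) * (8.4e20 / 0.10)
}

#' Percent deviation of a final reservoir mass from the modern estimate
#'
#' `100 * (final - modern) / modern`: positive values mean the model
#' overestimates the modern inventory.
#'
#' @param final_mass Modeled final P mass, kg.
#' @param modern_mass Estimated modern P content, kg (> 0).
#' @return Percent deviation.
#' @export
deviation_from_modern <- function(final_mass, modern_mass) {
  if (any(modern_mass <= 0)) {
    stop("deviation_from_modern: modern_mass must be > 0", call. = FALSE)
  }
  100 * (final_mass - modern_mass) / modern_mass
}

#' Time to apparent steady state
#'
#' The earliest time after which a reservoir series stays within
#' `rel_tol` (default 2%) of its final value for the rest of the run;
#' returns the run length if it never settles.
#'
#' @param t Snapshot times, years (strictly increasing).
#' @param x Reservoir P masses at those times, kg.
#' @param rel_tol Relative tolerance defining "steady" (default 0.02).
#' @return Convergence time, years.
#' @examples
#' t <- seq(0, 4.5e9, by = 1e7)
#' convergence_time(t, 5 + exp(-t / 2e8)) # ~ 2e8 * log(1 / (0.02 * 5))
#' @export
convergence_time <- function(t, x, rel_tol = 0.02) {
  if (length(t) == 0 || length(t) != length(x)) {
    stop("convergence_time: empty or mismatched series", call. = FALSE)
  }
  final <- x[length(x)]
  tol <- rel_tol * abs(final)
  ok <- abs(x - final) <= tol
  # earliest index from which `ok` holds for every later snapshot
  from_here <- rev(cumprod(rev(ok))) > 0
  if (!any(from_here)) return(t[length(t)] - t[1])
  t[which(from_here)[1]] - t[1]
}

#' Cumulative mass delivered by a constant flux
#'
#' Back-of-envelope helper: `rate * duration`. Supports order-of-magnitude
#' estimates such as the cumulative seabird-guano transfer from ocean to
#' land (1e8 kg/yr over 2e8 yr ~ 2e16 kg) or the total P delivered by a
#' bombardment episode at its peak flux.
#'
#' @param rate Constant flux, kg yr^-1 (>= 0).
#' @param duration Duration, years (>= 0).
#' @return Total mass, kg.
#' @export
cumulative_constant_flux <- function(rate, duration) {
  stopifnot(all(rate >= 0), all(duration >= 0))
  rate * duration
}

#' Run a randomly seeded ensemble
#'
#' Draws `n` independent initial seedings (per-run RNG seeds derived
#' deterministically from `master_seed`), integrates each over the full run
#' span, and summarizes final reservoir masses, percent deviations from the
#' modern estimates, per-reservoir convergence times and across-run spreads.
#'
#' @param n Number of ensemble members (>= 1; 50 in the main analysis).
#' @param params A [p_params()] object.
#' @param structure A [p_structure()] object.
#' @param master_seed Integer master seed; identical values give
#'   bit-identical ensembles.
#' @param bse_total Initial BSE P seed mass (default from
#'   `params$core_fraction` via [bse_seed_for_core_fraction()]).
#' @param stride Snapshot decimation for the per-run trajectories kept for
#'   convergence diagnostics (default 900, i.e. 4.5 Ma in the main
#'   configuration).
#' @param keep_trajectories Keep the decimated per-run trajectories in the
#'   returned object (default TRUE; needed for convergence times).
#' @return An object of class `p_ensemble`: a list with elements
#'   `summary` (per-reservoir tibble: ensemble-mean final mass, percent
#'   deviation from modern, median convergence time, across-run spread),
#'   `finals` (per run x reservoir tibble), `convergence` (per run x
#'   reservoir tibble), `seeds`, `n`, `master_seed`, and the configuration.
#' @examples
#' \donttest{
#' ens <- run_ensemble(5, p_params(), p_structure(), master_seed = 1)
#' tidy(ens)
#' }
#' @export
run_ensemble <- function(n, params, structure = p_structure(),
                         master_seed = 1L,
                         bse_total = bse_seed_for_core_fraction(params$core_fraction),
                         stride = 900, keep_trajectories = TRUE) {
  stopifnot(n >= 1)
  validate_params(params, structure)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, n)
  sat <- ocean_saturation_mass(params, structure)
  caps <- list(
    ATM = min(2.8e7, params$atm_cap), OCEAN = min(9.3e13, sat),
    CC = 100, MS = 100
  )

  runs <- purrr::map(seeds, function(s) {
    init <- seed_initial(seed_spec(bse_total = bse_total, caps = caps, rng_seed = s))
    traj <- run_simulation(init, params, structure, stride = stride)
    if (max(traj$residual) > 1e-6) {
      stop("run_ensemble: conservation audit failed for seed ", s, call. = FALSE)
    }
    traj
  })

  res_cols <- c(
    ATM = "atm_kg", OCEAN = "ocean_kg", CC = "cc_kg", OC = "oc_kg",
    MS = "ms_kg", UM = "um_kg", LM = "lm_kg"
  )
  finals <- purrr::imap_dfr(runs, function(traj, i) {
    last <- traj[nrow(traj), ]
    tibble::tibble(
      run = i, seed = seeds[i],
      reservoir = names(res_cols),
      final_kg = unlist(last[res_cols], use.names = FALSE)
    )
  })
  convergence <- purrr::imap_dfr(runs, function(traj, i) {
    tibble::tibble(
      run = i, seed = seeds[i],
      reservoir = names(res_cols),
      convergence_yr = vapply(
        res_cols, function(cl) convergence_time(traj$time_yr, traj[[cl]]),
        numeric(1)
      )
    )
  })

  modern <- structure$modern_p
  summary <- finals |>
    dplyr::group_by(.data$reservoir) |>
    dplyr::summarise(
      mean_final_kg = mean(.data$final_kg),
      spread_pct = if (mean(.data$final_kg) > 0) {
        100 * (max(.data$final_kg) - min(.data$final_kg)) / mean(.data$final_kg)
      } else 0,
      .groups = "drop"
    ) |>
    dplyr::left_join(
      convergence |>
        dplyr::group_by(.data$reservoir) |>
        dplyr::summarise(
          convergence_yr = stats::median(.data$convergence_yr),
          .groups = "drop"
        ),
      by = "reservoir"
    ) |>
    dplyr::mutate(
      modern_kg = unname(modern[.data$reservoir]),
      deviation_pct = dplyr::if_else(
        .data$reservoir %in% SOLID_RESERVOIRS,
        deviation_from_modern(.data$mean_final_kg, .data$modern_kg),
        NA_real_
      )
    ) |>
    dplyr::arrange(match(.data$reservoir, RESERVOIRS))

  structure(
    list(
      summary = summary, finals = finals, convergence = convergence,
      trajectories = if (keep_trajectories) runs else NULL,
      seeds = seeds, n = n, master_seed = master_seed,
      bse_total = bse_total, params = params, structure = structure
    ),
    class = "p_ensemble"
  )
}

#' Ensemble-mean percent deviation for one reservoir
#' @param ensemble A `p_ensemble` from [run_ensemble()].
#' @param reservoir Reservoir name (one of [SOLID_RESERVOIRS]).
#' @return Percent deviation of the ensemble-mean final mass from modern.
#' @export
ensemble_deviation <- function(ensemble, reservoir) {
  row <- ensemble$summary[ensemble$summary$reservoir == reservoir, ]
  if (nrow(row) != 1) stop("unknown reservoir '", reservoir, "'", call. = FALSE)
  row$deviation_pct
}

#' Serialize an ensemble summary to JSON
#'
#' Writes the per-reservoir summary plus the reproducibility metadata
#' (package version, master seed, configuration hash) as JSON.
#'
#' @param ensemble A `p_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_summary <- function(ensemble, path) {
  payload <- list(
    package = "phoscycle",
    version = as.character(utils::packageVersion("phoscycle")),
    master_seed = ensemble$master_seed,
    n_runs = ensemble$n,
    bse_total_kg = ensemble$bse_total,
    config_hash = config_hash(ensemble$params, ensemble$structure),
    summary = ensemble$summary
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @export
print.p_ensemble <- function(x, ...) {
  cat(sprintf(
    "<p_ensemble> %d runs, master seed %d, BSE seed %.3g kg\n",
    x$n, x$master_seed, x$bse_total
  ))
  print(x$summary)
  invisible(x)
}
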