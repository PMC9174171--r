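#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory into long reservoir series
#'
#' @param x A `p_trajectory` from [run_simulation()].
#' @param ... Unused.
#' @return Tibble with columns `time_yr`, `reservoir`, `mass_kg`.
#' @method tidy p_trajectory
#' @export
tidy.p_trajectory <- function(x, ...) {
  cols <- c(
    ATM = "atm_kg", OCEAN = "ocean_kg", CC = "cc_kg", OC = "oc_kg",
    MS = "ms_kg", UM = "um_kg", LM = "lm_kg"
  )
  tibble::as_tibble(x[, c("time_yr", unname(cols))]) |>
    tidyr::pivot_longer(-"time_yr",
      names_to = "reservoir", values_to = "mass_kg"
    ) |>
    dplyr::mutate(
      reservoir = names(cols)[match(.data$reservoir, cols)]
    )
}

#' One-row summary of a trajectory
#'
#' @param x A `p_trajectory`.
#' @param ... Unused.
#' @return Tibble with the run span, final reservoir masses, cumulative
#'   extraterrestrial input and maximum conservation residual.
#' @method glance p_trajectory
#' @export
glance.p_trajectory <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(
    span_yr = x$time_yr[n] - x$time_yr[1],
    n_snapshots = n,
    final_cc_kg = x$cc_kg[n], final_ms_kg = x$ms_kg[n],
    final_oc_kg = x$oc_kg[n], final_um_kg = x$um_kg[n],
    final_lm_kg = x$lm_kg[n],
    cum_et_kg = x$cum_et_kg[n],
    max_residual = max(x$residual)
  )
}

#' Tidy an ensemble into its per-reservoir summary
#'
#' @param x A `p_ensemble` from [run_ensemble()].
#' @param ... Unused.
#' @return The per-reservoir summary tibble (mean final mass, percent
#'   deviation from modern, median convergence time, across-run spread).
#' @method tidy p_ensemble
#' @export
tidy.p_ensemble <- function(x, ...) x$summary

#' One-row summary of an ensemble
#'
#' @param x A `p_ensemble`.
#' @param ... Unused.
#' @return Tibble with ensemble size, master seed, BSE seed and the
#'   mantle/crustal median convergence times.
#' @method glance p_ensemble
#' @export
glance.p_ensemble <- function(x, ...) {
  s <- x$summary
  conv <- stats::setNames(s$convergence_yr, s$reservoir)
  tibble::tibble(
    n_runs = x$n,
    master_seed = x$master_seed,
    bse_total_kg = x$bse_total,
    mantle_convergence_yr = stats::median(conv[c("UM", "LM")]),
    crustal_convergence_yr = stats::median(conv[c("CC", "OC", "MS")]),
    max_solid_spread_pct = max(s$spread_pct[s$reservoir %in% SOLID_RESERVOIRS])
  )
}

#' Tidy a sweep result
#'
#' @param x A `p_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return The sweep tibble, unchanged (already tidy).
#' @method tidy p_sweep
#' @export
tidy.p_sweep <- function(x, ...) tibble::as_tibble(x)
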