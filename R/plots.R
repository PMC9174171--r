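#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot reservoir evolution for a single run
#'
#' Log-scale P mass per reservoir against time, with dotted horizontal lines
#' marking the modern estimates. The atmosphere is omitted by default (it is
#' very small and pinned at its cap almost immediately).
#'
#' @param object A `p_trajectory` from [run_simulation()].
#' @param reservoirs Which reservoirs to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot p_trajectory
#' @export
autoplot.p_trajectory <- function(object,
                                  reservoirs = c("LM", "UM", "CC", "OC", "MS", "OCEAN"),
                                  ...) {
  long <- tidy(object) |> dplyr::filter(.data$reservoir %in% reservoirs)
  struct <- attr(object, "structure")
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_yr / 1e9, y = .data$mass_kg, colour = .data$reservoir
  )) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Time (Ga)", y = "Reservoir P mass (kg)", colour = "Reservoir",
      title = "Phosphorus reservoir evolution"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(struct)) {
    modern <- tibble::tibble(
      reservoir = reservoirs,
      mass_kg = unname(struct$modern_p[reservoirs])
    )
    p <- p + ggplot2::geom_hline(
      data = modern,
      ggplot2::aes(yintercept = .data$mass_kg, colour = .data$reservoir),
      linetype = "dotted", alpha = 0.7
    )
  }
  p
}

#' Plot ensemble spread of reservoir trajectories
#'
#' Per-run trajectories (thin lines) for the requested reservoirs across the
#' whole ensemble, on a log mass scale.
#'
#' @param object A `p_ensemble` from [run_ensemble()] with trajectories kept.
#' @param reservoirs Which reservoirs to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot p_ensemble
#' @export
autoplot.p_ensemble <- function(object,
                                reservoirs = c("LM", "UM", "CC", "OC", "MS"),
                                ...) {
  if (is.null(object$trajectories)) {
    stop("ensemble was run with keep_trajectories = FALSE", call. = FALSE)
  }
  long <- purrr::imap_dfr(object$trajectories, function(traj, i) {
    tidy(traj) |> dplyr::mutate(run = i)
  }) |>
    dplyr::filter(.data$reservoir %in% reservoirs)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_yr / 1e9, y = .data$mass_kg,
    colour = .data$reservoir, group = interaction(.data$run, .data$reservoir)
  )) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Time (Ga)", y = "Reservoir P mass (kg)", colour = "Reservoir",
      title = sprintf("Ensemble of %d randomly seeded runs", object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep
#'
#' Ensemble-mean final reservoir mass against the swept parameter value
#' (log x-axis for positive grids), one panel per reservoir.
#'
#' @param object A `p_sweep` from [run_sweep()].
#' @param reservoirs Which reservoirs to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot p_sweep
#' @export
autoplot.p_sweep <- function(object,
                             reservoirs = c("LM", "UM", "CC", "OC", "MS"),
                             ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::filter(.data$reservoir %in% reservoirs)
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$value, y = .data$mean_final_kg
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~reservoir, scales = "free_y") +
    ggplot2::labs(
      x = unique(dat$parameter), y = "Ensemble-mean final P mass (kg)",
      title = "One-at-a-time parameter sweep"
    ) +
    ggplot2::theme_minimal()
  if (all(dat$value > 0) && max(dat$value) / min(dat$value) > 100) {
    p <- p + ggplot2::scale_x_log10()
  }
  p
}
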