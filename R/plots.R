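# ggplot2 views of experiment output. These are working plots for inspecting
# sweeps, not publication figures; smoothing choices are left to the caller.

#' Plot structural and dynamical metrics against TIM frequency
#'
#' One panel per metric, per-condition means over replicates, coloured by
#' distribution model.
#'
#' @param records a `structure_records` tibble from
#'   [run_structure_experiment()].
#' @param metrics metric columns to display.
#' @return a ggplot object.
#' @export
plot_structure_metrics <- function(records,
                                   metrics = c(
                                     "connectance_A", "connectance_C",
                                     "variance_C", "degree_heterogeneity",
                                     "pairwise_correlation", "cov_BC"
                                   )) {
  metrics <- intersect(metrics, names(records))
  long <- records |>
    dplyr::select(dplyr::all_of(c("model", "lambda", metrics))) |>
    tidyr::pivot_longer(dplyr::all_of(metrics),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data$model, .data$lambda, .data$metric) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$lambda, .data$value, colour = .data$model)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "TIMs per species (lambda)", y = NULL, colour = "model"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_structure_metrics
#' @param object,... autoplot interface (`object` is the records tibble).
#' @export
autoplot.structure_records <- function(object, ...) {
  plot_structure_metrics(object, ...)
}

#' Plot critical strength against diversity
#'
#' Critical interaction strength (log scale) as a function of species count,
#' one line per scenario — the diversity-stability relationship under each
#' HOI distribution.
#'
#' @param records an `hoi_records` tibble from [run_hoi_experiment()].
#' @return a ggplot object.
#' @export
plot_critical_strength <- function(records) {
  ggplot2::ggplot(
    records,
    ggplot2::aes(
      .data$N, .data$critical_strength,
      colour = .data$scenario, group = .data$scenario
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "species count (N)", y = "critical strength", colour = "scenario"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_critical_strength
#' @param object,... autoplot interface (`object` is the records tibble).
#' @export
autoplot.hoi_records <- function(object, ...) {
  plot_critical_strength(object)
}
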