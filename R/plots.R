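#' Two-channel dot plot of gated events
#'
#' Expression reporter (x) against the functional readout (y) on log-log
#' axes, colored by expression level, with the gate boundaries drawn and a
#' dashed line at the GFP-negative baseline LC3 intensity.
#'
#' @param events Event table.
#' @param gate A [gate_config()].
#' @param max_points Downsample cap for plotting (default 20000).
#' @return A ggplot.
#' @export
plot_defac_dotplot <- function(events, gate, max_points = 20000L) {
  ev <- events |>
    exclude_dead(gate$viability_threshold) |>
    assign_levels(gate)
  baseline <- geometric_mfi(ev$lc3[ev$level == 0L])
  if (nrow(ev) > max_points) {
    ev <- ev[sort(sample.int(nrow(ev), max_points)), ]
  }
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$gfp, y = .data$lc3,
                                   colour = factor(.data$level))) +
    ggplot2::geom_point(alpha = 0.25, size = 0.4) +
    ggplot2::geom_vline(xintercept = gate$gfp_boundaries,
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_hline(yintercept = baseline, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "GFP intensity (a.u.)", y = "LC3 intensity (a.u.)",
                  colour = "Level") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.defac_tbl <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$level),
                                  y = .data$flux_mean,
                                  fill = factor(.data$level))) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$flux_mean - .data$flux_sd,
                   ymax = .data$flux_mean + .data$flux_sd),
      width = 0.25
    ) +
    ggplot2::labs(x = "GFP expression level", y = "LC3 flux (%)") +
    ggplot2::theme_minimal()
}

#' Stability-vs-GAG scatter of screen results
#'
#' The triage plane: stability reporter ratio (x) against the
#' cell-number-adjusted GAG reporter ratio (y), with the hit quadrant
#' delimited by the configured thresholds and the vehicle reference point
#' at (1, 1).
#'
#' @param results Normalized screen results (e.g. `run_funnel(...)$results`).
#' @param config A [screen_config()] providing the threshold lines.
#' @return A ggplot.
#' @export
plot_screen_scatter <- function(results, config = screen_config()) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$vps33a_ratio, y = .data$sdc1_cellnorm)) +
    ggplot2::geom_point(ggplot2::aes(colour = dplyr::coalesce(.data$dual_hit, FALSE)),
                        alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = config$vps33a_min, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = config$gag_max, linetype = "dashed") +
    ggplot2::annotate("point", x = 1, y = 1, colour = "darkgreen", size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red"),
                                 name = "dual hit") +
    ggplot2::labs(x = "VPS33A stability ratio (drug / vehicle)",
                  y = "GAG reporter ratio (cell-adjusted)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.screen_funnel <- function(object, ...) {
  rep <- as_tibble(object$report)
  d <- tibble(
    stage = factor(c("library", rep$stage_name),
                   levels = c("library", rep$stage_name)),
    n = c(rep$n_in[1L], rep$n_retained)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "drugs retained") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.decay_fit <- function(object, ...) {
  pts <- object$fitted
  grid <- tibble(time_h = seq(0, max(pts$time_h), length.out = 100))
  grid$value <- object$intercept * exp(-object$rate_k * grid$time_h)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "time after translation block (h)",
                  y = "remaining protein (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
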