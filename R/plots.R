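#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Two-panel view of an invasion trajectory: compartment abundances on a
#' log-friendly free scale, and the female/adult infected fractions with
#' the 90% establishment line.
#'
#' @param object A `wolb_traj` tibble from [simulate_invasion()] or
#'   [run_release()].
#' @param compartments Which compartments to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wolb_traj <- function(object,
                               compartments = c("Fu", "Fw", "Lu", "Lw"),
                               ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object),
                  dplyr::all_of(c("t", compartments,
                                  "frac_female", "frac_adult"))),
    cols = -"t", names_to = "series", values_to = "value"
  )
  long$panel <- ifelse(long$series %in% c("frac_female", "frac_adult"),
                       "infected fraction", "abundance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a bifurcation scan
#'
#' Draws the backward-bifurcation diagram in the `(R0, female infected
#' fraction)` plane: the stable branches at fractions 0 and 1 and the
#' unstable threshold branch between them for `R0 < 1`.
#'
#' @param scan A tibble from [bifurcation_scan()].
#' @return A ggplot object.
#' @export
plot_bifurcation <- function(scan) {
  branches <- dplyr::bind_rows(
    tibble::tibble(R0 = scan$R0, fraction = scan$dfe_fraction,
                   stability = scan$dfe_stability, branch = "disease-free"),
    tibble::tibble(R0 = scan$R0, fraction = scan$cie_fraction,
                   stability = scan$cie_stability,
                   branch = "complete infection"),
    tibble::tibble(R0 = scan$R0, fraction = scan$threshold_fraction,
                   stability = "unstable", branch = "threshold")
  )
  branches <- branches[!is.na(branches$fraction) &
                         !is.na(branches$stability), ]
  ggplot2::ggplot(branches,
                  ggplot2::aes(x = .data$R0, y = .data$fraction,
                               group = .data$branch,
                               linetype = .data$stability)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(stable = "solid",
                                              unstable = "dashed",
                                              marginal = "dotted")) +
    ggplot2::labs(x = expression(R[0]),
                  y = "female infected fraction at equilibrium") +
    ggplot2::theme_minimal()
}

#' Heatmap of establishment times over release sizes and batch counts
#'
#' @param grid A tibble from [batch_grid()].
#' @return A ggplot object.
#' @export
plot_batch_grid <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$n_batches, y = .data$size,
                                     fill = .data$days_to_90)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "number of release batches",
                  y = "total release size (x wild females at DFE)",
                  fill = "days to 90%") +
    ggplot2::theme_minimal()
}

#' Plot a seasonal forcing multiplier over one year
#'
#' @param forcing A [fit_seasonal_curve()] object.
#' @return A ggplot object.
#' @export
plot_forcing <- function(forcing) {
  tt <- seq(0, 365, by = 0.5)
  df <- tibble::tibble(day = tt, s = forcing_multiplier(forcing, tt))
  months <- tibble::tibble(
    day = (seq_len(12) - 0.5) * 365 / 12,
    value = forcing$monthly_values /
      mean(forcing$monthly_values)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$s)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = months,
                        ggplot2::aes(y = .data$value), shape = 1) +
    ggplot2::labs(x = "day of year",
                  y = "carrying-capacity multiplier s(t)") +
    ggplot2::theme_minimal()
}
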