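# ggplot2 figures for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_hline facet_wrap labs theme_minimal scale_fill_manual
#' @export
ggplot2::autoplot

#' Plot binned environment series
#'
#' Line plot of the binned, station-pooled environment variables over
#' time, faceted by variable.
#'
#' @param binned Output of [bin_and_average()].
#' @return A ggplot object.
#' @export
plot_environment <- function(binned) {
  ggplot(binned, aes(x = .data$bin_start, y = .data$mean)) +
    geom_line(linewidth = 0.3, na.rm = TRUE) +
    facet_wrap(~ .data$variable, scales = "free_y", ncol = 1) +
    labs(x = NULL, y = NULL,
         title = "Binned environment series (station-pooled, outlier-filtered)") +
    theme_minimal()
}

#' Plot a per-bin contrast series with its significant area
#'
#' Bars above the axis mark bins where the first arm ran higher, bars
#' below where the second arm ran higher; significant bins (p <= alpha)
#' are filled by sign, non-significant bins in grey - the visual
#' counterpart of the signed significant-area (aau) summary.
#'
#' @param object A `delta_series` from [delta_tleaf_series()] or
#'   [swc_contrast()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot delta_series
#' @export
autoplot.delta_series <- function(object, ...) {
  df <- object |>
    mutate(class = dplyr::case_when(
      .data$significant & .data$delta > 0 ~ "significant, positive",
      .data$significant & .data$delta < 0 ~ "significant, negative",
      TRUE ~ "not significant"
    ))
  ggplot(df, aes(x = .data$das, y = .data$delta, fill = .data$class)) +
    geom_col(width = 0.02) +
    geom_hline(yintercept = 0, linewidth = 0.2) +
    scale_fill_manual(values = c(
      "significant, positive" = "#2166ac",
      "significant, negative" = "#b2182b",
      "not significant" = "grey80"
    )) +
    labs(x = "days after sowing", y = "per-bin difference",
         fill = NULL) +
    theme_minimal()
}

#' Plot a PCoA ordination
#'
#' @param object A [pcoa_ordination()] result.
#' @param colour Optional vector of sample groupings (recycled against
#'   the score rows) used for point colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcoa_ord
#' @export
autoplot.pcoa_ord <- function(object, colour = NULL, ...) {
  df <- object$scores
  expl <- object$explained
  if (!is.null(colour)) df$group <- colour
  p <- if (is.null(colour)) {
    ggplot(df, aes(x = .data$Axis1, y = .data$Axis2))
  } else {
    ggplot(df, aes(x = .data$Axis1, y = .data$Axis2, colour = .data$group))
  }
  p + geom_point(size = 2) +
    labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * expl[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * expl[2]),
      colour = NULL
    ) +
    theme_minimal()
}

#' Plot daily sap-flow window means by arm
#'
#' Point-and-line display of the per-day window means of the two
#' inoculation arms with the star code of the daily test.
#'
#' @param windows Output of [daily_window_compare()].
#' @return A ggplot object.
#' @export
plot_sapflow_windows <- function(windows) {
  long <- windows |>
    tidyr::pivot_longer(c("mean_inoc", "mean_uninoc"),
                        names_to = "arm", values_to = "mean") |>
    mutate(arm = if_else(.data$arm == "mean_inoc", "inoculated", "uninoculated"))
  ggplot(long, aes(x = .data$das, y = .data$mean, colour = .data$arm)) +
    geom_line() + geom_point() +
    ggplot2::geom_text(
      data = windows, inherit.aes = FALSE,
      aes(x = .data$das, y = pmax(.data$mean_inoc, .data$mean_uninoc),
          label = .data$stars),
      vjust = -0.5
    ) +
    labs(x = "days after sowing", y = "window mean sap flow (g H2O/h)",
         colour = NULL) +
    theme_minimal()
}
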