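# Plant-level time-series analyses: 30-min aggregation with replicate
# outlier removal, the per-bin leaf-temperature contrast and its signed
# significant-area (aau) summary, Granier sap-flow conversion,
# daily-transpiration-window comparisons, and SWC contrasts.

#' Aggregate plant sensor records into 30-min treatment-cell bins
#'
#' Within each clock-aligned bin, each plant contributes the mean of its
#' raw points; the Tukey IQR filter is then applied across the replicate
#' values of each treatment cell (hybrid x inoculation x regime), and the
#' mean of the retained replicates is reported alongside the retained
#' values themselves (needed for the per-bin tests downstream).
#'
#' @param data Plant sensor tibble with `timestamp`, `plant_id`, `hybrid`,
#'   `inoculated`, `regime` and the value column.
#' @param value Column to aggregate (tidy-eval), e.g. `tleaf_c`.
#' @param width_min Bin width in minutes.
#' @param k Tukey fence multiplier.
#' @return Tibble with one row per (cell, bin): treatment labels,
#'   `bin_start`, `das`, `mean`, `sd`, `n_retained`, `n_removed`, and a
#'   `values` list-column of retained replicate values.
#' @export
aggregate_plant_series <- function(data, value, width_min = 30, k = 1.5) {
  needed <- c("timestamp", "plant_id", "hybrid", "inoculated", "regime")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("schema error: missing column '%s'", missing_cols[1]))
  }
  if (1440 %% width_min != 0) abort("invalid width: bin width must divide 24 hours")
  if (!is.logical(data$inoculated)) {
    abort("schema error: 'inoculated' must be logical")
  }
  if (!all(data$regime %in% c("WW", "DS", "SDS"))) {
    abort("schema error: unknown irrigation regime label")
  }
  plant_means <- data |>
    mutate(bin_start = lubridate::floor_date(.data$timestamp,
                                             unit = lubridate::minutes(width_min))) |>
    group_by(.data$hybrid, .data$inoculated, .data$regime, .data$bin_start,
             .data$plant_id) |>
    summarise(value = mean({{ value }}), .groups = "drop")
  plant_means |>
    group_by(.data$hybrid, .data$inoculated, .data$regime, .data$bin_start) |>
    summarise(tukey_bin_summary(.data$value, k = k), .groups = "drop") |>
    mutate(
      das = as.numeric(difftime(.data$bin_start, .sowing_origin(), units = "days")),
      width_min = width_min,
      .after = "bin_start"
    )
}

# Shared per-bin two-arm engine: joins two aggregated series on bin_start,
# computes delta = mean(a) - mean(b), a per-bin two-sample p-value and the
# significance flag.  Bins with < 2 retained replicates in either arm are
# untestable: flag FALSE, p missing.
two_arm_bin_contrast <- function(a, b, alpha = 0.05,
                                 test = c("welch", "mannwhitney"),
                                 adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (!setequal(a$bin_start, b$bin_start)) {
    abort("alignment error: the two series cover different bins")
  }
  j <- inner_join(
    a |> select("bin_start", das_a = "das", mean_a = "mean", sd_a = "sd",
                n_a = "n_retained", values_a = "values"),
    b |> select("bin_start", mean_b = "mean", sd_b = "sd",
                n_b = "n_retained", values_b = "values"),
    by = "bin_start"
  ) |> arrange(.data$bin_start)
  testable <- j$n_a >= 2 & j$n_b >= 2
  p <- rep(NA_real_, nrow(j))
  if (test == "welch") {
    p[testable] <- welch_from_stats(
      j$mean_a[testable], j$sd_a[testable], j$n_a[testable],
      j$mean_b[testable], j$sd_b[testable], j$n_b[testable]
    )
  } else {
    p[testable] <- purrr::map2_dbl(
      j$values_a[testable], j$values_b[testable],
      function(x, y) suppressWarnings(wilcox.test(x, y)$p.value)
    )
  }
  if (adjust == "BH") p <- p.adjust(p, method = "BH")
  out <- tibble(
    bin_start = j$bin_start,
    das = j$das_a,
    delta = j$mean_a - j$mean_b,
    n_a = j$n_a, n_b = j$n_b,
    p_value = p,
    testable = testable,
    significant = testable & !is.na(p) & p <= alpha
  )
  structure(out, class = c("delta_series", class(out)),
            alpha = alpha, test = test,
            width_min = attr(a, "width_min", exact = TRUE) %||%
              (a$width_min[1] %||% 30))
}

#' Per-bin leaf-temperature contrast between inoculation arms
#'
#' Computes the binned leaf-temperature difference `delta = mean(T_leaf,
#' inoculated) - mean(T_leaf, uninoculated)` with a per-bin two-sample
#' test at level `alpha`.  Positive values mean inoculated plants ran
#' hotter; negative values mean uninoculated plants ran hotter.  The
#' default per-bin test is the Welch two-sample t-test (with four
#' replicates per arm an exact rank test cannot go below p = 0.0286);
#' the Mann-Whitney test is available via `test = "mannwhitney"`.  No
#' multiple-testing correction is applied across bins by default; set
#' `adjust = "BH"` for a Benjamini-Hochberg sensitivity analysis.
#'
#' @param inoculated,uninoculated Aggregated series for the two arms, as
#'   returned by [aggregate_plant_series()] (a single treatment cell each,
#'   aligned on the same bins).
#' @param alpha Per-bin significance level.
#' @param test `"welch"` or `"mannwhitney"`.
#' @param adjust `"none"` (default, per-bin) or `"BH"`.
#' @return A `delta_series` tibble: `bin_start`, `das`, `delta`, per-arm
#'   replicate counts, `p_value`, `testable`, `significant`.
#' @export
delta_tleaf_series <- function(inoculated, uninoculated, alpha = 0.05,
                               test = c("welch", "mannwhitney"),
                               adjust = c("none", "BH")) {
  two_arm_bin_contrast(inoculated, uninoculated, alpha = alpha, test = test,
                       adjust = adjust)
}

#' Signed significant-area summary of a binned contrast
#'
#' Integrates the per-bin contrast over significant bins only, split by
#' sign, in "arbitrary area units" (aau): 1 aau = 1 degC persisting for
#' one 30-min bin (rectangle integration, no contiguity requirement).
#' `pos_area` collects significant bins with positive delta (inoculated
#' hotter), `neg_area` those with negative delta (uninoculated hotter).
#' Untestable bins count toward `n_bins` but never toward
#' `n_significant`, keeping the bin denominator purely temporal.
#'
#' @param delta A `delta_series` from [delta_tleaf_series()] or
#'   [swc_contrast()].
#' @param width_min Bin width in minutes (taken from the series when
#'   available).
#' @return One-row tibble: `pos_area`, `neg_area`, `n_bins`,
#'   `n_significant`, `pct_significant` (percent, rounded to 1 decimal).
#' @export
significant_area_summary <- function(delta, width_min = NULL) {
  if (nrow(delta) == 0) abort("empty delta series")
  width_min <- width_min %||% attr(delta, "width_min", exact = TRUE) %||% 30
  scale <- width_min / 30
  sig <- delta$significant
  tibble(
    pos_area = sum(delta$delta[sig & delta$delta > 0]) * scale,
    neg_area = -sum(delta$delta[sig & delta$delta < 0]) * scale,
    n_bins = nrow(delta),
    n_significant = sum(sig),
    pct_significant = round(100 * sum(sig) / nrow(delta), 1)
  )
}

#' Granier heat-dissipation calibration
#'
#' Calibration constants for converting the thermal-dissipation probe
#' signal to sap flow.  Defaults are the classic heat-dissipation
#' constants `alpha = 119e-6` m3 m-2 s-1 and `beta = 1.231`; the flow
#' index is `K = (dT_max - dT) / dT` with `dT_max` the no-flow reference
#' temperature difference.
#'
#' @param delta_t_max No-flow reference temperature difference, degC.
#' @param alpha Flux-density coefficient, m3 m-2 s-1.
#' @param beta Flux-density exponent.
#' @param sapwood_area_cm2 Conducting sapwood cross-section, cm2.
#' @return An object of class `granier_calibration`.
#' @export
granier_calibration <- function(delta_t_max, alpha = 119e-6, beta = 1.231,
                                sapwood_area_cm2 = 1) {
  if (delta_t_max <= 0) abort("invalid calibration: delta_t_max must be > 0")
  if (alpha <= 0 || beta <= 0 || sapwood_area_cm2 <= 0) {
    abort("invalid calibration: alpha, beta and sapwood area must be > 0")
  }
  structure(list(delta_t_max = delta_t_max, alpha = alpha, beta = beta,
                 sapwood_area_cm2 = sapwood_area_cm2),
            class = "granier_calibration")
}

#' Convert a thermal-dissipation signal to sap flow
#'
#' Applies the Granier heat-dissipation model: the flow index
#' `K = (dT_max - dT) / dT` feeds the flux density `u = alpha * K^beta`
#' (m3 m-2 s-1), which times the sapwood area and the density of water
#' gives flow in g H2O h-1.  `K = 0` (probe at the no-flow reference)
#' gives zero flow, and flow increases monotonically in `K`.
#'
#' @param delta_t Probe temperature difference, degC, in `(0, dT_max]`.
#' @param calibration A [granier_calibration()].
#' @return Sap flow in g H2O h-1.
#' @examples
#' cal <- granier_calibration(delta_t_max = 10)
#' granier_sap_flow(5, cal) # K = 1 -> 42.84 g/h with defaults
#' @export
granier_sap_flow <- function(delta_t, calibration) {
  stopifnot(inherits(calibration, "granier_calibration"))
  if (any(delta_t <= 0 | delta_t > calibration$delta_t_max, na.rm = TRUE)) {
    abort("sensor-range error: delta_t must lie in (0, delta_t_max]")
  }
  k <- (calibration$delta_t_max - delta_t) / delta_t
  flux <- calibration$alpha * k^calibration$beta # m3 m-2 s-1
  flux * calibration$sapwood_area_cm2 * 1e-4 * 1e6 * 3600
}

#' Compare two arms within daily transpiration windows
#'
#' For each day, averages each plant's in-window values (default window
#' 10:00-16:00, when transpiration is maximal) and runs a two-sample test
#' between the inoculated and uninoculated arms, reporting the star code
#' of the smallest passed threshold (`*` p <= 0.05, `**` p <= 0.01,
#' `***` p <= 0.001).
#'
#' @param data Plant sensor tibble (`timestamp` or `das`, `plant_id`,
#'   `inoculated`, value column).
#' @param value Column to analyse (tidy-eval), e.g. `sapflow`.
#' @param window Two "HH:MM" strings; the half-open daily window
#'   `[start, end)`.
#' @param days Optional integer DAS vector restricting the days analysed.
#' @param alpha_levels Thresholds for the star codes.
#' @param test `"welch"` or `"mannwhitney"`.
#' @return Tibble per day: `das`, per-arm n and window means, `p_value`,
#'   `stars`.
#' @export
daily_window_compare <- function(data, value, window = c("10:00", "16:00"),
                                 days = NULL,
                                 alpha_levels = c(0.05, 0.01, 0.001),
                                 test = c("welch", "mannwhitney")) {
  test <- match.arg(test)
  w <- parse_clock(window)
  if (w[2] <= w[1] || w[2] > 24) abort("invalid window: need start < end within one day")
  if (!"das" %in% names(data)) {
    data <- data |> mutate(das = as.numeric(difftime(.data$timestamp,
                                                     .sowing_origin(),
                                                     units = "days")))
  }
  windowed <- data |>
    mutate(day = floor(.data$das), hour = (.data$das - .data$day) * 24) |>
    filter(.data$hour >= w[1], .data$hour < w[2])
  if (!is.null(days)) windowed <- windowed |> filter(.data$day %in% days)
  if (nrow(windowed) == 0) abort("invalid window: no observations in window")
  plant_day <- windowed |>
    group_by(.data$day, .data$inoculated, .data$plant_id) |>
    summarise(value = mean({{ value }}), .groups = "drop")
  plant_day |>
    group_by(das = .data$day) |>
    summarise(
      n_inoc = sum(.data$inoculated),
      n_uninoc = sum(!.data$inoculated),
      mean_inoc = mean(.data$value[.data$inoculated]),
      mean_uninoc = mean(.data$value[!.data$inoculated]),
      p_value = two_sample_p(.data$value[.data$inoculated],
                             .data$value[!.data$inoculated], test = test),
      .groups = "drop"
    ) |>
    mutate(stars = star_code(.data$p_value, alpha_levels))
}

#' Soil-water-content contrast between irrigation regimes
#'
#' Applies the same per-bin two-sample machinery as
#' [delta_tleaf_series()] to aggregated SWC series, with
#' `delta = mean(DS) - mean(WW)` (negative when drought-stressed pots are
#' drier).
#'
#' @param ds,ww Aggregated SWC series for the DS and WW cells, from
#'   [aggregate_plant_series()].
#' @param period Optional `c(start, end)` DAS range restricting the bins.
#' @inheritParams delta_tleaf_series
#' @return A `delta_series` tibble.
#' @export
swc_contrast <- function(ds, ww, period = NULL, alpha = 0.05,
                         test = c("welch", "mannwhitney"),
                         adjust = c("none", "BH")) {
  if (!is.null(period)) {
    ds <- ds |> filter(.data$das >= period[1], .data$das < period[2])
    ww <- ww |> filter(.data$das >= period[1], .data$das < period[2])
  }
  two_arm_bin_contrast(ds, ww, alpha = alpha, test = test, adjust = adjust)
}
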