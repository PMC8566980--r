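# Environmental sensor processing: lux-to-PAR conversion, Arden-Buck VPD,
# Tukey IQR outlier removal, and 30-min binning with station pooling.

#' Convert illuminance to photosynthetically active radiation
#'
#' Applies the fixed greenhouse correction factor 0.0185 to convert lux to
#' PAR in umol m-2 s-1.
#'
#' @param lux Non-negative illuminance values (lux).
#' @return PAR, same length as `lux`.
#' @examples
#' lux_to_par(1000) # 18.5
#' @export
lux_to_par <- function(lux) {
  if (any(lux < 0, na.rm = TRUE)) abort("domain error: lux must be non-negative")
  0.0185 * lux
}

#' Vapor-pressure deficit via the Arden-Buck equation
#'
#' VPD (kPa) is the gap between saturation and actual vapor pressure,
#' computed as `(1 - RH/100) * 0.61121 * exp(17.502 * T / (240.97 + T))`
#' with air temperature `T` in degC and relative humidity `RH` in percent.
#' VPD is zero exactly at saturation (RH = 100), decreases in RH at fixed
#' temperature and increases in temperature at fixed RH < 100.
#'
#' @param temp_c Air temperature, degC (must exceed -240.97).
#' @param rh_pct Relative humidity, percent in [0, 100].
#' @return VPD in kPa, same length as the inputs.
#' @examples
#' vpd_arden_buck(25, 50)
#' @export
vpd_arden_buck <- function(temp_c, rh_pct) {
  if (any(rh_pct < 0 | rh_pct > 100, na.rm = TRUE)) {
    abort("domain error: relative humidity must be within [0, 100]")
  }
  if (any(temp_c <= -240.97, na.rm = TRUE)) {
    abort("domain error: temperature at or below -240.97 degC")
  }
  (1 - rh_pct / 100) * 0.61121 * exp(17.502 * temp_c / (240.97 + temp_c))
}

#' Tukey interquartile-range outlier filter
#'
#' Partitions a vector into retained and removed values using Tukey's
#' fences: points outside `[Q1 - k*IQR, Q3 + k*IQR]` are removed.
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7), and the conventional fence multiplier is
#' `k = 1.5`.
#'
#' @param x Numeric vector with at least one non-missing value.
#' @param k Fence multiplier.
#' @return List with components `retained` and `removed`; together they
#'   partition the input (missing values are dropped and counted as
#'   removed).
#' @examples
#' tukey_iqr_filter(c(1, 2, 3, 4, 100))$removed # 100
#' @export
tukey_iqr_filter <- function(x, k = 1.5) {
  if (length(x) == 0) abort("empty input: no values to filter")
  missing <- x[is.na(x)]
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("empty input: all values missing")
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  keep <- x >= lo & x <= hi
  list(retained = x[keep], removed = c(x[!keep], missing))
}

# One-row summary used inside grouped binning.
tukey_bin_summary <- function(x, k = 1.5) {
  if (all(is.na(x))) {
    return(tibble(mean = NA_real_, sd = NA_real_, n_retained = 0L,
                  n_removed = length(x), values = list(numeric(0))))
  }
  f <- tukey_iqr_filter(x, k)
  tibble(
    mean = if (length(f$retained) > 0) mean(f$retained) else NA_real_,
    sd = if (length(f$retained) > 1) sd(f$retained) else NA_real_,
    n_retained = length(f$retained),
    n_removed = length(f$removed),
    values = list(f$retained)
  )
}

#' Derive PAR and VPD columns for environment records
#'
#' Adds `par` (from `lux`) and `vpd` (from `temp_c` and `rh_pct`) to a
#' station log.
#'
#' @param data Tibble with `temp_c`, `rh_pct` and `lux` columns.
#' @return The input with `par` and `vpd` columns appended.
#' @export
derive_env_variables <- function(data) {
  data |>
    mutate(
      par = lux_to_par(.data$lux),
      vpd = vpd_arden_buck(.data$temp_c, .data$rh_pct)
    )
}

#' Bin environment records and average across stations
#'
#' Pools the raw points of all stations falling into each clock-aligned
#' bin (half-open `[start, start + width)` intervals starting at 00:00),
#' removes outliers per bin with the Tukey IQR filter, and reports the
#' mean of the retained points.  Bins in which every point was removed, or
#' with no data at all, are emitted with a missing mean - never as zero.
#'
#' @param data Tibble of environment records with a `timestamp` column
#'   (POSIXct) and the sensor variables.
#' @param vars Character vector of variable columns to bin (default: the
#'   standard channels present in `data`).
#' @param width_min Bin width in minutes; must divide 24 h.
#' @param k Tukey fence multiplier passed to [tukey_iqr_filter()].
#' @param fill_gaps If `TRUE`, emit missing bins for gaps in the record.
#' @return Tibble with `bin_start`, `width_min`, `variable`, `mean`,
#'   `n_retained`, `n_removed`.
#' @export
bin_and_average <- function(data, vars = NULL, width_min = 30, k = 1.5,
                            fill_gaps = TRUE) {
  if (1440 %% width_min != 0) {
    abort("invalid width: bin width must divide 24 hours")
  }
  if (is.null(vars)) {
    vars <- intersect(c("temp_c", "rh_pct", "lux", "par", "vpd"), names(data))
  }
  long <- data |>
    tidyr::pivot_longer(all_of(vars), names_to = "variable", values_to = "value") |>
    mutate(bin_start = lubridate::floor_date(.data$timestamp,
                                             unit = lubridate::minutes(width_min)))
  out <- long |>
    group_by(.data$variable, .data$bin_start) |>
    summarise(tukey_bin_summary(.data$value, k = k), .groups = "drop") |>
    select(-"values", -"sd")
  if (fill_gaps && nrow(out) > 0) {
    grid <- tidyr::expand_grid(
      variable = unique(out$variable),
      bin_start = seq(min(out$bin_start), max(out$bin_start), by = 60 * width_min)
    )
    out <- grid |>
      left_join(out, by = c("variable", "bin_start")) |>
      mutate(
        n_retained = tidyr::replace_na(.data$n_retained, 0L),
        n_removed = tidyr::replace_na(.data$n_removed, 0L)
      )
  }
  out |>
    mutate(width_min = width_min, .after = "bin_start") |>
    arrange(.data$variable, .data$bin_start)
}
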