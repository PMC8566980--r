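#' Define the greenhouse experiment layout
#'
#' Describes the factorial structure of the phenotyping experiment: maize
#' hybrids crossed with SynCom inoculation (inoculated / uninoculated) and
#' irrigation regime (well-watered `WW` / drought-stressed `DS`), together
#' with the sensor cadences and the drought window.  Defaults reproduce the
#' reference greenhouse trial: three commercial hybrids, four biological
#' replicates per treatment cell, plant sensors every 5 min, four
#' environment stations every 15 min, drought between 50 and 80 days after
#' sowing (DAS) with rehydration at 80 DAS, and harvest at 117 DAS.
#'
#' @param hybrids Character vector of hybrid (genotype) labels.
#' @param replicates_per_cell Plants per treatment cell carrying sensors.
#' @param plant_cadence_min Plant sensor logging interval, minutes.
#' @param env_cadence_min Environment station logging interval, minutes.
#' @param n_stations Number of environment stations.
#' @param ds_window Two-element numeric, first and last DAS of the reduced
#'   irrigation period.
#' @param rehydration_das Day after sowing at which full irrigation resumes.
#' @param duration_das Experiment length in days (sowing = 0).
#'
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design()
#' @export
experiment_design <- function(hybrids = c("DKB177", "SX7341", "P3707VYH"),
                              replicates_per_cell = 4,
                              plant_cadence_min = 5,
                              env_cadence_min = 15,
                              n_stations = 4,
                              ds_window = c(50, 80),
                              rehydration_das = 80,
                              duration_das = 117) {
  if (duration_das <= 0) abort("invalid design: duration_das must be positive")
  if (plant_cadence_min <= 0 || env_cadence_min <= 0) {
    abort("invalid design: cadences must be positive")
  }
  if (30 %% plant_cadence_min != 0 || 30 %% env_cadence_min != 0) {
    abort("invalid design: cadences must divide 30 minutes")
  }
  if (length(ds_window) != 2 || ds_window[1] >= ds_window[2]) {
    abort("invalid design: ds_window must be an increasing [start, end] pair")
  }
  if (ds_window[2] > duration_das) {
    abort("invalid design: ds_window must end within the experiment")
  }
  if (replicates_per_cell < 2) {
    abort("invalid design: at least 2 replicates per cell are required")
  }
  if (n_stations < 1) abort("invalid design: need at least one station")
  structure(
    list(
      hybrids = hybrids,
      replicates_per_cell = as.integer(replicates_per_cell),
      plant_cadence_min = as.integer(plant_cadence_min),
      env_cadence_min = as.integer(env_cadence_min),
      n_stations = as.integer(n_stations),
      ds_window = as.numeric(ds_window),
      rehydration_das = as.numeric(rehydration_das),
      duration_das = as.numeric(duration_das)
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>\n")
  cat("  hybrids:            ", paste(x$hybrids, collapse = ", "), "\n")
  cat("  treatment cells:    ", length(x$hybrids) * 4, " (hybrid x inoculation x regime)\n", sep = "")
  cat("  replicates/cell:    ", x$replicates_per_cell, "\n")
  cat("  plant cadence:      ", x$plant_cadence_min, "min\n")
  cat("  env cadence:        ", x$env_cadence_min, "min x", x$n_stations, "stations\n")
  cat("  drought window:     DAS", x$ds_window[1], "-", x$ds_window[2],
      "(rehydration at", x$rehydration_das, ")\n")
  cat("  duration:           ", x$duration_das, "DAS\n")
  invisible(x)
}

# Treatment cells of a design as a tibble.
design_cells <- function(design) {
  tidyr::expand_grid(
    hybrid = design$hybrids,
    inoculated = c(TRUE, FALSE),
    regime = c("WW", "DS")
  )
}

default_grain_means <- function() {
  tibble(
    hybrid = rep(c("DKB177", "SX7341", "P3707VYH"), each = 4),
    regime = rep(c("WW", "WW", "DS", "DS"), 3),
    inoculated = rep(c(TRUE, FALSE), 6),
    mean_g = c(
      120, 120, 38.7, 9.8,
      110, 110, 20, 18,
      115, 115, 42.7, 12.4
    )
  )
}

default_flowering_probs <- function() {
  tibble(
    hybrid = rep(c("DKB177", "SX7341", "P3707VYH"), each = 4),
    regime = rep(c("WW", "WW", "DS", "DS"), 3),
    inoculated = rep(c(TRUE, FALSE), 6),
    p_anthesis = c(
      1, 1, 0.80, 0.59,
      1, 1, 0.95, 0.95,
      1, 1, 0.95, 0.95
    ),
    p_silking = c(
      1, 1, 0.86, 0.61,
      1, 1, 0.95, 0.95,
      1, 1, 0.75, 0.60
    )
  )
}

#' Simulation parameters for the synthetic greenhouse experiment
#'
#' Bundles the knobs of the synthetic-data generator in four blocks:
#' diurnal environment, plant physiological response, OTU count table, and
#' yield/phenology.  Defaults encode the conditions of the reference trial
#' where the trial states them (e.g. the drought-stress grain-yield
#' contrast 38.7 vs 9.8 g per plant for the responsive hybrid, a clear-day
#' PAR peak near 400 umol m-2 s-1, 23 SynCom OTUs mapping onto 17
#' isolates) and field-realistic values elsewhere; see the package
#' vignette for the rationale behind each default.
#'
#' @param env Named list: `t_mean`, `t_amplitude` (degC), `t_peak_hour`,
#'   `rh_mean`, `rh_amplitude` (%), `lux_max`, `dawn_hour`,
#'   `day_length_h`, `ar1_rho`, and `noise_sd` (named per channel:
#'   `temp_c`, `rh_pct`, `lux`).
#' @param physiology Named list: `tleaf_coupling` (degC per kPa of VPD),
#'   `tleaf_offset` (degC; scalar, per-arm named vector, or per-cell data
#'   frame), `sapflow_gain` (g H2O h-1 kPa-1, same forms), soil-water
#'   dynamics (`swc_setpoint`, `swc_min`, `swc_decay`, `swc_recovery_days`,
#'   `swc_et_coef`) and `noise_sd` per channel (`tleaf_c`, `sapflow`, `swc`).
#' @param otu Named list: `n_syncom_otus`, `n_resident_otus`,
#'   `library_size`, `dirichlet_concentration`, `syncom_base_prop`,
#'   `syncom_fold_change`, `n_shifted_resident`, `resident_fold_change`.
#' @param yield Named list: `n_per_cell`, `grain_means` (data frame of
#'   per-cell means in g, or scalar), `biomass_mean` (named by regime),
#'   `residual_sd` (g, grain; other components scale with it),
#'   phenology means/sds and `flowering_prob` (data frame or scalar).
#'
#' @return An object of class `sim_params`.
#' @examples
#' p <- sim_params()
#' p$otu$n_syncom_otus
#' @export
sim_params <- function(env = list(), physiology = list(), otu = list(),
                       yield = list()) {
  defaults <- list(
    env = list(
      t_mean = 25, t_amplitude = 8, t_peak_hour = 14,
      rh_mean = 70, rh_amplitude = 20,
      lux_max = 21650, dawn_hour = 6, day_length_h = 12,
      ar1_rho = 0.6,
      noise_sd = c(temp_c = 0.8, rh_pct = 3, lux = 800)
    ),
    physiology = list(
      tleaf_coupling = 0.5,
      tleaf_offset = c(inoculated = -1.5, uninoculated = 0),
      sapflow_gain = c(inoculated = 2.27, uninoculated = 1.0),
      swc_setpoint = 60, swc_min = 15, swc_decay = 0.06,
      swc_recovery_days = 2, swc_et_coef = 1.5,
      noise_sd = c(tleaf_c = 0.3, sapflow = 0.3, swc = 1.0)
    ),
    otu = list(
      n_syncom_otus = 23, n_resident_otus = 200,
      library_size = 10000, dirichlet_concentration = 500,
      syncom_base_prop = 0.016,
      syncom_fold_change = 10,
      n_shifted_resident = 20, resident_fold_change = 5
    ),
    yield = list(
      n_per_cell = 10,
      grain_means = default_grain_means(),
      biomass_mean = c(WW = 200, DS = 150),
      residual_sd = 8,
      emergence_mean = 5, emergence_sd = 0.7,
      anthesis_mean = c(WW = 73, DS = 82),
      silking_lag_mean = 1.5, silking_lag_sd = 0.7,
      phenology_sd = 1.5,
      flowering_prob = default_flowering_probs()
    )
  )
  user <- list(env = env, physiology = physiology, otu = otu, yield = yield)
  out <- purrr::imap(defaults, function(block, name) {
    extra <- setdiff(names(user[[name]]), names(block))
    if (length(extra) > 0) {
      abort(sprintf("unknown %s parameter: '%s'", name, extra[1]))
    }
    # shallow merge: user values replace defaults wholesale (a user data
    # frame or named vector is never merged element-wise into the default)
    block[names(user[[name]])] <- user[[name]]
    block
  })
  validate_sim_params(out)
  structure(out, class = "sim_params")
}

validate_sim_params <- function(p) {
  sds <- c(p$env$noise_sd, p$physiology$noise_sd)
  if (any(sds < 0)) abort("invalid parameter: noise sds must be >= 0")
  if (p$env$ar1_rho < 0 || p$env$ar1_rho >= 1) {
    abort("invalid parameter: ar1_rho must be in [0, 1)")
  }
  if (p$otu$syncom_fold_change <= 0 || p$otu$resident_fold_change <= 0) {
    abort("invalid parameter: fold changes must be > 0")
  }
  if (p$otu$library_size <= 0) abort("invalid parameter: library_size must be > 0")
  if (p$yield$residual_sd < 0) abort("invalid parameter: residual_sd must be >= 0")
  gm <- p$yield$grain_means
  if (is.numeric(gm) && any(gm < 0)) {
    abort("invalid parameter: grain means must be non-negative")
  }
  if (is.data.frame(gm) && any(gm[[setdiff(names(gm), c("hybrid", "regime", "inoculated"))[1]]] < 0)) {
    abort("invalid parameter: grain means must be non-negative")
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat("  env:        T", x$env$t_mean, "+/-", x$env$t_amplitude,
      "degC; RH", x$env$rh_mean, "+/-", x$env$rh_amplitude,
      "%; AR(1) rho", x$env$ar1_rho, "\n")
  cat("  physiology: T_leaf coupling", x$physiology$tleaf_coupling,
      "degC/kPa; noise sd",
      paste(names(x$physiology$noise_sd), x$physiology$noise_sd,
            sep = "=", collapse = ", "), "\n")
  cat("  otu:       ", x$otu$n_syncom_otus, "SynCom +",
      x$otu$n_resident_otus, "resident OTUs; library",
      x$otu$library_size, "; SynCom fold", x$otu$syncom_fold_change, "\n")
  cat("  yield:     ", x$yield$n_per_cell, "plants/cell; residual sd",
      x$yield$residual_sd, "g\n")
  invisible(x)
}
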