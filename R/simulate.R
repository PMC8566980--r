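# Synthetic-data generators emulating the greenhouse experiment: diurnal
# environment cycles, treatment-structured plant sensor streams, a
# Dirichlet-multinomial OTU table with SynCom spike-ins, and per-plant
# yield/phenology tables.

#' Simulate environment-station sensor logs
#'
#' Generates per-station records of air temperature, relative humidity and
#' illuminance on the station cadence.  Temperature follows a sinusoidal
#' diurnal cycle peaking at `t_peak_hour`, relative humidity the anti-phase
#' cycle, and illuminance a clipped daylight sine that is exactly zero
#' between dusk and dawn.  Each station receives independent stationary
#' AR(1) Gaussian noise; humidity is clamped to [0, 100] and illuminance to
#' non-negative values.
#'
#' @param design An [experiment_design()].
#' @param params A [sim_params()]; only the `env` block is used.
#' @param seed Integer seed; identical inputs give bit-identical output.
#'
#' @return Tibble with columns `timestamp`, `das`, `station`, `temp_c`,
#'   `rh_pct`, `lux` (one row per station per cadence step).
#' @examples
#' env <- simulate_environment(experiment_design(duration_das = 2), seed = 1)
#' @export
simulate_environment <- function(design, params = sim_params(), seed) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(seed)
  e <- params$env
  minutes <- seq(0, design$duration_das * 1440 - design$env_cadence_min,
                 by = design$env_cadence_min)
  hour <- (minutes / 60) %% 24
  n <- length(minutes)
  temp_det <- e$t_mean + e$t_amplitude * cos(2 * pi * (hour - e$t_peak_hour) / 24)
  rh_det <- e$rh_mean - e$rh_amplitude * cos(2 * pi * (hour - e$t_peak_hour) / 24)
  frac <- (hour - e$dawn_hour) / e$day_length_h
  daylight <- ifelse(frac >= 0 & frac <= 1, sin(pi * pmin(pmax(frac, 0), 1)), 0)
  lux_det <- e$lux_max * daylight
  purrr::map_dfr(seq_len(design$n_stations), function(s) {
    temp <- temp_det + ar1_noise(n, e$ar1_rho, e$noise_sd[["temp_c"]])
    rh <- pmin(100, pmax(0, rh_det + ar1_noise(n, e$ar1_rho, e$noise_sd[["rh_pct"]])))
    lux_noise <- ar1_noise(n, e$ar1_rho, e$noise_sd[["lux"]])
    lux <- ifelse(daylight > 0, pmax(0, lux_det + lux_noise), 0)
    tibble(
      timestamp = .sowing_origin() + minutes * 60,
      das = minutes_to_das(minutes),
      station = paste0("ST", s),
      temp_c = temp, rh_pct = rh, lux = lux
    )
  })
}

# Station-averaged environment interpolated onto an arbitrary minute grid.
env_on_grid <- function(env, minutes) {
  env_mean <- env |>
    group_by(.data$das) |>
    summarise(temp_c = mean(.data$temp_c), rh_pct = mean(.data$rh_pct),
              .groups = "drop")
  tibble(
    temp_c = approx(env_mean$das, env_mean$temp_c, xout = minutes_to_das(minutes),
                    rule = 2)$y,
    rh_pct = approx(env_mean$das, env_mean$rh_pct, xout = minutes_to_das(minutes),
                    rule = 2)$y
  )
}

#' Simulate per-plant physiological sensor streams
#'
#' Builds leaf temperature, sap flow and soil water content (SWC) series
#' for every plant in the design on the plant cadence.  Leaf temperature
#' couples to air temperature and VPD with a per-cell inoculation offset;
#' sap flow is proportional to VPD times a soil-availability factor; SWC
#' holds its set point under WW, decays through the drought window under
#' DS and recovers after rehydration, with a diurnal evapotranspiration
#' dip proportional to VPD.
#'
#' @param design An [experiment_design()].
#' @param env Output of [simulate_environment()] covering the design
#'   duration.
#' @param params A [sim_params()]; the `physiology` block is used.
#' @param seed Integer seed.
#'
#' @return Tibble with `timestamp`, `das`, `plant_id`, `hybrid`,
#'   `inoculated` (logical), `regime`, `tleaf_c`, `sapflow`, `swc`.
#' @export
simulate_plants <- function(design, env, params = sim_params(), seed) {
  stopifnot(inherits(design, "experiment_design"))
  if (max(env$das) < design$duration_das - 1) {
    abort("alignment error: environment series does not cover the design duration")
  }
  set.seed(seed)
  ph <- params$physiology
  minutes <- seq(0, design$duration_das * 1440 - design$plant_cadence_min,
                 by = design$plant_cadence_min)
  das <- minutes_to_das(minutes)
  grid <- env_on_grid(env, minutes)
  vpd <- vpd_arden_buck(grid$temp_c, grid$rh_pct)

  cells <- design_cells(design)
  offs <- resolve_cell_values(cells, ph$tleaf_offset, "tleaf_offset")
  gains <- resolve_cell_values(cells, ph$sapflow_gain, "sapflow_gain")

  swc_base <- function(regime) {
    sp <- ph$swc_setpoint
    if (regime == "WW") return(rep(sp, length(das)))
    ds0 <- design$ds_window[1]
    reh <- design$rehydration_das
    base <- rep(sp, length(das))
    stressed <- das >= ds0 & das < reh
    base[stressed] <- pmax(ph$swc_min, sp * exp(-ph$swc_decay * (das[stressed] - ds0)))
    low <- max(ph$swc_min, sp * exp(-ph$swc_decay * (reh - ds0)))
    recov <- das >= reh & das < reh + ph$swc_recovery_days
    base[recov] <- low + (sp - low) * (das[recov] - reh) / ph$swc_recovery_days
    base
  }
  swc_base_ww <- swc_base("WW")
  swc_base_ds <- swc_base("DS")

  plants <- cells |>
    tidyr::expand_grid(replicate = seq_len(design$replicates_per_cell)) |>
    mutate(plant_id = sprintf("P%02d", row_number()))

  purrr::pmap_dfr(
    list(plants$plant_id, plants$hybrid, plants$inoculated, plants$regime,
         rep(offs, each = design$replicates_per_cell)[seq_len(nrow(plants))],
         rep(gains, each = design$replicates_per_cell)[seq_len(nrow(plants))]),
    function(pid, hyb, inoc, reg, off, gain) {
      n <- length(minutes)
      tleaf <- grid$temp_c + off + ph$tleaf_coupling * vpd +
        rnorm(n, 0, ph$noise_sd[["tleaf_c"]])
      base <- if (reg == "WW") swc_base_ww else swc_base_ds
      swc <- base - ph$swc_et_coef * vpd + rnorm(n, 0, ph$noise_sd[["swc"]])
      soil_factor <- pmin(1, pmax(0, swc) / ph$swc_setpoint)
      sap <- pmax(0, gain * pmax(vpd, 0) * soil_factor +
                    rnorm(n, 0, ph$noise_sd[["sapflow"]]))
      tibble(
        timestamp = .sowing_origin() + minutes * 60,
        das = das, plant_id = pid, hybrid = hyb, inoculated = inoc,
        regime = reg, tleaf_c = tleaf, sapflow = sap, swc = swc
      )
    }
  )
}

syncom_isolates <- function() {
  c("Agrobacterium sp. E09", "Asticcacaulis sp. F02", "Burkholderia sp. A10",
    "Dyella sp. G12", "Ensifer sp. B04", "Enterobacter sp. B02",
    "Lysobacter sp. A02", "Microbacterium sp. C05", "Pantoea sp. B02/C12",
    "Pedobacter sp. A01", "Sphingomonas sp. D05", "Stenotrophomonas sp. E09",
    "Streptomyces sp. G01", "Bradyrhizobiaceae C05", "Xanthomonadaceae B08",
    "Xanthomonadaceae G08", "Variovorax sp. F04")
}

# Map n SynCom OTUs onto the 17 isolate labels: each isolate gets one OTU,
# extra OTUs are assigned round-robin (23 OTUs -> 17 isolates by default).
map_otus_to_isolates <- function(n_otus) {
  iso <- syncom_isolates()
  iso[((seq_len(n_otus) - 1) %% length(iso)) + 1]
}

#' Simulate a SynCom colonization OTU count table
#'
#' Draws per-sample OTU counts from a Dirichlet-multinomial model.  The
#' community holds `n_syncom_otus` SynCom-member OTUs (mapped onto the 17
#' isolate labels) at a small baseline proportion plus `n_resident_otus`
#' resident OTUs with power-law base abundances.  In inoculated samples
#' the expected SynCom proportions are multiplied by `syncom_fold_change`
#' and `n_shifted_resident` resident OTUs by `resident_fold_change`
#' (recruitment/displacement), then renormalised.  Every sample's counts
#' sum to `library_size`.
#'
#' @inheritParams simulate_plants
#' @return Long tibble, one row per OTU x sample: `otu_id`, `sample_id`,
#'   `count`, `syncom` (logical), `isolate`, `taxonomy`, `shifted_resident`,
#'   `hybrid`, `inoculated`, `regime`, `replicate`.
#' @export
simulate_otu_table <- function(design, params = sim_params(), seed) {
  stopifnot(inherits(design, "experiment_design"))
  o <- params$otu
  if (o$library_size <= 0) abort("invalid parameter: library_size must be > 0")
  set.seed(seed)

  n_syn <- o$n_syncom_otus
  n_res <- o$n_resident_otus
  otus <- tibble(
    otu_id = c(sprintf("SC%02d", seq_len(n_syn)), sprintf("OTU%04d", seq_len(n_res))),
    syncom = rep(c(TRUE, FALSE), c(n_syn, n_res)),
    isolate = c(map_otus_to_isolates(n_syn), rep(NA_character_, n_res)),
    taxonomy = c(
      paste0("Bacteria;SynCom;", map_otus_to_isolates(n_syn)),
      paste0("Bacteria;Resident;Genus_", sprintf("%04d", seq_len(n_res)))
    )
  )
  # baseline relative weights: SynCom OTUs share syncom_base_prop, residents
  # the remainder with a power-law rank-abundance profile
  res_w <- (seq_len(n_res))^-0.7
  res_w <- res_w / sum(res_w) * (1 - o$syncom_base_prop)
  syn_w <- rep(o$syncom_base_prop / n_syn, n_syn)
  base_w <- c(syn_w, res_w)
  # shifted residents drawn from mid-rank taxa so the spike-ins dominate
  shifted_idx <- integer(0)
  if (o$n_shifted_resident > 0) {
    start <- min(n_res, 51)
    shifted_idx <- n_syn + seq(start, length.out = min(o$n_shifted_resident,
                                                       n_res - start + 1))
  }
  otus$shifted_resident <- seq_len(nrow(otus)) %in% shifted_idx

  samples <- design_cells(design) |>
    tidyr::expand_grid(replicate = seq_len(design$replicates_per_cell)) |>
    mutate(sample_id = sprintf("S%02d", row_number()))

  counts <- purrr::pmap_dfr(
    list(samples$sample_id, samples$inoculated),
    function(sid, inoc) {
      w <- base_w
      if (inoc) {
        w[otus$syncom] <- w[otus$syncom] * o$syncom_fold_change
        w[shifted_idx] <- w[shifted_idx] * o$resident_fold_change
      }
      p <- w / sum(w)
      g <- rgamma(length(p), shape = o$dirichlet_concentration * p, rate = 1)
      if (sum(g) == 0) g <- p
      cnt <- as.integer(rmultinom(1, o$library_size, g / sum(g)))
      tibble(otu_id = otus$otu_id, sample_id = sid, count = cnt)
    }
  )
  counts |>
    left_join(otus, by = "otu_id") |>
    left_join(samples, by = "sample_id") |>
    select("otu_id", "sample_id", "count", "syncom", "isolate", "taxonomy",
           "shifted_resident", "hybrid", "inoculated", "regime", "replicate")
}

#' Simulate per-plant yield components and phenology
#'
#' Draws grain yield per plant as its treatment-cell mean plus Gaussian
#' residual; the remaining yield components (kernel count, kernel rows,
#' ear dimensions) and aboveground biomass are generated consistently so
#' the harvest index is computable.  Phenology dates carry the
#' drought-stress flowering delay, and flowerless plants (no anthesis or
#' no silking) arise with per-cell probabilities.
#'
#' @inheritParams simulate_plants
#' @return Tibble, one row per plant, with yield component, biomass and
#'   phenology columns.
#' @export
simulate_yield <- function(design, params = sim_params(), seed) {
  stopifnot(inherits(design, "experiment_design"))
  y <- params$yield
  set.seed(seed)
  cells <- design_cells(design)
  gm <- y$grain_means
  if (is.data.frame(gm)) {
    val <- setdiff(names(gm), c("hybrid", "regime", "inoculated"))[1]
    if (any(gm[[val]] < 0)) abort("invalid parameter: negative grain mean")
  } else if (any(gm < 0)) {
    abort("invalid parameter: negative grain mean")
  }
  grain_mu <- resolve_cell_values(cells, gm, "grain_means")
  fl <- y$flowering_prob
  if (is.data.frame(fl)) {
    # cells absent from the table default to full flowering
    p_anth <- resolve_cell_values(cells, fl[, c("hybrid", "regime", "inoculated", "p_anthesis")], "flowering_prob", default = 1)
    p_silk <- resolve_cell_values(cells, fl[, c("hybrid", "regime", "inoculated", "p_silking")], "flowering_prob", default = 1)
  } else {
    p_anth <- p_silk <- rep(fl, nrow(cells))
  }
  scale <- y$residual_sd / 8 # component noise scales with the grain residual

  purrr::pmap_dfr(
    list(cells$hybrid, cells$inoculated, cells$regime, grain_mu, p_anth, p_silk,
         seq_len(nrow(cells))),
    function(hyb, inoc, reg, mu, pa, ps, cell_i) {
      n <- y$n_per_cell
      grain <- pmax(0, mu + rnorm(n, 0, y$residual_sd))
      anth <- y$anthesis_mean[[reg]] + rnorm(n, 0, y$phenology_sd * scale)
      silk <- anth + y$silking_lag_mean + rnorm(n, 0, y$silking_lag_sd * scale)
      anth[runif(n) > pa] <- NA_real_
      silk[runif(n) > ps] <- NA_real_
      tibble(
        plant_id = sprintf("Y%02d_%02d", cell_i, seq_len(n)),
        hybrid = hyb, inoculated = inoc, regime = reg,
        grain_yield_g = grain,
        kernels = round(grain * 3.3 + rnorm(n, 0, 6 * scale)),
        kernel_rows = pmin(24, pmax(8, round(12 + grain / 30 + rnorm(n, 0, 0.8 * scale)))),
        ear_length_mm = 110 + grain * 0.5 + rnorm(n, 0, 6 * scale),
        ear_diameter_mm = 28 + grain * 0.12 + rnorm(n, 0, 2 * scale),
        biomass_g = pmax(1, y$biomass_mean[[reg]] + rnorm(n, 0, 12 * scale)),
        emergence_das = y$emergence_mean + rnorm(n, 0, y$emergence_sd * scale),
        anthesis_das = anth,
        silking_das = silk
      )
    }
  )
}
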