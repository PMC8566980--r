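test_that("all generators are deterministic under a fixed seed", {
  d <- small_design()
  p <- sim_params(otu = list(n_resident_otus = 40), yield = list(n_per_cell = 3))
  env1 <- simulate_environment(d, p, seed = 7)
  env2 <- simulate_environment(d, p, seed = 7)
  expect_identical(env1, env2)
  expect_false(identical(env1, simulate_environment(d, p, seed = 8)))
  expect_identical(simulate_plants(d, env1, p, seed = 3),
                   simulate_plants(d, env1, p, seed = 3))
  expect_identical(simulate_otu_table(d, p, seed = 4),
                   simulate_otu_table(d, p, seed = 4))
  expect_identical(simulate_yield(d, p, seed = 5),
                   simulate_yield(d, p, seed = 5))
})

test_that("noise-free environment is the exact deterministic diurnal curve", {
  d <- small_design(duration = 2)
  p <- sim_params(env = list(ar1_rho = 0, noise_sd = c(temp_c = 0, rh_pct = 0, lux = 0)))
  env <- simulate_environment(d, p, seed = 1)
  st1 <- env[env$station == "ST1", ]
  hour <- (st1$das * 24) %% 24
  expect_equal(st1$temp_c, 25 + 8 * cos(2 * pi * (hour - 14) / 24))
  expect_equal(st1$rh_pct, pmin(100, pmax(0, 70 - 20 * cos(2 * pi * (hour - 14) / 24))))
  night <- hour < 6 | hour > 18
  expect_true(all(st1$lux[night] == 0))
  expect_equal(max(st1$lux), 21650, tolerance = 1e-2)
})

test_that("environment record counts follow the cadence arithmetic and physical ranges", {
  d <- experiment_design() # 117 days at 15-min cadence
  p <- sim_params(env = list(noise_sd = c(temp_c = 2, rh_pct = 40, lux = 20000)))
  env <- simulate_environment(d, p, seed = 2)
  expect_equal(sum(env$station == "ST1"), 117 * 96)
  expect_equal(length(unique(env$station)), 4)
  expect_true(all(env$rh_pct >= 0 & env$rh_pct <= 100))
  expect_true(all(env$lux >= 0))
  expect_error(experiment_design(duration_das = 0), "invalid design")
  expect_error(experiment_design(plant_cadence_min = 7), "invalid design")
})

test_that("a fixed inoculation offset propagates exactly through noise-free plants", {
  d <- small_design(duration = 2, hybrids = "DKB177")
  p <- sim_params(
    env = list(ar1_rho = 0, noise_sd = c(temp_c = 0, rh_pct = 0, lux = 0)),
    physiology = list(noise_sd = c(tleaf_c = 0, sapflow = 0, swc = 0))
  )
  env <- simulate_environment(d, p, seed = 1)
  pl <- simulate_plants(d, env, p, seed = 2)
  ww <- pl[pl$regime == "WW", ]
  agg_i <- aggregate_plant_series(ww[ww$inoculated, ], tleaf_c)
  agg_u <- aggregate_plant_series(ww[!ww$inoculated, ], tleaf_c)
  delta <- delta_tleaf_series(agg_i, agg_u)
  expect_equal(delta$delta, rep(-1.5, nrow(delta)))
})

test_that("soil water content is stationary under WW and declines under drought", {
  d <- experiment_design(hybrids = "DKB177", replicates_per_cell = 2,
                         duration_das = 85)
  env <- simulate_environment(d, seed = 3)
  pl <- simulate_plants(d, env, sim_params(), seed = 4)
  daily <- pl |>
    dplyr::group_by(regime, day = floor(das)) |>
    dplyr::summarise(swc = mean(swc), .groups = "drop")
  ww <- daily[daily$regime == "WW", ]
  expect_lt(abs(mean(ww$swc[ww$day %in% 70:79]) - mean(ww$swc[ww$day %in% 30:39])), 1)
  ds <- daily[daily$regime == "DS", ]
  expect_lt(mean(ds$swc[ds$day %in% 70:79]), mean(ds$swc[ds$day %in% 30:39]) - 10)
  expect_error(simulate_plants(small_design(), env[env$das < 1, ], seed = 1),
               "alignment")
})

test_that("OTU tables respect the multinomial constraint and the spike-in contract", {
  d <- small_design()
  p <- sim_params(otu = list(n_resident_otus = 100))
  otu <- simulate_otu_table(d, p, seed = 11)
  sums <- otu |> dplyr::count(sample_id, wt = count)
  expect_true(all(sums$n == 10000))
  expect_true(all(otu$count >= 0))
  expect_equal(sum(!duplicated(otu$otu_id[otu$syncom])), 23)
  expect_equal(length(unique(otu$isolate[otu$syncom])), 17)

  # null fold change: arms match within Monte-Carlo error
  p_null <- sim_params(otu = list(n_resident_otus = 100, syncom_fold_change = 1,
                                  resident_fold_change = 1))
  agg <- syncom_relative_abundance(simulate_otu_table(d, p_null, seed = 12)) |>
    dplyr::group_by(inoculated) |>
    dplyr::summarise(m = mean(syncom_rel_abund))
  expect_lt(abs(diff(agg$m)) / mean(agg$m), 0.25)

  # 10x spike-in alone (no resident shift): empirical abundance ratio
  # within +/-30% of 10 across the 48 samples
  d48 <- experiment_design(duration_das = 4, ds_window = c(1, 3), rehydration_das = 3)
  p10 <- sim_params(otu = list(n_resident_otus = 100, resident_fold_change = 1))
  agg10 <- syncom_relative_abundance(simulate_otu_table(d48, p10, seed = 13)) |>
    dplyr::group_by(inoculated) |>
    dplyr::summarise(m = mean(syncom_rel_abund))
  ratio <- agg10$m[agg10$inoculated] / agg10$m[!agg10$inoculated]
  expect_gt(ratio, 7)
  expect_lt(ratio, 13)

  expect_error(sim_params(otu = list(syncom_fold_change = 0)), "fold")
  expect_error(sim_params(otu = list(library_size = 0)), "library_size")
})

test_that("yield tables are exact at zero residual and reject negative means", {
  d <- small_design()
  p0 <- sim_params(yield = list(residual_sd = 0, n_per_cell = 3))
  y <- simulate_yield(d, p0, seed = 21)
  cells <- y |>
    dplyr::group_by(hybrid, inoculated, regime) |>
    dplyr::summarise(sd = sd(grain_yield_g), m = mean(grain_yield_g),
                     .groups = "drop")
  expect_true(all(cells$sd == 0))
  dk_ds <- cells[cells$hybrid == "DKB177" & cells$regime == "DS", ]
  expect_equal(sort(dk_ds$m), c(9.8, 38.7))
  expect_error(
    simulate_yield(d, sim_params(yield = list(grain_means = -5)), seed = 1),
    "negative"
  )
})
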