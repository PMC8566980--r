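origin <- as.POSIXct("2018-08-20", tz = "UTC")

plant_records <- function(values_by_plant, inoculated = TRUE, n_points = 1) {
  purrr::imap_dfr(values_by_plant, function(v, i) {
    tibble::tibble(
      timestamp = origin + seq(0, length.out = n_points, by = 300),
      plant_id = paste0("P", i), hybrid = "DKB177",
      inoculated = inoculated, regime = "WW", tleaf_c = v
    )
  })
}

test_that("aggregation averages within plants then filters across replicates", {
  agg <- aggregate_plant_series(plant_records(list(25, 25, 25, 25), n_points = 6),
                                tleaf_c)
  expect_equal(agg$mean, 25)
  expect_equal(agg$n_retained, 4L)

  agg <- aggregate_plant_series(plant_records(list(24, 25, 26, 80)), tleaf_c)
  expect_equal(agg$mean, 25)
  expect_equal(agg$n_removed, 1L)
  expect_error(
    aggregate_plant_series(dplyr::mutate(plant_records(list(1)), regime = "XX"),
                           tleaf_c),
    "schema"
  )
})

test_that("a 20-day window at 30-min bins yields 960 bins per cell", {
  set.seed(5)
  rec <- make_window_records(96, 116, offset = 0, sd = 0.1)
  agg <- aggregate_plant_series(rec[rec$inoculated, ], tleaf_c)
  expect_equal(nrow(agg), 960)
})

test_that("the per-bin contrast is zero and non-significant for identical arms", {
  set.seed(8)
  m <- matrix(rnorm(40 * 4, 25, 0.3), 40, 4)
  arm <- arm_bins_from_matrix(m)
  delta <- delta_tleaf_series(arm, arm)
  expect_true(all(delta$delta == 0))
  expect_true(all(!delta$significant))
  expect_true(all(delta$p_value == 1))
})

test_that("swapping the arms negates delta bin-wise and keeps the p-values", {
  set.seed(9)
  a <- make_arm(60, 4, 24, 0.3)
  b <- make_arm(60, 4, 25, 0.3)
  d1 <- delta_tleaf_series(a, b)
  d2 <- delta_tleaf_series(b, a)
  expect_equal(d2$delta, -d1$delta)
  expect_equal(d2$p_value, d1$p_value)
  for (tst in c("welch", "mannwhitney")) {
    d1 <- delta_tleaf_series(a, b, test = tst)
    d2 <- delta_tleaf_series(b, a, test = tst)
    expect_equal(d2$delta, -d1$delta)
    expect_equal(d2$p_value, d1$p_value)
  }
})

test_that("the vectorised per-bin Welch p-values match stats::t.test", {
  set.seed(10)
  a <- make_arm(50, 4, 25, 0.5)
  b <- make_arm(50, 5, 24.5, 0.4)
  d <- delta_tleaf_series(a, b)
  oracle <- purrr::map2_dbl(a$values, b$values, ~ t.test(.x, .y)$p.value)
  expect_equal(d$p_value, oracle, tolerance = 1e-12)
})

test_that("the signed area summary follows the stated aau rule", {
  delta <- tibble::tibble(
    bin_start = origin + (0:2) * 1800,
    das = 0, delta = c(1.0, -2.0, 0.5),
    n_a = 4, n_b = 4, p_value = c(0.01, 0.02, 0.5),
    testable = TRUE, significant = c(TRUE, TRUE, FALSE)
  )
  s <- significant_area_summary(delta, width_min = 30)
  expect_equal(s$pos_area, 1.0)
  expect_equal(s$neg_area, 2.0)
  expect_equal(s$n_significant, 2)
  expect_equal(s$pct_significant, round(100 * 2 / 3, 1))

  all_zero <- dplyr::mutate(delta, delta = 0, significant = FALSE)
  s0 <- significant_area_summary(all_zero, width_min = 30)
  expect_equal(c(s0$pos_area, s0$neg_area, s0$n_significant), c(0, 0, 0))
})

test_that("areas are additive over any split and scale with the data", {
  set.seed(11)
  a <- make_arm(80, 4, 24, 0.4)
  b <- make_arm(80, 4, 25, 0.4)
  d <- delta_tleaf_series(a, b)
  whole <- significant_area_summary(d, width_min = 30)
  for (cut in c(1, 13, 40, 79)) {
    left <- significant_area_summary(d[seq_len(cut), ], width_min = 30)
    right <- significant_area_summary(d[-seq_len(cut), ], width_min = 30)
    expect_equal(left$pos_area + right$pos_area, whole$pos_area)
    expect_equal(left$neg_area + right$neg_area, whole$neg_area)
    expect_equal(left$n_significant + right$n_significant, whole$n_significant)
  }
  # scale equivariance: multiplying both arms by c scales areas by c,
  # Welch p-values are scale invariant
  cc <- 3.7
  scale_arm <- function(x) {
    dplyr::mutate(x, mean = mean * cc, sd = sd * cc,
                  values = purrr::map(values, ~ .x * cc))
  }
  ds <- delta_tleaf_series(scale_arm(a), scale_arm(b))
  expect_equal(ds$p_value, d$p_value, tolerance = 1e-12)
  scaled <- significant_area_summary(ds, width_min = 30)
  expect_equal(scaled$pos_area, cc * whole$pos_area)
  expect_equal(scaled$neg_area, cc * whole$neg_area)
})

test_that("bins with fewer than two retained replicates are untestable", {
  a <- arm_bins_from_matrix(matrix(25, 4, 4))
  b <- arm_bins_from_matrix(matrix(24, 4, 4))
  a$n_retained[2] <- 1L
  d <- delta_tleaf_series(a, b)
  expect_false(d$testable[2])
  expect_true(is.na(d$p_value[2]))
  expect_false(d$significant[2])
  # untestable bins still count toward the bin total
  expect_equal(significant_area_summary(d, width_min = 30)$n_bins, 4)
  expect_error(delta_tleaf_series(a, b[-1, ]), "alignment")
})

test_that("Granier conversion matches the closed-form constants and is monotone", {
  cal <- granier_calibration(delta_t_max = 10)
  expect_equal(granier_sap_flow(10, cal), 0)
  # K = 1 at delta_t = 5: 119e-6 m/s x 1e-4 m2 x 1e6 g/m3 x 3600 s/h
  expect_equal(granier_sap_flow(5, cal), 42.84, tolerance = 0.01)
  k_grid <- granier_sap_flow(seq(9, 1, by = -0.5), cal)
  expect_true(all(diff(k_grid) > 0))
  expect_error(granier_sap_flow(0, cal), "sensor-range")
  expect_error(granier_sap_flow(11, cal), "sensor-range")
  expect_error(granier_calibration(0), "calibration")
})

test_that("daily windows average 72 five-minute points and star the daily test", {
  minutes <- seq(0, 1440 - 5, by = 5)
  day <- tibble::tibble(
    timestamp = origin + minutes * 60,
    das = minutes / 1440,
    plant_id = "A", hybrid = "H", inoculated = TRUE, regime = "WW",
    sapflow = seq_along(minutes) # distinct value per point
  )
  both <- dplyr::bind_rows(
    day,
    day |> dplyr::mutate(plant_id = "B"),
    day |> dplyr::mutate(plant_id = "C", inoculated = FALSE),
    day |> dplyr::mutate(plant_id = "D", inoculated = FALSE)
  )
  res <- daily_window_compare(both, sapflow)
  in_window <- minutes >= 10 * 60 & minutes < 16 * 60
  expect_equal(sum(in_window), 72)
  expect_equal(res$mean_inoc, mean(seq_along(minutes)[in_window]))
  expect_equal(res$stars, "") # identical arms: no stars

  # contrast mimicking the strongest observed day: ~2.2 vs ~5 g/h, n = 4
  set.seed(12)
  arm_day <- function(mu, inoc, ids) {
    purrr::map_dfr(ids, function(id) {
      day |> dplyr::mutate(plant_id = id, inoculated = inoc,
                           sapflow = mu + rnorm(dplyr::n(), 0, 0.2))
    })
  }
  strong <- dplyr::bind_rows(arm_day(5, TRUE, c("I1", "I2", "I3", "I4")),
                             arm_day(2.2, FALSE, c("U1", "U2", "U3", "U4")))
  res <- daily_window_compare(strong, sapflow)
  expect_equal(res$mean_inoc / res$mean_uninoc, 2.27, tolerance = 0.05)
  expect_true(res$p_value <= 0.05)
  expect_true(nchar(res$stars) >= 1)
  expect_error(daily_window_compare(both, sapflow, window = c("16:00", "10:00")),
               "window")
})

test_that("the SWC contrast reuses the contrast engine with regime semantics", {
  set.seed(13)
  ww <- make_arm(48, 4, 60, 1, das_start = 55)
  ds <- make_arm(48, 4, 40, 1, das_start = 55)
  ctr <- swc_contrast(ds, ww, period = c(50, 80))
  expect_true(all(ctr$delta < 0))
  expect_true(mean(ctr$significant) > 0.9)
  swapped <- swc_contrast(ww, ds, period = c(50, 80))
  expect_equal(swapped$delta, -ctr$delta)
  expect_equal(swapped$p_value, ctr$p_value)
  same <- swc_contrast(ww, ww)
  expect_true(all(!same$significant))
})
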