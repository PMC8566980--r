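# Shared fixtures, all generated in code.

# A short experiment compatible with the design invariants.
small_design <- function(duration = 4, reps = 4, hybrids = c("DKB177", "SX7341")) {
  experiment_design(
    hybrids = hybrids, replicates_per_cell = reps,
    ds_window = c(1, 2), rehydration_das = 2, duration_das = duration
  )
}

# Build an aggregated-series tibble (as aggregate_plant_series returns it,
# single cell) directly from a per-bin replicate matrix, bins spanning
# `n_bins` half-hour steps starting at DAS `das_start`.
arm_bins_from_matrix <- function(m, das_start = 96, width_min = 30) {
  n_bins <- nrow(m)
  minutes <- das_start * 1440 + (seq_len(n_bins) - 1) * width_min
  rm <- rowMeans(m)
  rsd <- sqrt(rowSums((m - rm)^2) / (ncol(m) - 1))
  tibble::tibble(
    bin_start = as.POSIXct("2018-08-20", tz = "UTC") + minutes * 60,
    das = minutes / 1440,
    width_min = width_min,
    mean = rm,
    sd = rsd,
    n_retained = ncol(m),
    n_removed = 0L,
    values = asplit(m, 1)
  )
}

# Gaussian replicate arm: n_bins x n_rep values around `mu`.
make_arm <- function(n_bins, n_rep, mu, sd, das_start = 96) {
  arm_bins_from_matrix(
    matrix(rnorm(n_bins * n_rep, mu, sd), n_bins, n_rep),
    das_start = das_start
  )
}

# Raw 5-min plant records for one treatment contrast over a DAS window,
# with a fixed leaf-temperature offset between arms.
make_window_records <- function(das_from, das_to, n_per_arm = 4,
                                offset = -1.5, sd = 0.3, base = 25,
                                cadence_min = 5) {
  minutes <- seq(das_from * 1440, das_to * 1440 - cadence_min, by = cadence_min)
  arms <- tidyr::expand_grid(
    inoculated = c(TRUE, FALSE),
    replicate = seq_len(n_per_arm)
  )
  purrr::pmap_dfr(arms, function(inoculated, replicate) {
    tibble::tibble(
      timestamp = as.POSIXct("2018-08-20", tz = "UTC") + minutes * 60,
      das = minutes / 1440,
      plant_id = sprintf("%s%d", ifelse(inoculated, "I", "U"), replicate),
      hybrid = "DKB177",
      inoculated = inoculated,
      regime = "WW",
      tleaf_c = base + ifelse(inoculated, offset, 0) +
        rnorm(length(minutes), 0, sd)
    )
  })
}

# Minimal long OTU table from an OTU x sample count matrix plus arm labels.
otu_long_from_matrix <- function(counts, inoculated, syncom = NULL,
                                 hybrid = "DKB177", regime = "WW") {
  n_otu <- nrow(counts)
  n_smp <- ncol(counts)
  if (is.null(syncom)) syncom <- rep(FALSE, n_otu)
  tidyr::expand_grid(otu = seq_len(n_otu), smp = seq_len(n_smp)) |>
    dplyr::mutate(
      otu_id = sprintf("OTU%03d", otu),
      sample_id = sprintf("S%02d", smp),
      count = counts[cbind(otu, smp)],
      syncom = syncom[otu],
      isolate = ifelse(syncom[otu], paste0("Isolate_", otu), NA_character_),
      taxonomy = "Bacteria",
      hybrid = hybrid,
      inoculated = inoculated[smp],
      regime = regime,
      replicate = smp
    ) |>
    dplyr::select(-otu, -smp)
}
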