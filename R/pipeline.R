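# End-to-end orchestration: a validated run configuration (YAML), staged
# execution (simulate -> environment -> physiology -> agronomy ->
# microbiome -> report) and a checksummed run manifest for
# reproducibility audits.

.pipeline_stages <- c("simulate", "environment", "physiology", "agronomy",
                      "microbiome", "report")

#' Build a validated pipeline run configuration
#'
#' Collects every threshold and convention used by the analysis stages in
#' one object so a complete run is reproducible from a single file:
#' output directory, master seed, experiment design, simulation
#' parameters, the enabled stages, bin width, Tukey fence multiplier,
#' significance level, per-bin test engine, daily transpiration window,
#' the DAS windows analysed, and the ANOSIM permutation count.
#'
#' @param out_dir Directory receiving every stage output.
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param design An [experiment_design()].
#' @param params A [sim_params()].
#' @param stages Character subset of
#'   `c("simulate", "environment", "physiology", "agronomy", "microbiome",
#'   "report")`.
#' @param alpha Significance level used by every stage.
#' @param bin_width_min Bin width, minutes.
#' @param iqr_k Tukey fence multiplier.
#' @param test Per-bin test engine, `"welch"` or `"mannwhitney"`.
#' @param window Daily transpiration window, two "HH:MM" strings.
#' @param tleaf_window_das DAS range (inclusive start, exclusive end day
#'   + 1) for the leaf-temperature contrast.
#' @param sapflow_days DAS values for the sap-flow window comparison.
#' @param n_perm ANOSIM permutation count.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, design = experiment_design(),
                       params = sim_params(), stages = .pipeline_stages,
                       alpha = 0.05, bin_width_min = 30, iqr_k = 1.5,
                       test = "welch", window = c("10:00", "16:00"),
                       tleaf_window_das = c(96, 116), sapflow_days = 77:83,
                       n_perm = 999) {
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad) > 0) abort(sprintf("unknown stage '%s'", bad[1]))
  if (!test %in% c("welch", "mannwhitney")) {
    abort(sprintf("unknown test engine '%s'", test))
  }
  if (any(c("physiology", "agronomy", "microbiome") %in% stages) &&
      is.null(seed) && "simulate" %in% stages) {
    abort("a seed is required when stochastic stages are enabled")
  }
  stopifnot(inherits(design, "experiment_design"), inherits(params, "sim_params"))
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), design = design,
         params = params, stages = stages, alpha = alpha,
         bin_width_min = bin_width_min, iqr_k = iqr_k, test = test,
         window = window, tleaf_window_das = tleaf_window_das,
         sapflow_days = sapflow_days, n_perm = n_perm),
    class = "run_config"
  )
}

# Fields serialised as data frames need record-list form in YAML.
.df_params <- list(
  c("params", "yield", "grain_means"),
  c("params", "yield", "flowering_prob"),
  c("params", "physiology", "tleaf_offset"),
  c("params", "physiology", "sapflow_gain")
)

config_to_list <- function(config) {
  x <- unclass(config)
  x$design <- unclass(x$design)
  x$params <- unclass(x$params)
  for (path in .df_params) {
    v <- x[[path[1]]][[path[2]]][[path[3]]]
    if (is.data.frame(v)) {
      x[[path[1]]][[path[2]]][[path[3]]] <-
        purrr::transpose(purrr::map(as.list(v), as.list))
    }
  }
  # named vectors must become YAML maps or their names are lost
  x$params <- purrr::map(x$params, function(block) {
    purrr::map(block, function(v) {
      if (is.atomic(v) && !is.null(names(v))) as.list(v) else v
    })
  })
  x
}

list_to_config <- function(x, path = "<config>") {
  known <- c("out_dir", "seed", "design", "params", "stages", "alpha",
             "bin_width_min", "iqr_k", "test", "window", "tleaf_window_das",
             "sapflow_days", "n_perm")
  extra <- setdiff(names(x), known)
  if (length(extra) > 0) {
    abort(sprintf("configuration error in %s: unknown key '%s'", path, extra[1]))
  }
  design <- if (is.null(x$design)) experiment_design() else do.call(experiment_design, x$design)
  params_in <- x$params %||% list()
  bad_block <- setdiff(names(params_in), c("env", "physiology", "otu", "yield"))
  if (length(bad_block) > 0) {
    abort(sprintf("configuration error: unknown params block '%s'", bad_block[1]))
  }
  params_in <- purrr::map(params_in, function(block) {
    purrr::map(block, function(v) {
      if (is.list(v) && length(v) > 0 && is.list(v[[1]])) {
        bind_rows(purrr::map(v, as_tibble))
      } else if (is.list(v)) {
        unlist(v)
      } else v
    })
  })
  params <- do.call(sim_params, params_in)
  args <- x[setdiff(names(x), c("design", "params"))]
  args <- purrr::map(args, function(v) if (is.list(v)) unlist(v) else v)
  do.call(run_config, c(args, list(design = design, params = params)))
}

#' Write a run configuration to YAML
#'
#' @param config A [run_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' Load and validate a run configuration from YAML
#'
#' Unknown keys are rejected by name; omitted fields are filled with the
#' documented defaults (bin width 30 min, alpha 0.05, window
#' 10:00-16:00, Welch per-bin test, Tukey fence k = 1.5).
#'
#' @param path YAML file written by [write_run_config()] or by hand.
#' @return An object of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("configuration file '%s' not found", path))
  list_to_config(yaml::read_yaml(path), path = path)
}

write_stage_file <- function(data, dir, name) {
  path <- file.path(dir, name)
  if (grepl("\\.tsv$", name)) {
    readr::write_tsv(data, path)
  } else {
    readr::write_csv(data, path)
  }
  tibble(file = name, n_rows = nrow(data))
}

#' Execute the pipeline described by a run configuration
#'
#' Runs the enabled stages in order.  `simulate` writes the synthetic
#' station logs, plant sensor streams, OTU table and yield table;
#' `environment` derives PAR/VPD and produces the binned, station-pooled,
#' outlier-filtered series; `physiology` computes the per-hybrid
#' leaf-temperature contrast over the configured DAS window with its
#' signed significant-area summary, the daily sap-flow window
#' comparisons, and the WW-vs-DS soil-water contrast; `agronomy` runs the
#' yield ANOVA chain, harvest-index and phenology reports; `microbiome`
#' produces colonization-robustness calls, resident shifts, the
#' Bray-Curtis matrix, PCoA scores and the ANOSIM test; `report` writes a
#' Markdown summary.  Stages that are disabled read their inputs from
#' `out_dir` (written by an earlier run).
#'
#' Every output file is listed in the returned manifest with a content
#' checksum; an identical configuration and seed reproduces identical
#' checksums.
#'
#' @param config A [run_config()].
#' @return The run manifest: a tibble with `stage`, `file`, `n_rows`,
#'   `md5`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- config$design
  params <- config$params
  manifest <- tibble(stage = character(), file = character(),
                     n_rows = integer())
  add <- function(stage, entries) {
    manifest <<- bind_rows(manifest, entries |> mutate(stage = stage, .before = 1))
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            partial_manifest = manifest)
    })
  }
  read_input <- function(name) {
    path <- file.path(config$out_dir, name)
    if (!file.exists(path)) {
      abort(sprintf("missing input '%s' (run the simulate stage or provide it)", name))
    }
    if (grepl("\\.tsv$", name)) {
      readr::read_tsv(path, show_col_types = FALSE)
    } else {
      readr::read_csv(path, show_col_types = FALSE)
    }
  }

  env <- plants <- otu <- yield <- NULL
  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      env <<- simulate_environment(design, params, seed = config$seed)
      plants <<- simulate_plants(design, env, params, seed = config$seed + 1L)
      otu <<- simulate_otu_table(design, params, seed = config$seed + 2L)
      yield <<- simulate_yield(design, params, seed = config$seed + 3L)
      add("simulate", bind_rows(
        write_stage_file(env, config$out_dir, "env_stations.csv"),
        write_stage_file(plants, config$out_dir, "plant_sensors.csv"),
        write_stage_file(otu, config$out_dir, "otu_table.tsv"),
        write_stage_file(yield, config$out_dir, "yield.csv")
      ))
    })
  }

  if ("environment" %in% config$stages) {
    run_stage("environment", function() {
      if (is.null(env)) env <<- read_input("env_stations.csv")
      binned <- env |>
        derive_env_variables() |>
        bin_and_average(width_min = config$bin_width_min, k = config$iqr_k)
      add("environment", write_stage_file(binned, config$out_dir, "env_binned.csv"))
    })
  }

  if ("physiology" %in% config$stages) {
    run_stage("physiology", function() {
      if (is.null(plants)) plants <<- read_input("plant_sensors.csv")
      win <- config$tleaf_window_das
      entries <- list()
      areas <- list()
      for (hyb in design$hybrids) {
        ww <- plants |> filter(.data$hybrid == hyb, .data$regime == "WW",
                               .data$das >= win[1], .data$das < win[2])
        agg <- function(arm) {
          aggregate_plant_series(ww |> filter(.data$inoculated == arm),
                                 .data$tleaf_c,
                                 width_min = config$bin_width_min,
                                 k = config$iqr_k)
        }
        delta <- delta_tleaf_series(agg(TRUE), agg(FALSE),
                                    alpha = config$alpha, test = config$test)
        entries[[hyb]] <- write_stage_file(
          delta |> select(-dplyr::any_of("values")),
          config$out_dir, paste0("delta_tleaf_", hyb, ".csv"))
        areas[[hyb]] <- significant_area_summary(delta) |>
          mutate(hybrid = hyb, .before = 1)
      }
      add("physiology", bind_rows(entries))
      add("physiology", write_stage_file(bind_rows(areas), config$out_dir,
                                         "area_summary.csv"))
      sap <- plants |>
        filter(floor(.data$das) %in% config$sapflow_days) |>
        group_by(.data$hybrid, .data$regime) |>
        dplyr::group_modify(function(d, key) {
          daily_window_compare(d, .data$sapflow, window = config$window,
                               test = config$test)
        }) |>
        ungroup()
      add("physiology", write_stage_file(sap, config$out_dir,
                                         "sapflow_windows.csv"))
      swc <- purrr::map_dfr(design$hybrids, function(hyb) {
        h <- plants |> filter(.data$hybrid == hyb, !.data$inoculated)
        agg <- function(reg) {
          aggregate_plant_series(h |> filter(.data$regime == reg), .data$swc,
                                 width_min = config$bin_width_min,
                                 k = config$iqr_k)
        }
        swc_contrast(agg("DS"), agg("WW"), period = design$ds_window,
                     alpha = config$alpha, test = config$test) |>
          significant_area_summary() |>
          mutate(hybrid = hyb, .before = 1)
      })
      add("physiology", write_stage_file(swc, config$out_dir,
                                         "swc_contrast.csv"))
    })
  }

  if ("agronomy" %in% config$stages) {
    run_stage("agronomy", function() {
      if (is.null(yield)) yield <<- read_input("yield.csv")
      ys <- yield_stats(yield, "grain_yield_g", alpha = config$alpha)
      add("agronomy", bind_rows(
        write_stage_file(tidy(ys), config$out_dir, "yield_anova.csv"),
        write_stage_file(glance(ys), config$out_dir, "yield_diagnostics.csv"),
        write_stage_file(
          if (length(ys$tukey) > 0) bind_rows(ys$tukey) else
            tibble(term = character(), level = character(),
                   mean = numeric(), letters = character()),
          config$out_dir, "yield_tukey.csv"),
        write_stage_file(harvest_index_table(yield), config$out_dir,
                         "harvest_index.csv"),
        write_stage_file(phenology_summary(yield, by = "regime"),
                         config$out_dir, "phenology.csv")
      ))
    })
  }

  anosim_res <- NULL
  if ("microbiome" %in% config$stages) {
    run_stage("microbiome", function() {
      if (is.null(otu)) {
        otu <<- read_input("otu_table.tsv") |>
          mutate(inoculated = as.logical(.data$inoculated))
      }
      otu_ra <- relative_abundance(otu)
      robust <- classify_robust_colonizers(otu_ra, alpha = config$alpha)
      shifts <- classify_enriched_depleted(otu_ra, alpha = config$alpha)
      d <- bray_curtis(otu_ra, value = "rel_abund")
      ord <- pcoa_ordination(d, k = 2)
      meta <- otu_ra |> distinct(.data$sample_id, .data$inoculated)
      groups <- meta$inoculated[match(labels(d), meta$sample_id)]
      anosim_res <<- anosim_test(d, ifelse(groups, "inoculated", "uninoculated"),
                                 n_perm = config$n_perm,
                                 seed = config$seed + 4L)
      dm <- as.matrix(d)
      add("microbiome", bind_rows(
        write_stage_file(syncom_relative_abundance(otu_ra), config$out_dir,
                         "syncom_abundance.csv"),
        write_stage_file(robust$calls, config$out_dir, "robust_colonizers.csv"),
        write_stage_file(robust$otu_summary, config$out_dir,
                         "robust_otu_summary.csv"),
        write_stage_file(shifts$calls, config$out_dir, "resident_shifts.csv"),
        write_stage_file(shifts$summary, config$out_dir,
                         "resident_shift_summary.csv"),
        write_stage_file(as_tibble(dm, rownames = "sample_id"),
                         config$out_dir, "bray_curtis.tsv"),
        write_stage_file(ord$scores, config$out_dir, "pcoa_scores.csv"),
        write_stage_file(tidy(anosim_res), config$out_dir, "anosim.csv")
      ))
    })
  }

  if ("report" %in% config$stages) {
    run_stage("report", function() {
      lines <- c(
        "# Pipeline run summary", "",
        sprintf("- seed: %d", config$seed),
        sprintf("- stages: %s", paste(config$stages, collapse = ", ")),
        sprintf("- alpha: %g; bin width: %d min; test: %s",
                config$alpha, config$bin_width_min, config$test),
        "", "## Outputs", "",
        sprintf("- %s (%d rows)", manifest$file, manifest$n_rows)
      )
      path <- file.path(config$out_dir, "summary.md")
      writeLines(lines, path)
      add("report", tibble(file = "summary.md", n_rows = length(lines)))
    })
  }

  manifest <- manifest |>
    mutate(md5 = unname(tools::md5sum(file.path(config$out_dir, .data$file))))
  readr::write_csv(manifest, file.path(config$out_dir, "manifest.csv"))
  manifest
}
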