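# Yield, harvest-index and phenology statistics: Shapiro-Wilk and Levene
# diagnostics, full-factorial three-way ANOVA (genotype x inoculation x
# irrigation) with Tukey HSD letters, emergence/flowering t-tests and the
# flowering-proportion rule.

#' Harvest index
#'
#' `HI = 100 * grain / biomass`, in percent, from mean grain yield and
#' mean total aboveground biomass (both in grams).  Invariant under
#' simultaneous rescaling of both inputs.
#'
#' @param grain Mean grain yield, g (>= 0).
#' @param biomass Mean total aboveground biomass, g (> 0).
#' @return Harvest index in percent.
#' @examples
#' harvest_index(50, 100) # 50
#' @export
harvest_index <- function(grain, biomass) {
  if (any(biomass <= 0, na.rm = TRUE)) {
    abort("domain error: biomass must be positive")
  }
  if (any(grain < 0, na.rm = TRUE)) {
    abort("domain error: grain yield must be non-negative")
  }
  100 * grain / biomass
}

#' Per-cell harvest-index table
#'
#' Computes the harvest index of each treatment cell from the cell means
#' of grain yield and aboveground biomass.
#'
#' @param data Per-plant yield tibble with `hybrid`, `inoculated`,
#'   `regime`, `grain_yield_g`, `biomass_g`.
#' @return Tibble per cell with mean grain, mean biomass and `hi_pct`.
#' @export
harvest_index_table <- function(data) {
  data |>
    group_by(.data$hybrid, .data$inoculated, .data$regime) |>
    summarise(
      mean_grain_g = mean(.data$grain_yield_g, na.rm = TRUE),
      mean_biomass_g = mean(.data$biomass_g, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(hi_pct = harvest_index(.data$mean_grain_g, .data$mean_biomass_g))
}

# Tukey HSD letters for one model term, from the fitted aov.
tukey_term_letters <- function(fit, term, data, response, alpha = 0.05) {
  hsd <- TukeyHSD(fit, which = term)[[term]]
  comps <- strsplit(rownames(hsd), "-", fixed = TRUE)
  # level labels themselves never contain "-" (checked upstream)
  levs <- unique(unlist(comps))
  pmat <- matrix(NA_real_, length(levs), length(levs),
                 dimnames = list(levs, levs))
  for (i in seq_len(nrow(hsd))) {
    a <- comps[[i]][1]; b <- comps[[i]][2]
    pmat[a, b] <- pmat[b, a] <- hsd[i, "p adj"]
  }
  fac <- interaction(data[strsplit(term, ":", fixed = TRUE)[[1]]],
                     sep = ":", lex.order = TRUE)
  means <- tapply(data[[response]], fac, mean)[levs]
  lett <- letter_display(pmat, alpha = alpha, means = means)
  tibble(term = term, level = levs, mean = as.numeric(means),
         letters = unname(lett)) |>
    arrange(dplyr::desc(.data$mean))
}

#' Yield-component statistics: diagnostics, three-way ANOVA, Tukey groups
#'
#' Runs the full yield-analysis chain on one response: Shapiro-Wilk
#' normality of the model residuals, Levene homogeneity of variances
#' across the twelve treatment cells, a full-factorial three-way ANOVA
#' (genotype, irrigation regime, inoculation and all interactions; seven
#' effect terms plus residual) with Type II sums of squares, and Tukey
#' HSD compact-letter groups for every term significant at `alpha`.
#'
#' @param data Per-plant yield tibble with `hybrid`, `inoculated`,
#'   `regime` and the response column.
#' @param response Response column (tidy-eval or string), e.g.
#'   `grain_yield_g`.
#' @param alpha Significance level gating the post-hoc letters.
#' @return An object of class `yield_stats`; see [tidy.yield_stats()] and
#'   [glance.yield_stats()].
#' @export
yield_stats <- function(data, response, alpha = 0.05) {
  response <- as_name(enquo(response))
  if (!response %in% names(data)) {
    abort(sprintf("unknown response column '%s'", response))
  }
  df <- data |>
    mutate(
      hybrid = factor(.data$hybrid),
      inoculated = factor(if_else(.data$inoculated, "inoculated", "uninoculated")),
      regime = factor(.data$regime)
    ) |>
    filter(!is.na(.data[[response]]))
  if (nlevels(df$hybrid) < 2 || nlevels(df$inoculated) < 2 ||
      nlevels(df$regime) < 2) {
    abort("degenerate design: every factor needs at least 2 levels")
  }
  cell_n <- df |> count(.data$hybrid, .data$inoculated, .data$regime)
  n_cells <- nlevels(df$hybrid) * nlevels(df$inoculated) * nlevels(df$regime)
  if (nrow(cell_n) < n_cells || any(cell_n$n < 2)) {
    abort("degenerate design: every treatment cell needs at least 2 plants")
  }
  form <- stats::as.formula(paste(response, "~ hybrid * inoculated * regime"))
  fit <- aov(form, data = df)
  shapiro_p <- shapiro.test(residuals(fit))$p.value
  lev <- car::leveneTest(
    df[[response]],
    interaction(df$hybrid, df$inoculated, df$regime)
  )
  levene_p <- lev[["Pr(>F)"]][1]
  a2 <- car::Anova(fit, type = 2)
  anova_tbl <- tibble(
    term = trimws(rownames(a2)),
    sumsq = a2[["Sum Sq"]],
    df = a2[["Df"]],
    statistic = a2[["F value"]],
    p_value = a2[["Pr(>F)"]]
  )
  eff_terms <- anova_tbl$term[anova_tbl$term != "Residuals"]
  sig_terms <- eff_terms[!is.na(anova_tbl$p_value[match(eff_terms, anova_tbl$term)]) &
                           anova_tbl$p_value[match(eff_terms, anova_tbl$term)] <= alpha]
  tukey <- purrr::map(
    setNames(sig_terms, sig_terms),
    function(tm) tukey_term_letters(fit, tm, df, response, alpha = alpha)
  )
  structure(
    list(response = response, anova = anova_tbl, shapiro_p = shapiro_p,
         levene_p = levene_p, tukey = tukey, alpha = alpha, fit = fit,
         n = nrow(df)),
    class = "yield_stats"
  )
}

#' @export
print.yield_stats <- function(x, ...) {
  cat("<yield_stats> response:", x$response, " (n =", x$n, ")\n")
  cat(sprintf("  Shapiro-Wilk residuals p = %.4g; Levene p = %.4g\n",
              x$shapiro_p, x$levene_p))
  cat("  Three-way ANOVA (Type II):\n")
  print(as.data.frame(x$anova), digits = 4)
  if (length(x$tukey) > 0) {
    cat("  Tukey HSD letters for terms with p <=", x$alpha, ":",
        paste(names(x$tukey), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Emergence, flowering and ASI summary per hybrid
#'
#' For each hybrid, compares the inoculation arms with unpaired t-tests
#' on seedling-emergence day, anthesis day, silking day and the
#' anthesis-silking interval (ASI; plants lacking either date are
#' excluded from ASI but counted in the flowering proportions).  The
#' flowering row reports the proportion of plants with both anthesis and
#' silking per arm and raises `inoculation_flag` when the proportions
#' differ by more than `flowering_margin` percentage points - an explicit,
#' configurable reading of the "exceeded by 10%" decision rule.
#' Arms with fewer than two observations are marked untestable rather
#' than raising an error.
#'
#' @param data Per-plant yield tibble with phenology columns
#'   `emergence_das`, `anthesis_das`, `silking_das`.
#' @param flowering_margin Flag threshold, percentage points.
#' @param by Optional extra grouping column (e.g. `"regime"`).
#' @return Tibble with one row per hybrid x measure.
#' @export
phenology_summary <- function(data, flowering_margin = 10, by = NULL) {
  groups <- c("hybrid", by)
  data <- data |>
    mutate(asi = .data$silking_das - .data$anthesis_das,
           flowering = !is.na(.data$anthesis_das) & !is.na(.data$silking_das))
  arm_test <- function(d, col) {
    x <- d[[col]][d$inoculated]
    y <- d[[col]][!d$inoculated]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble(n_inoculated = length(x), n_uninoculated = length(y),
                    mean_inoculated = if (length(x)) mean(x) else NA_real_,
                    mean_uninoculated = if (length(y)) mean(y) else NA_real_,
                    statistic = NA_real_, p_value = NA_real_,
                    untestable = TRUE))
    }
    if (sd(x) == 0 && sd(y) == 0) {
      same <- mean(x) == mean(y)
      return(tibble(n_inoculated = length(x), n_uninoculated = length(y),
                    mean_inoculated = mean(x), mean_uninoculated = mean(y),
                    statistic = if (same) 0 else Inf,
                    p_value = if (same) 1 else 0, untestable = FALSE))
    }
    tt <- t.test(x, y)
    tibble(n_inoculated = length(x), n_uninoculated = length(y),
           mean_inoculated = mean(x), mean_uninoculated = mean(y),
           statistic = unname(tt$statistic), p_value = tt$p.value,
           untestable = FALSE)
  }
  data |>
    group_by(across(all_of(groups))) |>
    dplyr::group_modify(function(d, key) {
      rows <- purrr::map_dfr(
        c("emergence_das", "anthesis_das", "silking_das", "asi"),
        function(col) arm_test(d, col) |> mutate(measure = col, .before = 1)
      )
      prop_i <- mean(d$flowering[d$inoculated])
      prop_u <- mean(d$flowering[!d$inoculated])
      fl <- tibble(
        measure = "flowering",
        n_inoculated = sum(d$inoculated), n_uninoculated = sum(!d$inoculated),
        mean_inoculated = NA_real_, mean_uninoculated = NA_real_,
        statistic = NA_real_, p_value = NA_real_,
        untestable = sum(d$inoculated) == 0 || sum(!d$inoculated) == 0,
        prop_inoculated = prop_i, prop_uninoculated = prop_u,
        inoculation_flag = isTRUE(abs(prop_i - prop_u) * 100 > flowering_margin)
      )
      bind_rows(rows, fl)
    }) |>
    ungroup()
}
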