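# OTU-table analyses: relative abundance, per-OTU Kruskal-Wallis with
# exact small-sample p-values, SynCom colonization-robustness calls,
# resident enrichment/depletion, Bray-Curtis, PCoA and ANOSIM.

#' Per-sample relative abundance
#'
#' Converts counts to within-sample proportions; every sample's
#' proportions sum to one.
#'
#' @param data Long OTU tibble with `otu_id`, `sample_id`, `count`.
#' @return The input with a `rel_abund` column appended.
#' @export
relative_abundance <- function(data) {
  sums <- data |>
    group_by(.data$sample_id) |>
    summarise(total = sum(.data$count), .groups = "drop")
  if (any(sums$total <= 0)) {
    abort(sprintf("degenerate sample: '%s' has zero total count",
                  sums$sample_id[sums$total <= 0][1]))
  }
  data |>
    left_join(sums, by = "sample_id") |>
    mutate(rel_abund = .data$count / .data$total) |>
    select(-"total")
}

#' Aggregate SynCom relative abundance per sample
#'
#' Sums the relative abundances of SynCom-flagged OTUs within each
#' sample.
#'
#' @param data Long OTU tibble with a logical `syncom` column; the
#'   `rel_abund` column is computed if absent.
#' @return Tibble per sample with metadata and `syncom_rel_abund`.
#' @export
syncom_relative_abundance <- function(data) {
  if (!"rel_abund" %in% names(data)) data <- relative_abundance(data)
  meta <- intersect(c("hybrid", "inoculated", "regime", "replicate"), names(data))
  data |>
    group_by(across(all_of(c("sample_id", meta)))) |>
    summarise(syncom_rel_abund = sum(.data$rel_abund[.data$syncom]),
              .groups = "drop")
}

# Kruskal-Wallis H for a fixed two-group split, from pooled ranks, with
# tie correction; vectorised over subsets (columns of `idx`).
kw_h_from_ranks <- function(r, idx, n1, n) {
  n2 <- n - n1
  rx <- matrix(r[idx], nrow = n1)
  Rx <- colSums(rx)
  Ry <- sum(r) - Rx
  h <- 12 / (n * (n + 1)) * (Rx^2 / n1 + Ry^2 / n2) - 3 * (n + 1)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr > 0) h <- h / tie_corr
  h
}

#' Two-group Kruskal-Wallis test with exact small-sample p-values
#'
#' Computes the tie-corrected Kruskal-Wallis H statistic for two groups.
#' The p-value uses the chi-square approximation (df = 1) or, when the
#' pooled sample size is at most `exact_max` (default 10, the sizes seen
#' with four biological replicates per arm), exact enumeration of all
#' group labelings.  Constant pooled data give `H = 0`, `p = 1` by
#' convention.
#'
#' @param x,y Numeric vectors, at least two values each.
#' @param mode `"auto"` (exact when `length(x) + length(y) <= exact_max`),
#'   `"exact"`, or `"asymptotic"`.
#' @param exact_max Pooled-size cutoff for the automatic exact mode.
#' @return One-row tibble: `statistic` (H), `p_value`, `method`, `n_x`,
#'   `n_y`.
#' @examples
#' kw_test(c(10, 11, 12, 9), c(0, 0, 0.1, 0.05), mode = "exact")
#' @export
kw_test <- function(x, y, mode = c("auto", "exact", "asymptotic"),
                    exact_max = 10) {
  mode <- match.arg(mode)
  if (length(x) < 2 || length(y) < 2) {
    abort("need at least two values per group")
  }
  n1 <- length(x); n <- n1 + length(y)
  if (mode == "auto") mode <- if (n <= exact_max) "exact" else "asymptotic"
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    return(tibble(statistic = 0, p_value = 1,
                  method = paste0("kruskal-wallis (", mode, ")"),
                  n_x = n1, n_y = n - n1))
  }
  r <- rank(pooled)
  h_obs <- kw_h_from_ranks(r, matrix(seq_len(n1)), n1, n)
  if (mode == "exact") {
    idx <- combn(n, n1)
    h_all <- kw_h_from_ranks(r, idx, n1, n)
    p <- mean(h_all >= h_obs - 1e-9)
  } else {
    p <- pchisq(h_obs, df = 1, lower.tail = FALSE)
  }
  tibble(statistic = as.numeric(h_obs), p_value = p,
         method = paste0("kruskal-wallis (", mode, ")"),
         n_x = n1, n_y = n - n1)
}

# Per-group two-arm Kruskal-Wallis call on relative abundances.
kw_arm_call <- function(x_inoc, x_uninoc, alpha, mode) {
  if (length(x_inoc) < 2 || length(x_uninoc) < 2) {
    return(tibble(n_inoc = length(x_inoc), n_uninoc = length(x_uninoc),
                  median_inoc = median(x_inoc), median_uninoc = median(x_uninoc),
                  statistic = NA_real_, p_value = NA_real_, untestable = TRUE))
  }
  kt <- kw_test(x_inoc, x_uninoc, mode = mode)
  tibble(n_inoc = length(x_inoc), n_uninoc = length(x_uninoc),
         median_inoc = median(x_inoc), median_uninoc = median(x_uninoc),
         statistic = kt$statistic, p_value = kt$p_value, untestable = FALSE)
}

#' Classify SynCom OTUs as robust colonizers
#'
#' For every SynCom OTU within each hybrid x regime cell, compares the
#' relative abundance between inoculated and uninoculated plants with the
#' Kruskal-Wallis test.  An OTU is a robust colonizer in a cell iff the
#' test is significant at `alpha` AND its median relative abundance is
#' higher in inoculated plants (significance alone would also flag
#' displaced taxa).  Rollups report, per regime, the OTUs robust in at
#' least one hybrid and the per-isolate aggregation.  No multiple-testing
#' correction is applied, matching the per-OTU `P < 0.05` procedure.
#'
#' @param data Long OTU tibble with `syncom`, `isolate` and sample
#'   metadata columns; `rel_abund` computed if absent.
#' @param alpha Per-OTU significance level.
#' @param mode Kruskal-Wallis p-value mode, see [kw_test()].
#' @return An object of class `colonization_calls`: list with `calls`
#'   (per OTU x hybrid x regime), `otu_summary` (per OTU x regime:
#'   robust in >= 1 hybrid) and `isolate_summary`.
#' @export
classify_robust_colonizers <- function(data, alpha = 0.05,
                                       mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (!"rel_abund" %in% names(data)) data <- relative_abundance(data)
  syn <- data |> filter(.data$syncom)
  if (nrow(syn) == 0) abort("no SynCom-flagged OTUs in table")
  calls <- syn |>
    group_by(.data$otu_id, .data$isolate, .data$hybrid, .data$regime) |>
    summarise(
      kw_arm_call(.data$rel_abund[.data$inoculated],
                  .data$rel_abund[!.data$inoculated], alpha, mode),
      .groups = "drop"
    ) |>
    mutate(robust = !.data$untestable & !is.na(.data$p_value) &
             .data$p_value < alpha & .data$median_inoc > .data$median_uninoc)
  otu_summary <- calls |>
    group_by(.data$otu_id, .data$isolate, .data$regime) |>
    summarise(robust_any_hybrid = any(.data$robust),
              n_hybrids_robust = sum(.data$robust), .groups = "drop")
  isolate_summary <- calls |>
    group_by(.data$isolate, .data$regime) |>
    summarise(robust_any = any(.data$robust), .groups = "drop")
  structure(list(calls = calls, otu_summary = otu_summary,
                 isolate_summary = isolate_summary, alpha = alpha),
            class = "colonization_calls")
}

#' @export
print.colonization_calls <- function(x, ...) {
  cat("<colonization_calls> alpha =", x$alpha, "\n")
  robust <- x$otu_summary |> filter(.data$robust_any_hybrid)
  for (reg in unique(x$otu_summary$regime)) {
    cat(sprintf("  %s: %d / %d OTUs robust in >= 1 hybrid\n", reg,
                sum(robust$regime == reg),
                sum(x$otu_summary$regime == reg)))
  }
  invisible(x)
}

#' Classify resident OTUs as enriched, depleted or unchanged
#'
#' Applies the per-OTU Kruskal-Wallis comparison between inoculation arms
#' to every resident (non-SynCom) OTU, within each irrigation regime.
#' Significant OTUs with a higher median relative abundance in inoculated
#' plants are `enriched`, with a lower median `depleted`; all others are
#' `unchanged` (ties in median direction stay unchanged).  The summary
#' reports per-regime counts plus the union and intersection of shifted
#' OTUs across regimes.
#'
#' @inheritParams classify_robust_colonizers
#' @param pool_hybrids If `TRUE` (default), hybrids are pooled within
#'   each regime; if `FALSE`, tests run per hybrid and an OTU counts as
#'   shifted in a regime when shifted in any hybrid.
#' @return An object of class `abundance_shifts`: list with `calls`,
#'   `summary` (per-regime counts) and `shifted` (per-regime, union and
#'   intersection OTU id sets).
#' @export
classify_enriched_depleted <- function(data, alpha = 0.05,
                                       mode = c("auto", "exact", "asymptotic"),
                                       pool_hybrids = TRUE) {
  mode <- match.arg(mode)
  if (!"rel_abund" %in% names(data)) data <- relative_abundance(data)
  res <- data |> filter(!.data$syncom)
  if (nrow(res) == 0) abort("no resident OTUs in table")
  grouping <- if (pool_hybrids) c("otu_id", "regime") else c("otu_id", "regime", "hybrid")
  calls <- res |>
    group_by(across(all_of(grouping))) |>
    summarise(
      kw_arm_call(.data$rel_abund[.data$inoculated],
                  .data$rel_abund[!.data$inoculated], alpha, mode),
      .groups = "drop"
    ) |>
    mutate(status = dplyr::case_when(
      .data$untestable | is.na(.data$p_value) ~ "untestable",
      .data$p_value < alpha & .data$median_inoc > .data$median_uninoc ~ "enriched",
      .data$p_value < alpha & .data$median_inoc < .data$median_uninoc ~ "depleted",
      TRUE ~ "unchanged"
    ))
  shifted_calls <- calls |> filter(.data$status %in% c("enriched", "depleted"))
  regimes <- unique(calls$regime)
  shifted_sets <- lapply(setNames(regimes, regimes), function(rg) {
    unique(shifted_calls$otu_id[shifted_calls$regime == rg])
  })
  summary_tbl <- calls |>
    group_by(.data$regime) |>
    summarise(
      n_tested = sum(.data$status != "untestable"),
      n_enriched = sum(.data$status == "enriched"),
      n_depleted = sum(.data$status == "depleted"),
      n_shifted = .data$n_enriched + .data$n_depleted,
      .groups = "drop"
    )
  structure(
    list(
      calls = calls, summary = summary_tbl,
      shifted = list(
        per_regime = shifted_sets,
        union = Reduce(union, shifted_sets, accumulate = FALSE) %||% character(0),
        intersection = if (length(shifted_sets) > 0) Reduce(intersect, shifted_sets) else character(0)
      ),
      alpha = alpha
    ),
    class = "abundance_shifts"
  )
}

#' @export
print.abundance_shifts <- function(x, ...) {
  cat("<abundance_shifts> alpha =", x$alpha, "\n")
  print(as.data.frame(x$summary))
  cat("  shifted union:", length(x$shifted$union),
      "| intersection:", length(x$shifted$intersection), "\n")
  invisible(x)
}

# Long OTU tibble -> samples x OTUs matrix.
otu_matrix <- function(data, value = "count") {
  wide <- data |>
    select("sample_id", "otu_id", all_of(value)) |>
    tidyr::pivot_wider(names_from = "otu_id", values_from = all_of(value),
                       values_fill = 0)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample_id
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' Computes pairwise Bray-Curtis dissimilarities
#' `d(u, v) = 1 - 2 * sum(min(u, v)) / (sum(u) + sum(v))` between samples
#' (delegating to [vegan::vegdist()]), from counts or proportions.
#'
#' @param data Long OTU tibble (`otu_id`, `sample_id`, value column) or a
#'   samples x OTUs numeric matrix.
#' @param value Value column when `data` is a tibble: `"count"` or
#'   `"rel_abund"`.
#' @return A `dist` object with sample labels; values in [0, 1].
#' @export
bray_curtis <- function(data, value = "count") {
  m <- if (is.matrix(data)) data else otu_matrix(data, value = value)
  if (nrow(m) < 2) abort("need at least two samples")
  zero <- rowSums(m) == 0
  if (sum(zero) >= 2) {
    abort("undefined distance: more than one all-zero sample")
  }
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix: eigendecomposition
#' of the double-centred squared-distance matrix, axes ordered by
#' eigenvalue.  Negative eigenvalues (non-Euclidean dissimilarities such
#' as Bray-Curtis) are reported, not silently dropped; explained
#' proportions are relative to the sum of positive eigenvalues.
#'
#' @param d A `dist` object.
#' @param k Number of axes to return; truncated with a warning when it
#'   exceeds the number of positive eigenvalues.
#' @return An object of class `pcoa_ord`: list with `scores` (tibble:
#'   `sample_id`, `Axis1`..`Axisk`), `eigenvalues`, `explained`.
#' @export
pcoa_ordination <- function(d, k = 2) {
  n <- attr(d, "Size")
  res <- suppressWarnings(cmdscale(d, k = min(k, n - 1), eig = TRUE))
  n_pos <- sum(res$eig > sqrt(.Machine$double.eps) * max(abs(res$eig)))
  if (k > n_pos) {
    warn(sprintf("only %d positive eigenvalues; returning %d axes", n_pos, n_pos))
    k <- n_pos
  }
  pts <- res$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(k))
  scores <- bind_cols(tibble(sample_id = labels(d)), as_tibble(pts))
  structure(
    list(scores = scores, eigenvalues = res$eig,
         explained = res$eig / sum(res$eig[res$eig > 0])),
    class = "pcoa_ord"
  )
}

#' @export
print.pcoa_ord <- function(x, ...) {
  k <- ncol(x$scores) - 1
  cat("<pcoa_ord>", nrow(x$scores), "samples,", k, "axes;",
      "explained:", paste(sprintf("%.1f%%", 100 * x$explained[seq_len(k)]),
                          collapse = ", "), "\n")
  invisible(x)
}

# ANOSIM R from a rank vector of pairwise distances and a within-group
# indicator over the same pairs.
anosim_r <- function(ranks, within, m_pairs) {
  (mean(ranks[!within]) - mean(ranks[within])) / (m_pairs / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation on a dissimilarity
#' matrix.  With all pairwise distances ranked (average ranks on ties),
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)`
#' where `M = n(n-1)/2`, so `R = 1` when every between-group distance
#' exceeds every within-group distance.  The p-value is
#' `(1 + #permuted R >= observed R) / (1 + n_perm)` under seeded label
#' permutations, or exact enumeration of all labelings for two groups
#' when `exact = TRUE`.
#'
#' @param d A `dist` object.
#' @param groups Group labels, one per sample; at least two groups with
#'   two samples each.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutations (required for
#'   reproducibility; the global RNG state is restored afterwards).
#' @param exact If `TRUE`, enumerate all two-group labelings instead of
#'   sampling permutations.
#' @return An object of class `anosim_result`: list with `statistic`
#'   (R), `p_value`, `n_perm`, `perm_r` (null statistics), `method`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed, exact = FALSE) {
  groups <- as.factor(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) abort("groups must match the distance matrix size")
  sizes <- table(groups)
  if (length(sizes) < 2) abort("invalid grouping: need at least two groups")
  if (any(sizes < 2)) abort("invalid grouping: a group of size 1 is not allowed")
  ranks <- rank(as.vector(d))
  m_pairs <- n * (n - 1) / 2
  pair_i <- unlist(lapply(seq_len(n - 1), function(j) seq(j + 1, n)))
  pair_j <- rep(seq_len(n - 1), times = (n - 1):1)
  within_of <- function(g) g[pair_i] == g[pair_j]
  r_obs <- anosim_r(ranks, within_of(groups), m_pairs)
  if (exact) {
    if (length(sizes) != 2) {
      abort("exact enumeration is implemented for two groups only")
    }
    lev <- levels(groups)
    idx <- combn(n, sizes[[1]])
    perm_r <- apply(idx, 2, function(sel) {
      g <- rep(lev[2], n); g[sel] <- lev[1]
      anosim_r(ranks, within_of(g), m_pairs)
    })
    p <- mean(perm_r >= r_obs - 1e-12)
    method <- "anosim (exact enumeration)"
    n_perm <- ncol(idx)
  } else {
    if (missing(seed)) abort("a permutation seed is required")
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    perm_r <- vapply(seq_len(n_perm), function(i) {
      g <- sample(groups)
      anosim_r(ranks, within_of(g), m_pairs)
    }, numeric(1))
    p <- (1 + sum(perm_r >= r_obs - 1e-12)) / (1 + n_perm)
    method <- "anosim (permutation)"
  }
  structure(
    list(statistic = r_obs, p_value = p, n_perm = n_perm, perm_r = perm_r,
         method = method, groups = groups),
    class = "anosim_result"
  )
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("<anosim_result> R = %.3f, p = %.4g (%s, %d labelings)\n",
              x$statistic, x$p_value, x$method, x$n_perm))
  invisible(x)
}
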