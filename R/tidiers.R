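# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a yield-statistics object
#'
#' @param x A [yield_stats()] object.
#' @param ... Unused.
#' @return The ANOVA table as a tibble: `term`, `sumsq`, `df`,
#'   `statistic`, `p_value`.
#' @method tidy yield_stats
#' @export
tidy.yield_stats <- function(x, ...) x$anova

#' One-row diagnostics for a yield-statistics object
#'
#' @param x A [yield_stats()] object.
#' @param ... Unused.
#' @return Tibble with the response, sample size, Shapiro-Wilk and
#'   Levene p-values and the count of significant terms.
#' @method glance yield_stats
#' @export
glance.yield_stats <- function(x, ...) {
  tibble(
    response = x$response, n = x$n,
    shapiro_p = x$shapiro_p, levene_p = x$levene_p,
    n_significant_terms = length(x$tukey), alpha = x$alpha
  )
}

#' Tidy an ANOSIM result
#'
#' @param x An [anosim_test()] result.
#' @param ... Unused.
#' @return One-row tibble: `statistic` (R), `p_value`, `n_perm`,
#'   `method`.
#' @method tidy anosim_result
#' @export
tidy.anosim_result <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_perm = x$n_perm, method = x$method)
}

#' @rdname tidy.anosim_result
#' @method glance anosim_result
#' @export
glance.anosim_result <- function(x, ...) tidy(x)

#' Tidy colonization-robustness calls
#'
#' @param x A [classify_robust_colonizers()] result.
#' @param ... Unused.
#' @return The per (OTU, hybrid, regime) calls tibble.
#' @method tidy colonization_calls
#' @export
tidy.colonization_calls <- function(x, ...) x$calls

#' Tidy resident enrichment/depletion calls
#'
#' @param x A [classify_enriched_depleted()] result.
#' @param ... Unused.
#' @return The per-OTU calls tibble with `status`.
#' @method tidy abundance_shifts
#' @export
tidy.abundance_shifts <- function(x, ...) x$calls

#' Tidy a PCoA ordination
#'
#' @param x A [pcoa_ordination()] result.
#' @param ... Unused.
#' @return The sample scores tibble.
#' @method tidy pcoa_ord
#' @export
tidy.pcoa_ord <- function(x, ...) x$scores
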