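# Internal helpers shared across modules.

# Stationary AR(1) noise with marginal standard deviation `sd`.
ar1_noise <- function(n, rho, sd) {
  if (sd == 0 || n == 0) return(numeric(n))
  if (rho == 0) return(rnorm(n, 0, sd))
  innov <- rnorm(n, 0, sd * sqrt(1 - rho^2))
  init <- rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, rho, method = "recursive", init = init))
}

# Convert minutes-of-experiment to fractional days after sowing.
minutes_to_das <- function(minutes) minutes / 1440

# Parse "HH:MM" into fractional hours.
parse_clock <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) + as.numeric(p[2]) / 60, numeric(1))
}

# Resolve a per-cell parameter against the design's treatment cells.
# `spec` may be a single number (all cells), a numeric vector named
# "inoculated"/"uninoculated", or a data frame keyed by any subset of
# hybrid / inoculated / regime.
resolve_cell_values <- function(cells, spec, what, default = NULL) {
  if (is.numeric(spec) && is.null(names(spec)) && length(spec) == 1) {
    return(rep(spec, nrow(cells)))
  }
  if (is.numeric(spec) && !is.null(names(spec))) {
    bad <- setdiff(names(spec), c("inoculated", "uninoculated"))
    if (length(bad) > 0) {
      abort(sprintf("unknown arm label '%s' in %s", bad[1], what))
    }
    out <- ifelse(cells$inoculated, spec[["inoculated"]], spec[["uninoculated"]])
    return(unname(out))
  }
  if (is.data.frame(spec)) {
    keys <- intersect(c("hybrid", "inoculated", "regime"), names(spec))
    val_col <- setdiff(names(spec), keys)
    if (length(val_col) != 1) {
      abort(sprintf("%s table must have exactly one value column", what))
    }
    joined <- left_join(cells, spec, by = keys)
    out <- joined[[val_col]]
    if (anyNA(out)) {
      if (is.null(default)) {
        abort(sprintf("%s table does not cover every design cell", what))
      }
      out[is.na(out)] <- default
    }
    return(out)
  }
  abort(sprintf("cannot interpret %s specification", what))
}

# Vectorised Welch two-sample test from per-group summary statistics.
# Degenerate bins (zero pooled standard error) get p = 1 when the means
# agree and p = 0 when they differ; callers flag bins with n < 2 upstream.
welch_from_stats <- function(m1, s1, n1, m2, s2, n2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  delta <- m1 - m2
  p <- rep(NA_real_, length(delta))
  zero <- !is.na(se2) & se2 == 0
  p[zero] <- ifelse(delta[zero] == 0, 1, 0)
  ok <- !is.na(se2) & se2 > 0
  tval <- delta[ok] / sqrt(se2[ok])
  df <- se2[ok]^2 / ((s1[ok]^2 / n1[ok])^2 / (n1[ok] - 1) +
    (s2[ok]^2 / n2[ok])^2 / (n2[ok] - 1))
  p[ok] <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  p
}

# Two-sample test dispatch used by every per-bin / per-day comparison.
two_sample_p <- function(x, y, test = c("welch", "mannwhitney")) {
  test <- match.arg(test)
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (test == "welch") {
    welch_from_stats(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  } else {
    suppressWarnings(wilcox.test(x, y)$p.value)
  }
}

# Star code for the smallest passed threshold among `levels` (sorted
# descending, e.g. 0.05 > 0.01 > 0.001).
star_code <- function(p, levels = c(0.05, 0.01, 0.001)) {
  levels <- sort(levels, decreasing = TRUE)
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    passed <- which(pi <= levels)
    if (length(passed) == 0) "" else strrep("*", max(passed))
  }, character(1))
}

# Compact letter display from a symmetric p-value matrix: two levels share
# a letter iff they are not significantly different.  Maximal cliques of
# the non-significance graph each receive one letter.
letter_display <- function(pmat, alpha = 0.05, means = NULL) {
  lev <- rownames(pmat)
  adj <- (pmat > alpha) | is.na(pmat)
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  cliques <- igraph::max_cliques(g)
  if (!is.null(means)) {
    ord <- vapply(cliques, function(cl) max(means[lev[as.integer(cl)]]), numeric(1))
    cliques <- cliques[order(-ord)]
  }
  letters_out <- setNames(rep("", length(lev)), lev)
  for (i in seq_along(cliques)) {
    members <- lev[as.integer(cliques[[i]])]
    letters_out[members] <- paste0(letters_out[members], letters[i])
  }
  letters_out
}
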