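test_that("relative abundance normalises within samples and rejects empty ones", {
  m <- matrix(c(30, 70, 5, 0), nrow = 2)
  tb <- otu_long_from_matrix(m, inoculated = c(TRUE, FALSE))
  ra <- relative_abundance(tb)
  expect_equal(sort(ra$rel_abund[ra$sample_id == "S01"]), c(0.3, 0.7))
  expect_equal(max(ra$rel_abund[ra$sample_id == "S02"]), 1)
  sums <- ra |> dplyr::count(sample_id, wt = rel_abund)
  expect_equal(sums$n, rep(1, 2))
  m0 <- matrix(c(1, 1, 0, 0), nrow = 2)
  expect_error(relative_abundance(otu_long_from_matrix(m0, c(TRUE, FALSE))),
               "degenerate")
})

test_that("Kruskal-Wallis H matches the rank formula and exact enumeration", {
  # tie-free complete separation: ranks 5-8 vs 1-4, H = 5.333
  tie_free <- kw_test(c(10, 11, 12, 9), c(0.01, 0.02, 0.1, 0.05), mode = "exact")
  expect_equal(tie_free$statistic, 16 / 3, tolerance = 1e-3)
  expect_lt(abs(tie_free$p_value - 2 / 70), 1e-6)

  # same comparison with tied zeros: p unchanged, H carries the tie correction
  tied <- kw_test(c(10, 11, 12, 9), c(0, 0, 0.1, 0.05), mode = "exact")
  expect_lt(abs(tied$p_value - 0.0286), 1e-4)
  expect_gt(tied$statistic, 16 / 3)

  # oracle: enumerate all 70 labelings through stats::kruskal.test
  pooled <- c(10, 11, 12, 9, 0, 0, 0.1, 0.05)
  h_of <- function(idx) {
    g <- factor(seq_along(pooled) %in% idx)
    suppressWarnings(unname(kruskal.test(pooled, g)$statistic))
  }
  h_obs <- h_of(1:4)
  h_all <- apply(combn(8, 4), 2, h_of)
  expect_equal(tied$statistic, h_obs, tolerance = 1e-10)
  expect_equal(tied$p_value, mean(h_all >= h_obs - 1e-9), tolerance = 1e-10)

  expect_equal(kw_test(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(kw_test(c(2, 2), c(2, 2))$p_value, 1) # constant convention
  expect_error(kw_test(1, c(1, 2)), "two values")
})

test_that("robust colonizers require significance plus higher inoculated abundance", {
  set.seed(51)
  inoc <- rep(c(TRUE, FALSE), each = 4)
  counts <- matrix(500, nrow = 4, ncol = 8)
  counts[1, ] <- ifelse(inoc, c(400, 420, 410, 415), c(40, 42, 41, 44)) # spike-in
  counts[2, ] <- 0                                                      # absent
  counts[3, ] <- ifelse(inoc, c(40, 42, 41, 44), c(400, 420, 410, 415)) # displaced
  counts[4, ] <- round(runif(8, 390, 410))                              # flat
  tb <- otu_long_from_matrix(counts, inoc, syncom = rep(TRUE, 4))
  calls <- classify_robust_colonizers(tb, mode = "exact")$calls
  expect_equal(calls$robust[calls$otu_id == "OTU001"], TRUE)
  expect_equal(calls$p_value[calls$otu_id == "OTU001"], 2 / 70, tolerance = 1e-6)
  expect_false(calls$robust[calls$otu_id == "OTU002"])
  expect_false(calls$robust[calls$otu_id == "OTU003"]) # direction rule
  expect_false(calls$robust[calls$otu_id == "OTU004"])
})

test_that("resident classification is a partition and never includes SynCom OTUs", {
  set.seed(52)
  inoc <- rep(c(TRUE, FALSE), each = 4)
  counts <- matrix(rpois(20 * 8, 100), nrow = 20)
  counts[3, inoc] <- counts[3, inoc] * 8  # enriched resident
  counts[4, inoc] <- round(counts[4, inoc] / 8) # depleted resident
  syncom <- c(TRUE, TRUE, rep(FALSE, 18))
  tb <- otu_long_from_matrix(counts, inoc, syncom = syncom)
  shifts <- classify_enriched_depleted(tb, mode = "exact")
  expect_false(any(shifts$calls$otu_id %in% c("OTU001", "OTU002")))
  expect_true(all(shifts$calls$status %in%
                    c("enriched", "depleted", "unchanged", "untestable")))
  expect_equal(nrow(shifts$calls), 18) # one call per resident OTU per regime
  expect_equal(shifts$calls$status[shifts$calls$otu_id == "OTU003"], "enriched")
  expect_equal(shifts$calls$status[shifts$calls$otu_id == "OTU004"], "depleted")
})

test_that("Bray-Curtis reproduces hand-computed values and its invariances", {
  m <- rbind(a = c(2, 2, 0), b = c(4, 0, 0), c = c(2, 2, 0), d = c(0, 0, 5))
  d <- bray_curtis(m)
  dm <- as.matrix(d)
  expect_equal(dm["a", "c"], 0)        # identical samples
  expect_equal(dm["a", "d"], 1)        # disjoint supports
  expect_equal(dm["a", "b"], 0.5)      # 1 - 2*2/8
  expect_true(all(dm >= 0 & dm <= 1))
  expect_equal(dm, t(dm))
  expect_equal(as.matrix(bray_curtis(m * 7)), dm) # joint rescaling
  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0))), "undefined")
})

test_that("PCoA matches closed forms and reproduces Euclidean distances", {
  d2 <- stats::as.dist(matrix(c(0, 2, 2, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  o <- pcoa_ordination(d2, k = 1)
  expect_equal(sort(o$scores$Axis1), c(-1, 1))

  m3 <- matrix(1, 3, 3) - diag(3)
  dimnames(m3) <- list(letters[1:3], letters[1:3])
  o3 <- pcoa_ordination(stats::as.dist(m3), k = 2)
  expect_equal(o3$eigenvalues[1], o3$eigenvalues[2], tolerance = 1e-10)

  set.seed(53)
  pts <- matrix(rnorm(12), 6, 2)
  rownames(pts) <- paste0("s", 1:6)
  de <- dist(pts)
  oe <- pcoa_ordination(de, k = 2)
  rec <- dist(as.matrix(oe$scores[, c("Axis1", "Axis2")]))
  expect_equal(as.vector(rec), as.vector(de), tolerance = 1e-10)
  expect_warning(pcoa_ordination(de, k = 5), "positive eigenvalues")
})

test_that("ANOSIM attains R = 1 on separated data and matches vegan's statistic", {
  pts <- rbind(matrix(rnorm(8, 0, 0.01), 4), matrix(rnorm(8, 10, 0.01), 4))
  rownames(pts) <- paste0("s", 1:8)
  g <- rep(c("A", "B"), each = 4)
  res <- anosim_test(dist(pts), g, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)

  set.seed(54)
  m <- matrix(abs(rnorm(48)), 8)
  d <- vegan::vegdist(m, "bray")
  mine <- anosim_test(d, g, n_perm = 99, seed = 2)
  ref <- vegan::anosim(d, factor(g), permutations = 99)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_true(mine$statistic >= -1 && mine$statistic <= 1)

  # determinism and null behaviour of the permutation distribution
  again <- anosim_test(d, g, n_perm = 99, seed = 2)
  expect_identical(mine$p_value, again$p_value)
  expect_lt(abs(mean(mine$perm_r)), 0.15)

  expect_error(anosim_test(d, c(g[-1], "C")), "size 1")
  expect_error(anosim_test(d, rep("A", 8)), "two groups")
})

test_that("exact ANOSIM enumeration equals an independent brute-force oracle", {
  set.seed(55)
  pts <- matrix(rnorm(12), 6, 2)
  rownames(pts) <- paste0("s", 1:6)
  d <- dist(pts)
  g <- rep(c("A", "B"), each = 3)
  res <- anosim_test(d, g, exact = TRUE)
  expect_equal(res$n_perm, 20) # all balanced labelings of 6 samples

  # oracle: naive R over explicit pair loops, full enumeration
  r_naive <- function(grp) {
    dm <- as.matrix(d); rk <- matrix(0, 6, 6)
    rk[lower.tri(rk)] <- rank(dm[lower.tri(dm)])
    rw <- c(); rb <- c()
    for (i in 2:6) for (j in 1:(i - 1)) {
      if (grp[i] == grp[j]) rw <- c(rw, rk[i, j]) else rb <- c(rb, rk[i, j])
    }
    (mean(rb) - mean(rw)) / (15 / 2)
  }
  expect_equal(res$statistic, r_naive(g), tolerance = 1e-12)
  all_r <- apply(combn(6, 3), 2, function(sel) {
    grp <- rep("B", 6); grp[sel] <- "A"; r_naive(grp)
  })
  expect_equal(res$p_value, mean(all_r >= res$statistic - 1e-12),
               tolerance = 1e-12)
})
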