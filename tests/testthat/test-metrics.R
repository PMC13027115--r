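test_that("clonality follows the top-10% cumulative frequency definition", {
  r <- clonalityScore(c(5, 5, 5, 5))
  expect_equal(r$clonality, 0.25)
  expect_equal(r$k_used, 1L)
  expect_equal(clonalityScore(7)$clonality, 1)
  # n = 20, k = 2, top sizes 30 and 20 of total 100
  sizes <- c(30, 20, rep(5, 8), rep(1, 10))
  expect_equal(sum(sizes), 100)
  expect_equal(clonalityScore(sizes)$clonality, 0.5)
  expect_equal(clonalityScore(sizes)$k_used, 2L)
  # configurable bracket
  expect_equal(clonalityScore(rep(1, 15), bracket = "round")$k_used, 2L)
  expect_equal(clonalityScore(rep(1, 15), bracket = "floor")$k_used, 1L)
  expect_error(clonalityScore(numeric(0)), "empty")
  expect_error(clonalityScore(c(3, 0)), "positive")
})

test_that("diversity is richness over total cells", {
  expect_equal(diversityScore(10, 10), 1)
  expect_equal(diversityScore(1, 100), 0.01)
  expect_error(diversityScore(0, 10), "positive")
  expect_error(diversityScore(11, 10), "exceed")
  # oracle on a simulated truth table: brute-force recount
  ref <- sharedRef()
  cfg <- simConfig(seed = 81L, patients = "P01",
                   groups = c(P01 = "MSS"), tissues = "blood",
                   timepoints = "Pre", n_clonotypes_per_sample = 15L,
                   reads_per_cell_chain = 1L, shared_clone_fraction = 0)
  sim <- simulateRepertoire(cfg, ref, tempfile())
  tr <- sim$truth
  key <- paste(tr$locus, sub("\\*.*", "", tr$v_call), tr$junction_aa)
  want <- length(unique(key)) / nrow(tr)
  tab <- callClonotypes(tr, sim$samples)
  m <- sampleMetrics(tab)
  expect_equal(m$diversity, want)
})

test_that("the clonal expansion index collapses to 1/N on proportions", {
  expect_equal(clonalExpansionIndex(c(0.7, 0.1, 0.1, 0.1)), 0.25)
  expect_equal(clonalExpansionIndex(c(2, 4, 6), mode = "count"), 4)
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    p <- p / sum(p)
    expect_equal(clonalExpansionIndex(p) * length(p), 1, tolerance = 1e-12)
  }
  expect_error(clonalExpansionIndex(numeric(0)), "empty")
  expect_error(clonalExpansionIndex(c(0.2, 0.2)), "sum to 1")
})

test_that("expansion proportions split the pooled total as percentages", {
  expect_equal(unname(expansionProportion(50, 150)), c(25, 75))
  expect_equal(unname(expansionProportion(10, 10)), c(50, 50))
  expect_equal(unname(expansionProportion(0, 7)), c(0, 100))
  expect_error(expansionProportion(0, 0), "zero")
  set.seed(14)
  for (i in 1:50) {
    x <- sample(0:100, 2)
    if (sum(x) == 0) next
    expect_equal(sum(expansionProportion(x[1], x[2])), 100)
  }
})

test_that("enrichment and response scores are exact log2 ratios", {
  expect_equal(tissueEnrichmentScore(8, 2), 2)
  expect_equal(tissueEnrichmentScore(5, 5), 0)
  expect_error(tissueEnrichmentScore(0, 4), "pseudocount")
  expect_equal(tissueEnrichmentScore(0, 4, pseudocount = 1), log2(1 / 5))
  expect_equal(tumorResponseScore(4, 8), 1)
  expect_equal(tumorResponseScore(8, 4), -1)
  set.seed(15)
  for (i in 1:30) {
    ab <- sample(1:500, 2)
    expect_equal(tumorResponseScore(ab[1], ab[2]),
                 -tumorResponseScore(ab[2], ab[1]))
    # scale invariance of the log ratio
    g <- runif(1, 0.5, 4)
    expect_equal(tissueEnrichmentScore(ab[1] * g, ab[2] * g),
                 tissueEnrichmentScore(ab[1], ab[2]), tolerance = 1e-12)
  }
})

test_that("the net tumor-minus-normal response table is antisymmetric", {
  tp <- c(a = 10, b = 4); tq <- c(a = 14, b = 2)
  np <- c(a = 6, b = 6); nq <- c(a = 5, b = 9)
  tab <- netResponseTable(tp, tq, np, nq)
  swapped <- netResponseTable(np, nq, tp, tq)
  expect_equal(tab$net, -swapped$net)
  expect_equal(tab$net, (tq - tp) - (nq - np), ignore_attr = TRUE)
})

test_that("group comparisons delegate to standard two-sided tests", {
  # identical distributions: permutation p-value is 1
  r <- compareGroups(c(1, 2, 3), c(1, 2, 3), test = "wilcoxon")
  expect_gte(r$p_value, 0.99)
  # full separation at n=3,3: minimal attainable two-sided p = 2/C(6,3)
  r2 <- compareGroups(c(0, 0, 0), c(1, 1, 1), test = "wilcoxon")
  expect_equal(r2$p_value, 2 / choose(6, 3))
  r3 <- compareGroups(1:3, 4:6, test = "wilcoxon")
  expect_equal(r3$p_value, 0.1)
  # t statistic flips sign when the groups swap
  a <- c(1.2, 3.1, 2.2); b <- c(4.0, 5.5, 3.9)
  t1 <- compareGroups(a, b, test = "t_test")
  t2 <- compareGroups(b, a, test = "t_test")
  expect_equal(t1$statistic, -t2$statistic)
  expect_equal(t1$p_value, t2$p_value)
  expect_error(compareGroups(1, c(1, 2), test = "t_test"), ">= 2")
  expect_error(compareGroups(c(1, 1), c(2, 2), test = "t_test"),
               "zero variance")
})

test_that("clonality never decreases when cells move to the largest clone", {
  set.seed(16)
  for (i in 1:200) {
    sizes <- randomCloneSizes()
    c0 <- clonalityScore(sizes)$clonality
    # move one cell from a small surviving clone to the largest
    # (clone count n stays fixed, so k is unchanged)
    cand <- which(sizes >= 2L)
    if (length(cand) == 0L) next
    from <- cand[which.min(sizes[cand])]; to <- which.max(sizes)
    if (from == to) next
    sizes2 <- sizes
    sizes2[from] <- sizes2[from] - 1L
    sizes2[to] <- sizes2[to] + 1L
    c1 <- clonalityScore(sizes2)$clonality
    expect_gte(c1 + 1e-12, c0)
    # relabeling invariance
    expect_equal(clonalityScore(sample(sizes))$clonality, c0)
    expect_true(c0 > 0 && c0 <= 1)
    d <- diversityScore(length(sizes), sum(sizes))
    expect_true(d > 0 && d <= 1)
  }
})

test_that("group metric comparison applies FDR across metrics", {
  ref <- sharedRef()
  cfg <- smallSimConfig(seed = 91L, n_clonotypes_per_sample = 8L)
  sim <- simulateRepertoire(cfg, ref, tempfile())
  tab <- callClonotypes(sim$truth, sim$samples)
  cmp <- compareGroupMetrics(sampleMetrics(tab))
  expect_equal(cmp$metric, c("clonality", "diversity"))
  expect_true(all(cmp$fdr >= cmp$p_value - 1e-12))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
})
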