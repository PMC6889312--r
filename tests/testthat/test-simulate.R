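test_that("species tree simulation honors depth, connecting branch and seeding", {
  sim <- simulateSpeciesTree(5, 8, h = 0.7, L = 0.2, seed = 3)
  phy <- sim$tree
  expect_setequal(phy$tip.label, c(sim$partition$A, sim$partition$B))
  # ultrametric clades with all within-domain tip depths equal to h
  for (dom in sim$partition) {
    cd <- cladeDepths(phy, dom)
    expect_equal(unname(cd$depths), rep(0.7, length(dom)), tolerance = 1e-9)
  }
  expect_equal(normalizedABBranch(phy, sim$partition) * 0.7, 0.2,
               tolerance = 1e-9)
  # seeded determinism
  expect_identical(writeNewick(simulateSpeciesTree(5, 8, h = 0.7, L = 0.2,
                                                   seed = 3)$tree),
                   writeNewick(phy))
  # clade shapes independent of L (so L can be swept)
  sim2 <- simulateSpeciesTree(5, 8, h = 0.7, L = 0.9, seed = 3)
  d1 <- tipDistances(phy)[sim$partition$A, sim$partition$A]
  d2 <- tipDistances(sim2$tree)[sim$partition$A, sim$partition$A]
  expect_equal(d1, d2, tolerance = 1e-9)
  # L = 0 makes the two domain ancestors coincide
  sim0 <- simulateSpeciesTree(4, 4, L = 0, seed = 1)
  expect_equal(normalizedABBranch(sim0$tree, sim0$partition), 0)
  expect_error(simulateSpeciesTree(1, 5), "nA")
})

test_that("gene tree discordance scales with the SPR rate and dropout is binomial", {
  sim <- simulateSpeciesTree(10, 15, h = 0.5, L = 0.1, seed = 21)
  # zero SPR and dropout reproduces the species tree exactly
  g0 <- simulateGeneTrees(sim$tree, nGenes = 5, sprMean = 0, dropout = 0,
                          seed = 1)
  for (gt in g0) expect_equal(rfDistance(sim$tree, gt), 0)
  # discordance increases with the SPR rate
  conc <- sapply(c(0, 5), function(spr) {
    gts <- simulateGeneTrees(sim$tree, nGenes = 20, sprMean = spr,
                             seed = 2)
    mean(sapply(gts, function(g) quartetConcordance(sim$tree, g)$score))
  })
  expect_gt(conc[1], conc[2])
  expect_equal(conc[1], 1)
  # dropout: mean retained tip count within 3 binomial sd of (1-p)n
  n <- length(sim$tree$tip.label)
  gts <- simulateGeneTrees(sim$tree, nGenes = 40, sprMean = 0,
                           dropout = 0.3, seed = 3)
  kept <- sapply(gts, function(g) length(g$tip.label))
  se <- sqrt(n * 0.3 * 0.7 / 40)
  expect_lt(abs(mean(kept) - 0.7 * n), 3 * se)
})

test_that("alignment simulation separates rate classes and injects gaps", {
  sim <- simulateSpeciesTree(6, 6, h = 0.4, L = 0.1, seed = 31)
  al <- simulateAlignment(sim$tree, length = 200, seed = 5)
  m <- alnMatrix(al$alignment)
  expect_equal(ncol(m), 200)
  expect_equal(length(al$siteClass), 200)
  inv <- which(al$siteClass == "invariant")
  expect_true(all(apply(m[, inv, drop = FALSE], 2,
                        function(col) length(unique(col)) == 1)))
  meanHam <- function(cols) {
    mean(sapply(cols, function(j) {
      v <- m[, j]
      keep <- v != "-"
      mean(outer(v[keep], v[keep], "!=")[upper.tri(diag(sum(keep)))])
    }), na.rm = TRUE)
  }
  expect_gt(meanHam(which(al$siteClass == "fast")),
            meanHam(which(al$siteClass == "slow")))
  expect_gt(sum(m == "-"), 0)
  # seeded determinism
  al2 <- simulateAlignment(sim$tree, length = 200, seed = 5)
  expect_identical(alnMatrix(al2$alignment), m)
  expect_error(simulateAlignment(sim$tree, length = 0), "length")
})

test_that("taxonomy simulation plants monophyletic taxa and calibrated noise", {
  sim <- simulateSpeciesTree(30, 70, L = 0.2, seed = 41)
  tx <- simulateTaxonomy(sim$tree, seed = 1)
  # noise-free: every multi-tip taxon strictly monophyletic
  for (rk in c("domain", "phylum", "class", "genus")) {
    for (taxon in unique(tx$taxonomy[[rk]])) {
      tips <- tx$taxonomy$tip_id[tx$taxonomy[[rk]] == taxon]
      if (length(tips) < 2) next
      expect_true(isMonophyletic(sim$tree, tips, "strict"))
    }
  }
  expect_equal(nrow(tx$flags), 0)
  # mislabel rate lands within 3 binomial sd of its target
  tx2 <- simulateTaxonomy(sim$tree, mislabelRate = 0.05, seed = 2)
  ncell <- 6 * 100  # six noised ranks x 100 tips
  expect_lt(abs(sum(tx2$flags$mislabeled) - 0.05 * ncell),
            3 * sqrt(ncell * 0.05 * 0.95))
  # blanked cells are blank and never double-counted as mislabeled
  tx3 <- simulateTaxonomy(sim$tree, mislabelRate = 0.05,
                          unclassifiedRate = 0.3, seed = 3)
  bl <- tx3$flags[tx3$flags$blanked, ]
  for (i in seq_len(min(nrow(bl), 50))) {
    expect_identical(
      tx3$taxonomy[tx3$taxonomy$tip_id == bl$tip_id[i], bl$rank[i]], "")
  }
  expect_false(any(tx3$flags$blanked & tx3$flags$mislabeled))
})

test_that("genome pair simulation provides an exact, monotone Jaccard oracle", {
  g <- simulateGenomes(genomeLen = 800, overlapGrid = c(1, 0.7, 0.4, 0),
                       seed = 7)
  expect_equal(g$jaccard[1], 1)
  expect_lt(g$jaccard[4], 0.02)
  expect_true(all(diff(g$jaccard) <= 0))
  expect_identical(g$seqA[1], g$seqB[1])
})

test_that("metadata simulation is seeded and honors degenerate distributions", {
  md <- simulateMetadata(sprintf("G%03d", 1:50), seed = 4)
  expect_identical(md, simulateMetadata(sprintf("G%03d", 1:50), seed = 4))
  expect_true(all(md$contamination >= 0 & md$contamination <= 100))
  expect_true(all(md$marker_count >= 0 & md$marker_count <= 400))
  cst <- simulateMetadata(c("a", "b"), distributions = list(
    marker_count = function(n) rep(200L, n)), seed = 1)
  expect_equal(cst$marker_count, c(200L, 200L))
})

test_that("per-gene inter-domain distances recover the species-tree signal", {
  meds <- numeric(0)
  for (L in c(0.05, 0.1, 0.2)) {
    sim <- simulateSpeciesTree(10, 15, h = 0.5, L = L, seed = 21)
    gts <- simulateGeneTrees(sim$tree, nGenes = 30, sprMean = 0.5,
                             dropout = 0.1, seed = 22)
    vals <- vapply(gts, function(g) {
      pa <- list(A = intersect(sim$partition$A, g$tip.label),
                 B = intersect(sim$partition$B, g$tip.label))
      if (length(pa$A) < 2 || length(pa$B) < 2) return(NA_real_)
      relativeABDistance(g, pa)
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    sp <- relativeABDistance(sim$tree, sim$partition)
    # the species statistic sits inside the inter-gene IQR
    expect_gte(sp, quantile(vals, 0.25))
    expect_lte(sp, quantile(vals, 0.75))
    meds <- c(meds, median(vals))
  }
  expect_true(all(diff(meds) > 0))
})
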