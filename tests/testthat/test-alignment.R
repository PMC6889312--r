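test_that("gap filters remove sites then sequences, in that order", {
  # gap-free alignment is untouched
  aln <- markerAlignment(c(a = "ACDEF", b = "ACDEG", c = "ACDEH"))
  f <- filterAlignment(aln)
  expect_equal(alnMatrix(f$alignment), alnMatrix(aln))
  # a fully gapped column goes, rows stay
  aln2 <- markerAlignment(c(a = "AC-DEF", b = "AC-DEG", c = "AC-DEH",
                            d = "AC-DEI"))
  f2 <- filterAlignment(aln2)
  expect_equal(f2$removedSites, 3L)
  expect_length(f2$removedSeqs, 0)
  # toy 4x6: one all-gap column, then one row above 66% gaps of survivors
  aln3 <- markerAlignment(c(a = "AC-DEF", b = "AC-D-G", c = "AC-REF",
                            d = "-G----"))
  f3 <- filterAlignment(aln3)
  expect_equal(dim(alnMatrix(f3$alignment)), c(3L, 5L))
  expect_equal(f3$removedSites, 3L)
  expect_identical(f3$removedSeqs, "d")
  # idempotence
  f4 <- filterAlignment(f3$alignment)
  expect_equal(alnMatrix(f4$alignment), alnMatrix(f3$alignment))
  expect_error(filterAlignment(markerAlignment(c(a = "--", b = "--"))),
               "gap threshold")
})

test_that("gene gap fraction drives the marker retention rule", {
  expect_equal(geneGapFraction(markerAlignment(c(a = "ACD", b = "EFG"))), 0)
  expect_true(isRetainedGene(markerAlignment(c(a = "ACD", b = "EFG"))))
  expect_equal(geneGapFraction(markerAlignment(c(a = "---", b = "---"))), 1)
  expect_false(isRetainedGene(markerAlignment(c(a = "---", b = "---"))))
  expect_equal(geneGapFraction(markerAlignment(c(a = "A-CD", b = "--AB"))),
               3 / 8)
})

test_that("trident scores match the formula and rank conserved sites first", {
  w <- tridentWeights()
  expect_equal(tridentScore(rep("A", 8), w), 1)
  expect_equal(tridentScore(rep("-", 8), w), 0)
  # 50/50 two-residue gap-free column, alpha=beta=gamma=1: evaluate the
  # three components independently from the published BLOSUM62 entries
  w1 <- tridentWeights(alpha = 1, beta = 1, gamma = 1)
  col <- c("A", "A", "V", "V")
  t <- (-2 * 0.5 * log(0.5)) / log(4)
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  Bm <- as.matrix(e$BLOSUM62)
  S <- Bm[c("A", "V"), c("A", "V")]
  dAV <- 1 - S["A", "V"] / sqrt(S["A", "A"] * S["V", "V"])
  aa <- rownames(tridentWeights()$dissim)
  full <- 1 - Bm[aa, aa] / sqrt(outer(diag(Bm[aa, aa]), diag(Bm[aa, aa])))
  full[full < 0] <- 0
  r <- 2 * 0.25 * (dAV / max(full))
  expect_equal(tridentScore(col, w1), (1 - t) * (1 - r), tolerance = 1e-12)
  # monotone non-increasing in gap fraction holding residues fixed
  sc <- sapply(0:5, function(g) tridentScore(c(rep("A", 6), rep("-", g)), w))
  expect_true(all(diff(sc) <= 1e-12))
  # planted invariant columns are selected first
  set.seed(41)
  m <- matrix(sample(c("A", "C", "D", "E", "F", "G"), 10 * 30,
                     replace = TRUE), 10, 30)
  inv <- c(3, 9, 14, 22, 28)
  for (j in inv) m[, j] <- "W"
  rownames(m) <- paste0("s", 1:10)
  aln <- markerAlignment(m)
  sel <- sampleConserved(aln, m = 5)
  expect_identical(siteIndices(sel), sort(as.integer(inv)))
  # invariant under row permutation
  aln2 <- markerAlignment(m[sample(10), ])
  expect_identical(siteIndices(sampleConserved(aln2, m = 5)),
                   siteIndices(sel))
  # m >= length keeps everything
  expect_length(siteIndices(sampleConserved(aln, m = 100)), 30)
})

test_that("random site sampling respects eligibility and the seed", {
  m <- matrix("A", 6, 20, dimnames = list(paste0("s", 1:6), NULL))
  m[1:4, 1:8] <- "-"   # columns 1..8 are 66% gapped, ineligible
  aln <- markerAlignment(m)
  s1 <- sampleRandom(aln, m = 5, seed = 7)
  expect_true(all(siteIndices(s1) > 8))
  expect_identical(siteIndices(sampleRandom(aln, m = 5, seed = 7)),
                   siteIndices(s1))
  expect_false(identical(siteIndices(sampleRandom(aln, m = 5, seed = 8)),
                         siteIndices(s1)))
  # eligible < m returns all eligible with a warning
  expect_warning(s2 <- sampleRandom(aln, m = 15), "eligible")
  expect_length(siteIndices(s2), 12)
  allgap <- markerAlignment(matrix("-", 3, 4,
                                   dimnames = list(letters[1:3], NULL)))
  expect_error(sampleRandom(allgap, m = 2), "no site")
})

test_that("concatenation builds a gap-filled supermatrix with a bijective partition map", {
  a1 <- markerAlignment(c(x = "ACDE", y = "ACDF"), gene = "g1")
  a2 <- markerAlignment(c(y = "WW", z = "WV"), gene = "g2")
  cc <- concatenateAlignments(list(a1, a2))
  sm <- alnMatrix(cc$alignment)
  expect_equal(dim(sm), c(3L, 6L))
  expect_equal(paste(sm["x", ], collapse = ""), "ACDE--")
  expect_equal(paste(sm["z", ], collapse = ""), "----WV")
  # partition round-trips every supermatrix column to its source
  for (i in seq_len(nrow(cc$partitions))) {
    p <- cc$partitions[i, ]
    src <- if (p$gene == "g1") a1 else a2
    srcm <- alnMatrix(src)
    for (tx in rownames(srcm)) {
      expect_identical(sm[tx, p$supermatrix_col], srcm[tx, p$gene_col])
    }
  }
  # with site selections, extraction recovers the selected sub-alignment
  sel <- list(sampleConserved(a1, m = 2), sampleConserved(a2, m = 1))
  cc2 <- concatenateAlignments(list(a1, a2), sel)
  expect_equal(ncol(alnMatrix(cc2$alignment)), 3L)
  g1cols <- cc2$partitions$supermatrix_col[cc2$partitions$gene == "g1"]
  expect_equal(alnMatrix(cc2$alignment)[c("x", "y"), g1cols],
               alnMatrix(a1)[, siteIndices(sel[[1]])])
  lines <- writePartitions(cc2$partitions)
  expect_match(lines[1], "g1 = 1-2")
})

test_that("gap-free Hamming distance uses only shared residue positions", {
  expect_equal(hammingGapFree("ACDE", "ACDE"), 0)
  expect_equal(hammingGapFree("AC-G", "AG-G"), 1 / 3)
  expect_equal(hammingGapFree("AAAA", "CCCC"), 1)
  expect_true(is.na(hammingGapFree("A-C-", "-G-T")))
})

test_that("saturation scan finds comparable distance/divergence ratios across groups", {
  sim <- simulateSpeciesTree(12, 12, h = 0.2, L = 0.05, seed = 51)
  alns <- lapply(1:3, function(g) {
    a <- simulateAlignment(sim$tree, length = 150, seed = 60 + g)$alignment
    a@gene <- paste0("g", g)
    a
  })
  w <- capture_warnings(
    sc <- saturationScan(sim$tree, alns, sim$partition, nBins = 6,
                         nPerDomain = 20, seed = 1))
  expect_length(w, 2)  # both domains are smaller than the requested sample
  expect_match(w, "using all", all = TRUE)
  expect_true(all(c("A-A", "A-B", "B-B") %in% sc$records$group))
  expect_true(all(sc$summary$n >= 1))
  # on a short (unsaturated) tree the pooled y/x slope of inter-domain
  # pairs tracks the within-domain slope
  rat <- sapply(split(sc$records, sc$records$group),
                function(df) sum(df$y) / sum(df$x))
  within <- mean(rat[c("A-A", "B-B")])
  expect_lt(abs(rat["A-B"] - within) / within, 0.10)
  # deterministic under a fixed seed
  sc2 <- suppressWarnings(saturationScan(sim$tree, alns, sim$partition,
                                         nBins = 6, nPerDomain = 20,
                                         seed = 1))
  expect_equal(sc$summary, sc2$summary)
})
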