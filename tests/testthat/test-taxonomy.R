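toyTaxonomy <- function(tips, rank = "phylum", labels) {
  df <- data.frame(tip_id = tips, stringsAsFactors = FALSE)
  for (rk in c("domain", "phylum", "class", "order", "family", "genus",
               "species")) df[[rk]] <- ""
  df[[rank]] <- labels
  df
}

test_that("taxonomy readers accept TSV and Greengenes lineage strings", {
  tx <- toyTaxonomy(c("t1", "t2"), "phylum", c("P1", "P2"))
  f <- tempfile(fileext = ".tsv")
  writeTaxonomy(tx, f)
  expect_equal(readTaxonomy(f), tx)
  gg <- parseLineageStrings(
    c("t1", "t2"),
    c("k__Bacteria; p__Firmicutes; c__Bacilli; o__; f__; g__; s__",
      "d__Archaea; p__Crenarchaeota"))
  expect_equal(gg$domain, c("Bacteria", "Archaea"))
  expect_equal(gg$class, c("Bacilli", ""))
  expect_equal(gg$order, c("", ""))
})

test_that("F-measure scores follow the precision/recall definitions", {
  phy <- asPhylo(readNewick("(((a,b),(c,d)),((e,f),(g,h)));"))
  tx <- toyTaxonomy(letters[1:8], "phylum",
                    c("P", "P", "P", "P", "Q", "Q", "Q", "Q"))
  nt <- 8
  tb <- phylodomain:::.tipsBelow(phy)
  nodeFor <- function(tips) {
    which(vapply(seq_along(tb), function(v)
      setequal(phy$tip.label[tb[[v]]], tips), logical(1)))[1]
  }
  # node exactly the taxon
  sc <- fmeasure(phy, nodeFor(c("a", "b", "c", "d")), "P", tx, "phylum")
  expect_equal(unname(sc), c(1, 1, 1))
  # node covering half the taxon and nothing else
  sc2 <- fmeasure(phy, nodeFor(c("a", "b")), "P", tx, "phylum")
  expect_equal(unname(sc2), c(1, 0.5, 2 / 3))
  # node disjoint from the taxon
  sc3 <- fmeasure(phy, nodeFor(c("e", "f")), "P", tx, "phylum")
  expect_equal(unname(sc3["f"]), 0)
  # unclassified tips do not count against precision
  tx2 <- toyTaxonomy(letters[1:8], "phylum",
                     c("P", "P", "P", "", "Q", "Q", "Q", "Q"))
  sc4 <- fmeasure(phy, nodeFor(c("a", "b", "c", "d")), "P", tx2, "phylum")
  expect_equal(unname(sc4["precision"]), 1)
  expect_error(fmeasure(phy, nodeFor(c("a", "b")), "Z", tx, "phylum"),
               "no tips")
})

test_that("strict and relaxed monophyly behave per definition", {
  tr <- readNewick("(((t1,(t2,u)),x),(y,z));")
  expect_true(isMonophyletic(tr, "t1"))
  expect_false(isMonophyletic(tr, c("t1", "t2"), "strict"))
  expect_true(isMonophyletic(tr, c("t1", "t2"), "relaxed",
                             unclassified = "u"))
  expect_false(isMonophyletic(tr, c("t1", "x"), "relaxed",
                              unclassified = "u"))
  expect_true(isMonophyletic(tr, c("t1", "t2", "u")))
})

test_that("consistency equals 1 exactly at strict monophyly on planted cases", {
  set.seed(91)
  for (i in 1:25) {
    phy <- ape::rtree(12)
    tb <- phylodomain:::.tipsBelow(phy)
    if (i %% 2 == 0) {
      # planted clade -> strictly monophyletic
      v <- sample(13:(12 + phy$Nnode), 1)
      taxon <- phy$tip.label[tb[[v]]]
    } else {
      taxon <- sample(phy$tip.label, sample(2:6, 1))
    }
    if (length(taxon) >= 12) next
    cons <- consistencyScore(phy, taxon)
    mono <- isMonophyletic(phy, taxon, "strict")
    expect_equal(cons == 1, mono)
    if (!mono) expect_lt(cons, 1)
  }
  # worked asymmetric cases: min(precision, recall)
  phy <- asPhylo(readNewick("(((a,b),(c,d)),(e,(f,g)));"))
  # best clade {a,b,c,d} for taxon {a,b,c,d,e}: P=1, R=0.8
  expect_equal(consistencyScore(phy, c("a", "b", "c", "d", "e")), 0.8)
  # best clade {a,b,c,d} for taxon {a,b,c}: P=0.75, R=1 -> 0.75
  expect_equal(consistencyScore(phy, c("a", "b", "c")), 0.75)
})

test_that("taxon quartet score separates monophyletic from interleaved taxa", {
  phy <- readNewick("(((a,b),(c,d)),((e,f),(g,h)));")
  expect_equal(taxonQuartetScore(phy, c("a", "b", "c", "d"))$score, 1)
  q4 <- readNewick("((a,c),(b,d));")
  expect_equal(taxonQuartetScore(q4, c("a", "b"))$score, 0)
  # sampled mode within 3 stderr of exhaustive
  set.seed(92)
  big <- ape::rtree(20)
  taxon <- sample(big$tip.label, 7)
  ex <- taxonQuartetScore(big, taxon)$score
  sa <- taxonQuartetScore(big, taxon, nSamples = 500, seed = 5, cap = 10)
  expect_lt(abs(sa$score - ex), 3 * sa$stderr)
  expect_error(taxonQuartetScore(phy, "a"), ">= 2")
})

test_that("support/rejection degree carries the right value and sign", {
  tr <- readNewick("(((a:1,b:1)0.97:1,(c:1,d:1)0.3:1)0.8:1,(e:1,f:1)0.7:1);")
  # monophyletic clade: + support of its subtending branch
  expect_equal(supportRejection(tr, c("a", "b")), 0.97)
  # taxon broken only by the 0.3 branch
  expect_equal(supportRejection(tr, c("a", "b", "c")), -0.3)
  # taxon broken by the maximally supported branch
  tr2 <- readNewick("(((a:1,b:1)0.99:1,c:1)0.5:1,(d:1,e:1)0.4:1);")
  expect_equal(supportRejection(tr2, c("a", "c")), -0.99)
  # taxon = all tips is undefined
  expect_true(is.na(supportRejection(tr, letters[1:6])))
  # sign agrees with strict monophyly on random draws
  for (i in 1:100) {
    phy <- supportedTree(10, seed = 500 + i)
    taxon <- sample(phy$tip.label, sample(2:8, 1))
    sr <- supportRejection(phy, taxon)
    if (is.na(sr)) next
    expect_equal(sr > 0, isMonophyletic(phy, taxon, "strict"))
  }
})

test_that("decoration recovers a noise-free planted taxonomy exactly", {
  sim <- simulateSpeciesTree(25, 55, L = 0.2, seed = 95)
  tx <- simulateTaxonomy(sim$tree, seed = 96)
  dec <- decorateTree(sim$tree, tx$taxonomy)
  cur <- curatedTaxonomy(dec)
  for (rk in c("domain", "phylum", "class", "order", "family", "genus")) {
    expect_identical(cur[[rk]],
                     tx$truth[[rk]][match(cur$tip_id, tx$truth$tip_id)])
  }
  # monophyletic taxa carry no polyphyly suffix
  expect_false(any(grepl("_[0-9]+$", nodeAssignments(dec)$label)))
})

test_that("a split phylum receives size-ordered polyphyly suffixes", {
  # two pure clades of 3 and 2 tips carry the same phylum label
  phy <- readNewick("(((a,b,c),(d,e)),((p,q),(r,(s,u))));")
  tx <- toyTaxonomy(c("a", "b", "c", "d", "e", "p", "q", "r", "s", "u"),
                    "phylum",
                    c("X", "X", "X", "Y", "Y", "X", "X", "Y", "Y", "Y"))
  dec <- decorateTree(phy, tx)
  a <- nodeAssignments(dec)
  ax <- a[a$taxon == "X", ]
  expect_equal(sort(ax$label), c("X_1", "X_2"))
  expect_equal(ax$ntips[ax$label == "X_1"], 3)
  expect_equal(ax$ntips[ax$label == "X_2"], 2)
})

test_that("curation corrects the bulk of planted mislabels", {
  sim <- simulateSpeciesTree(40, 110, L = 0.2, seed = 97)
  hits <- misses <- 0
  for (sd in 1:3) {
    tx <- simulateTaxonomy(sim$tree, mislabelRate = 0.05, seed = sd)
    cur <- curatedTaxonomy(decorateTree(sim$tree, tx$taxonomy))
    fl <- tx$flags[tx$flags$mislabeled, ]
    ok <- mapply(function(tip, rk)
      sub("_[0-9]+$", "", cur[cur$tip_id == tip, rk]) ==
        tx$truth[tx$truth$tip_id == tip, rk],
      fl$tip_id, fl$rank)
    hits <- hits + sum(ok)
    misses <- misses + sum(!ok)
  }
  expect_gte(hits / (hits + misses), 0.95)
})

test_that("blanked tips are filled from the decorated clades", {
  sim <- simulateSpeciesTree(20, 40, L = 0.2, seed = 98)
  tx <- simulateTaxonomy(sim$tree, unclassifiedRate = 0.1, seed = 99)
  expect_false(any(tx$flags$mislabeled))
  cur <- curatedTaxonomy(decorateTree(sim$tree, tx$taxonomy))
  fl <- tx$flags[tx$flags$blanked & tx$flags$rank != "species", ]
  ok <- mapply(function(tip, rk)
    sub("_[0-9]+$", "", cur[cur$tip_id == tip, rk]) ==
      tx$truth[tx$truth$tip_id == tip, rk],
    fl$tip_id, fl$rank)
  expect_gte(mean(ok), 0.9)
})
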