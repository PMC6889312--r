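# Taxonomy tables, F-measure scoring, and cladistic assessment of taxon
# sets against a species tree (strict/relaxed monophyly, consistency,
# taxon quartet score, support/rejection degree).

.TAXRANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

#' Read / write a taxonomy table
#'
#' The TSV format is tip_id plus the seven rank columns domain..species;
#' empty cells mean unclassified at that rank.
#'
#' @param file path to a TSV file.
#' @return a data.frame with columns tip_id and the seven ranks.
#' @export
readTaxonomy <- function(file) {
  df <- read.delim(file, colClasses = "character", check.names = FALSE)
  need <- c("tip_id", .TAXRANKS)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("taxonomy lacks column(s): ",
                         paste(miss, collapse = ", "))
  df[need]
}

#' @rdname readTaxonomy
#' @param taxonomy a taxonomy data.frame.
#' @export
writeTaxonomy <- function(taxonomy, file) {
  write.table(taxonomy, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Parse Greengenes-style lineage strings
#'
#' Accepts strings like "k__Bacteria; p__Firmicutes; ...; s__"; the k/d
#' prefix maps to the domain rank and empty segments mean unclassified.
#'
#' @param tip_id character vector of tip identifiers.
#' @param lineages character vector of lineage strings, parallel to
#'   \code{tip_id}.
#' @return a taxonomy data.frame as in \code{\link{readTaxonomy}}.
#' @export
parseLineageStrings <- function(tip_id, lineages) {
  prefmap <- c(k = "domain", d = "domain", p = "phylum", c = "class",
               o = "order", f = "family", g = "genus", s = "species")
  out <- data.frame(tip_id = tip_id, stringsAsFactors = FALSE)
  for (rk in .TAXRANKS) out[[rk]] <- ""
  for (i in seq_along(lineages)) {
    for (seg in strsplit(lineages[i], ";", fixed = TRUE)[[1]]) {
      seg <- trimws(seg)
      m <- regmatches(seg, regexec("^([kdpcofgs])__(.*)$", seg))[[1]]
      if (length(m) == 3 && nzchar(m[3]))
        out[i, prefmap[[m[2]]]] <- m[3]
    }
  }
  out
}

.taxonTips <- function(taxonomy, rank, taxon) {
  taxonomy$tip_id[!is.na(taxonomy[[rank]]) & taxonomy[[rank]] == taxon]
}

.unclassifiedTips <- function(taxonomy, rank) {
  taxonomy$tip_id[is.na(taxonomy[[rank]]) | taxonomy[[rank]] == ""]
}

# precision / recall / F of assigning `taxon` (at `rank`) to tree node v.
# Unclassified tips at the rank do not count against precision.
.nodeFScore <- function(tipLabelsBelow, taxonSet, unclassifiedSet,
                        recallDenom) {
  classifiedBelow <- setdiff(tipLabelsBelow, unclassifiedSet)
  hit <- length(intersect(tipLabelsBelow, taxonSet))
  P <- if (length(classifiedBelow)) hit / length(classifiedBelow) else 0
  R <- if (recallDenom) hit / recallDenom else 0
  FF <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(precision = P, recall = R, f = FF)
}

#' F-measure of assigning a taxon to a tree node
#'
#' Precision is the fraction of the node's tips (classified at the rank)
#' that belong to the taxon; recall is the fraction of the taxon's tips in
#' the tree that fall under the node; F = 2PR/(P+R). Unclassified tips at
#' the rank are excluded from the precision denominator, mirroring the
#' relaxed monophyly convention.
#'
#' @param tree a rooted \code{phylo} or \code{AnnotatedTree}.
#' @param node internal node number.
#' @param taxon taxon name at \code{rank}.
#' @param taxonomy taxonomy data.frame (see \code{\link{readTaxonomy}}).
#' @param rank rank column holding \code{taxon}.
#' @return named vector c(precision, recall, f).
#' @export
fmeasure <- function(tree, node, taxon, taxonomy, rank) {
  phy <- asPhylo(tree)
  nt <- length(phy$tip.label)
  if (node <= nt || node > nt + phy$Nnode) stop("node must be internal")
  taxonSet <- intersect(.taxonTips(taxonomy, rank, taxon), phy$tip.label)
  if (!length(taxonSet)) stop("taxon has no tips in the tree: ", taxon)
  below <- phy$tip.label[.tipsBelow(phy)[[node]]]
  .nodeFScore(below, taxonSet, .unclassifiedTips(taxonomy, rank),
              length(taxonSet))
}

#' Strict or relaxed monophyly of a taxon's tips
#'
#' Strict: some clade's tip set equals the taxon's tips exactly. Relaxed:
#' some clade's classified tips equal the taxon's tips, any extra tips in
#' the clade being unclassified at the rank.
#'
#' @param tree a \code{phylo} or \code{AnnotatedTree}.
#' @param taxonTips nonempty character vector of the taxon's tip labels.
#' @param mode "strict" or "relaxed".
#' @param unclassified tip labels unclassified at the taxon's rank (used by
#'   relaxed mode).
#' @return logical flag.
#' @export
isMonophyletic <- function(tree, taxonTips, mode = c("strict", "relaxed"),
                           unclassified = character(0)) {
  mode <- match.arg(mode)
  phy <- asPhylo(tree)
  if (!length(taxonTips)) stop("empty taxon tip set")
  idx <- match(taxonTips, phy$tip.label)
  if (anyNA(idx)) stop("unknown tip: ", taxonTips[which(is.na(idx))[1]])
  if (length(taxonTips) == 1) return(TRUE)
  tb <- .tipsBelow(phy)
  lca <- .mrcaNodes(phy, idx)
  below <- phy$tip.label[tb[[lca]]]
  extra <- setdiff(below, taxonTips)
  if (mode == "strict") return(length(extra) == 0)
  all(extra %in% unclassified)
}

#' Classification consistency of a taxon against a tree
#'
#' The maximum over clades of min(precision, recall), with precision
#' computed over tips classified at the rank. Equals 1 exactly when the
#' taxon is strictly monophyletic (up to unclassified tips inside the
#' clade); values below 1 quantify how far the best clade is from
#' containing the taxon and nothing else.
#'
#' @inheritParams isMonophyletic
#' @return a value in [0, 1].
#' @export
consistencyScore <- function(tree, taxonTips, unclassified = character(0)) {
  phy <- asPhylo(tree)
  if (!length(taxonTips)) stop("empty taxon tip set")
  nt <- length(phy$tip.label)
  tb <- .tipsBelow(phy)
  best <- 0
  for (v in (nt + 1):(nt + phy$Nnode)) {
    sc <- .nodeFScore(phy$tip.label[tb[[v]]], taxonTips, unclassified,
                      length(taxonTips))
    best <- max(best, min(sc["precision"], sc["recall"]))
  }
  # a taxon that is a single tip, or whose best clade is a tip, is covered
  # by tip "clades" too
  if (length(taxonTips) == 1) best <- max(best, 1)
  unname(best)
}

#' Taxon quartet score
#'
#' Over quartets made of exactly 2 taxon members and 2 non-members, the
#' fraction whose induced unrooted topology pairs the two members (i.e.
#' separates the taxon from the rest). Exhaustive when the quartet count is
#' within \code{cap}, otherwise a seeded uniform sample.
#'
#' @param tree a \code{phylo} or \code{AnnotatedTree}.
#' @param taxonTips at least 2 member tips; at least 2 non-members must
#'   exist.
#' @param nSamples quartets drawn in sampled mode (default 1000).
#' @param seed RNG seed for sampled mode.
#' @param cap exhaustive ceiling (default 5e6).
#' @return list with \code{score}, \code{stderr} (NA when exhaustive) and
#'   \code{nQuartets}.
#' @export
taxonQuartetScore <- function(tree, taxonTips, nSamples = 1000, seed = 1,
                              cap = 5e6) {
  phy <- asPhylo(tree)
  members <- match(taxonTips, phy$tip.label)
  if (anyNA(members)) stop("unknown tip in taxon set")
  others <- setdiff(seq_along(phy$tip.label), members)
  if (length(members) < 2 || length(others) < 2)
    stop("need >= 2 members and >= 2 non-members")
  D <- .topoDistances(phy)
  lab <- phy$tip.label
  pairScore <- function(m1, m2, o1, o2) {
    topo <- .quartetTopology(D, c(lab[m1], lab[m2], lab[o1], lab[o2]))
    as.numeric(topo == 1L)
  }
  total <- choose(length(members), 2) * choose(length(others), 2)
  if (total <= cap) {
    mp <- combn(members, 2)
    op <- combn(others, 2)
    s <- 0
    for (i in seq_len(ncol(mp))) {
      for (j in seq_len(ncol(op))) {
        s <- s + pairScore(mp[1, i], mp[2, i], op[1, j], op[2, j])
      }
    }
    return(list(score = s / total, stderr = NA_real_, nQuartets = total))
  }
  m <- nSamples
  sc <- withr::with_seed(seed, {
    vapply(seq_len(m), function(i) {
      mm <- sample(members, 2)
      oo <- sample(others, 2)
      pairScore(mm[1], mm[2], oo[1], oo[2])
    }, numeric(1))
  })
  s <- mean(sc)
  list(score = s, stderr = sqrt(max(s * (1 - s), 1e-12) / m), nQuartets = m)
}

# is the taxon's monophyly compatible with the (possibly polytomous) tree?
.monophylyCompatible <- function(phy, taxonTips) {
  idx <- match(taxonTips, phy$tip.label)
  lca <- .mrcaNodes(phy, idx)
  tb <- .tipsBelow(phy)
  ch <- .childrenList(phy)
  if (lca <= length(phy$tip.label)) return(TRUE)
  for (c in ch[[lca]]) {
    below <- phy$tip.label[tb[[c]]]
    inTax <- below %in% taxonTips
    if (any(inTax) && !all(inTax)) return(FALSE)
  }
  TRUE
}

#' Support or rejection degree of a taxon's monophyly
#'
#' If the taxon's tips form a clade, returns the support value of the
#' branch connecting the clade to its parent (positive). Otherwise scans
#' the distinct support values from low to high and returns, with a
#' negative sign, the lowest value v such that contracting every internal
#' branch with support <= v leaves the monophyly unrejected (resolvable
#' within a polytomy).
#'
#' @param tree a \code{phylo} or \code{AnnotatedTree} carrying the support
#'   key on its internal branches.
#' @param taxonTips the taxon's tip labels; must not be all tips.
#' @param supportKey column of \code{\link{annotationTable}} to use.
#' @return a signed support degree, or NA if the taxon equals all tips.
#' @export
supportRejection <- function(tree, taxonTips, supportKey = "support") {
  phy <- asPhylo(tree)
  if (setequal(taxonTips, phy$tip.label)) return(NA_real_)
  idx <- match(taxonTips, phy$tip.label)
  if (anyNA(idx)) stop("unknown tip in taxon set")
  ann <- .parseAnnotations(tree)
  vals <- ann[[supportKey]]
  if (is.null(vals)) stop("unknown support key: ", supportKey)
  root <- .rootNode(phy)
  tb <- .tipsBelow(phy)
  lca <- .mrcaNodes(phy, idx)
  if (setequal(tb[[lca]], idx)) {
    if (lca == root) return(NA_real_)
    v <- vals[ann$node == lca]
    return(unname(v))
  }
  internal <- ann$node[ann$node != root]
  sup <- vals[ann$node != root]
  if (anyNA(sup))
    stop("support absent on an internal branch; cannot scan thresholds")
  for (v in sort(unique(sup))) {
    cut <- internal[sup <= v]
    collapsed <- .contractNodes(phy, cut)
    if (.monophylyCompatible(collapsed, taxonTips)) return(-v)
  }
  # contracting everything yields a star, which never rejects monophyly,
  # so the scan cannot fall through
  -max(sup)
}
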