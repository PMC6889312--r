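# Headline tree statistics: patristic distances, branch-contribution group
# means, the relative inter-domain distance, clade depths, the normalized
# inter-domain branch, and the three concordance metrics (RF, quartet,
# tip distance).

#' Tip-to-tip patristic distance matrix
#'
#' @param tree a \code{phylo} or \code{AnnotatedTree} with branch lengths;
#'   missing lengths are treated as 0 with a warning.
#' @return symmetric matrix of path lengths, dimnames = tip labels.
#' @export
tipDistances <- function(tree) {
  phy <- asPhylo(tree)
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; treating them as 0")
    phy$edge.length <- numeric(nrow(phy$edge))
  }
  if (anyNA(phy$edge.length)) {
    warning("missing branch lengths treated as 0")
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  m <- ape::cophenetic.phylo(phy)
  m[phy$tip.label, phy$tip.label]
}

#' Mean within- and between-group tip distances (branch-contribution engine)
#'
#' Computes mean(A-A), mean(B-B) and mean(A-B) over unordered tip pairs in
#' a single O(n) pass: each branch contributes its length times the number
#' of pairs whose path straddles it. Equals the naive all-pairs computation
#' to numerical precision.
#'
#' @param tree a \code{phylo} or \code{AnnotatedTree} with branch lengths.
#' @param partition list with character elements \code{A} and \code{B}
#'   (disjoint subsets of the tip labels; tips in neither set are ignored).
#' @return named numeric vector c(AA = , BB = , AB = ).
#' @export
groupMeanDistances <- function(tree, partition) {
  phy <- asPhylo(tree)
  A <- partition$A
  B <- partition$B
  if (length(intersect(A, B))) stop("groups overlap")
  if (!all(c(A, B) %in% phy$tip.label))
    stop("partition names tips absent from the tree")
  el <- phy$edge.length
  if (is.null(el)) {
    warning("tree has no branch lengths; treating them as 0")
    el <- numeric(nrow(phy$edge))
  }
  if (anyNA(el)) {
    warning("missing branch lengths treated as 0")
    el[is.na(el)] <- 0
  }
  nA <- length(A)
  nB <- length(B)
  inA <- phy$tip.label %in% A
  inB <- phy$tip.label %in% B
  tb <- .tipsBelow(phy)
  sAA <- sBB <- sAB <- 0
  for (i in seq_len(nrow(phy$edge))) {
    below <- tb[[phy$edge[i, 2]]]
    a <- sum(inA[below])
    b <- sum(inB[below])
    l <- el[i]
    sAA <- sAA + l * a * (nA - a)
    sBB <- sBB + l * b * (nB - b)
    sAB <- sAB + l * (a * (nB - b) + b * (nA - a))
  }
  c(AA = if (nA >= 2) sAA / choose(nA, 2) else NA_real_,
    BB = if (nB >= 2) sBB / choose(nB, 2) else NA_real_,
    AB = if (nA >= 1 && nB >= 1) sAB / (nA * nB) else NA_real_)
}

#' Relative inter-domain (A-B) distance
#'
#' mean(A-B)^2 / (mean(A-A) * mean(B-B)) over tip-pair path lengths. The
#' groups need not be monophyletic (gene trees rarely separate the domains
#' perfectly); the statistic reads as the average evolutionary distance
#' between members of the two groups relative to the within-group spread,
#' and is invariant to a global rescaling of branch lengths. Equals 1 on an
#' equal-radius star.
#'
#' @inheritParams groupMeanDistances
#' @return a non-negative scalar.
#' @export
relativeABDistance <- function(tree, partition) {
  if (length(partition$A) < 2 || length(partition$B) < 2)
    stop("each group needs at least 2 tips")
  m <- groupMeanDistances(tree, partition)
  unname(m["AB"]^2 / (m["AA"] * m["BB"]))
}

#' Depths of a clade's tips to their common ancestor
#'
#' For each tip in \code{tipset}, the sum of branch lengths from the tip to
#' the lowest common ancestor of the set.
#'
#' @param tree a rooted \code{phylo} or \code{AnnotatedTree}.
#' @param tipset character vector of tip labels (nonempty).
#' @return list with \code{depths} (named vector) and \code{median}.
#' @export
cladeDepths <- function(tree, tipset) {
  phy <- asPhylo(tree)
  if (!length(tipset)) stop("empty tip set")
  idx <- match(tipset, phy$tip.label)
  if (anyNA(idx)) stop("unknown tip: ", tipset[which(is.na(idx))[1]])
  lca <- .mrcaNodes(phy, idx)
  d <- .nodeDepths(phy)
  depths <- d[idx] - d[lca]
  names(depths) <- tipset
  list(depths = depths, median = median(depths))
}

#' Inter-domain branch length normalized by tip depth
#'
#' Path length between the common ancestors of the two (monophyletic)
#' domains, divided by the median over tips of the depth to their own
#' domain ancestor (\code{baseline = "domain"}), or to the root
#' (\code{baseline = "root"}). Scale-invariant. For non-monophyletic
#' groups (e.g. gene trees) use \code{\link{relativeABDistance}}.
#'
#' @inheritParams groupMeanDistances
#' @param baseline depth definition for the denominator.
#' @return a non-negative scalar.
#' @export
normalizedABBranch <- function(tree, partition,
                               baseline = c("domain", "root")) {
  baseline <- match.arg(baseline)
  phy <- asPhylo(tree)
  tb <- .tipsBelow(phy)
  check <- function(tips) {
    idx <- match(tips, phy$tip.label)
    lca <- .mrcaNodes(phy, idx)
    if (!setequal(tb[[lca]], idx))
      stop("group is not monophyletic on this tree; use relativeABDistance")
    lca
  }
  lcaA <- check(partition$A)
  lcaB <- check(partition$B)
  d <- .nodeDepths(phy)
  anc <- .mrcaNodes(phy, c(lcaA, lcaB))
  branch <- d[lcaA] + d[lcaB] - 2 * d[anc]
  tips <- c(partition$A, partition$B)
  idx <- match(tips, phy$tip.label)
  depths <- if (baseline == "domain") {
    ifelse(tips %in% partition$A, d[idx] - d[lcaA], d[idx] - d[lcaB])
  } else {
    d[idx]
  }
  md <- median(depths)
  if (md == 0) {
    if (branch == 0) return(0)
    stop("median tip depth is zero; normalization undefined")
  }
  unname(branch / md)
}

#' Tip-distance metric between two trees
#'
#' (1 - r) / 2, where r is the Pearson correlation between the two trees'
#' tip-to-tip distance matrices restricted to shared taxa (strict upper
#' triangles). 0 for identical (or proportionally scaled) trees. Returns
#' NA when either matrix is constant.
#'
#' @param tree1,tree2 trees sharing at least 3 tips.
#' @return a value in [0, 1], or NA_real_.
#' @export
tipDistanceMetric <- function(tree1, tree2) {
  sh <- shearTrees(tree1, tree2)
  t1 <- asPhylo(sh$tree1)
  t2 <- asPhylo(sh$tree2)
  taxa <- sort(t1$tip.label)
  m1 <- tipDistances(t1)[taxa, taxa]
  m2 <- tipDistances(t2)[taxa, taxa]
  v1 <- m1[upper.tri(m1)]
  v2 <- m2[upper.tri(m2)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
  (1 - cor(v1, v2)) / 2
}

# canonical keys of the non-trivial bipartitions of a tree (unrooted sense)
.bipartitionKeys <- function(phy) {
  nt <- length(phy$tip.label)
  if (nt < 4) return(character(0))
  ref <- sort(phy$tip.label)[1]
  tb <- .tipsBelow(phy)
  root <- .rootNode(phy)
  keys <- character(0)
  for (i in seq_len(nrow(phy$edge))) {
    v <- phy$edge[i, 2]
    if (v <= nt) next
    side <- phy$tip.label[tb[[v]]]
    if (length(side) < 2 || length(side) > nt - 2) next
    if (ref %in% side) side <- setdiff(phy$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the trees' non-trivial bipartitions
#' on their shared taxa; when \code{normalized}, divided by the total
#' number of non-trivial bipartitions in the two trees (so polytomous trees
#' normalize by what they can resolve).
#'
#' @param tree1,tree2 trees sharing at least 4 tips.
#' @param normalized return the normalized distance (default TRUE).
#' @return a count, or a value in [0, 1] when normalized.
#' @export
rfDistance <- function(tree1, tree2, normalized = TRUE) {
  sh <- shearTrees(tree1, tree2)
  t1 <- asPhylo(sh$tree1)
  t2 <- asPhylo(sh$tree2)
  if (length(t1$tip.label) < 4)
    stop("RF distance requires at least 4 shared tips")
  k1 <- .bipartitionKeys(t1)
  k2 <- .bipartitionKeys(t2)
  rf <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
  if (!normalized) return(rf)
  denom <- length(k1) + length(k2)
  if (denom == 0) return(0)
  rf / denom
}

# topology of quartet q (tip indices) from a topological distance matrix:
# 1 = q1q2|q3q4, 2 = q1q3|q2q4, 3 = q1q4|q2q3, 0 = unresolved
.quartetTopology <- function(D, q) {
  s <- c(D[q[1], q[2]] + D[q[3], q[4]],
         D[q[1], q[3]] + D[q[2], q[4]],
         D[q[1], q[4]] + D[q[2], q[3]])
  w <- which(s == min(s))
  if (length(w) > 1) 0L else w
}

.topoDistances <- function(phy) {
  phy$edge.length <- rep(1, nrow(phy$edge))
  ape::cophenetic.phylo(phy)
}

# unrank 4-subsets of 1..n from combination indices (colex order)
.unrankQuartet <- function(r, n) {
  q <- integer(4)
  for (k in 4:1) {
    v <- k - 1
    while (choose(v + 1, k) <= r) v <- v + 1
    q[k] <- v + 1
    r <- r - choose(v, k)
  }
  q
}

#' Quartet concordance between two trees
#'
#' Fraction of 4-tip subsets of the shared taxa whose induced unrooted
#' topologies agree; an unresolved induced quartet in either tree counts as
#' 1/3 agreement (the expectation under random resolution). Exhaustive up
#' to \code{cap} quartets, otherwise (or on request) a uniform seeded
#' sample without replacement, with a binomial standard error.
#'
#' @param tree1,tree2 trees sharing at least 4 tips.
#' @param mode "auto" (exhaustive when within cap), "exhaustive", or
#'   "sampled".
#' @param nSamples number of quartets in sampled mode (default 1000).
#' @param seed RNG seed for sampled mode.
#' @param cap exhaustive-mode ceiling on C(n, 4) (default 5e6).
#' @return list with \code{score}, \code{stderr} (NA in exhaustive mode)
#'   and \code{nQuartets}.
#' @export
quartetConcordance <- function(tree1, tree2,
                               mode = c("auto", "exhaustive", "sampled"),
                               nSamples = 1000, seed = 1, cap = 5e6) {
  mode <- match.arg(mode)
  sh <- shearTrees(tree1, tree2)
  t1 <- asPhylo(sh$tree1)
  t2 <- asPhylo(sh$tree2)
  taxa <- sort(t1$tip.label)
  n <- length(taxa)
  if (n < 4) stop("need at least 4 shared tips")
  D1 <- .topoDistances(t1)[taxa, taxa]
  D2 <- .topoDistances(t2)[taxa, taxa]
  total <- choose(n, 4)
  if (mode == "auto") mode <- if (total <= cap) "exhaustive" else "sampled"
  if (mode == "exhaustive" && total > cap)
    stop("C(n,4) exceeds the exhaustive cap; use sampled mode")
  agree1 <- function(q) {
    a <- .quartetTopology(D1, q)
    b <- .quartetTopology(D2, q)
    if (a == 0L || b == 0L) 1 / 3 else as.numeric(a == b)
  }
  if (mode == "exhaustive") {
    qs <- combn(n, 4)
    sc <- mean(apply(qs, 2, agree1))
    return(list(score = sc, stderr = NA_real_, nQuartets = total))
  }
  m <- min(nSamples, total)
  ranks <- withr::with_seed(seed, sample.int(total, m) - 1)
  sc <- mean(vapply(ranks, function(r) agree1(.unrankQuartet(r, n)),
                    numeric(1)))
  list(score = sc, stderr = sqrt(max(sc * (1 - sc), 1e-12) / m),
       nQuartets = m)
}
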