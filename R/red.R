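# Relative evolutionary divergence (RED): a [0,1] normalization of node
# depth (root 0, tips 1) that is robust to rate variation across clades,
# used to pick deep, evenly spread taxon subsamples.

#' RED values for all nodes of a rooted tree
#'
#' RED(root) = 0 and RED(tip) = 1. For an internal node n with parent p,
#' RED(n) = RED(p) + (d/u) * (1 - RED(p)), where d is the branch length
#' from p to n and u is the mean length of the paths from p to the tips
#' descending from n (i.e. d plus the mean tip distance from n). RED is
#' monotone non-decreasing along every root-to-tip path.
#'
#' @param tree a rooted \code{phylo} or \code{AnnotatedTree} with branch
#'   lengths.
#' @return numeric vector indexed by node number (tips first), with tip
#'   labels / node labels as names where available.
#' @export
redValues <- function(tree) {
  phy <- asPhylo(tree)
  if (!ape::is.rooted(phy)) stop("RED requires a rooted tree")
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  depth <- .nodeDepths(phy)
  tb <- .tipsBelow(phy)
  len <- .edgeAbove(phy)
  # mean distance from each node down to its descendant tips
  meanTip <- vapply(seq_len(nt + nn), function(v)
    mean(depth[tb[[v]]]) - depth[v], numeric(1))
  red <- rep(NA_real_, nt + nn)
  root <- .rootNode(phy)
  pa <- .parentVec(phy)
  red[root] <- 0
  for (v in .preorder(phy)) {
    if (v == root) next
    p <- pa[v]
    if (v <= nt) {
      red[v] <- 1
      next
    }
    d <- len[v]
    if (is.na(d)) d <- 0
    u <- d + meanTip[v]
    if (u <= 0) {
      warning(sprintf("zero root-to-tip span at node %d; RED set to parent's", v))
      red[v] <- red[p]
    } else {
      red[v] <- red[p] + (d / u) * (1 - red[p])
    }
  }
  nm <- character(nt + nn)
  nm[seq_len(nt)] <- phy$tip.label
  if (!is.null(phy$node.label)) nm[(nt + 1):(nt + nn)] <- phy$node.label
  names(red) <- nm
  red
}

#' RED-guided taxon downsampling
#'
#' Selects n disjoint clades by walking the RED list from the low end:
#' each node is added to the selection and any of its ancestors currently
#' selected are dropped, until exactly n clades are selected. Within each
#' clade one representative tip is chosen by sequential criteria:
#' (1) highest marker-gene count; (2) lowest contamination; (3) highest DNA
#' quality score; (4) seeded random draw among remaining ties.
#'
#' @param tree a rooted \code{phylo} or \code{AnnotatedTree} with branch
#'   lengths.
#' @param n number of clades/taxa to retain (<= number of tips).
#' @param metadata data.frame with columns genome_id, marker_count,
#'   contamination, quality_score covering every tip.
#' @param seed RNG seed for the final random tie-break.
#' @return data.frame with columns clade_node, red, tip (one row per
#'   selected clade, ordered by RED).
#' @export
redDownsample <- function(tree, n, metadata, seed = 1) {
  phy <- asPhylo(tree)
  nt <- length(phy$tip.label)
  if (n > nt) stop("n exceeds the number of tips")
  red <- redValues(phy)
  pa <- .parentVec(phy)
  ord <- order(red, seq_along(red))
  selected <- integer(0)
  for (v in ord) {
    anc <- .ancestors(pa, v)
    selected <- setdiff(selected, anc)
    selected <- c(selected, v)
    if (length(selected) == n) break
  }
  if (length(selected) != n)
    stop("could not reach the requested number of clades")
  tb <- .tipsBelow(phy)
  pickTip <- function(tips) {
    ids <- phy$tip.label[tips]
    md <- metadata[match(ids, metadata$genome_id), , drop = FALSE]
    if (anyNA(md$genome_id))
      stop("metadata missing for tip: ", ids[which(is.na(md$genome_id))[1]])
    keep <- md$marker_count == max(md$marker_count)
    md <- md[keep, , drop = FALSE]
    md <- md[md$contamination == min(md$contamination), , drop = FALSE]
    md <- md[md$quality_score == max(md$quality_score), , drop = FALSE]
    if (nrow(md) == 1) md$genome_id else sample(md$genome_id, 1)
  }
  withr::with_seed(seed, {
    data.frame(clade_node = selected, red = unname(red[selected]),
               tip = vapply(selected, function(v) pickTip(tb[[v]]),
                            character(1)),
               stringsAsFactors = FALSE)
  })
}
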