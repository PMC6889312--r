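# Tree post-manipulations: rooting between two domains, stable node IDs,
# shearing to shared tips, predicate-based branch collapsing, and support
# threshold matching between trees of different support types.

.rewrap <- function(tree, phy) {
  if (is(tree, "AnnotatedTree"))
    new("AnnotatedTree", tree = phy, dialect = tree@dialect)
  else phy
}

#' Root a tree on the branch separating two tip sets
#'
#' Places the root on the single branch that separates \code{tipsA} from
#' \code{tipsB} (e.g. the Archaea and Bacteria tips), splitting that branch
#' length equally between the two root edges. Tip-to-tip path lengths are
#' unchanged.
#'
#' @param tree a \code{phylo} or \code{AnnotatedTree}; \code{tipsA} and
#'   \code{tipsB} must partition its tips and be separable by one branch.
#' @param tipsA,tipsB character vectors of tip labels.
#' @return the rooted tree, same class as the input; the root has exactly
#'   two children, one ancestral to each set.
#' @export
rootBetween <- function(tree, tipsA, tipsB) {
  phy <- asPhylo(tree)
  tips <- phy$tip.label
  if (length(intersect(tipsA, tipsB)))
    stop("tip sets overlap: ", intersect(tipsA, tipsB)[1])
  if (!setequal(union(tipsA, tipsB), tips))
    stop("tipsA and tipsB must partition the tips of the tree")
  un <- if (ape::is.rooted(phy)) ape::unroot(phy) else phy
  tb <- .tipsBelow(un)
  nt <- length(un$tip.label)
  found <- NULL
  for (i in seq_len(nrow(un$edge))) {
    S <- un$tip.label[tb[[un$edge[i, 2]]]]
    if (setequal(S, tipsA) || setequal(S, tipsB)) {
      found <- i
      break
    }
  }
  if (is.null(found)) {
    lca <- .mrcaNodes(un, match(tipsA, un$tip.label))
    bad <- setdiff(un$tip.label[tb[[lca]]], tipsA)
    stop(sprintf(
      "tip sets are not separated by a single branch (e.g. tip '%s' groups inside the other set)",
      if (length(bad)) bad[1] else tipsA[1]))
  }
  w <- if (is.null(un$edge.length)) 0 else un$edge.length[found]
  if (is.na(w)) w <- 0
  og <- un$tip.label[tb[[un$edge[found, 2]]]]
  rooted <- ape::root(un, outgroup = og, resolve.root = TRUE,
                      edgelabel = TRUE)
  root <- .rootNode(rooted)
  kids <- which(rooted$edge[, 1] == root)
  if (length(kids) != 2L) stop("internal error: root is not bifurcating")
  if (is.null(rooted$edge.length))
    rooted$edge.length <- numeric(nrow(rooted$edge))
  rooted$edge.length[kids] <- w / 2
  .rewrap(tree, rooted)
}

#' Assign stable internal node identifiers
#'
#' Sorts the children of every internal node ascending by descendant count
#' (ties by smallest descendant tip name), then labels internal nodes
#' "N1", "N2", ... in a preorder traversal from the root; so the root is N1
#' and, on a domain-rooted tree, the two domain ancestors are N2 and N3.
#'
#' @param tree a rooted \code{phylo} or \code{AnnotatedTree}.
#' @return a \code{phylo} with reordered children and node labels N1..Nk.
#' @export
assignNodeIds <- function(tree) {
  phy <- asPhylo(tree)
  if (!ape::is.rooted(phy)) stop("assignNodeIds requires a rooted tree")
  tb <- .tipsBelow(phy)
  ord <- function(v, kids) {
    nkid <- lengths(tb[kids])
    minlab <- vapply(kids, function(k) min(phy$tip.label[tb[[k]]]),
                     character(1))
    kids[order(nkid, minlab)]
  }
  out <- .readNewickRaw(.writeNewickString(phy, childOrder = ord))
  nt <- length(out$tip.label)
  pre <- .preorder(out)
  internals <- pre[pre > nt]
  out$node.label <- character(out$Nnode)
  out$node.label[internals - nt] <- paste0("N", seq_along(internals))
  out
}

#' Restrict two trees to their shared tips
#'
#' Both trees are pruned to the intersection of their tip sets; unbranched
#' internal nodes left behind are suppressed with their branch lengths
#' summed, so pairwise distances among surviving tips are preserved.
#'
#' @param tree1,tree2 \code{phylo} or \code{AnnotatedTree} objects sharing
#'   at least 3 tips.
#' @return a list with elements \code{tree1} and \code{tree2}.
#' @export
shearTrees <- function(tree1, tree2) {
  p1 <- asPhylo(tree1)
  p2 <- asPhylo(tree2)
  shared <- intersect(p1$tip.label, p2$tip.label)
  if (length(shared) < 3)
    stop(sprintf("trees share only %d tips; at least 3 required",
                 length(shared)))
  s1 <- if (length(shared) < length(p1$tip.label))
    ape::keep.tip(p1, shared) else p1
  s2 <- if (length(shared) < length(p2$tip.label))
    ape::keep.tip(p2, shared) else p2
  list(tree1 = .rewrap(tree1, s1), tree2 = .rewrap(tree2, s2))
}

.contractNodes <- function(phy, nodes) {
  if (!length(nodes)) return(phy)
  tab <- .phyloToTable(phy)
  n <- length(tab$parent)
  flag <- rep(FALSE, n)
  flag[nodes] <- TRUE
  flag[tab$root] <- FALSE
  flag[tab$isTip] <- FALSE
  for (v in seq_len(n)) {
    if (flag[v]) next
    p <- tab$parent[v]
    if (is.na(p)) next
    while (!is.na(p) && flag[p]) p <- tab$parent[p]
    tab$parent[v] <- p
  }
  tab$dead <- flag
  .tableToPhylo(tab)
}

#' Collapse internal branches matching a predicate into polytomies
#'
#' The predicate is evaluated on each internal branch's annotation row (see
#' \code{\link{annotationTable}}); branches for which it returns TRUE are
#' contracted, promoting the child's children. Tip branches are never
#' contracted. The classic low-support rule of the two-domain study is
#' \code{function(a) a$en <= 5 & a$lpp <= 0.5}.
#'
#' @param tree a \code{phylo} or \code{AnnotatedTree} with annotations.
#' @param predicate function of one annotation row returning TRUE/FALSE;
#'   an NA result (annotation absent on that branch) is an error.
#' @return list with \code{tree} (same class as input) and \code{nInternal}
#'   (internal node count after collapsing).
#' @export
collapseBranches <- function(tree, predicate) {
  phy <- asPhylo(tree)
  ann <- .parseAnnotations(tree)
  nt <- length(phy$tip.label)
  root <- .rootNode(phy)
  cand <- ann$node[ann$node != root]
  hit <- integer(0)
  for (v in cand) {
    row <- ann[ann$node == v, , drop = FALSE]
    res <- predicate(row)
    if (length(res) != 1L || is.na(res))
      stop(sprintf(
        "predicate is undefined on internal branch above node %d (label '%s'): annotation absent",
        v, row$label))
    if (isTRUE(res)) hit <- c(hit, v)
  }
  out <- .contractNodes(phy, hit)
  list(tree = .rewrap(tree, out), nInternal = out$Nnode)
}

#' Collapse lowest-support branches until a target resolution is reached
#'
#' Contracts internal branches in ascending order of a chosen support value
#' until the internal node count equals \code{nInternalGoal}; branches tied
#' on support are contracted together. If a tie block would overshoot the
#' goal, collapsing stops before the block and the nearest achievable count
#' is reported with a warning. Used to put trees with incomparable support
#' types (e.g. local posterior probability vs. bootstrap) on an equal
#' resolution footing.
#'
#' @param tree a \code{phylo} or \code{AnnotatedTree} with the support key
#'   present on all internal branches.
#' @param supportKey column of \code{\link{annotationTable}} to rank by
#'   (e.g. "lpp", "bootstrap", "support").
#' @param nInternalGoal target number of internal nodes (<= current count).
#' @return list with \code{threshold} (support of the last contracted
#'   branch; -Inf if nothing was contracted), \code{tree}, and
#'   \code{nInternal}.
#' @export
matchResolution <- function(tree, supportKey = "support", nInternalGoal) {
  phy <- asPhylo(tree)
  ann <- .parseAnnotations(tree)
  root <- .rootNode(phy)
  nt <- length(phy$tip.label)
  ann <- ann[ann$node != root, , drop = FALSE]
  # only branches subtending internal nodes can be contracted
  vals <- ann[[supportKey]]
  if (is.null(vals)) stop("unknown support key: ", supportKey)
  if (anyNA(vals))
    stop(sprintf("support '%s' absent on internal branch above node %d",
                 supportKey, ann$node[which(is.na(vals))[1]]))
  if (nInternalGoal > phy$Nnode)
    stop("goal exceeds the current internal node count")
  ord <- order(vals, ann$node)
  nodes <- ann$node[ord]
  svals <- vals[ord]
  cut <- integer(0)
  threshold <- -Inf
  count <- phy$Nnode
  for (v in unique(svals)) {
    block <- nodes[svals == v]
    if (count - length(block) < nInternalGoal) break
    cut <- c(cut, block)
    count <- count - length(block)
    threshold <- v
    if (count == nInternalGoal) break
  }
  if (count != nInternalGoal)
    warning(sprintf(
      "tied support values prevent reaching exactly %d internal nodes; nearest achievable is %d",
      nInternalGoal, count))
  out <- .contractNodes(phy, cut)
  list(threshold = threshold, tree = .rewrap(tree, out),
       nInternal = out$Nnode)
}
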