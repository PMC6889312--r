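# Internal phylo plumbing shared by the tree modules. All helpers operate on
# plain ape phylo objects and node numbers (tips 1..Ntip, internals follow).

.rootNode <- function(phy) {
  unique(phy$edge[, 1][!phy$edge[, 1] %in% phy$edge[, 2]])[1]
}

.parentVec <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  pa <- rep(NA_integer_, n)
  pa[phy$edge[, 2]] <- phy$edge[, 1]
  pa
}

# children in edge-matrix (cladewise/newick) order
.childrenList <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    ch[[p]] <- c(ch[[p]], phy$edge[i, 2])
  }
  ch
}

# length of the edge above each node (NA for the root)
.edgeAbove <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  len <- rep(NA_real_, n)
  if (!is.null(phy$edge.length)) len[phy$edge[, 2]] <- phy$edge.length
  else len[phy$edge[, 2]] <- 0
  len
}

# list: node number -> integer vector of descendant tip numbers
.tipsBelow <- function(phy) {
  nt <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")$edge
  res <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nt)) res[[i]] <- i
  for (j in seq_len(nrow(po))) {
    res[[po[j, 1]]] <- c(res[[po[j, 1]]], res[[po[j, 2]]])
  }
  res
}

# distance from the root to every node; missing lengths count as 0 (warns)
.nodeDepths <- function(phy, warn = TRUE) {
  nt <- length(phy$tip.label)
  co <- ape::reorder.phylo(phy, "cladewise")
  el <- co$edge.length
  if (is.null(el)) {
    if (warn) warning("tree has no branch lengths; treating them as 0")
    el <- numeric(nrow(co$edge))
  }
  if (anyNA(el)) {
    if (warn) warning("missing branch lengths treated as 0")
    el[is.na(el)] <- 0
  }
  d <- numeric(nt + phy$Nnode)
  for (j in seq_len(nrow(co$edge))) {
    d[co$edge[j, 2]] <- d[co$edge[j, 1]] + el[j]
  }
  d
}

.ancestors <- function(pa, v) {
  out <- integer(0)
  while (!is.na(pa[v])) {
    v <- pa[v]
    out <- c(out, v)
  }
  out
}

# most recent common ancestor of a set of node numbers
.mrcaNodes <- function(phy, nodes) {
  if (length(nodes) == 1L) return(nodes)
  pa <- .parentVec(phy)
  chain <- c(nodes[1], .ancestors(pa, nodes[1]))
  for (v in nodes[-1]) {
    keep <- c(v, .ancestors(pa, v))
    chain <- chain[chain %in% keep]
  }
  chain[1]
}

# preorder node numbers (root first, children in stored order)
.preorder <- function(phy) {
  ch <- .childrenList(phy)
  root <- .rootNode(phy)
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[1]
    stack <- stack[-1]
    out <- c(out, v)
    if (!is.null(ch[[v]])) stack <- c(ch[[v]], stack)
  }
  out
}

.needsQuote <- function(lab) {
  grepl("[][(),:;'\" \t=]", lab)
}

.quoteLabel <- function(lab) {
  ifelse(is.na(lab) | lab == "", "",
         ifelse(.needsQuote(lab), paste0("'", lab, "'"), lab))
}

.fmtLen <- function(x) {
  ifelse(is.na(x), "", paste0(":", vapply(x, function(v)
    sprintf("%.15g", v), character(1))))
}

# Serialize a phylo (with optional node labels) to Newick, quoting labels
# that contain Newick syntax characters. Children kept in stored order
# unless childOrder is a function(node, children) -> reordered children.
.writeNewickString <- function(phy, childOrder = NULL) {
  nt <- length(phy$tip.label)
  ch <- .childrenList(phy)
  len <- .edgeAbove(phy)
  nl <- phy$node.label
  rec <- function(v) {
    if (v <= nt) {
      tok <- .quoteLabel(phy$tip.label[v])
    } else {
      kids <- ch[[v]]
      if (!is.null(childOrder)) kids <- childOrder(v, kids)
      inner <- vapply(kids, rec, character(1))
      lab <- if (!is.null(nl)) nl[v - nt] else ""
      if (is.na(lab)) lab <- ""
      tok <- paste0("(", paste(inner, collapse = ","), ")", .quoteLabel(lab))
    }
    if (!is.na(len[v])) tok <- paste0(tok, .fmtLen(len[v])) else tok
  }
  paste0(rec(.rootNode(phy)), ";")
}

# Rebuild a phylo from a parent-vector "node table". Nodes flagged dead are
# skipped; a live internal node must have >= 2 live children except the root
# (callers are responsible for suppressing unbranched nodes beforehand).
# tab: list(parent = int vec, length = num vec, label = chr vec,
#           isTip = logical vec, root = int, dead = logical vec)
.tableToPhylo <- function(tab) {
  n <- length(tab$parent)
  kids <- vector("list", n)
  for (v in seq_len(n)) {
    if (tab$dead[v] || v == tab$root) next
    p <- tab$parent[v]
    kids[[p]] <- c(kids[[p]], v)
  }
  rec <- function(v) {
    if (tab$isTip[v]) {
      tok <- .quoteLabel(tab$label[v])
    } else {
      inner <- vapply(kids[[v]], rec, character(1))
      lab <- tab$label[v]
      if (is.na(lab)) lab <- ""
      tok <- paste0("(", paste(inner, collapse = ","), ")", .quoteLabel(lab))
    }
    if (v != tab$root && !is.na(tab$length[v]))
      tok <- paste0(tok, .fmtLen(tab$length[v]))
    tok
  }
  .readNewickRaw(paste0(rec(tab$root), ";"))
}

# phylo -> node table (see .tableToPhylo)
.phyloToTable <- function(phy) {
  nt <- length(phy$tip.label)
  n <- nt + phy$Nnode
  lab <- character(n)
  lab[seq_len(nt)] <- phy$tip.label
  if (!is.null(phy$node.label)) lab[(nt + 1):n] <- phy$node.label
  list(parent = .parentVec(phy), length = .edgeAbove(phy), label = lab,
       isTip = seq_len(n) <= nt, root = .rootNode(phy),
       dead = rep(FALSE, n))
}
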