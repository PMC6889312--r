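# F-measure taxonomy decoration: assign every taxon (per rank) to the tree
# node(s) that best contain it, suffix para/polyphyletic taxa by clade size,
# then re-derive per-tip lineages from the decorated nodes and back-fill
# single-genome taxa.

#' Decorate a tree with taxonomic labels and curate the taxonomy
#'
#' For each rank and each taxon with at least two classified tips, the
#' internal node maximizing the F-measure (see \code{\link{fmeasure}}) is
#' assigned the taxon; tips of the taxon left uncovered are assigned
#' further clades greedily. Every accepted clade must hold a strict
#' majority (precision > \code{minPrecision}) of classified tips carrying
#' the taxon, and a secondary clade must cover at least \code{minorFrac}
#' of the tips covered by the first clade, so isolated mislabeled tips do
#' not seed spurious clades (the same minor-clade floor used when
#' reporting polyphyletic groups). When a taxon ends
#' up on k > 1 disjoint clades the labels get numeric suffixes "_1".."_k"
#' ordered by descendant count (ties by smallest tip name). Lineages are
#' then re-derived for every tip from the smallest decorated clade
#' containing it at each rank, which corrects mislabeled tips and fills
#' unclassified ones; taxa represented by a single genome are back-filled
#' from the input taxonomy.
#'
#' @param tree a rooted \code{phylo} or \code{AnnotatedTree}.
#' @param taxonomy taxonomy data.frame (see \code{\link{readTaxonomy}})
#'   covering the tree tips.
#' @param ranks rank columns to decorate (default: all seven).
#' @param minPrecision precision floor for accepting a clade (default 0.5,
#'   strict).
#' @param minorFrac secondary clades covering fewer than this fraction of
#'   the primary clade's covered tips are dropped (default 0.05).
#' @return a \code{\linkS4class{TreeDecoration}}.
#' @export
decorateTree <- function(tree, taxonomy, ranks = .TAXRANKS,
                         minPrecision = 0.5, minorFrac = 0.05) {
  phy <- asPhylo(tree)
  if (!ape::is.rooted(phy)) stop("decoration requires a rooted tree")
  if (!nrow(taxonomy)) stop("empty taxonomy")
  taxonomy <- taxonomy[taxonomy$tip_id %in% phy$tip.label, , drop = FALSE]
  if (!nrow(taxonomy)) stop("taxonomy covers none of the tree tips")
  nt <- length(phy$tip.label)
  tb <- .tipsBelow(phy)
  internals <- (nt + 1):(nt + phy$Nnode)
  belowLabels <- lapply(tb, function(v) phy$tip.label[v])
  asg <- list()
  k <- 0L
  for (rk in intersect(ranks, names(taxonomy))) {
    uncl <- .unclassifiedTips(taxonomy, rk)
    vals <- taxonomy[[rk]]
    taxa <- sort(unique(vals[!is.na(vals) & vals != ""]))
    for (tx in taxa) {
      tipsT <- .taxonTips(taxonomy, rk, tx)
      if (length(tipsT) < 2) next  # single-genome taxa back-filled later
      remaining <- tipsT
      clades <- list()
      while (length(remaining)) {
        bestF <- -1
        bestV <- NA_integer_
        bestSc <- NULL
        for (v in internals) {
          below <- belowLabels[[v]]
          if (!any(remaining %in% below)) next
          sc <- .nodeFScore(below, remaining, uncl, length(remaining))
          # prefer higher F; on (near) ties prefer the larger clade
          if (sc["f"] > bestF + 1e-12 ||
              (abs(sc["f"] - bestF) <= 1e-12 && !is.na(bestV) &&
               length(below) > length(belowLabels[[bestV]]))) {
            bestF <- sc["f"]
            bestV <- v
            bestSc <- sc
          }
        }
        if (is.na(bestV) || bestF <= 0) break
        if (bestSc["precision"] <= minPrecision) break
        covered <- intersect(belowLabels[[bestV]], remaining)
        if (!length(covered)) break
        if (length(clades) >= 1 &&
            length(covered) < minorFrac * clades[[1]]$ncovered) break
        clades[[length(clades) + 1L]] <- list(node = bestV, sc = bestSc,
                                              ncovered = length(covered))
        remaining <- setdiff(remaining, belowLabels[[bestV]])
      }
      if (!length(clades)) next
      sizes <- vapply(clades, function(cl) length(belowLabels[[cl$node]]),
                      numeric(1))
      minTip <- vapply(clades, function(cl) min(belowLabels[[cl$node]]),
                       character(1))
      ord <- order(-sizes, minTip)
      for (j in seq_along(ord)) {
        cl <- clades[[ord[j]]]
        k <- k + 1L
        asg[[k]] <- data.frame(
          node = cl$node, rank = rk, taxon = tx,
          label = if (length(clades) > 1) sprintf("%s_%d", tx, j) else tx,
          precision = unname(cl$sc["precision"]),
          recall = unname(cl$sc["recall"]), f = unname(cl$sc["f"]),
          ntips = length(belowLabels[[cl$node]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  assignments <- if (k) do.call(rbind, asg) else
    data.frame(node = integer(0), rank = character(0), taxon = character(0),
               label = character(0), precision = numeric(0),
               recall = numeric(0), f = numeric(0), ntips = integer(0))

  # curated lineages: smallest decorated clade containing each tip per rank
  curated <- data.frame(tip_id = phy$tip.label, stringsAsFactors = FALSE)
  for (rk in intersect(ranks, names(taxonomy))) {
    col <- rep("", nt)
    rkAsg <- assignments[assignments$rank == rk, , drop = FALSE]
    if (nrow(rkAsg)) {
      ordSize <- order(rkAsg$ntips)
      for (j in ordSize) {
        tipsIn <- tb[[rkAsg$node[j]]]
        col[tipsIn[col[tipsIn] == ""]] <- rkAsg$label[j]
      }
      # nested decorated clades: smallest wins, so fill in size order and
      # never overwrite
    }
    # back-fill: keep the original label for tips of single-genome taxa
    vals <- taxonomy[[rk]]
    counts <- table(vals[!is.na(vals) & vals != ""])
    singles <- names(counts)[counts == 1]
    soloTips <- taxonomy$tip_id[vals %in% singles]
    idx <- match(soloTips, phy$tip.label)
    orig <- vals[match(soloTips, taxonomy$tip_id)]
    fill <- !is.na(idx) & col[idx] == ""
    col[idx[fill]] <- orig[fill]
    # rescue tips outside every decorated clade: walk up the ancestors and
    # adopt the first strict-majority curated label among the tips below
    pa <- .parentVec(phy)
    snapshot <- col
    for (i in which(col == "")) {
      v <- pa[i]
      while (!is.na(v)) {
        labs <- snapshot[tb[[v]]]
        labs <- labs[labs != ""]
        if (length(labs)) {
          cnt <- sort(table(labs), decreasing = TRUE)
          if (cnt[1] > 0.5 * length(labs)) {
            col[i] <- names(cnt)[1]
            break
          }
        }
        v <- pa[v]
      }
    }
    curated[[rk]] <- col
  }
  new("TreeDecoration", tree = phy, assignments = assignments,
      curated = curated)
}
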