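# Seeded synthetic-data generators emulating a two-domain genome
# collection: species tree, discordant gene trees (random SPR + dropout),
# rate-class amino-acid alignments, clade-consistent taxonomies with
# planted noise, genome sequence pairs with planted k-mer overlap, and
# genome metadata. Every generator is a pure function of (spec, seed).

#' Simulate a two-domain species tree
#'
#' Two seeded pure-birth ultrametric clades (depth rescaled to \code{h})
#' joined by a connecting branch of length \code{L}, rooted on that branch
#' (L/2 on each side). Optional lognormal multiplicative branch noise.
#' Tips are labeled A0001.. and B0001.. For a fixed seed the clades are
#' identical across different \code{L}, so inter-domain statistics can be
#' swept over L with clade shapes held constant.
#'
#' @param nA,nB tips per domain (>= 2).
#' @param h ultrametric clade depth, substitutions/site (default 1).
#' @param L connecting branch length (default 0.1).
#' @param birth pure-birth rate used to draw the clade shapes (default 1).
#' @param noiseSd sd of lognormal branch noise (0 = none).
#' @param seed RNG seed.
#' @return list with \code{tree} (rooted phylo) and \code{partition}
#'   (list A, B of tip labels).
#' @export
simulateSpeciesTree <- function(nA, nB, h = 1, L = 0.1, birth = 1,
                                noiseSd = 0, seed = 1) {
  stopifnot(nA >= 2, nB >= 2, L >= 0, h > 0, noiseSd >= 0)
  clade <- function(n, pref, s) {
    phy <- withr::with_seed(s, ape::rphylo(n, birth = birth, death = 0))
    depth <- max(.nodeDepths(phy, warn = FALSE))
    phy$edge.length <- phy$edge.length * (h / depth)
    phy$tip.label <- sprintf("%s%04d", pref, seq_len(n))
    phy
  }
  ca <- clade(nA, "A", seed)
  cb <- clade(nB, "B", seed + 104729L)
  nwk <- function(p) sub(";$", "", .writeNewickString(p))
  text <- sprintf("(%s:%.15g,%s:%.15g);", nwk(ca), L / 2, nwk(cb), L / 2)
  tree <- .readNewickRaw(text)
  if (noiseSd > 0) {
    tree$edge.length <- withr::with_seed(seed + 2L,
      tree$edge.length * rlnorm(length(tree$edge.length),
                                meanlog = -noiseSd^2 / 2, sdlog = noiseSd))
  }
  list(tree = tree,
       partition = list(A = sprintf("A%04d", seq_len(nA)),
                        B = sprintf("B%04d", seq_len(nB))))
}

# one random subtree-prune-regraft move, preserving branch lengths; the
# pruned subtree is reattached at the midpoint of a random backbone edge
.sprMove <- function(phy) {
  nt <- length(phy$tip.label)
  tab <- .phyloToTable(phy)
  tb <- .tipsBelow(phy)
  root <- tab$root
  nAll <- length(tab$parent)
  candV <- setdiff(which(vapply(seq_len(nAll), function(v)
    v != root && nt - length(tb[[v]]) >= 2, logical(1))), root)
  if (!length(candV)) return(phy)
  v <- if (length(candV) == 1) candV else sample(candV, 1)
  p <- tab$parent[v]
  inSub <- c(v, which(vapply(seq_len(nAll), function(u)
    v %in% .ancestors(tab$parent, u), logical(1))))
  # detach v
  tab$parent[v] <- NA_integer_
  sibs <- setdiff(which(tab$parent == p & !tab$dead), v)
  if (length(sibs) == 1L) {
    c1 <- sibs
    if (p == root) {
      tab$dead[p] <- TRUE
      tab$root <- c1
      tab$length[c1] <- NA_real_
    } else {
      tab$length[c1] <- tab$length[c1] + tab$length[p]
      tab$parent[c1] <- tab$parent[p]
      tab$dead[p] <- TRUE
    }
  }
  candW <- setdiff(which(!tab$dead), c(inSub, tab$root, v))
  candW <- setdiff(candW, if (!tab$dead[p]) integer(0) else integer(0))
  if (!length(candW)) return(phy)
  w <- if (length(candW) == 1) candW else sample(candW, 1)
  # new node m splits the edge above w
  m <- length(tab$parent) + 1L
  tab$parent <- c(tab$parent, tab$parent[w])
  tab$length <- c(tab$length, tab$length[w] / 2)
  tab$label <- c(tab$label, "")
  tab$isTip <- c(tab$isTip, FALSE)
  tab$dead <- c(tab$dead, FALSE)
  tab$parent[w] <- m
  tab$length[w] <- tab$length[w] / 2
  tab$parent[v] <- m
  .tableToPhylo(tab)
}

#' Simulate gene trees discordant from a species tree
#'
#' Per gene: copy the species tree, apply a Poisson-distributed number of
#' random SPR moves (horizontal-transfer-like topological discordance),
#' drop each tip independently with probability \code{dropout} (marker
#' absence), and rescale all branches by a lognormal per-gene rate
#' multiplier. Genes left with fewer than 4 tips are resampled (with a
#' message).
#'
#' @param speciesTree a \code{phylo} (e.g. from
#'   \code{\link{simulateSpeciesTree}}).
#' @param nGenes number of gene trees.
#' @param sprMean Poisson mean of SPR moves per gene.
#' @param dropout per-tip dropout probability in [0, 1).
#' @param rateSdLog sd(log) of the per-gene rate multiplier (default 0.25).
#' @param seed RNG seed.
#' @return list of \code{phylo} gene trees.
#' @export
simulateGeneTrees <- function(speciesTree, nGenes = 50, sprMean = 1,
                              dropout = 0, rateSdLog = 0.25, seed = 1) {
  stopifnot(sprMean >= 0, dropout >= 0, dropout < 1, rateSdLog >= 0)
  phy <- asPhylo(speciesTree)
  withr::with_seed(seed, {
    lapply(seq_len(nGenes), function(g) {
      repeat {
        gt <- phy
        nm <- rpois(1, sprMean)
        for (i in seq_len(nm)) gt <- .sprMove(gt)
        if (dropout > 0) {
          drop <- gt$tip.label[runif(length(gt$tip.label)) < dropout]
          if (length(gt$tip.label) - length(drop) >= 4)
            gt <- if (length(drop)) ape::drop.tip(gt, drop) else gt
          else {
            message(sprintf("gene %d left with < 4 tips; resampled", g))
            next
          }
        }
        rate <- rlnorm(1, meanlog = 0, sdlog = rateSdLog)
        gt$edge.length <- gt$edge.length * rate
        return(gt)
      }
    })
  })
}

#' Simulate a gapped amino-acid alignment down a tree
#'
#' Sites fall into rate classes (e.g. invariant / slow / fast); invariant
#' columns replicate a random root residue, the others evolve under an
#' exchangeable substitution process with the class rate multiplier
#' (phangorn's sequence simulator). Gaps are injected per cell with the
#' class gap probability.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param length total number of columns.
#' @param profile data.frame with columns class, prop, rate, gapProb; the
#'   default mixes 20\% invariant, 50\% slow (0.3x), 30\% fast (2x) sites.
#' @param seed RNG seed.
#' @return list with \code{alignment} (a \code{MarkerAlignment}) and
#'   \code{siteClass} (character vector, one entry per column).
#' @export
simulateAlignment <- function(tree, length = 200,
                              profile = data.frame(
                                class = c("invariant", "slow", "fast"),
                                prop = c(0.2, 0.5, 0.3),
                                rate = c(0, 0.3, 2),
                                gapProb = c(0, 0.05, 0.10)),
                              seed = 1) {
  if (length < 1) stop("alignment length must be >= 1")
  phy <- asPhylo(tree)
  nSite <- round(length * profile$prop / sum(profile$prop))
  nSite[1] <- length - sum(nSite[-1])
  withr::with_seed(seed, {
    blocks <- list()
    classes <- character(0)
    for (i in seq_len(nrow(profile))) {
      k <- nSite[i]
      if (k <= 0) next
      if (profile$rate[i] <= 0) {
        res <- sample(.AA20, k, replace = TRUE)
        block <- matrix(rep(res, each = length(phy$tip.label)),
                        nrow = length(phy$tip.label),
                        dimnames = list(phy$tip.label, NULL))
      } else {
        sim <- phangorn::simSeq(phy, l = k, type = "AA",
                                rate = profile$rate[i])
        block <- as.character(sim)
        block[] <- toupper(block)
        block <- block[phy$tip.label, , drop = FALSE]
      }
      gp <- profile$gapProb[i]
      if (gp > 0) block[runif(length(block)) < gp] <- "-"
      blocks[[length(blocks) + 1L]] <- block
      classes <- c(classes, rep(profile$class[i], k))
    }
    m <- do.call(cbind, blocks)
    list(alignment = new("MarkerAlignment", seqs = m, gene = "sim"),
         siteClass = classes)
  })
}

#' Simulate a clade-consistent taxonomy with planted noise
#'
#' Ranks are defined by cutting the tree into nested clade partitions of
#' increasing size (so the noise-free taxonomy is perfectly monophyletic);
#' then each tip x rank cell is independently mislabeled (swapped to a
#' random other taxon at that rank) with probability \code{mislabelRate}
#' and blanked (unclassified) with probability \code{unclassifiedRate}.
#' A blanked cell is never counted as mislabeled.
#'
#' @param tree a rooted \code{phylo}.
#' @param groups named integer vector: number of taxa per rank. The
#'   default (NULL) scales with the tip count n -- domain 2, phylum n/40,
#'   class n/25, order n/15, family n/8, genus n/5 (each at least 2) --
#'   mirroring the taxon-size spectrum of large public genome collections,
#'   where an average genus holds about five genomes. The species rank is
#'   always one taxon per tip.
#' @param mislabelRate,unclassifiedRate per-cell rates in [0, 1).
#' @param seed RNG seed.
#' @return list with \code{taxonomy} (observed), \code{truth} (noise-free)
#'   and \code{flags} (data.frame tip_id, rank, mislabeled, blanked).
#' @export
simulateTaxonomy <- function(tree, groups = NULL,
                             mislabelRate = 0, unclassifiedRate = 0,
                             seed = 1) {
  stopifnot(mislabelRate >= 0, mislabelRate < 1,
            unclassifiedRate >= 0, unclassifiedRate < 1)
  phy <- asPhylo(tree)
  if (!ape::is.rooted(phy)) stop("requires a rooted tree")
  nt <- length(phy$tip.label)
  if (is.null(groups))
    groups <- c(domain = 2,
                phylum = max(2, round(nt / 40)),
                class = max(2, round(nt / 25)),
                order = max(2, round(nt / 15)),
                family = max(2, round(nt / 8)),
                genus = max(2, round(nt / 5)))
  tb <- .tipsBelow(phy)
  # nested partitions: repeatedly split the largest current clade
  part <- .rootNode(phy)
  ch <- .childrenList(phy)
  truth <- data.frame(tip_id = phy$tip.label, stringsAsFactors = FALSE)
  prefixes <- c(domain = "d", phylum = "p", class = "c", order = "o",
                family = "f", genus = "g")
  for (rk in names(prefixes)) {
    target <- min(groups[[rk]], nt)
    while (length(part) < target) {
      sizes <- lengths(tb[part])
      splittable <- part[part > nt]
      if (!length(splittable)) break
      v <- splittable[which.max(lengths(tb[splittable]))]
      part <- c(setdiff(part, v), ch[[v]])
    }
    part <- part[order(-lengths(tb[part]), part)]
    col <- character(nt)
    for (i in seq_along(part)) {
      col[tb[[part[i]]]] <- sprintf("%s%d", prefixes[[rk]], i)
    }
    truth[[rk]] <- col
  }
  truth$species <- paste0("s_", phy$tip.label)
  obs <- truth
  flags <- list()
  fi <- 0L
  withr::with_seed(seed, {
    for (rk in names(prefixes)) {
      taxa <- unique(truth[[rk]])
      for (i in seq_len(nt)) {
        mis <- length(taxa) > 1 && runif(1) < mislabelRate
        if (mis) {
          obs[i, rk] <- sample(setdiff(taxa, truth[i, rk]), 1)
        }
        bl <- runif(1) < unclassifiedRate
        if (bl) obs[i, rk] <- ""
        if (mis || bl) {
          fi <- fi + 1L
          flags[[fi]] <- data.frame(tip_id = truth$tip_id[i], rank = rk,
                                    mislabeled = mis && !bl, blanked = bl,
                                    stringsAsFactors = FALSE)
        }
      }
    }
  })
  list(taxonomy = obs, truth = truth,
       flags = if (fi) do.call(rbind, flags) else
         data.frame(tip_id = character(0), rank = character(0),
                    mislabeled = logical(0), blanked = logical(0)))
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]),
                                     collapse = ""), character(1)))
}

.kmerSet <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, seq_len(n - k + 1), k:n)
  rc <- .revcomp(km)
  unique(pmin(km, rc))
}

#' Simulate genome pairs with planted k-mer overlap
#'
#' For each value in \code{overlapGrid}, a base random genome and a partner
#' that keeps the leading \code{overlap} fraction of the base and replaces
#' the rest with fresh random sequence; the exact canonical k-mer set
#' Jaccard index of each pair is computed as an oracle for sketch-based
#' estimates.
#'
#' @param genomeLen genome length in bp.
#' @param overlapGrid vector of overlap fractions in [0, 1].
#' @param k k-mer size used for the exact Jaccard oracle (default 21).
#' @param seed RNG seed.
#' @return data.frame with columns overlap, seqA, seqB, jaccard.
#' @export
simulateGenomes <- function(genomeLen = 5000, overlapGrid = c(1, 0.5, 0),
                            k = 21, seed = 1) {
  stopifnot(all(overlapGrid >= 0 & overlapGrid <= 1), genomeLen > k)
  withr::with_seed(seed, {
    rows <- lapply(seq_along(overlapGrid), function(i) {
      o <- overlapGrid[i]
      base <- paste(sample(c("A", "C", "G", "T"), genomeLen,
                           replace = TRUE), collapse = "")
      keep <- round(o * genomeLen)
      partner <- if (keep >= genomeLen) base else paste0(
        substr(base, 1, keep),
        paste(sample(c("A", "C", "G", "T"), genomeLen - keep,
                     replace = TRUE), collapse = ""))
      ka <- .kmerSet(base, k)
      kb <- .kmerSet(partner, k)
      data.frame(overlap = o, seqA = base, seqB = partner,
                 jaccard = length(intersect(ka, kb)) /
                   length(union(ka, kb)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate genome metadata
#'
#' Draws per-genome marker counts, contamination, completeness, quality
#' scores and reference flags from configurable samplers whose defaults
#' mimic a large public genome collection (marker counts approximately
#' 286 +/- 80 out of 400, mostly low contamination, high completeness).
#'
#' @param tips character vector of genome identifiers.
#' @param distributions named list of sampler functions(n); any subset of
#'   marker_count, contamination, completeness, quality_score,
#'   is_reference, is_representative may be overridden.
#' @param taxonomy optional taxonomy data.frame merged into the result.
#' @param seed RNG seed.
#' @return a metadata data.frame as consumed by \code{\link{sampleGenomes}}
#'   and \code{\link{redDownsample}}.
#' @export
simulateMetadata <- function(tips, distributions = list(), taxonomy = NULL,
                             seed = 1) {
  def <- list(
    marker_count = function(n) pmax(0, pmin(400, round(rnorm(n, 286, 80)))),
    contamination = function(n) pmin(100, rexp(n, rate = 1 / 2)),
    completeness = function(n) 100 * rbeta(n, 9, 1),
    quality_score = function(n) pmin(1, pmax(0, rnorm(n, 0.8, 0.1))),
    is_reference = function(n) runif(n) < 0.02,
    is_representative = function(n) runif(n) < 0.05)
  def[names(distributions)] <- distributions
  md <- withr::with_seed(seed, {
    n <- length(tips)
    data.frame(genome_id = tips,
               marker_count = def$marker_count(n),
               contamination = def$contamination(n),
               completeness = def$completeness(n),
               quality_score = def$quality_score(n),
               is_reference = def$is_reference(n),
               is_representative = def$is_representative(n),
               stringsAsFactors = FALSE)
  })
  if (!is.null(taxonomy)) {
    tx <- taxonomy[match(tips, taxonomy$tip_id), setdiff(names(taxonomy),
                                                         "tip_id")]
    md <- cbind(md, tx)
    rownames(md) <- NULL
  } else {
    for (rk in .TAXRANKS) md[[rk]] <- ""
  }
  md
}
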