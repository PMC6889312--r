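# Per-column conservation scoring (the "trident" composition of symbol
# diversity, stereochemical diversity and gap fraction), conservation-based
# and random site sampling, supermatrix concatenation, and the substitution
# saturation scan.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

# similarity matrix -> normalized dissimilarity with zero diagonal:
# d(a,b) = 1 - S(a,b)/sqrt(S(a,a) S(b,b)), rescaled to [0,1]
.dissimilarityMatrix <- function(S) {
  S <- S[.AA20, .AA20]
  d <- 1 - S / sqrt(outer(diag(S), diag(S)))
  d[d < 0] <- 0
  d / max(d)
}

.loadSubstMatrix <- function(name) {
  e <- new.env()
  data(list = name, package = "Biostrings", envir = e)
  as.matrix(e[[name]])
}

#' Trident weight set
#'
#' @param alpha symbol-diversity exponent (default 1).
#' @param beta stereochemical exponent (default 0.5).
#' @param gamma gap exponent (default 3).
#' @param matrix substitution matrix: a name resolvable in Biostrings
#'   (default "BLOSUM62") or a numeric similarity matrix over the 20
#'   standard residues.
#' @return list used by \code{\link{tridentScore}}.
#' @export
tridentWeights <- function(alpha = 1, beta = 0.5, gamma = 3,
                           matrix = "BLOSUM62") {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0)
  S <- if (is.character(matrix)) .loadSubstMatrix(matrix) else matrix
  list(alpha = alpha, beta = beta, gamma = gamma,
       dissim = .dissimilarityMatrix(S))
}

#' Trident conservation score of an alignment column
#'
#' score = (1 - t)^alpha * (1 - r)^beta * (1 - g)^gamma, where t is the
#' Shannon entropy of the residue frequencies normalized by
#' log(min(20, n)) over the n non-gap symbols, r is the frequency-weighted
#' mean pairwise stereochemical dissimilarity (substitution-matrix based,
#' normalized to [0,1]), and g is the gap fraction. "X" counts as a gap.
#' A fully conserved gap-free column scores 1; an all-gap column scores 0.
#'
#' @param column character vector of residues (one alignment column).
#' @param weights a \code{\link{tridentWeights}} list.
#' @return a score in [0, 1].
#' @export
tridentScore <- function(column, weights = tridentWeights()) {
  if (!length(column)) stop("empty column")
  column <- toupper(column)
  gap <- .isGap(column) | !column %in% .AA20
  g <- mean(gap)
  res <- column[!gap]
  if (!length(res)) return(0)
  f <- table(factor(res, levels = .AA20)) / length(res)
  f <- as.numeric(f)
  nz <- f > 0
  norm <- log(min(20, length(res)))
  t <- if (norm <= 0) 0 else min(1, -sum(f[nz] * log(f[nz])) / norm)
  r <- as.numeric(t(f) %*% weights$dissim %*% f)
  (1 - t)^weights$alpha * (1 - r)^weights$beta * (1 - g)^weights$gamma
}

.tridentScores <- function(aln, weights = tridentWeights()) {
  apply(alnMatrix(aln), 2, tridentScore, weights = weights)
}

#' Select the most conserved sites of a gene alignment
#'
#' Ranks columns by trident score and keeps the top m ("up to m": shorter
#' alignments keep everything); ties are broken by leftmost position.
#'
#' @param aln a filtered \code{MarkerAlignment}.
#' @param m number of sites to keep (default 100).
#' @param weights a \code{\link{tridentWeights}} list.
#' @return a \code{\linkS4class{SiteSelection}} (1-based indices).
#' @export
sampleConserved <- function(aln, m = 100, weights = tridentWeights()) {
  sc <- .tridentScores(aln, weights)
  m <- min(m, length(sc))
  top <- order(-sc, seq_along(sc))[seq_len(m)]
  keep <- sort(top)
  new("SiteSelection", gene = geneId(aln), sites = as.integer(keep),
      mode = "conserved", seed = NA_real_, scores = sc[keep])
}

#' Randomly sample low-gap sites of a gene alignment
#'
#' Uniform sample without replacement from the columns with gap fraction
#' strictly below \code{maxGap}. If fewer eligible columns than m exist,
#' all of them are returned with a warning.
#'
#' @param aln a filtered \code{MarkerAlignment}.
#' @param m number of sites to draw (default 100).
#' @param maxGap eligibility ceiling on the column gap fraction (default
#'   0.50, strict "<").
#' @param seed RNG seed.
#' @return a \code{\linkS4class{SiteSelection}}.
#' @export
sampleRandom <- function(aln, m = 100, maxGap = 0.50, seed = 1) {
  g <- colMeans(.isGap(alnMatrix(aln)))
  elig <- which(g < maxGap)
  if (!length(elig)) stop("no site has gap fraction below the threshold")
  if (length(elig) <= m) {
    if (length(elig) < m)
      warning(sprintf("only %d eligible sites (< m = %d); keeping all",
                      length(elig), m))
    keep <- elig
  } else {
    keep <- withr::with_seed(seed, sort(sample(elig, m)))
  }
  new("SiteSelection", gene = geneId(aln), sites = as.integer(keep),
      mode = "random", seed = as.numeric(seed),
      scores = rep(NA_real_, length(keep)))
}

#' Concatenate per-gene site selections into a supermatrix
#'
#' Builds one row per taxon in the union of the genes' taxa; genes missing
#' for a taxon are filled with gaps. The partition table maps every
#' supermatrix column back to its (gene, original column) source.
#'
#' @param alignments list of \code{MarkerAlignment} objects.
#' @param selections optional list of \code{SiteSelection} objects parallel
#'   to \code{alignments} (NULL keeps all columns of every gene).
#' @return list with \code{alignment} (the supermatrix) and
#'   \code{partitions} (data.frame supermatrix_col, gene, gene_col).
#' @export
concatenateAlignments <- function(alignments, selections = NULL) {
  if (!length(alignments)) stop("no alignments given")
  taxa <- sort(unique(unlist(lapply(alignments,
                                    function(a) rownames(alnMatrix(a))))))
  blocks <- list()
  parts <- list()
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    m <- alnMatrix(a)
    cols <- if (is.null(selections)) seq_len(ncol(m))
            else siteIndices(selections[[i]])
    block <- matrix("-", nrow = length(taxa), ncol = length(cols),
                    dimnames = list(taxa, NULL))
    block[rownames(m), ] <- m[, cols, drop = FALSE]
    blocks[[i]] <- block
    parts[[i]] <- data.frame(gene = geneId(a), gene_col = as.integer(cols),
                             stringsAsFactors = FALSE)
  }
  sm <- do.call(cbind, blocks)
  pt <- do.call(rbind, parts)
  pt <- cbind(data.frame(supermatrix_col = seq_len(nrow(pt))), pt)
  list(alignment = new("MarkerAlignment", seqs = sm, gene = "concat"),
       partitions = pt)
}

#' Write a partition table (RAxML-style lines plus a TSV map)
#'
#' @param partitions the partition data.frame from
#'   \code{\link{concatenateAlignments}}.
#' @param raxmlFile,tsvFile output paths (NULL skips either).
#' @return invisibly, the RAxML-style lines.
#' @export
writePartitions <- function(partitions, raxmlFile = NULL, tsvFile = NULL) {
  lines <- vapply(split(partitions, partitions$gene), function(df) {
    sprintf("LG, %s = %d-%d", df$gene[1], min(df$supermatrix_col),
            max(df$supermatrix_col))
  }, character(1))
  lines <- unname(lines[order(vapply(split(partitions$supermatrix_col,
                                           partitions$gene), min,
                                     numeric(1)))])
  if (!is.null(raxmlFile)) writeLines(lines, raxmlFile)
  if (!is.null(tsvFile))
    write.table(partitions, tsvFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(lines)
}

#' Substitution saturation scan
#'
#' Samples taxa from each domain, and for every sampled pair records the
#' phylogenetic (patristic) distance x and the per-gene gap-free Hamming
#' distance y, grouped A-A, A-B, B-B. Pairs are binned on x with
#' equal-width bins over the observed range; per bin and group the mean y
#' and the pair count are reported. A roughly constant y/x relationship
#' across the three groups indicates that inter-domain distances are not
#' disproportionately saturated.
#'
#' @param tree a \code{phylo}/\code{AnnotatedTree} with branch lengths.
#' @param alignments list of \code{MarkerAlignment} objects sharing (a
#'   subset of) the tree tips.
#' @param domains list with character elements \code{A} and \code{B}.
#' @param nBins number of equal-width distance bins (default 10).
#' @param nPerDomain taxa sampled per domain (default 100; capped at the
#'   domain size with a warning).
#' @param seed RNG seed for the taxon sampling.
#' @return list with \code{records} (pair x gene rows) and \code{summary}
#'   (bin x group means and counts).
#' @export
saturationScan <- function(tree, alignments, domains, nBins = 10,
                           nPerDomain = 100, seed = 1) {
  phy <- asPhylo(tree)
  pickDomain <- function(tips, n, nm) {
    tips <- intersect(tips, phy$tip.label)
    if (length(tips) < n) {
      warning(sprintf("domain %s has only %d taxa (< %d); using all",
                      nm, length(tips), n))
      return(tips)
    }
    sort(sample(tips, n))
  }
  sel <- withr::with_seed(seed, list(
    A = pickDomain(domains$A, nPerDomain, "A"),
    B = pickDomain(domains$B, nPerDomain, "B")))
  taxa <- c(sel$A, sel$B)
  D <- tipDistances(phy)[taxa, taxa]
  pairs <- t(combn(taxa, 2))
  grp <- function(a, b) {
    ga <- ifelse(a %in% sel$A, "A", "B")
    gb <- ifelse(b %in% sel$A, "A", "B")
    paste0(pmin(ga, gb), "-", pmax(ga, gb))
  }
  rec <- list()
  k <- 0L
  for (gi in seq_along(alignments)) {
    m <- alnMatrix(alignments[[gi]])
    gene <- geneId(alignments[[gi]])
    for (pi in seq_len(nrow(pairs))) {
      a <- pairs[pi, 1]
      b <- pairs[pi, 2]
      if (!(a %in% rownames(m)) || !(b %in% rownames(m))) next
      y <- hammingGapFree(m[a, ], m[b, ])
      if (is.na(y)) next
      k <- k + 1L
      rec[[k]] <- data.frame(tipA = a, tipB = b, group = grp(a, b),
                             gene = gene, x = D[a, b], y = y,
                             stringsAsFactors = FALSE)
    }
  }
  if (!k) stop("no comparable taxon pair found in the alignments")
  records <- do.call(rbind, rec)
  brks <- seq(min(records$x), max(records$x), length.out = nBins + 1)
  brks[1] <- brks[1] - 1e-9
  records$bin <- cut(records$x, brks, labels = FALSE)
  agg <- aggregate(y ~ bin + group, data = records,
                   FUN = function(v) c(mean = mean(v), n = length(v)))
  summary <- data.frame(bin = agg$bin, group = agg$group,
                        mean_y = agg$y[, "mean"], n = agg$y[, "n"])
  for (g in c("A-A", "A-B", "B-B")) {
    if (!any(summary$group == g))
      warning(sprintf("group %s is empty in every bin", g))
  }
  list(records = records, summary = summary)
}
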