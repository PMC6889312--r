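# Alignment container, FASTA I/O, and the gap-based quality filters applied
# to per-gene amino-acid alignments before site sampling.

.GAPCHARS <- c("-", ".", "X", "x")

#' Construct a MarkerAlignment
#'
#' @param seqs named character vector of equal-length aligned sequences, a
#'   character matrix of residues (rownames = ids), or a
#'   \code{Biostrings} \code{AAStringSet}.
#' @param gene gene identifier.
#' @return a \code{\linkS4class{MarkerAlignment}}.
#' @export
markerAlignment <- function(seqs, gene = "gene") {
  if (inherits(seqs, "AAStringSet")) seqs <- as.character(seqs)
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (length(unique(nchar(seqs))) != 1)
      stop("aligned sequences must all have the same length")
    ids <- names(seqs)
    if (is.null(ids)) stop("sequences must be named")
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(seqs) <- ids
  }
  new("MarkerAlignment", seqs = seqs, gene = gene)
}

#' Read / write an aligned amino-acid FASTA
#'
#' @param file path to a FASTA file.
#' @param gene gene identifier attached to the alignment.
#' @return \code{readAlignmentFasta}: a \code{MarkerAlignment}.
#' @export
readAlignmentFasta <- function(file, gene = sub("\\.[^.]*$", "", basename(file))) {
  aa <- Biostrings::readAAStringSet(file)
  markerAlignment(aa, gene = gene)
}

#' @rdname readAlignmentFasta
#' @param aln a \code{MarkerAlignment}.
#' @export
writeAlignmentFasta <- function(aln, file) {
  s <- apply(alnMatrix(aln), 1, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(s), file)
  invisible(file)
}

.isGap <- function(m) {
  g <- m %in% .GAPCHARS
  if (!is.null(dim(m))) dim(g) <- dim(m)
  g
}

#' Filter gappy sites then gappy sequences from an alignment
#'
#' Columns with gap fraction strictly above \code{maxSiteGap} are removed
#' first; then rows whose gap fraction over the remaining columns is
#' strictly above \code{maxSeqGap} are dropped. The order matters and is
#' fixed. Unknown residues ("X") count as gaps.
#'
#' @param aln a \code{MarkerAlignment}.
#' @param maxSiteGap per-column gap-fraction ceiling (default 0.90).
#' @param maxSeqGap per-sequence gap-fraction ceiling (default 0.66).
#' @return list with \code{alignment}, \code{removedSites} (original
#'   1-based column indices) and \code{removedSeqs} (ids).
#' @export
filterAlignment <- function(aln, maxSiteGap = 0.90, maxSeqGap = 0.66) {
  m <- alnMatrix(aln)
  g <- .isGap(m)
  siteGap <- colMeans(g)
  badSites <- which(siteGap > maxSiteGap)
  if (length(badSites) == ncol(m))
    stop("every site exceeds the gap threshold; nothing left to align")
  keepSites <- setdiff(seq_len(ncol(m)), badSites)
  m2 <- m[, keepSites, drop = FALSE]
  seqGap <- rowMeans(.isGap(m2))
  badSeqs <- which(seqGap > maxSeqGap)
  if (length(badSeqs) == nrow(m2))
    stop("every sequence exceeds the gap threshold; nothing left to align")
  m3 <- m2[setdiff(seq_len(nrow(m2)), badSeqs), , drop = FALSE]
  list(alignment = new("MarkerAlignment", seqs = m3, gene = geneId(aln)),
       removedSites = as.integer(badSites),
       removedSeqs = rownames(m)[badSeqs])
}

#' Overall gap fraction of a gene alignment, and the marker retention rule
#'
#' A marker gene is retained in the pool iff its overall gap fraction (gaps
#' over all cells) does not exceed \code{maxGap} (strict ">" excludes).
#'
#' @param aln a \code{MarkerAlignment}.
#' @return \code{geneGapFraction}: fraction of gap characters over all
#'   cells; \code{isRetainedGene}: logical.
#' @export
geneGapFraction <- function(aln) {
  mean(.isGap(alnMatrix(aln)))
}

#' @rdname geneGapFraction
#' @param maxGap retention threshold (default 0.75).
#' @export
isRetainedGene <- function(aln, maxGap = 0.75) {
  geneGapFraction(aln) <= maxGap
}

#' Hamming distance over shared gap-free sites
#'
#' Proportion of differing positions among positions where both rows carry
#' a residue. Returns NA (undefined) when no position is shared.
#'
#' @param rowA,rowB equal-length character vectors of residues, or strings.
#' @return a proportion in [0, 1], or NA_real_.
#' @export
hammingGapFree <- function(rowA, rowB) {
  if (length(rowA) == 1 && nchar(rowA) > 1) rowA <- strsplit(rowA, "")[[1]]
  if (length(rowB) == 1 && nchar(rowB) > 1) rowB <- strsplit(rowB, "")[[1]]
  if (length(rowA) != length(rowB)) stop("rows differ in length")
  shared <- !.isGap(rowA) & !.isGap(rowB)
  if (!any(shared)) return(NA_real_)
  mean(rowA[shared] != rowB[shared])
}
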