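# MinHash sketching of genome sequences and Mash-style distances. Defaults
# follow common practice for bacterial/archaeal genomes: sketch size 1000,
# k-mer size 21. Hashing is a fixed seedable non-cryptographic function
# (splitmix64 masked to 53 bits so values are exact in R doubles); only
# self-consistency across a genome pool matters, not binary compatibility
# with any particular sketching tool.

#' Build a MinHash sketch of a genome
#'
#' Extracts all k-mers over {A,C,G,T} (k-mers containing any other symbol
#' are skipped), canonicalizes each as the lexicographic minimum of the
#' k-mer and its reverse complement, hashes with a seeded 53-bit hash, and
#' keeps the s smallest distinct hash values.
#'
#' @param sequences character vector of DNA sequences (one genome), or a
#'   \code{Biostrings} \code{DNAStringSet}.
#' @param id genome identifier.
#' @param k k-mer size (1..31), default 21.
#' @param s sketch size, default 1000.
#' @param seed hash seed; sketches are only comparable under the same seed.
#' @return a \code{\linkS4class{MinHashSketch}}.
#' @export
minhashSketch <- function(sequences, id = "genome", k = 21L, s = 1000L,
                          seed = 42) {
  if (inherits(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (!length(sequences) || all(nchar(sequences) < k))
    stop("all sequences are shorter than k")
  h <- .minhashSketchCpp(as.character(sequences), as.integer(k),
                         as.integer(s), as.numeric(seed))
  new("MinHashSketch", id = id, k = as.integer(k), s = as.integer(s),
      seed = as.numeric(seed), hashes = h)
}

#' Mash distance between two sketches
#'
#' The Jaccard index j is estimated from the bottom-s' of the merged hash
#' union (s' = min(s, union size)); the distance is
#' d = -log(2j / (1 + j)) / k, clamped to [0, 1], with d = 1 when j = 0.
#'
#' @param sketchA,sketchB \code{MinHashSketch} objects with equal k and s.
#' @return a distance in [0, 1].
#' @export
mashDistance <- function(sketchA, sketchB) {
  if (sketchA@k != sketchB@k || sketchA@s != sketchB@s)
    stop("sketches have mismatched k or s and cannot be compared")
  if (sketchA@seed != sketchB@seed)
    stop("sketches were built with different hash seeds")
  u <- sort(unique(c(sketchA@hashes, sketchB@hashes)))
  sp <- min(sketchA@s, length(u))
  bottom <- u[seq_len(sp)]
  shared <- sum(bottom %in% sketchA@hashes & bottom %in% sketchB@hashes)
  j <- shared / sp
  if (j == 0) return(1)
  min(1, max(0, -log(2 * j / (1 + j)) / sketchA@k))
}

#' All-pairs Mash distance matrix
#'
#' @param sketches list of \code{MinHashSketch} objects (>= 2) with unique
#'   identifiers and compatible parameters.
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
sketchDistanceMatrix <- function(sketches) {
  if (length(sketches) < 2) stop("need at least 2 sketches")
  ids <- vapply(sketches, function(x) x@id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sketch id: ", ids[duplicated(ids)][1])
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- mashDistance(sketches[[i]], sketches[[j]])
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

.checkDistanceMatrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("distance matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop("distance matrix must have identical row and column identifiers")
  if (any(abs(m - t(m)) > 1e-12))
    stop("distance matrix is not symmetric")
  if (any(diag(m) != 0))
    stop("distance matrix diagonal must be zero")
  if (any(m < 0)) stop("distances must be non-negative")
  invisible(m)
}

#' Read / write a labelled square distance matrix (LSMat-style TSV)
#'
#' The format is a header row of identifiers preceded by a tab, then one row
#' per identifier with the square body.
#'
#' @param file path to a TSV file.
#' @return \code{readDistanceMatrix}: a validated symmetric matrix.
#' @export
readDistanceMatrix <- function(file) {
  df <- read.delim(file, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  .checkDistanceMatrix(m)
  m
}

#' @rdname readDistanceMatrix
#' @param m a symmetric distance matrix with dimnames.
#' @export
writeDistanceMatrix <- function(m, file) {
  .checkDistanceMatrix(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- ""
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
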