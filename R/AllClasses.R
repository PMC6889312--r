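setOldClass("phylo")

#' Phylogenetic tree with per-branch support annotations
#'
#' Thin S4 wrapper around an \code{ape} \code{phylo} object in which internal
#' node labels carry branch support annotations, either as bare numeric
#' support labels (e.g. RAxML bootstrap) or as quoted key=value blocks
#' (e.g. ASTRAL's \code{'[lpp=0.97;EN=120]'}). The raw label strings stay on
#' the \code{phylo}; \code{\link{annotationTable}} parses them on demand.
#'
#' @slot tree a \code{phylo} object; node labels hold the raw annotations.
#' @slot dialect one of \code{"support"}, \code{"keyvalue"}, \code{"none"}.
#' @seealso \code{\link{readNewick}}, \code{\link{annotationTable}},
#'   \code{\link{collapseBranches}}
#' @exportClass AnnotatedTree
setClass("AnnotatedTree",
  representation(tree = "phylo", dialect = "character"),
  prototype(dialect = "none"))

setValidity("AnnotatedTree", function(object) {
  phy <- object@tree
  msg <- character(0)
  if (!inherits(phy, "phylo"))
    msg <- c(msg, "slot 'tree' must be a phylo object")
  else {
    if (anyDuplicated(phy$tip.label))
      msg <- c(msg, sprintf("duplicate tip name: '%s'",
                            phy$tip.label[duplicated(phy$tip.label)][1]))
    if (!is.null(phy$edge.length) && any(phy$edge.length < 0, na.rm = TRUE))
      msg <- c(msg, "negative branch lengths are not allowed")
  }
  if (!object@dialect %in% c("support", "keyvalue", "none"))
    msg <- c(msg, "dialect must be 'support', 'keyvalue' or 'none'")
  if (length(msg)) msg else TRUE
})

#' Gapped amino-acid alignment for one marker gene
#'
#' Rows are sequences (rownames are sequence identifiers), columns are
#' alignment sites. The alphabet is the 20 standard residues plus the gap
#' character \code{"-"} and the unknown character \code{"X"}; \code{"X"} and
#' \code{"."} are treated as gaps by every gap-fraction rule.
#'
#' @slot seqs character matrix of single residues.
#' @slot gene gene identifier.
#' @exportClass MarkerAlignment
setClass("MarkerAlignment",
  representation(seqs = "matrix", gene = "character"))

setValidity("MarkerAlignment", function(object) {
  m <- object@seqs
  msg <- character(0)
  if (!is.character(m)) msg <- c(msg, "seqs must be a character matrix")
  if (ncol(m) < 1) msg <- c(msg, "alignment must have at least one column")
  if (nrow(m) < 1) msg <- c(msg, "alignment must have at least one sequence")
  if (is.null(rownames(m))) msg <- c(msg, "sequences must be named")
  else if (anyDuplicated(rownames(m)))
    msg <- c(msg, "duplicate sequence identifiers")
  if (length(object@gene) != 1) msg <- c(msg, "gene must be a single string")
  if (length(msg)) msg else TRUE
})

#' MinHash sketch of a genome
#'
#' Bottom-s sketch: the s smallest (seeded, 53-bit) hash values of the
#' canonical k-mers of the genome, stored sorted ascending.
#'
#' @slot id genome identifier.
#' @slot k k-mer size.
#' @slot s sketch size (the stored vector may be shorter for tiny genomes).
#' @slot seed hash seed.
#' @slot hashes strictly increasing numeric vector of hash values.
#' @exportClass MinHashSketch
setClass("MinHashSketch",
  representation(id = "character", k = "integer", s = "integer",
                 seed = "numeric", hashes = "numeric"))

setValidity("MinHashSketch", function(object) {
  msg <- character(0)
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(object@hashes) > object@s)
    msg <- c(msg, "more hash values than the sketch size")
  if (is.unsorted(object@hashes, strictly = TRUE))
    msg <- c(msg, "hash values must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Result of a prototype (max-sum dispersion) selection
#'
#' @slot selected identifiers of the selected genomes (sorted).
#' @slot objective sum of pairwise distances among the selected genomes.
#' @slot seeds identifiers that were forced into the selection.
#' @slot trace data.frame audit trail (one row per removal or addition).
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(selected = "character", objective = "numeric",
                 seeds = "character", trace = "data.frame"))

setValidity("SelectionResult", function(object) {
  msg <- character(0)
  if (!all(object@seeds %in% object@selected))
    msg <- c(msg, "all seeds must be part of the selection")
  if (length(msg)) msg else TRUE
})

#' Selected alignment sites for one gene
#'
#' Column indices are stored 1-based (R convention) and strictly increasing.
#'
#' @slot gene gene identifier.
#' @slot sites 1-based retained column indices, strictly increasing.
#' @slot mode \code{"conserved"} or \code{"random"}.
#' @slot seed RNG seed used for random mode (NA for conserved mode).
#' @slot scores per-site conservation score (conserved mode only).
#' @exportClass SiteSelection
setClass("SiteSelection",
  representation(gene = "character", sites = "integer", mode = "character",
                 seed = "numeric", scores = "numeric"))

setValidity("SiteSelection", function(object) {
  msg <- character(0)
  if (length(object@sites) && is.unsorted(object@sites, strictly = TRUE))
    msg <- c(msg, "site indices must be strictly increasing")
  if (any(object@sites < 1L)) msg <- c(msg, "site indices are 1-based")
  if (!object@mode %in% c("conserved", "random"))
    msg <- c(msg, "mode must be 'conserved' or 'random'")
  if (length(msg)) msg else TRUE
})

#' Taxonomic decoration of a phylogeny
#'
#' Maps internal nodes of a rooted tree to taxonomic labels (possibly with
#' \code{"_k"} polyphyly suffixes) together with the F-measure of each
#' assignment, plus the curated per-tip taxonomy derived from it.
#'
#' @slot tree the decorated phylo object.
#' @slot assignments data.frame with columns node, rank, taxon, label,
#'   precision, recall, f, ntips.
#' @slot curated curated taxonomy data.frame (tip_id + one column per rank).
#' @exportClass TreeDecoration
setClass("TreeDecoration",
  representation(tree = "phylo", assignments = "data.frame",
                 curated = "data.frame"))

## ------------------------------------------------------------------ show

setMethod("show", "AnnotatedTree", function(object) {
  phy <- object@tree
  cat(sprintf("AnnotatedTree: %d tips, %d internal nodes, dialect '%s', %s\n",
              length(phy$tip.label), phy$Nnode, object@dialect,
              if (ape::is.rooted(phy)) "rooted" else "unrooted"))
})

setMethod("show", "MarkerAlignment", function(object) {
  cat(sprintf("MarkerAlignment '%s': %d sequences x %d sites (%.1f%% gaps)\n",
              object@gene, nrow(object@seqs), ncol(object@seqs),
              100 * geneGapFraction(object)))
})

setMethod("show", "MinHashSketch", function(object) {
  cat(sprintf("MinHashSketch '%s': k=%d, s=%d, %d hashes (seed %g)\n",
              object@id, object@k, object@s, length(object@hashes),
              object@seed))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d selected (%d seeds), objective %.6g\n",
              length(object@selected), length(object@seeds),
              object@objective))
})

setMethod("show", "SiteSelection", function(object) {
  cat(sprintf("SiteSelection '%s': %d sites, mode '%s'\n",
              object@gene, length(object@sites), object@mode))
})

setMethod("show", "TreeDecoration", function(object) {
  cat(sprintf("TreeDecoration: %d assignments over %d ranks, %d tips curated\n",
              nrow(object@assignments),
              length(unique(object@assignments$rank)), nrow(object@curated)))
})
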