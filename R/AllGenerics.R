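#' Extract the underlying phylo object
#'
#' @param x a tree-like object (\code{phylo} or \code{AnnotatedTree}).
#' @return a \code{phylo} object.
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))

#' @rdname asPhylo
setMethod("asPhylo", "phylo", function(x) x)

#' @rdname asPhylo
setMethod("asPhylo", "AnnotatedTree", function(x) x@tree)

#' Accessors for alignment and sketch objects
#'
#' \code{alnMatrix} returns the residue matrix of a \code{MarkerAlignment};
#' \code{geneId} its gene identifier; \code{sketchHashes} the hash vector of
#' a \code{MinHashSketch}; \code{selectedIds} the identifiers in a
#' \code{SelectionResult}; \code{selectionTrace} its audit trail;
#' \code{siteIndices} the 1-based columns of a \code{SiteSelection};
#' \code{curatedTaxonomy} and \code{nodeAssignments} the two components of a
#' \code{TreeDecoration}.
#'
#' @param x the object.
#' @return see description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("alnMatrix", function(x) standardGeneric("alnMatrix"))
#' @rdname accessors
setMethod("alnMatrix", "MarkerAlignment", function(x) x@seqs)

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
setMethod("geneId", "MarkerAlignment", function(x) x@gene)
#' @rdname accessors
setMethod("geneId", "SiteSelection", function(x) x@gene)

#' @rdname accessors
#' @export
setGeneric("sketchHashes", function(x) standardGeneric("sketchHashes"))
#' @rdname accessors
setMethod("sketchHashes", "MinHashSketch", function(x) x@hashes)

#' @rdname accessors
#' @export
setGeneric("selectedIds", function(x) standardGeneric("selectedIds"))
#' @rdname accessors
setMethod("selectedIds", "SelectionResult", function(x) x@selected)

#' @rdname accessors
#' @export
setGeneric("selectionTrace", function(x) standardGeneric("selectionTrace"))
#' @rdname accessors
setMethod("selectionTrace", "SelectionResult", function(x) x@trace)

#' @rdname accessors
#' @export
setGeneric("siteIndices", function(x) standardGeneric("siteIndices"))
#' @rdname accessors
setMethod("siteIndices", "SiteSelection", function(x) x@sites)

#' @rdname accessors
#' @export
setGeneric("curatedTaxonomy", function(x) standardGeneric("curatedTaxonomy"))
#' @rdname accessors
setMethod("curatedTaxonomy", "TreeDecoration", function(x) x@curated)

#' @rdname accessors
#' @export
setGeneric("nodeAssignments", function(x) standardGeneric("nodeAssignments"))
#' @rdname accessors
setMethod("nodeAssignments", "TreeDecoration", function(x) x@assignments)
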