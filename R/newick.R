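# Newick I/O supporting two annotation dialects:
#   "support"  - bare numeric internal-node labels, e.g. ((a,b)90,c);
#   "keyvalue" - quoted key=value blocks, e.g. ((a,b)'[lpp=0.97;EN=120]',c);
# ape::read.tree strips square-bracket comments and chokes on quoted labels,
# so quoted chunks are tokenized before parsing and restored afterwards.

.checkParens <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  inq <- FALSE
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (c == "'") inq <- !inq
    if (inq) next
    if (c == "(") depth <- depth + 1L
    if (c == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at position %d", i))
    }
  }
  if (inq) stop("malformed Newick: unterminated quoted label")
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' at end of string", depth))
  invisible(TRUE)
}

# parse Newick text into a plain phylo, handling quoted labels
.readNewickRaw <- function(text) {
  text <- trimws(text)
  .checkParens(text)
  m <- gregexpr("'[^']*'", text)[[1]]
  quoted <- character(0)
  if (m[1] != -1L) {
    quoted <- regmatches(text, gregexpr("'[^']*'", text))[[1]]
    for (i in seq_along(quoted)) {
      text <- sub(quoted[i], sprintf("PDQTOK%dX", i), text, fixed = TRUE)
    }
    quoted <- substr(quoted, 2, nchar(quoted) - 1L)
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("malformed Newick: parser failed on the input string")
  restore <- function(labs) {
    if (is.null(labs)) return(labs)
    ok <- grepl("^PDQTOK[0-9]+X$", labs)
    idx <- as.integer(sub("^PDQTOK([0-9]+)X$", "\\1", labs[ok]))
    labs[ok] <- quoted[idx]
    labs
  }
  phy$tip.label <- restore(phy$tip.label)
  phy$node.label <- restore(phy$node.label)
  if (anyDuplicated(phy$tip.label))
    stop(sprintf("duplicate tip name: '%s'",
                 phy$tip.label[duplicated(phy$tip.label)][1]))
  phy
}

.detectDialect <- function(phy) {
  nl <- phy$node.label
  if (is.null(nl)) return("none")
  nl <- nl[!is.na(nl) & nl != ""]
  if (!length(nl)) return("none")
  if (any(grepl("\\[.*=.*\\]", nl))) return("keyvalue")
  if (all(!is.na(suppressWarnings(as.numeric(nl))))) return("support")
  "none"
}

#' Read a Newick tree with branch support annotations
#'
#' Accepts both bare numeric internal-node labels (classical bootstrap) and
#' quoted key=value annotation blocks such as \code{'[lpp=0.97;EN=120]'}
#' (the summary-method style). The dialect is auto-detected and remembered so
#' \code{\link{writeNewick}} emits what was read.
#'
#' @param text a Newick string, or \code{NULL} to read from \code{file}.
#' @param file path to a Newick file (used when \code{text} is NULL).
#' @return an \code{\linkS4class{AnnotatedTree}}.
#' @examples
#' at <- readNewick("((a:1,b:1)90:1,c:2);")
#' annotationTable(at)
#' @export
readNewick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'text' or 'file'")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  phy <- .readNewickRaw(text)
  new("AnnotatedTree", tree = phy, dialect = .detectDialect(phy))
}

#' Write a tree back to Newick
#'
#' Emits the annotation dialect carried by the object; labels containing
#' Newick syntax characters are single-quoted.
#'
#' @param tree a \code{phylo} or \code{AnnotatedTree}.
#' @param file optional output path; when NULL the string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
writeNewick <- function(tree, file = NULL) {
  phy <- asPhylo(tree)
  s <- .writeNewickString(phy)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

# Parse node-label annotations into a per-internal-node data.frame with
# columns: node, label, bootstrap, en, qt, lpp, support. "support" is the
# bare label in the support dialect, else lpp, else bootstrap, else qt.
.parseAnnotations <- function(tree) {
  phy <- asPhylo(tree)
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  nl <- phy$node.label
  if (is.null(nl)) nl <- rep("", nn)
  out <- data.frame(node = (nt + 1):(nt + nn), label = nl,
                    bootstrap = NA_real_, en = NA_real_, qt = NA_real_,
                    lpp = NA_real_, support = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nn)) {
    lab <- nl[i]
    if (is.na(lab) || lab == "") next
    if (grepl("\\[.*\\]", lab)) {
      body <- sub("^.*\\[", "", sub("\\].*$", "", lab))
      for (kv in strsplit(body, ";", fixed = TRUE)[[1]]) {
        parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
        if (length(parts) != 2) next
        key <- tolower(trimws(parts[1]))
        val <- suppressWarnings(as.numeric(trimws(parts[2])))
        if (key %in% c("bootstrap", "en", "qt", "lpp"))
          out[i, key] <- val
        else if (key %in% c("q1", "pp1", "support"))
          out[i, "support"] <- val
      }
    } else {
      val <- suppressWarnings(as.numeric(lab))
      if (!is.na(val)) {
        out$bootstrap[i] <- val
        out$support[i] <- val
      }
    }
    if (is.na(out$support[i])) {
      out$support[i] <- if (!is.na(out$lpp[i])) out$lpp[i]
        else if (!is.na(out$bootstrap[i])) out$bootstrap[i]
        else out$qt[i]
    }
  }
  out
}

#' Branch annotation table of a tree
#'
#' One row per internal node, parsed from the node labels: effective number
#' of genes (\code{en}), quartet support (\code{qt}), local posterior
#' probability (\code{lpp}), \code{bootstrap}, plus a generic \code{support}
#' column (the bare label in the support dialect, otherwise lpp, bootstrap or
#' qt, in that order).
#'
#' @param tree a \code{phylo} or \code{AnnotatedTree}.
#' @return a data.frame keyed by node number.
#' @export
annotationTable <- function(tree) .parseAnnotations(tree)
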