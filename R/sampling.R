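# The multi-criteria genome sampling workflow built around prototype
# selection: quality filters, forced inclusions, sole-representative rules,
# diversity maximization with the forced genomes as seeds, and post-hoc
# best-marker per-taxon additions.

.rankCols <- c("phylum", "class", "order", "family", "genus")

#' Sampling criteria for the genome selection workflow
#'
#' @param minMarkers minimum marker-gene count (genomes below are excluded).
#' @param maxContamination maximum contamination percentage.
#' @param target total number of genomes to select with the diversity step.
#' @return a list of class "samplingCriteria".
#' @export
samplingCriteria <- function(minMarkers = 100, maxContamination = 10,
                             target = NULL) {
  stopifnot(minMarkers >= 0, maxContamination >= 0,
            maxContamination <= 100)
  structure(list(minMarkers = minMarkers,
                 maxContamination = maxContamination, target = target),
            class = "samplingCriteria")
}

.bestByMarkers <- function(md) {
  # ties: lowest contamination, then highest quality score, then id
  ord <- order(-md$marker_count, md$contamination, -md$quality_score,
               md$genome_id)
  md$genome_id[ord[1]]
}

#' Multi-criteria genome sampling
#'
#' Applies, in order: (1) exclusion of genomes with marker count below
#' \code{minMarkers} or contamination above \code{maxContamination};
#' (2) forced inclusion of reference/representative genomes; (3) inclusion
#' of the sole representative of each taxonomic group from phylum to genus;
#' (4) inclusion of the sole representative of each lineage-less species;
#' (5) destructive max-distance selection up to \code{target} with the
#' genomes from steps 2-4 as seeds; (6) per-taxon addition of the genome
#' with the highest marker count (ties: lowest contamination, highest
#' quality score, smallest id). The report records which step admitted each
#' genome.
#'
#' @param metadata data.frame with columns genome_id, marker_count,
#'   contamination, completeness, quality_score, is_reference,
#'   is_representative, phylum, class, order, family, genus, species.
#' @param dm symmetric distance matrix covering all metadata genome ids.
#' @param criteria a \code{\link{samplingCriteria}} object.
#' @return list with \code{selection} (data.frame genome_id,
#'   admitted_by_step) and \code{excluded} (data.frame genome_id, reason).
#' @export
sampleGenomes <- function(metadata, dm, criteria = samplingCriteria()) {
  need <- c("genome_id", "marker_count", "contamination", "quality_score",
            "is_reference", "is_representative", .rankCols, "species")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  .checkDistanceMatrix(dm)
  if (!all(rownames(dm) %in% metadata$genome_id))
    stop("metadata does not cover every id in the distance matrix")
  metadata <- metadata[metadata$genome_id %in% rownames(dm), , drop = FALSE]

  # step 1: quality exclusions
  lowMark <- metadata$marker_count < criteria$minMarkers
  highCont <- metadata$contamination > criteria$maxContamination
  excluded <- data.frame(
    genome_id = metadata$genome_id[lowMark | highCont],
    reason = ifelse(lowMark[lowMark | highCont],
                    sprintf("marker_count < %g", criteria$minMarkers),
                    sprintf("contamination > %g%%",
                            criteria$maxContamination)),
    stringsAsFactors = FALSE)
  pool <- metadata[!(lowMark | highCont), , drop = FALSE]
  if (!nrow(pool)) stop("no genome passes the exclusion filters")

  admitted <- integer(0)
  names(admitted) <- character(0)
  admit <- function(ids, step) {
    newids <- setdiff(ids, names(admitted))
    if (length(newids)) {
      add <- rep(step, length(newids))
      names(add) <- newids
      admitted <<- c(admitted, add)
    }
  }

  # step 2: forced inclusions
  admit(pool$genome_id[pool$is_reference | pool$is_representative], 2L)

  # step 3: sole representative of each taxon, phylum -> genus
  for (rk in .rankCols) {
    vals <- pool[[rk]]
    counts <- table(vals[!is.na(vals) & vals != ""])
    solo <- names(counts)[counts == 1]
    admit(pool$genome_id[vals %in% solo], 3L)
  }

  # step 4: sole representative of each lineage-less species
  lineageless <- apply(pool[, .rankCols, drop = FALSE], 1,
                       function(r) all(is.na(r) | r == ""))
  sp <- pool$species
  hasSp <- lineageless & !is.na(sp) & sp != ""
  spCounts <- table(sp[hasSp])
  soloSp <- names(spCounts)[spCounts == 1]
  admit(pool$genome_id[hasSp & sp %in% soloSp], 4L)

  # step 5: diversity maximization with the admitted genomes as seeds
  target <- criteria$target
  if (is.null(target)) target <- nrow(pool)
  if (target < length(admitted))
    stop(sprintf("target (%d) is below the number of seed genomes (%d)",
                 target, length(admitted)))
  target <- min(target, nrow(pool))
  sub <- dm[pool$genome_id, pool$genome_id, drop = FALSE]
  sel <- selectMaxDist(sub, p = target, seeds = names(admitted))
  admit(selectedIds(sel), 5L)

  # step 6: per-taxon best-marker additions
  for (rk in .rankCols) {
    vals <- pool[[rk]]
    for (tx in unique(vals[!is.na(vals) & vals != ""])) {
      admit(.bestByMarkers(pool[vals %in% tx, , drop = FALSE]), 6L)
    }
  }
  for (tx in unique(sp[hasSp])) {
    admit(.bestByMarkers(pool[hasSp & sp %in% tx, , drop = FALSE]), 6L)
  }

  sel <- data.frame(genome_id = names(admitted),
                    admitted_by_step = unname(admitted),
                    stringsAsFactors = FALSE)
  sel <- sel[order(sel$admitted_by_step, sel$genome_id), ]
  rownames(sel) <- NULL
  list(selection = sel, excluded = excluded)
}
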