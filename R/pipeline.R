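# Genome identifier normalization and the demo pipeline orchestrator with
# a reproducibility manifest.

#' Normalize assembly accessions to study identifiers
#'
#' Strips the "GCA_"/"GCF_" prefix and the version suffix and prepends
#' "G", so "GCF_000123456.1" becomes "G000123456". Vectorized.
#'
#' @param accession character vector of GenBank/RefSeq assembly accessions.
#' @return character vector of normalized identifiers.
#' @export
normalizeGenomeId <- function(accession) {
  m <- regexec("^GC[AF]_([0-9]+)\\.[0-9]+$", accession)
  bad <- vapply(regmatches(accession, m), length, integer(1)) != 2
  if (any(bad))
    stop("non-conforming assembly accession: ", accession[bad][1])
  paste0("G", vapply(regmatches(accession, m), `[`, character(1), 2))
}

#' Deduplicate accessions, preferring RefSeq
#'
#' When the same assembly exists as both GenBank (GCA_) and RefSeq (GCF_),
#' only the RefSeq accession is kept.
#'
#' @param accessions character vector of assembly accessions.
#' @return the deduplicated accession vector, original order preserved.
#' @export
dedupAccessions <- function(accessions) {
  ids <- normalizeGenomeId(accessions)
  refseq <- grepl("^GCF_", accessions)
  keep <- logical(length(accessions))
  for (id in unique(ids)) {
    w <- which(ids == id)
    keep[if (any(refseq[w])) w[refseq[w]][1] else w[1]] <- TRUE
  }
  accessions[keep]
}

.defaultConfig <- function() {
  list(seed = 1, outDir = "pipeline_out",
       nA = 10, nB = 20, h = 1, L = 0.1,
       nGenes = 5, sprMean = 1, dropout = 0.1,
       alnLength = 120, sitesPerGene = 30,
       minMarkers = 100, maxContamination = 10, targetFraction = 0.8,
       maxSiteGap = 0.90, maxSeqGap = 0.66, maxGeneGap = 0.75,
       randomSiteMaxGap = 0.50,
       redClades = 6)
}

#' Run the demo pipeline end to end
#'
#' Simulates a two-domain collection (species tree, gene trees, metadata,
#' taxonomy, alignments), sketches and selects genomes, filters alignments
#' and samples conserved sites into a supermatrix, computes the headline
#' tree statistics (relative A-B distance, normalized A-B branch, RED
#' downsample, per-gene concordance), and decorates the taxonomy. Every
#' stage writes plain-text outputs under \code{outDir}; a YAML manifest
#' records the package version, seed, all parameters and the MD5 digest of
#' every output file, so a re-run with the same configuration is
#' bit-identical.
#'
#' @param config a named list overriding the defaults (seed, outDir, sizes,
#'   thresholds), or the path to a YAML file with the same fields.
#' @return the manifest, invisibly (also written to
#'   \code{outDir/manifest.yml}).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .defaultConfig()
  cfg[names(config)] <- config
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out <- function(f) {
    f <- file.path(cfg$outDir, f)
    outputs <<- c(outputs, f)
    f
  }

  env <- new.env()
  stage("simulate", function() {
    sim <- simulateSpeciesTree(cfg$nA, cfg$nB, h = cfg$h, L = cfg$L,
                               seed = cfg$seed)
    env$species <- sim$tree
    env$partition <- sim$partition
    writeNewick(sim$tree, out("species.nwk"))
    env$genes <- simulateGeneTrees(sim$tree, nGenes = cfg$nGenes,
                                   sprMean = cfg$sprMean,
                                   dropout = cfg$dropout,
                                   seed = cfg$seed + 1)
    writeLines(vapply(env$genes, writeNewick, character(1)),
               out("gene_trees.nwk"))
    tx <- simulateTaxonomy(sim$tree, seed = cfg$seed + 2)
    env$taxonomy <- tx$taxonomy
    writeTaxonomy(tx$taxonomy, out("taxonomy.tsv"))
    env$metadata <- simulateMetadata(sim$tree$tip.label,
                                     taxonomy = tx$taxonomy,
                                     seed = cfg$seed + 3)
    write.table(env$metadata, out("metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  stage("distances", function() {
    gsim <- simulateGenomes(genomeLen = 2000,
                            overlapGrid = seq(1, 0,
                              length.out = length(env$species$tip.label)),
                            seed = cfg$seed + 4)
    sketches <- lapply(seq_len(nrow(gsim)), function(i)
      minhashSketch(gsim$seqA[i], id = env$species$tip.label[i], s = 200,
                    seed = cfg$seed))
    env$dm <- sketchDistanceMatrix(sketches)
    writeDistanceMatrix(env$dm, out("distances.tsv"))
  })

  stage("select", function() {
    target <- max(2, round(cfg$targetFraction * nrow(env$dm)))
    crit <- samplingCriteria(minMarkers = cfg$minMarkers,
                             maxContamination = cfg$maxContamination,
                             target = target)
    res <- sampleGenomes(env$metadata, env$dm, crit)
    write.table(res$selection, out("selection.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  stage("sites", function() {
    alns <- lapply(seq_len(max(2, min(3, cfg$nGenes))), function(g)
      simulateAlignment(env$species, length = cfg$alnLength,
                        seed = cfg$seed + 10 + g)$alignment)
    alns <- lapply(seq_along(alns), function(i) {
      a <- alns[[i]]
      a@gene <- sprintf("gene%02d", i)
      filterAlignment(a, cfg$maxSiteGap, cfg$maxSeqGap)$alignment
    })
    alns <- Filter(function(a) isRetainedGene(a, cfg$maxGeneGap), alns)
    sels <- lapply(alns, sampleConserved, m = cfg$sitesPerGene)
    cc <- concatenateAlignments(alns, sels)
    writeAlignmentFasta(cc$alignment, out("supermatrix.fasta"))
    writePartitions(cc$partitions, raxmlFile = out("partitions.txt"),
                    tsvFile = out("partitions.tsv"))
    env$alignments <- alns
  })

  stage("statistics", function() {
    stats <- data.frame(
      metric = c("relative_ab_distance", "normalized_ab_branch",
                 vapply(seq_along(env$genes), function(g)
                   sprintf("gene%02d_quartet_concordance", g),
                   character(1))),
      value = c(relativeABDistance(env$species, env$partition),
                normalizedABBranch(env$species, env$partition),
                vapply(env$genes, function(gt)
                  quartetConcordance(env$species, gt, mode = "sampled",
                                     nSamples = 300,
                                     seed = cfg$seed)$score,
                  numeric(1))))
    write.table(stats, out("tree_stats.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    red <- redDownsample(env$species, n = min(cfg$redClades,
                                              length(env$species$tip.label)),
                         metadata = env$metadata, seed = cfg$seed + 5)
    write.table(red, out("red_downsample.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  stage("decorate", function() {
    dec <- decorateTree(env$species, env$taxonomy)
    writeTaxonomy(curatedTaxonomy(dec), out("curated_taxonomy.tsv"))
    write.table(nodeAssignments(dec), out("decoration.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  manifest <- list(
    package = "phylodomain",
    version = as.character(packageVersion("phylodomain")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("seed", "outDir"))],
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f))))
  yaml::write_yaml(manifest, file.path(cfg$outDir, "manifest.yml"))
  invisible(manifest)
}
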