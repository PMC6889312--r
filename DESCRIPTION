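Package: phylodomain
Title: Diversity-Maximizing Genome Sampling and Inter-Domain Phylogenomic
    Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for large-scale bacterial and archaeal phylogenomics:
    MinHash sketching of genome sequences and Mash-style distances,
    diversity-maximizing ("max-sum dispersion") genome subsampling with a
    destructive greedy heuristic and an exhaustive oracle, alignment quality
    filtering and trident conservation-based site sampling, inter-domain
    evolutionary distance statistics (relative Archaea-Bacteria distance,
    normalized inter-domain branch length, substitution-saturation scan),
    tree concordance metrics (Robinson-Foulds, quartet concordance, tip
    distance), relative evolutionary divergence (RED) and RED-guided taxon
    downsampling, F-measure taxonomy decoration with polyphyly suffixes and
    cladistic assessment, and seeded synthetic-data generators that emulate
    a two-domain genome collection end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
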