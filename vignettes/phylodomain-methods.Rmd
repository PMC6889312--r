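---
title: "Methods and design of phylodomain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of phylodomain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodomain)
```

## Scope

phylodomain implements the non-standard computational stages of a
large-scale two-domain (Archaea/Bacteria) phylogenomics workflow: genome
sketching and diversity-maximizing subsampling, alignment quality control
and conservation-based site sampling, the inter-domain distance
statistics, tree concordance metrics, RED-guided taxon reduction, and
tree-based taxonomy curation. Alignment construction, gene/species tree
inference and divergence dating are deliberately out of scope — those are
served by dedicated tools; this package consumes and produces their
standard formats (Newick, FASTA, TSV).

## Models and statistics

### MinHash genome distances

Each genome is summarized by the `s` smallest hash values of its canonical
k-mers (lexicographic minimum of the k-mer and its reverse complement;
k-mers containing non-ACGT symbols are skipped). Defaults are `s = 1000`
and `k = 21`, the settings commonly used for bacterial and archaeal
assemblies. The Jaccard index `j` of two genomes is estimated from the
bottom-`s` of the merged hash union — the unbiased estimator for bottom
sketches — and converted to a distance by `d = -log(2j/(1+j))/k`, capped
to `[0, 1]` with `d = 1` at `j = 0`. The hash is a seeded splitmix64
masked to 53 bits so values are exactly representable as R doubles; only
self-consistency across a genome pool matters, so no attempt is made to
match any external tool's hash bit-for-bit. When `s` is at least the
union size the estimate equals the exact Jaccard index, which the tests
exploit as an oracle.

### Prototype selection

Given a distance matrix, the goal is a subset of size `p` maximizing the
sum of pairwise distances (max-sum dispersion), optionally containing
mandatory seed genomes. The production algorithm is destructive: starting
from the full pool it repeatedly removes the non-seed element with the
smallest summed distance to the current remaining set, updating the sums
incrementally (O(n²) total). Ties are broken by removing the
lexicographically smallest identifier, so a run is fully deterministic
and leaves an auditable removal trace. The exhaustive enumerator
`selectExhaustive` provides the global optimum at toy sizes; the tests
hold the heuristic to at least 90% of the optimum on 200 genome-pool
instances (k-mer distance matrices of sequences derived from a few
ancestors at mutation rates between 1% and 25%) and verify it never
exceeds the optimum. On adversarial geometries the greedy rule can fall
slightly below that bound (we observed ~0.897 on rare uniform 2-D point
configurations); on genome-like instances it is essentially optimal.

The six-step sampling workflow wires the heuristic into the full
genome-selection protocol: exclusion of genomes with fewer than 100
marker genes or more than 10% contamination, forced inclusion of
reference/representative genomes, sole representatives of each taxon from
phylum to genus and of lineage-less species, diversity maximization to
the target size with the forced genomes as seeds, and a final per-taxon
best-marker-count addition (ties resolved by lowest contamination, then
highest quality score, then identifier). A genome qualifying under
several steps is recorded at the first.

### Alignment filters and trident scores

Gap filters run in a fixed order: sites with more than 90% gaps are
removed first, then sequences with more than 66% gaps over the remaining
sites; genes whose overall gap fraction exceeds 75% leave the marker
pool. All comparisons are strict, matching the wording of the rules, and
`X`/`.` count as gaps everywhere.

Column conservation uses the trident composition
`(1-t)^α (1-r)^β (1-g)^γ`:

- `t` — Shannon entropy of the residue frequencies over non-gap symbols,
  normalized by `log(min(20, n))`;
- `r` — frequency-weighted mean pairwise stereochemical dissimilarity,
  where the dissimilarity of residues a, b is
  `1 - S(a,b)/sqrt(S(a,a) S(b,b))` rescaled to `[0, 1]` over all residue
  pairs. This normalization keeps `d(a,a) = 0` for every residue, so a
  fully conserved gap-free column scores exactly 1 — a simple
  max-diagonal shift would not, because substitution-matrix diagonals
  vary;
- `g` — the gap fraction.

The exponent defaults α = 1, β = 0.5, γ = 3 are the metric's original
recommendation and are configurable. The substitution matrix is a
parameter; the default is BLOSUM62 (loaded from Biostrings at run time),
and any similarity matrix over the 20 standard residues may be supplied.
Conserved-site sampling takes the top `m` columns by score with leftmost
tie-breaking; random sampling draws uniformly, seeded, from columns with
gap fraction strictly below 50%.

### Inter-domain distance statistics

The relative A–B distance is `mean(A–B)² / (mean(A–A) · mean(B–B))` over
tip-to-tip path lengths. It does not require the groups to be
monophyletic, so it applies to individual gene trees, and it is invariant
to a global rescaling of branch lengths. The group means are computed by
branch contribution: each branch adds its length times the number of
group pairs whose path crosses it, giving all three means in one O(n)
pass; the tests pin this against the naive cophenetic computation to
1e-9. On an equal-radius star the statistic is exactly 1; on the
symmetric cherry-pair construction (tip depth 0.5, connecting branch 1)
it is exactly 4.

The normalized A–B branch divides the path between the two domain
ancestors by the median tip depth. Depth is measured to the tip's own
domain ancestor by default, consistent with the clade-depth definition
used alongside it; measuring to the root instead is available behind the
`baseline` argument, since the phrase "depth of all tips in the tree"
admits both readings.

### Tree concordance

Robinson–Foulds distances are computed from canonical non-trivial
bipartition sets, normalized by the total bipartition count of the two
sheared trees so polytomous trees normalize by what they can resolve.
Quartet concordance is the fraction of 4-tip subsets inducing the same
unrooted topology; an induced quartet unresolved in either tree counts
as 1/3 — its expected agreement under random resolution. Exhaustive
enumeration is used up to a cap (default 5×10⁶ quartets), above which
quartets are drawn uniformly without replacement via combinadic
unranking, with a binomial standard error. The tip-distance metric is
`(1 - r)/2` for the Pearson correlation `r` of the two cophenetic
matrices' upper triangles. All three metrics shear the trees to shared
taxa first and require at least 3 (tip distance) or 4 (RF, quartet)
shared tips.

### RED and taxon downsampling

Relative evolutionary divergence anchors the root at 0 and every tip at
1; an internal node with parent RED `p`, subtending branch `d`, and mean
parent-to-descendant-tip length `u` gets `p + (d/u)(1-p)`. The
definition includes the subtending branch in `u`, which makes RED
monotone along every root-to-tip path. Downsampling walks the RED list
from the low end, adding each node and dropping any selected ancestors,
until exactly `n` disjoint clades are selected; a representative tip is
chosen per clade by highest marker count, then lowest contamination,
then highest quality score, then a seeded random draw. Because RED is
monotone, with `n = 2` on a domain-rooted tree the two domain ancestors
are always the first disjoint pair, yielding one representative per
domain.

### Taxonomy decoration and cladistic scores

For each rank, each taxon with at least two classified tips is assigned
the internal node maximizing `F = 2PR/(P+R)`, where precision `P`
ignores tips unclassified at that rank (mirroring relaxed monophyly) and
recall `R` is relative to the taxon's tips in the tree. Remaining taxon
tips are covered greedily by further nodes. Three robustness rules make
the assignment stable under annotation noise, and are this package's
design on top of the bare max-F rule:

1. every accepted clade must hold a strict majority of classified tips
   carrying the taxon (`minPrecision = 0.5`), so an isolated mislabeled
   tip cannot seed a clade;
2. a secondary clade must cover at least 5% of the tips covered by the
   primary clade — the same minor-clade floor used when reporting
   polyphyletic groups — so scattered strays are treated as noise rather
   than genuine polyphyly;
3. after decoration, a tip outside every decorated clade at a rank
   adopts the first strict-majority curated label found walking up its
   ancestors, implementing lineage re-derivation for tips whose true
   clade was eroded by noise.

Polyphyletic taxa get suffixes `_1.._k` ordered by descendant count
(ties by smallest tip name); taxa observed on a single genome are
back-filled from the input taxonomy after decoration. On a noise-free
clade-consistent taxonomy decoration reproduces the input exactly; with
5% planted mislabels the curated lineages recover at least 95% of the
mislabeled cells in the tests.

Cladistic assessment offers strict monophyly (a clade equals the taxon's
tips), relaxed monophyly (extra tips are unclassified at the rank),
consistency, the taxon quartet score (fraction of 2-member/2-non-member
quartets pairing the members), and the support/rejection degree. The
text definition of consistency (the covered fraction, i.e. recall)
conflicts with the stated equivalence "consistency 1 ⇔ strict
monophyly", since a proper super-clade can reach recall 1; we return
`max over clades of min(precision, recall)`, which preserves the
equivalence, and expose raw precision and recall through `fmeasure`.
The support/rejection degree returns the subtending branch support for a
monophyletic taxon, and otherwise scans the distinct support values from
low to high, returning with negative sign the lowest value whose
contraction (of all branches with support up to and including it) leaves
the taxon's monophyly compatible with the resulting polytomies. The
inclusive contraction is required for a taxon broken by a single branch
of support v to be rejected at exactly −v.

## Tree manipulation choices

- Rooting between two tip sets splits the separating branch length
  50/50 between the two root edges. The source protocol does not state
  an apportionment; the even split is deterministic and preserves all
  tip-to-tip distances, which is the property downstream statistics
  need.
- Node identifiers are assigned in preorder after sorting children
  ascending by descendant count, ties by smallest descendant tip name,
  so the root is N1 and the smaller domain's ancestor N2.
- `matchResolution` contracts tied support values as a block; when a tie
  block would overshoot the target internal-node count, collapsing stops
  before the block and the nearest achievable count is reported with a
  warning, keeping the procedure deterministic.
- Missing branch lengths are treated as 0 with a warning in every
  distance computation.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, as pure
functions of their parameters and a seed:

- **Species trees** — two pure-birth ultrametric clades rescaled to depth
  `h`, joined by a connecting branch `L` (L/2 per side), with optional
  lognormal branch noise. For a fixed seed the clade shapes are identical
  across `L`, so inter-domain statistics can be swept over `L` with
  everything else held constant.
- **Gene trees** — copies of the species tree with a Poisson number of
  random subtree-prune-regraft moves (transfer-like topological
  discordance), independent tip dropout (marker absence), and a lognormal
  per-gene rate multiplier. The tests use mean 0.5 moves per gene as
  "moderate" discordance: at that level the species-tree relative A–B
  distance sits inside the inter-gene interquartile range while the
  per-gene median still rises strictly with `L`. SPR was chosen over an
  explicit coalescent because the workflow treats discordance sources
  agnostically and SPR gives direct control of topological distance.
- **Alignments** — invariant/slow/fast site classes (default 20/50/30%
  at rates 0/0.3/2) under a simple exchangeable amino-acid process, with
  per-class gap injection. This is sufficient for conservation-ranking
  and saturation-scan behavior; it does not emulate empirical residue
  profiles or compositional biases.
- **Taxonomies** — nested clade partitions cut from the tree, so the
  noise-free taxonomy is perfectly monophyletic, with per-cell mislabel
  swaps and blanking. Default group counts scale with the tip count
  (about n/5 genera, n/8 families, ...), mirroring the taxon-size
  spectrum of large public genome collections, where an average genus
  holds roughly five genomes; a blanked cell is never also counted as
  mislabeled.
- **Genome pairs** — a base random sequence and a partner sharing a
  planted prefix fraction, with the exact canonical k-mer Jaccard index
  returned as an oracle for sketch estimates.
- **Metadata** — marker counts (≈286 ± 80 of 400), contamination,
  completeness, quality scores and reference flags from configurable
  samplers.

Passing tests on these inputs demonstrates the algebra and the
algorithms, not robustness to real-data pathologies (contaminated
assemblies, compositional attraction, alignment error), which the
synthetic models deliberately do not contain.

## Numerical and scale choices

Problem sizes in the test suite and acceptance script are chosen to
exercise every code path at desk scale: trees of 10–200 tips for the
distance engine, 150-tip trees for taxonomy curation, 200 selection
instances of n ≤ 10, sketches of 1000 hashes over 4 kb genomes. Equality
of the branch-contribution engine with the naive computation is asserted
to 1e-9; distance-matrix symmetry to 1e-12. Sampled quartet scores are
compared to exhaustive values within three binomial standard errors. The
hash space is 2^53; collisions are negligible at these sketch sizes.

## Known limitations

- The decoration is a faithful implementation of the F-measure rule plus
  the three robustness rules above, not a reimplementation of any
  specific curation tool's internals (e.g. its parent/child rank
  conflict resolution).
- Newick support covers the two annotation dialects described; exotic
  comment syntaxes are not parsed.
- `selectExhaustive` is an oracle, not a production path; it refuses
  instances above its enumeration cap.
- The MinHash stage targets distance estimation for subsampling, not ANI
  estimation or compatibility with external sketch files.
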