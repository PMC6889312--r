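# Shared fixtures, all built in code.

# 1-D worked instance: points 0, 1, 2, 10 with absolute-difference distances
worked1D <- function() {
  pts <- c(0, 1, 2, 10)
  ids <- c("g0", "g1", "g2", "g10")
  dm <- abs(outer(pts, pts, "-"))
  dimnames(dm) <- list(ids, ids)
  dm
}

# random 2-D Euclidean distance matrix (metric, like genome signatures)
euclideanDM <- function(n, seed) {
  set.seed(seed)
  X <- matrix(runif(n * 2), n)
  m <- as.matrix(dist(X))
  dimnames(m) <- list(letters[seq_len(n)], letters[seq_len(n)])
  m
}

# genome-pool distance instance: n genomes derived from 3 ancestor
# sequences at varying mutation rates, exact k-mer Jaccard-derived distance
genomeKmerDM <- function(seed, n = NULL, k = 15) {
  set.seed(seed)
  if (is.null(n)) n <- sample(6:10, 1)
  mutate <- function(seq, rate) {
    ch <- strsplit(seq, "")[[1]]
    hit <- runif(length(ch)) < rate
    ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
    paste(ch, collapse = "")
  }
  anc <- replicate(3, paste(sample(c("A", "C", "G", "T"), 400,
                                   replace = TRUE), collapse = ""))
  seqs <- vapply(seq_len(n), function(j)
    mutate(sample(anc, 1), runif(1, 0.01, 0.25)), character(1))
  sets <- lapply(seqs, phylodomain:::.kmerSet, k = k)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      jac <- length(intersect(sets[[i]], sets[[j]])) /
        length(union(sets[[i]], sets[[j]]))
      d <- if (jac == 0) 1 else min(1, -log(2 * jac / (1 + jac)) / k)
      m[i, j] <- m[j, i] <- d
    }
  }
  dimnames(m) <- list(letters[seq_len(n)], letters[seq_len(n)])
  m
}

# the hand-computable cherry-pair tree: two 2-tip cherries with tip branches
# 0.5 joined by a connecting branch of total length 1.0
cherryPairTree <- function() {
  readNewick("((a1:0.5,a2:0.5):0.5,(b1:0.5,b2:0.5):0.5);")
}

cherryPartition <- function() list(A = c("a1", "a2"), B = c("b1", "b2"))

# equal-radius star over 2 + 2 tips
starTree <- function(r = 1) {
  readNewick(sprintf("(a1:%g,a2:%g,b1:%g,b2:%g);", r, r, r, r))
}

# random tree with random support labels in (0, 1)
supportedTree <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtree(n)
  phy$node.label <- as.character(round(runif(phy$Nnode, 0.01, 0.99), 3))
  phy
}

# naive all-pairs group means via the cophenetic matrix (oracle)
naiveGroupMeans <- function(phy, partition) {
  D <- ape::cophenetic.phylo(phy)
  A <- partition$A
  B <- partition$B
  c(AA = mean(D[A, A][upper.tri(D[A, A])]),
    BB = mean(D[B, B][upper.tri(D[B, B])]),
    AB = mean(D[A, B, drop = FALSE]))
}
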