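# Prototype selection: pick p genomes from a distance matrix maximizing the
# sum of pairwise distances (max-sum dispersion), optionally with mandatory
# seed genomes. The production path is a destructive greedy heuristic that
# repeatedly discards the element contributing least summed distance to the
# remaining pool; an exhaustive enumerator serves as optimum oracle at toy
# sizes.

#' Sum of pairwise distances within a subset
#'
#' @param dm symmetric distance matrix with identifier dimnames.
#' @param subset character vector of identifiers.
#' @return the sum over unordered pairs within the subset.
#' @export
prototypeObjective <- function(dm, subset) {
  .checkDistanceMatrix(dm)
  missing <- setdiff(subset, rownames(dm))
  if (length(missing)) stop("unknown id: ", missing[1])
  if (length(subset) < 2) return(0)
  sub <- dm[subset, subset, drop = FALSE]
  sum(sub[upper.tri(sub)])
}

#' Destructive max-distance prototype selection
#'
#' Starts from the full pool and repeatedly removes the non-seed element
#' with the minimal summed distance to the current remaining set, until p
#' elements remain. Ties are broken by removing the lexicographically
#' smallest identifier first, making the procedure fully deterministic.
#' Contributions are updated incrementally, so a full run is O(n^2).
#'
#' @param dm symmetric distance matrix with identifier dimnames.
#' @param p target selection size.
#' @param seeds identifiers that must remain selected.
#' @return a \code{\linkS4class{SelectionResult}}.
#' @examples
#' ids <- c("g0", "g1", "g2", "g10")
#' pts <- c(0, 1, 2, 10)
#' dm <- abs(outer(pts, pts, "-")); dimnames(dm) <- list(ids, ids)
#' selectedIds(selectMaxDist(dm, 2))   # g0 and g10
#' @export
selectMaxDist <- function(dm, p, seeds = character(0)) {
  .checkDistanceMatrix(dm)
  ids <- rownames(dm)
  if (!all(seeds %in% ids)) stop("unknown seed id")
  if (p < length(seeds)) stop("p is smaller than the number of seeds")
  if (p > length(ids)) stop("p exceeds the pool size")
  current <- ids
  contrib <- rowSums(dm)
  trace <- list()
  step <- 0L
  while (length(current) > p) {
    cand <- setdiff(current, seeds)
    ord <- order(contrib[cand], cand)
    drop <- cand[ord[1]]
    step <- step + 1L
    trace[[step]] <- data.frame(order = step, id = drop, action = "removed",
                                contribution = unname(contrib[drop]),
                                stringsAsFactors = FALSE)
    contrib <- contrib - dm[names(contrib), drop]
    contrib <- contrib[names(contrib) != drop]
    current <- setdiff(current, drop)
  }
  sel <- sort(current)
  new("SelectionResult", selected = sel,
      objective = prototypeObjective(dm, sel), seeds = sort(seeds),
      trace = if (length(trace)) do.call(rbind, trace) else
        data.frame(order = integer(0), id = character(0),
                   action = character(0), contribution = numeric(0)))
}

#' Exhaustive prototype selection (optimum oracle)
#'
#' Enumerates all subsets of size p containing the seeds and returns the
#' global maximum of the pairwise-distance sum. Intended as a test oracle
#' at small n; refuses instances above an enumeration cap.
#'
#' @inheritParams selectMaxDist
#' @param cap maximum number of subsets to enumerate (default 2e6).
#' @return a \code{\linkS4class{SelectionResult}}; ties are broken
#'   lexicographically on the sorted identifier tuple.
#' @export
selectExhaustive <- function(dm, p, seeds = character(0), cap = 2e6) {
  .checkDistanceMatrix(dm)
  ids <- rownames(dm)
  if (!all(seeds %in% ids)) stop("unknown seed id")
  if (p < length(seeds)) stop("p is smaller than the number of seeds")
  if (p > length(ids)) stop("p exceeds the pool size")
  free <- sort(setdiff(ids, seeds))
  kk <- p - length(seeds)
  if (choose(length(free), kk) > cap)
    stop("instance too large for exhaustive enumeration; use selectMaxDist")
  best <- NULL
  bestObj <- -Inf
  bestKey <- ""
  pick <- function(extra) {
    sel <- sort(c(seeds, extra))
    obj <- prototypeObjective(dm, sel)
    key <- paste(sel, collapse = "\r")
    if (obj > bestObj + 1e-15 ||
        (abs(obj - bestObj) <= 1e-15 && key < bestKey)) {
      best <<- sel
      bestObj <<- obj
      bestKey <<- key
    }
  }
  if (kk == 0) pick(character(0))
  else apply(combn(free, kk), 2, pick)
  new("SelectionResult", selected = best, objective = bestObj,
      seeds = sort(seeds),
      trace = data.frame(order = seq_along(best), id = best,
                         action = "enumerated",
                         contribution = NA_real_,
                         stringsAsFactors = FALSE))
}
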