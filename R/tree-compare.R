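## Tree / distance-matrix agreement: split distance, random-topology null,
## permutation Mantel test.

#' Normalized split distance between two trees
#'
#' The fraction of non-trivial splits (bipartitions induced by internal
#' edges) not shared between the two unrooted topologies:
#' \deqn{SD = \frac{|S_1 \setminus S_2| + |S_2 \setminus S_1|}{|S_1| + |S_2|}.}
#' 0 for identical topologies, 1 when no non-trivial split is shared.
#' Branch lengths, rooting and support labels are ignored. Both trees must
#' have identical leaf sets (\code{\link{pruneToCommonLeaves}} first if not).
#'
#' @param t1,t2 \code{phylo} trees on the same leaf set.
#' @return the split distance in [0, 1].
#' @export
splitDistance <- function(t1, t2) {
  l1 <- t1$tip.label
  l2 <- t2$tip.label
  if (!setequal(l1, l2)) {
    diffs <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop("leaf sets differ; symmetric difference: ",
         paste(diffs, collapse = ", "))
  }
  s1 <- .treeSplits(t1)
  s2 <- .treeSplits(t2)
  tot <- length(s1) + length(s2)
  if (tot == 0L) return(0)
  (sum(!s1 %in% s2) + sum(!s2 %in% s1)) / tot
}

#' Prune two trees to their common leaf set
#'
#' @param t1,t2 \code{phylo} trees.
#' @return list with pruned \code{t1} and \code{t2}.
#' @export
pruneToCommonLeaves <- function(t1, t2) {
  common <- intersect(t1$tip.label, t2$tip.label)
  if (length(common) < 3L) stop("fewer than 3 shared leaves")
  list(t1 = ape::drop.tip(t1, setdiff(t1$tip.label, common)),
       t2 = ape::drop.tip(t2, setdiff(t2$tip.label, common)))
}

#' Random-topology null distribution of the split distance
#'
#' Generates \code{nRandom} uniform random labeled topologies on the
#' reference tree's leaf set and computes the split distance of each against
#' the fixed reference (\code{scheme = "reference"}, default) or against an
#' independently drawn second random topology (\code{scheme = "pairwise"}).
#'
#' @param reference a \code{phylo} tree.
#' @param nRandom number of random trees (>= 1).
#' @param seed integer seed; results are deterministic given the seed.
#' @param scheme "reference" or "pairwise" (see above).
#' @return list with \code{null_values}, \code{null_mean} and
#'   \code{n_random}.
#' @export
randomSplitDistanceNull <- function(reference, nRandom = 100L, seed = 1L,
                                    scheme = c("reference", "pairwise")) {
  scheme <- match.arg(scheme)
  if (nRandom < 1L) stop("nRandom must be >= 1")
  set.seed(seed)
  labs <- reference$tip.label
  vals <- vapply(seq_len(nRandom), function(i) {
    r1 <- randomTopology(labs)
    if (scheme == "reference") splitDistance(reference, r1)
    else splitDistance(r1, randomTopology(labs))
  }, numeric(1))
  list(null_values = vals, null_mean = mean(vals), n_random = nRandom)
}

#' Split-distance report of two trees against a random null
#'
#' Convenience wrapper: observed split distance plus the random-topology
#' null of \code{\link{randomSplitDistanceNull}}.
#'
#' @param t1,t2 \code{phylo} trees on the same leaf set.
#' @param nRandom,seed,scheme passed to \code{\link{randomSplitDistanceNull}}
#'   (the null is built on \code{t1}'s leaf set).
#' @return list with \code{observed}, \code{null_mean}, \code{null_values},
#'   \code{n_random}.
#' @export
compareTrees <- function(t1, t2, nRandom = 100L, seed = 1L,
                         scheme = "reference") {
  obs <- splitDistance(t1, t2)
  nul <- randomSplitDistanceNull(t1, nRandom = nRandom, seed = seed,
                                 scheme = scheme)
  c(list(observed = obs), nul)
}

.lowerTri <- function(d) d[lower.tri(d)]

#' Permutation Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries, with a
#' two-sided permutation test: rows and columns of \code{d2} are permuted
#' simultaneously and \eqn{p = (1 + \#\{|r^*| \ge |r|\}) / (nPerm + 1)}.
#' The attainable p-value floor is therefore \code{1 / (nPerm + 1)}.
#'
#' @param d1,d2 symmetric labeled distance matrices with identical labels in
#'   identical order, n >= 3.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with \code{r}, \code{p} and \code{n_perm}.
#' @export
mantelTest <- function(d1, d2, nPerm = 999L, seed = 1L) {
  .checkDistMatrix(d1)
  .checkDistMatrix(d2)
  if (!identical(rownames(d1), rownames(d2)))
    stop("distance matrices must carry identical labels in identical order")
  n <- nrow(d1)
  if (n < 3L) stop("need at least 3 taxa")
  v1 <- .lowerTri(d1)
  r <- cor(v1, .lowerTri(d2))
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(nPerm)) {
    p <- sample.int(n)
    rp <- cor(v1, .lowerTri(d2[p, p]))
    if (abs(rp) >= abs(r) - 1e-12) hits <- hits + 1L
  }
  list(r = r, p = (1 + hits) / (nPerm + 1), n_perm = as.integer(nPerm))
}
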