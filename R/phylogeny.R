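## Allele-frequency matrix, chord distances, NJ, bootstrap, rooting.

#' Build the strain-by-site allele-frequency matrix
#'
#' The site set is the union of called positions over all strains. At an
#' included site a strain with a call gets occupancy mass on each derived
#' base and the remainder on the reference base; a strain without a call is
#' coded as a point mass on the reference base.
#'
#' @param calls a call data.frame (as from \code{\link{callStrain}}, rows
#'   for any number of strains concatenated).
#' @param strains ordered strain identifiers to include (strains without
#'   calls are legal and coded as all-reference).
#' @param reference the rDNA reference unit (character or
#'   \code{DNAStringSet}).
#' @return an \code{\link{AlleleFrequencyMatrix-class}} object; zero sites
#'   when there are no calls.
#' @export
buildFrequencyMatrix <- function(calls, strains, reference) {
  refc <- .refChars(reference)
  if (nrow(calls) && any(calls$pos > length(refc)))
    stop("call position exceeds reference length")
  if (nrow(calls) && !all(calls$strain %in% strains))
    stop("calls contain strains not in the strain list")
  sites <- sort(unique(as.integer(calls$pos)))
  nS <- length(strains)
  freq <- array(0, dim = c(nS, length(sites), 4L),
                dimnames = list(strains, sites, BASES))
  refIdx <- match(refc[sites], BASES)
  if (length(sites))
    for (i in seq_len(nS)) freq[cbind(i, seq_along(sites), refIdx)] <- 1
  if (nrow(calls)) {
    occSum <- tapply(calls$occupancy, list(calls$strain, calls$pos), sum)
    if (any(occSum > 1 + 1e-9, na.rm = TRUE))
      stop("summed derived occupancy exceeds 1 at some (strain, site)")
    si <- match(calls$strain, strains)
    pi <- match(calls$pos, sites)
    bi <- match(calls$derived, BASES)
    for (r in seq_len(nrow(calls))) {
      freq[si[r], pi[r], bi[r]] <- freq[si[r], pi[r], bi[r]] +
        calls$occupancy[r]
      freq[si[r], pi[r], refIdx[pi[r]]] <- freq[si[r], pi[r], refIdx[pi[r]]] -
        calls$occupancy[r]
    }
    freq[abs(freq) < 1e-12] <- 0
  }
  new("AlleleFrequencyMatrix", strains = strains, sites = sites,
      refBases = refc[sites], freq = freq)
}

## Chord distance on a raw (strains x sites x 4) frequency array.
.chordCore <- function(freq) {
  nS <- dim(freq)[1]
  S <- dim(freq)[2]
  sq <- sqrt(freq)
  d <- matrix(0, nS, nS)
  for (i in seq_len(nS - 1)) {
    for (j in (i + 1):nS) {
      inner <- rowSums(matrix(sq[i, , ], S, 4L) * matrix(sq[j, , ], S, 4L))
      d[i, j] <- d[j, i] <- sqrt(max(0, mean(1 - inner)))
    }
  }
  d
}

#' Cavalli-Sforza--Edwards chord distance between strains
#'
#' Treats each polymorphic site as a 4-allele locus. For strains x and y,
#' \deqn{D(x,y) = \sqrt{ \frac{1}{L} \sum_s \left(1 - \sum_b
#'   \sqrt{f_{x,s,b} f_{y,s,b}}\right) }.}
#' D is 0 iff all site vectors coincide and is bounded by 1; the classical
#' constant prefactor is omitted, which rescales distances uniformly and
#' leaves any distance-based topology unchanged.
#'
#' @param matrix an \code{\link{AlleleFrequencyMatrix-class}} with at least
#'   2 strains and 1 site.
#' @return a symmetric labeled distance matrix (base \code{matrix}).
#' @export
chordDistance <- function(matrix) {
  stopifnot(is(matrix, "AlleleFrequencyMatrix"))
  if (length(matrix@strains) < 2L) stop("need at least 2 strains")
  if (!length(matrix@sites)) stop("empty frequency matrix")
  d <- .chordCore(matrix@freq)
  dimnames(d) <- list(matrix@strains, matrix@strains)
  d
}

.checkDistMatrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix must be labeled")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  invisible(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative Q-criterion neighbor joining. Negative estimated
#' branch lengths are clamped to 0 and the total clamped deficit is reported
#' via \code{message()}.
#'
#' @param d symmetric labeled distance matrix with >= 3 taxa.
#' @return an unrooted \code{phylo}.
#' @export
neighborJoining <- function(d) {
  .checkDistMatrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  phy <- ape::nj(d)
  neg <- phy$edge.length < 0
  if (any(neg)) {
    message(sprintf("clamped %d negative branch length(s); total deficit %.6g",
                    sum(neg), -sum(phy$edge.length[neg])))
    phy$edge.length[neg] <- 0
  }
  phy
}

## Non-trivial splits of an unrooted tree, canonicalized so the stored side
## excludes the alphabetically first leaf. Keys are "\r"-joined sorted labels.
.treeSplits <- function(phy) {
  n <- length(phy$tip.label)
  if (n < 4L) return(character(0))
  phy <- ape::unroot(phy)
  labs <- phy$tip.label
  first <- sort(labs)[1]
  po <- ape::reorder.phylo(phy, "postorder")
  nNode <- n + phy$Nnode
  sets <- vector("list", nNode)
  for (i in seq_len(n)) sets[[i]] <- labs[i]
  keys <- character(0)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]
    chl <- po$edge[e, 2L]
    sets[[par]] <- c(sets[[par]], sets[[chl]])
    if (chl > n) {
      side <- sets[[chl]]
      if (length(side) >= 2L && length(side) <= n - 2L) {
        if (first %in% side) side <- setdiff(labs, side)
        keys <- c(keys, paste(sort(side), collapse = "\r"))
      }
    }
  }
  unique(keys)
}

#' Site-bootstrap supports for the neighbor-joining tree
#'
#' Resamples the matrix's sites (frequency columns) with replacement
#' \code{nReps} times, recomputes chord distance + NJ for each replicate,
#' and scores each internal edge of the original tree by the fraction of
#' replicates containing the same bipartition. Supports are attached as
#' numeric \code{node.label}s in [0, 1] (ape convention: the label of the
#' node subtending the edge); the root position carries \code{NA}.
#'
#' @param matrix an \code{\link{AlleleFrequencyMatrix-class}}.
#' @param nReps number of bootstrap replicates (>= 1).
#' @param seed integer seed; replicates are reproducible bit-for-bit.
#' @return the original NJ \code{phylo} with node labels set to supports.
#' @export
bootstrapSupport <- function(matrix, nReps = 1000L, seed = 1L) {
  stopifnot(is(matrix, "AlleleFrequencyMatrix"))
  if (nReps < 1L) stop("nReps must be >= 1")
  S <- length(matrix@sites)
  if (S < 1L) stop("empty frequency matrix")
  if (S == 1L) warning("single-site matrix: bootstrap supports are degenerate")
  tree <- neighborJoining(chordDistance(matrix))
  obs <- .treeSplits(tree)
  hits <- setNames(numeric(length(obs)), obs)
  set.seed(seed)
  labs <- matrix@strains
  for (r in seq_len(nReps)) {
    idx <- sample.int(S, S, replace = TRUE)
    d <- .chordCore(matrix@freq[, idx, , drop = FALSE])
    dimnames(d) <- list(labs, labs)
    repl <- suppressMessages(neighborJoining(d))
    sp <- .treeSplits(repl)
    inRep <- obs %in% sp
    hits[inRep] <- hits[inRep] + 1
  }
  support <- hits / nReps

  # map supports onto internal nodes: node.label[i] for node n_tip + i
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  nodeKey <- rep(NA_character_, tree$Nnode)
  first <- sort(tree$tip.label)[1]
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]
    chl <- po$edge[e, 2L]
    sets[[par]] <- c(sets[[par]], sets[[chl]])
    if (chl > n) {
      side <- sets[[chl]]
      if (length(side) >= 2L && length(side) <= n - 2L) {
        if (first %in% side) side <- setdiff(tree$tip.label, side)
        nodeKey[chl - n] <- paste(sort(side), collapse = "\r")
      }
    }
  }
  tree$node.label <- unname(support[nodeKey])
  tree
}

#' Root a tree on an outgroup's pendant edge
#'
#' Inserts the root at the midpoint of the outgroup's pendant edge; the leaf
#' set and all bipartitions are preserved.
#'
#' @param tree an unrooted (or rooted) \code{phylo}.
#' @param outgroup a tip label of \code{tree}.
#' @return a rooted \code{phylo}.
#' @export
rootWithOutgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  rootNode <- length(rooted$tip.label) + 1L
  kids <- which(rooted$edge[, 1L] == rootNode)
  tipIdx <- match(outgroup, rooted$tip.label)
  outEdge <- kids[rooted$edge[kids, 2L] == tipIdx]
  inEdge <- setdiff(kids, outEdge)
  if (length(outEdge) == 1L && length(inEdge) == 1L) {
    len <- rooted$edge.length[outEdge] + rooted$edge.length[inEdge]
    rooted$edge.length[outEdge] <- len / 2
    rooted$edge.length[inEdge] <- len / 2
  }
  rooted
}
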