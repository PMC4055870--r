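## Concerted-evolution simulator: tandem-array occupancy dynamics along a
## strain phylogeny, optional hybridization, and noisy read sampling.

#' Moran homogenization updates on variant unit counts
#'
#' Models gene conversion / unequal sister-chromatid exchange as a neutral
#' Moran process on the number of array units \code{k} (out of
#' \code{arraySize}) carrying a variant: at each step \code{k} moves to
#' \code{k + 1} or \code{k - 1}, each with probability
#' \code{k (R - k) / R^2}, and otherwise stays. 0 and R are absorbing; a
#' variant absorbed at R has become a fixed substitution. The fixation
#' probability from count k is the classical k / R.
#'
#' @param k integer vector of current unit counts (one entry per variant).
#' @param arraySize total units R.
#' @param nSteps number of updates; \code{Inf} runs until all entries are
#'   absorbed at 0 or R.
#' @return the updated integer vector (entries in 0..R).
#' @examples
#' set.seed(1)
#' table(moranUpdate(rep(1L, 100), 2L, Inf))
#' @export
moranUpdate <- function(k, arraySize, nSteps) {
  k <- as.integer(k)
  R <- as.integer(arraySize)
  step <- 0
  while (step < nSteps) {
    act <- which(k > 0L & k < R)
    if (!length(act)) break
    p <- k[act] * (R - k[act]) / R^2
    u <- runif(length(act))
    k[act] <- k[act] + ifelse(u < p, 1L, ifelse(u < 2 * p, -1L, 0L))
    step <- step + 1
  }
  k
}

#' Random labeled topology with exponential branch lengths
#'
#' Uniform over labeled unrooted binary topologies (successive random leaf
#' attachment); branch lengths i.i.d. exponential with mean 0.1.
#'
#' @param labels tip labels, or a single integer n (labels s1..sn).
#' @param seed optional integer seed; \code{NULL} uses the current RNG state.
#' @return an unrooted \code{phylo}.
#' @export
randomTopology <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(labels) && length(labels) == 1L)
    labels <- paste0("s", seq_len(labels))
  n <- length(labels)
  if (n < 2L) stop("need at least 2 tips")
  if (n == 2L) {
    phy <- ape::read.tree(text = "(t1:1,t2:1);")
    phy$edge.length <- rexp(2, rate = 10)
  } else {
    phy <- ape::rtopology(n, rooted = FALSE, br = function(m) rexp(m, rate = 10))
  }
  phy$tip.label <- sample(labels, n)
  phy
}

## Resolve config@tree into a checked phylo object (or NULL for random).
.resolveTree <- function(config) {
  tr <- config@tree
  if (is.null(tr)) {
    tr <- randomTopology(paste0("s", seq_len(config@nStrains)))
  } else if (is.character(tr)) {
    tr <- ape::read.tree(text = tr)
    if (is.null(tr)) stop("could not parse Newick tree")
  }
  if (!inherits(tr, "phylo")) stop("tree must be a phylo object or Newick string")
  labs <- tr$tip.label
  if (is.null(labs) || anyNA(labs) || any(labs == "") || anyDuplicated(labs))
    stop("input tree must have unique, non-empty tip labels")
  if (length(labs) < 2L) stop("tree must have at least 2 leaves")
  if (!ape::is.binary(tr)) stop("input tree must be binary")
  if (is.null(tr$edge.length)) stop("input tree must have branch lengths")
  tr
}

.refChars <- function(reference) {
  if (inherits(reference, "DNAStringSet"))
    reference <- as.character(reference[[1]])
  if (inherits(reference, "DNAString"))
    reference <- as.character(reference)
  if (!is.character(reference) || length(reference) != 1L)
    stop("reference must be a single DNA sequence")
  strsplit(toupper(reference), "")[[1]]
}

#' Simulate variant occupancies along a strain phylogeny
#'
#' Evolves a tandem rDNA array down the tree. Along each branch of length
#' \code{b}, new single-unit variants arise at
#' Poisson(\code{mutationRate * unitLength * b}) previously untouched sites
#' (derived base uniform over the three non-ancestral bases, initial
#' occupancy 1/R), after which every segregating variant undergoes
#' \code{round(homogenizationSteps * b)} Moran updates
#' (\code{\link{moranUpdate}}). Variants absorbed at R become fixed
#' substitutions inherited by all descendants; variants absorbed at 0 are
#' lost. A site mutates at most once per lineage.
#'
#' @param config a \code{\link{simConfig}}.
#' @param reference optional ancestral unit (character or
#'   \code{DNAStringSet}); a random sequence of \code{unitLength} bases is
#'   generated when \code{NULL}.
#' @param .reseed set the RNG from \code{config@seed} (internal callers that
#'   manage the stream themselves pass \code{FALSE}).
#' @return list with \code{states} (named list of
#'   \code{\link{OccupancyState-class}} objects, one per tip), \code{tree}
#'   (the generating \code{phylo}), and \code{reference}
#'   (\code{DNAStringSet}).
#' @export
simulateOccupancies <- function(config, reference = NULL, .reseed = TRUE) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (.reseed) set.seed(config@seed)
  tr <- .resolveTree(config)
  L <- config@unitLength
  R <- config@arraySize
  if (is.null(reference))
    reference <- paste(sample(BASES, L, replace = TRUE), collapse = "")
  refc <- .refChars(reference)
  if (length(refc) != L)
    stop("reference length does not match config unitLength")
  refIdx <- match(refc, BASES)

  nTip <- length(tr$tip.label)
  root <- nTip + 1L
  po <- ape::reorder.phylo(tr, "postorder")
  nNode <- nTip + tr$Nnode
  states <- vector("list", nNode)
  states[[root]] <- list(
    variants = data.frame(pos = integer(0), base = character(0), k = integer(0)),
    used = logical(L))

  evolve <- function(st, bl) {
    v <- st$variants
    used <- st$used
    nNew <- rpois(1, config@mutationRate * L * bl)
    avail <- which(!used)
    nNew <- min(nNew, length(avail))
    if (nNew > 0) {
      pos <- avail[sample.int(length(avail), nNew)]
      off <- sample.int(3L, nNew, replace = TRUE)
      bIdx <- ((refIdx[pos] - 1L + off) %% 4L) + 1L
      v <- rbind(v, data.frame(pos = pos, base = BASES[bIdx],
                               k = rep(1L, nNew)))
      used[pos] <- TRUE
    }
    nSteps <- round(config@homogenizationSteps * bl)
    if (nrow(v) && nSteps > 0) v$k <- moranUpdate(v$k, R, nSteps)
    v <- v[v$k > 0L, , drop = FALSE]
    rownames(v) <- NULL
    list(variants = v, used = used)
  }

  # preorder: reversed postorder edge list visits parents before children
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1L]
    chl <- po$edge[e, 2L]
    states[[chl]] <- evolve(states[[par]], po$edge.length[e])
  }

  tipStates <- lapply(seq_len(nTip), function(i)
    occupancyState(tr$tip.label[i], R, L, states[[i]]$variants))
  names(tipStates) <- tr$tip.label
  refSet <- Biostrings::DNAStringSet(structure(paste(refc, collapse = ""),
                                               names = "ancestral_unit"))
  list(states = tipStates, tree = tr, reference = refSet)
}

#' Mix two parental arrays into a hybrid occupancy state
#'
#' The hybrid array takes \code{round(lambda * R)} units from parent A's
#' array composition and the remainder from parent B's. With deterministic
#' rounding (the default) the hybrid unit count of each allele is
#' \code{round(uA * kA / R + uB * kB / R)}, so a site fixed in A and absent
#' in B yields a mid-occupancy pSNP at occupancy ~ lambda. With
#' \code{stochastic = TRUE} unit draws are hypergeometric.
#'
#' @param parentA,parentB \code{OccupancyState}s on the same reference unit.
#' @param lambda mixing proportion of parent A, in [0, 1].
#' @param strain identifier of the hybrid.
#' @param stochastic hypergeometric unit sampling instead of deterministic
#'   rounding.
#' @param seed optional seed (stochastic mode only).
#' @return the hybrid \code{OccupancyState}.
#' @export
applyHybridization <- function(parentA, parentB, lambda, strain = "hybrid",
                               stochastic = FALSE, seed = NULL) {
  stopifnot(is(parentA, "OccupancyState"), is(parentB, "OccupancyState"))
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (parentA@unitLength != parentB@unitLength)
    stop("mismatched unit lengths between parents")
  if (parentA@arraySize != parentB@arraySize)
    stop("parents must have equal array sizes")
  if (!is.null(seed)) set.seed(seed)
  R <- parentA@arraySize
  uA <- round(lambda * R)
  uB <- R - uA

  va <- parentA@variants
  vb <- parentB@variants
  key <- union(paste(va$pos, va$base), paste(vb$pos, vb$base))
  if (!length(key))
    return(occupancyState(strain, R, parentA@unitLength))
  kA <- va$k[match(key, paste(va$pos, va$base))]
  kB <- vb$k[match(key, paste(vb$pos, vb$base))]
  kA[is.na(kA)] <- 0L
  kB[is.na(kB)] <- 0L
  if (stochastic) {
    kH <- rhyper(length(key), kA, R - kA, uA) +
          rhyper(length(key), kB, R - kB, uB)
  } else {
    kH <- as.integer(round(uA * kA / R + uB * kB / R))
  }
  parts <- strsplit(key, " ")
  v <- data.frame(pos = as.integer(vapply(parts, `[`, "", 1L)),
                  base = vapply(parts, `[`, "", 2L),
                  k = kH)
  v <- v[v$k > 0L, , drop = FALSE]
  # rounding can, at ties, push a site's allele total past R: trim largest
  if (nrow(v)) {
    tot <- tapply(v$k, v$pos, sum)
    bad <- as.integer(names(tot)[tot > R])
    for (p in bad) {
      i <- which(v$pos == p)
      j <- i[which.max(v$k[i])]
      v$k[j] <- v$k[j] - (sum(v$k[i]) - R)
    }
    v <- v[v$k > 0L, , drop = FALSE]
  }
  v <- v[order(v$pos, v$base), , drop = FALSE]
  occupancyState(strain, R, parentA@unitLength, v)
}

#' Sample a read pileup from an occupancy state
#'
#' Per site, the total read count is Poisson(\code{depth}); each read is
#' drawn from the array's base mix at that site and miscalled with
#' probability \code{errorRate}, uniformly over the three other bases. For
#' a site with a single derived allele at occupancy q this gives a
#' Binomial(total, q (1 - e) + (1 - q) e / 3) derived-base count.
#'
#' @param state an \code{OccupancyState}.
#' @param reference ancestral unit (character or \code{DNAStringSet}).
#' @param depth mean per-base fold coverage (>= 0).
#' @param errorRate per-base miscall probability in [0, 0.25).
#' @param seed optional integer seed.
#' @return a \code{\link{BaseCounts-class}} object.
#' @export
sampleBaseCounts <- function(state, reference, depth, errorRate = 0,
                             seed = NULL) {
  stopifnot(is(state, "OccupancyState"))
  if (depth < 0) stop("depth must be >= 0")
  if (errorRate < 0 || errorRate >= 0.25)
    stop("errorRate must lie in [0, 0.25)")
  if (!is.null(seed)) set.seed(seed)
  refc <- .refChars(reference)
  L <- state@unitLength
  if (length(refc) != L) stop("reference length does not match state")
  R <- state@arraySize
  refIdx <- match(refc, BASES)

  f <- matrix(0, L, 4L)
  f[cbind(seq_len(L), refIdx)] <- 1
  v <- state@variants
  if (nrow(v)) {
    bIdx <- match(v$base, BASES)
    occ <- v$k / R
    f[cbind(v$pos, bIdx)] <- f[cbind(v$pos, bIdx)] + occ
    agg <- tapply(occ, v$pos, sum)
    p0 <- as.integer(names(agg))
    f[cbind(p0, refIdx[p0])] <- f[cbind(p0, refIdx[p0])] - as.numeric(agg)
  }
  p <- f * (1 - errorRate) + (1 - f) * (errorRate / 3)

  tot <- rpois(L, depth)
  counts <- matrix(0L, L, 4L)
  rem <- tot
  pleft <- rep(1, L)
  for (j in 1:3) {
    pj <- ifelse(pleft > 0, p[, j] / pleft, 0)
    pj <- pmin(pmax(pj, 0), 1)
    counts[, j] <- rbinom(L, rem, pj)
    rem <- rem - counts[, j]
    pleft <- pleft - p[, j]
  }
  counts[, 4L] <- rem
  baseCounts(state@strain, counts)
}

#' Simulate a complete dataset with truth
#'
#' Composes \code{\link{simulateOccupancies}}, optional
#' \code{\link{applyHybridization}} events and
#' \code{\link{sampleBaseCounts}} into a \code{SyntheticDataset}. All draws
#' come from one RNG stream seeded once from \code{config@seed}, in a fixed
#' order (tree, reference, per-branch evolution, copy-number jitter, read
#' sampling strain by strain in tip order), so equal configs give identical
#' outputs. Truth copy numbers are the array size jittered by a uniform
#' integer factor in [0.8, 1.2]; each strain's rDNA read depth is
#' \code{genomeCoverage * copy number} (or scaled from \code{readDepth} when
#' set), which keeps the coverage-ratio copy-number estimator's input
#' self-consistent.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \code{\link{SyntheticDataset-class}} object.
#' @examples
#' ds <- simulateDataset(simConfig(nStrains = 4, unitLength = 500L, seed = 7))
#' truthCopyNumbers(ds)
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  so <- simulateOccupancies(config, .reseed = FALSE)
  states <- so$states
  strains <- names(states)
  R <- config@arraySize

  hybrid <- setNames(rep(FALSE, length(strains)), strains)
  for (h in config@hybridizations) {
    miss <- setdiff(c(h$child, h$parentA, h$parentB), strains)
    if (length(miss))
      stop("hybridization references unknown strain(s): ",
           paste(miss, collapse = ", "))
    states[[h$child]] <- applyHybridization(
      states[[h$parentA]], states[[h$parentB]], h$lambda, strain = h$child)
    hybrid[h$child] <- TRUE
  }

  cn <- pmax(2L, as.integer(round(R * runif(length(strains), 0.8, 1.2))))
  names(cn) <- strains
  depth <- if (is.na(config@readDepth)) {
    config@genomeCoverage * cn
  } else {
    config@readDepth * cn / R
  }

  bc <- lapply(strains, function(s)
    sampleBaseCounts(states[[s]], so$reference, depth[[s]],
                     config@errorRate))
  names(bc) <- strains

  new("SyntheticDataset", baseCounts = bc, tree = so$tree, states = states,
      copyNumbers = cn, hybridFlags = hybrid, reference = so$reference,
      config = config)
}
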