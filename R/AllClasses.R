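## Central S4 containers.

#' Simulation configuration for the concerted-evolution generator
#'
#' Holds the study conditions of one synthetic dataset: the strain phylogeny
#' (explicit or random), tandem-array size, mutation and homogenization
#' rates, optional hybridization events, and the read-sampling model.
#'
#' @slot nStrains number of strains (tips) when the tree is random.
#' @slot tree an \code{ape::phylo} tree, a Newick string, or \code{NULL} for
#'   a random topology on \code{nStrains} leaves.
#' @slot arraySize rDNA units per array (R).
#' @slot mutationRate expected new single-unit variants per site per unit of
#'   branch length.
#' @slot homogenizationSteps Moran updates per unit of branch length (h).
#' @slot hybridizations list of \code{list(child, parentA, parentB, lambda)}
#'   entries; the child tip's array is replaced by a lambda:(1-lambda)
#'   mixture of the two parents' arrays.
#' @slot unitLength rDNA unit length in bp.
#' @slot readDepth mean rDNA per-base fold coverage at the nominal array
#'   size; \code{NA} derives depth as \code{genomeCoverage * copy number}.
#' @slot errorRate per-base miscall probability (epsilon).
#' @slot genomeCoverage genome-wide fold coverage (G).
#' @slot seed integer seed governing every random draw.
#' @export
setClass("SimConfig",
  representation(
    nStrains = "integer",
    tree = "ANY",
    arraySize = "integer",
    mutationRate = "numeric",
    homogenizationSteps = "numeric",
    hybridizations = "list",
    unitLength = "integer",
    readDepth = "numeric",
    errorRate = "numeric",
    genomeCoverage = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  if (object@arraySize < 2L) msgs <- c(msgs, "arraySize must be >= 2")
  if (object@unitLength < 1L) msgs <- c(msgs, "unitLength must be >= 1")
  if (object@mutationRate < 0) msgs <- c(msgs, "mutationRate must be >= 0")
  if (object@homogenizationSteps < 0)
    msgs <- c(msgs, "homogenizationSteps must be >= 0")
  if (!is.na(object@readDepth) && object@readDepth < 0)
    msgs <- c(msgs, "readDepth must be >= 0")
  if (object@errorRate < 0 || object@errorRate >= 0.25)
    msgs <- c(msgs, "errorRate must lie in [0, 0.25)")
  if (object@genomeCoverage <= 0)
    msgs <- c(msgs, "genomeCoverage must be > 0")
  for (h in object@hybridizations) {
    if (!all(c("child", "parentA", "parentB", "lambda") %in% names(h)))
      msgs <- c(msgs, "each hybridization needs child, parentA, parentB, lambda")
    else if (h$lambda < 0 || h$lambda > 1)
      msgs <- c(msgs, "hybridization lambda must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe a single-locus yeast-like rDNA system: a 9137-bp unit,
#' 100 tandem copies, low-coverage shotgun sequencing (3-fold genome
#' coverage, so roughly 300-fold over the rDNA), and a 1\% per-base miscall
#' rate. Branch lengths of random trees are exponential with mean 0.1.
#'
#' @param nStrains tips of the random tree when \code{tree} is \code{NULL}.
#' @param tree \code{phylo}, Newick string, or \code{NULL}.
#' @param arraySize units per array (R).
#' @param mutationRate new variants per site per branch-length unit.
#' @param homogenizationSteps Moran updates per branch-length unit.
#' @param hybridizations list of \code{list(child, parentA, parentB, lambda)}.
#' @param unitLength unit length, bp.
#' @param readDepth optional explicit rDNA fold coverage (see class doc).
#' @param errorRate per-base miscall probability.
#' @param genomeCoverage genome-wide fold coverage.
#' @param seed integer seed.
#' @return a validated \code{SimConfig}.
#' @examples
#' cfg <- simConfig(nStrains = 6, seed = 42)
#' @export
simConfig <- function(nStrains = 8L, tree = NULL, arraySize = 100L,
                      mutationRate = 0.005, homogenizationSteps = 200,
                      hybridizations = list(), unitLength = 9137L,
                      readDepth = NA_real_, errorRate = 0.01,
                      genomeCoverage = 3, seed = 1L) {
  new("SimConfig",
    nStrains = as.integer(nStrains), tree = tree,
    arraySize = as.integer(arraySize), mutationRate = mutationRate,
    homogenizationSteps = homogenizationSteps,
    hybridizations = hybridizations, unitLength = as.integer(unitLength),
    readDepth = readDepth, errorRate = errorRate,
    genomeCoverage = genomeCoverage, seed = as.integer(seed))
}

#' Per-strain occupancy state of a tandem rDNA array
#'
#' One row of \code{variants} per (position, derived base): \code{k} of the
#' \code{arraySize} units carry that base instead of the ancestral one.
#' \code{k == arraySize} is a fixed substitution (occupancy 1, a SNP);
#' intermediate \code{k} are pSNPs in transit under concerted evolution.
#'
#' @slot strain strain identifier.
#' @slot arraySize number of rDNA units (R).
#' @slot unitLength unit length in bp.
#' @slot variants data.frame with columns \code{pos}, \code{base}, \code{k}.
#' @export
setClass("OccupancyState",
  representation(
    strain = "character",
    arraySize = "integer",
    unitLength = "integer",
    variants = "data.frame"
  )
)

setValidity("OccupancyState", function(object) {
  v <- object@variants
  msgs <- character(0)
  if (!all(c("pos", "base", "k") %in% names(v)))
    return("variants must have columns pos, base, k")
  if (nrow(v)) {
    if (any(v$k < 1L) || any(v$k > object@arraySize))
      msgs <- c(msgs, "variant unit counts k must lie in 1..arraySize")
    if (any(v$pos < 1L) || any(v$pos > object@unitLength))
      msgs <- c(msgs, "variant positions must lie in 1..unitLength")
    if (anyDuplicated(paste(v$pos, v$base)))
      msgs <- c(msgs, "duplicate (pos, base) variant rows")
    if (any(tapply(v$k, v$pos, sum) > object@arraySize))
      msgs <- c(msgs, "derived unit counts at a site exceed arraySize")
    if (!all(v$base %in% BASES)) msgs <- c(msgs, "bases must be A/C/G/T")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param strain,arraySize,unitLength,variants see the class slots.
#' @return a validated \code{OccupancyState}.
#' @rdname OccupancyState-class
#' @export
occupancyState <- function(strain, arraySize, unitLength,
                           variants = data.frame(pos = integer(0),
                                                 base = character(0),
                                                 k = integer(0))) {
  rownames(variants) <- NULL
  new("OccupancyState", strain = strain, arraySize = as.integer(arraySize),
      unitLength = as.integer(unitLength), variants = variants)
}

#' Per-strain base counts along the rDNA reference unit
#'
#' The pipeline's raw input: for each position of the reference unit, the
#' number of reads supporting A, C, G and T in one strain (strand-collapsed).
#'
#' @slot strain strain identifier.
#' @slot counts integer matrix, one row per reference position, columns
#'   A, C, G, T.
#' @export
setClass("BaseCounts",
  representation(strain = "character", counts = "matrix")
)

setValidity("BaseCounts", function(object) {
  m <- object@counts
  if (ncol(m) != 4L || !identical(colnames(m), BASES))
    return("counts must have columns A, C, G, T")
  if (any(m < 0)) return("counts must be non-negative")
  TRUE
})

#' @param strain,counts see the class slots (any column names on
#'   \code{counts} are replaced by A, C, G, T).
#' @return a validated \code{BaseCounts}.
#' @rdname BaseCounts-class
#' @export
baseCounts <- function(strain, counts) {
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(NULL, BASES)
  new("BaseCounts", strain = strain, counts = counts)
}

#' Strain-by-site allele-frequency matrix
#'
#' The central coding of rDNA heterogeneity: for every site carrying a SNP
#' or pSNP in at least one strain, each strain gets a 4-vector of allele
#' frequencies over (A, C, G, T). A strain without a call at an included
#' site is coded as a point mass on the reference base.
#'
#' @slot strains ordered strain identifiers.
#' @slot sites strictly increasing 1-based reference positions.
#' @slot refBases reference base at each site.
#' @slot freq numeric array of dim (strains, sites, 4).
#' @export
setClass("AlleleFrequencyMatrix",
  representation(
    strains = "character",
    sites = "integer",
    refBases = "character",
    freq = "array"
  )
)

setValidity("AlleleFrequencyMatrix", function(object) {
  msgs <- character(0)
  d <- dim(object@freq)
  if (length(d) != 3L || d[1] != length(object@strains) ||
      d[2] != length(object@sites) || d[3] != 4L)
    return("freq must be an array of dim (n strains, n sites, 4)")
  if (length(object@sites) != length(object@refBases))
    return("refBases must align with sites")
  if (any(object@freq < -1e-12)) msgs <- c(msgs, "frequencies must be >= 0")
  if (length(object@sites)) {
    if (any(diff(object@sites) <= 0))
      msgs <- c(msgs, "sites must be strictly increasing")
    sums <- apply(object@freq, c(1, 2), sum)
    if (any(abs(sums - 1) > 1e-9))
      msgs <- c(msgs, "each 4-vector must sum to 1 (tol 1e-9)")
    ref_idx <- match(object@refBases, BASES)
    for (s in seq_along(object@sites)) {
      if (all(abs(object@freq[, s, ref_idx[s]] - 1) < 1e-12))
        msgs <- c(msgs,
          sprintf("site %d is not polymorphic in any strain", object@sites[s]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Variant-calling parameters
#'
#' @slot errorRate assumed per-base miscall probability (epsilon).
#' @slot snpThreshold summed derived occupancy at or above which a call is a
#'   fully resolved SNP rather than a pSNP.
#' @slot minAlleleReads minimum reads supporting a derived allele.
#' @slot minDepth minimum site depth for any call.
#' @slot alpha family-wise level of the one-sided binomial error test
#'   (Bonferroni-corrected over the number of sites tested).
#' @export
setClass("CallParams",
  representation(errorRate = "numeric", snpThreshold = "numeric",
                 minAlleleReads = "integer", minDepth = "integer",
                 alpha = "numeric")
)

setValidity("CallParams", function(object) {
  msgs <- character(0)
  if (object@snpThreshold <= 0 || object@snpThreshold > 1)
    msgs <- c(msgs, "snpThreshold must lie in (0, 1]")
  if (object@minAlleleReads < 1L) msgs <- c(msgs, "minAlleleReads must be >= 1")
  if (object@errorRate < 0 || object@errorRate >= 0.25)
    msgs <- c(msgs, "errorRate must lie in [0, 0.25)")
  if (object@alpha <= 0 || object@alpha > 1)
    msgs <- c(msgs, "alpha must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @param errorRate,snpThreshold,minAlleleReads,minDepth,alpha see the
#'   \code{CallParams} class slots.
#' @return a validated \code{CallParams} object.
#' @rdname CallParams-class
#' @examples
#' callParams(errorRate = 0.005)
#' @export
callParams <- function(errorRate = 0.01, snpThreshold = 0.95,
                       minAlleleReads = 2L, minDepth = 10L, alpha = 0.05) {
  new("CallParams", errorRate = errorRate, snpThreshold = snpThreshold,
      minAlleleReads = as.integer(minAlleleReads),
      minDepth = as.integer(minDepth), alpha = alpha)
}

#' Windowed coverage profile of the rDNA unit
#'
#' @slot strain strain identifier (may be \code{NA}).
#' @slot windowLength window width in bp.
#' @slot windowValues mean per-base depth in each window; the final partial
#'   window is averaged over its actual width.
#' @slot unitLength reference unit length in bp.
#' @export
setClass("CoverageProfile",
  representation(strain = "character", windowLength = "integer",
                 windowValues = "numeric", unitLength = "integer")
)

setValidity("CoverageProfile", function(object) {
  nw <- ceiling(object@unitLength / object@windowLength)
  if (length(object@windowValues) != nw)
    return("window count must be ceiling(unitLength / windowLength)")
  if (any(object@windowValues < 0)) return("window values must be >= 0")
  TRUE
})

#' A simulated dataset with full truth
#'
#' @slot baseCounts named list of \code{BaseCounts}, one per strain.
#' @slot tree the generating tree (\code{phylo}).
#' @slot states named list of truth \code{OccupancyState}s.
#' @slot copyNumbers named integer truth copy numbers.
#' @slot hybridFlags named logical; \code{TRUE} for constructed hybrids.
#' @slot reference the ancestral unit as a \code{DNAStringSet} of length 1.
#' @slot config the \code{SimConfig} that produced the dataset.
#' @export
setClass("SyntheticDataset",
  representation(baseCounts = "list", tree = "ANY", states = "list",
                 copyNumbers = "integer", hybridFlags = "logical",
                 reference = "ANY", config = "SimConfig")
)

setValidity("SyntheticDataset", function(object) {
  nm <- names(object@baseCounts)
  if (!identical(nm, names(object@states)) ||
      !identical(nm, names(object@copyNumbers)) ||
      !identical(nm, names(object@hybridFlags)))
    return("strain sets of all components must be identical")
  if (!setequal(nm, object@tree$tip.label))
    return("strains must match the truth tree's tips")
  TRUE
})
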