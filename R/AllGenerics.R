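## Generics, accessors and show methods.

#' @rdname accessors
#' @export
setGeneric("strainName", function(x) standardGeneric("strainName"))
#' @rdname accessors
#' @export
setGeneric("arraySize", function(x) standardGeneric("arraySize"))
#' @rdname accessors
#' @export
setGeneric("unitLength", function(x) standardGeneric("unitLength"))
#' @rdname accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))
#' @rdname accessors
#' @export
setGeneric("countMatrix", function(x) standardGeneric("countMatrix"))
#' @rdname accessors
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))
#' @rdname accessors
#' @export
setGeneric("siteSet", function(x) standardGeneric("siteSet"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("refBases", function(x) standardGeneric("refBases"))
#' @rdname accessors
#' @export
setGeneric("windowValues", function(x) standardGeneric("windowValues"))
#' @rdname accessors
#' @export
setGeneric("truthTree", function(x) standardGeneric("truthTree"))
#' @rdname accessors
#' @export
setGeneric("truthStates", function(x) standardGeneric("truthStates"))
#' @rdname accessors
#' @export
setGeneric("truthCopyNumbers", function(x) standardGeneric("truthCopyNumbers"))
#' @rdname accessors
#' @export
setGeneric("hybridFlags", function(x) standardGeneric("hybridFlags"))
#' @rdname accessors
#' @export
setGeneric("referenceUnit", function(x) standardGeneric("referenceUnit"))
#' @rdname accessors
#' @export
setGeneric("baseCountList", function(x) standardGeneric("baseCountList"))

#' Accessors for rDNAphylo S4 containers
#'
#' Slot access for the package's data classes; user code should use these
#' rather than \code{@}.
#'
#' @param x an rDNAphylo S4 object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("strainName", "OccupancyState", function(x) x@strain)
#' @rdname accessors
#' @export
setMethod("strainName", "BaseCounts", function(x) x@strain)
#' @rdname accessors
#' @export
setMethod("strainName", "CoverageProfile", function(x) x@strain)
#' @rdname accessors
#' @export
setMethod("arraySize", "OccupancyState", function(x) x@arraySize)
#' @rdname accessors
#' @export
setMethod("arraySize", "SimConfig", function(x) x@arraySize)
#' @rdname accessors
#' @export
setMethod("unitLength", "OccupancyState", function(x) x@unitLength)
#' @rdname accessors
#' @export
setMethod("unitLength", "SimConfig", function(x) x@unitLength)
#' @rdname accessors
#' @export
setMethod("unitLength", "BaseCounts", function(x) nrow(x@counts))

#' @rdname accessors
#' @export
setMethod("variantTable", "OccupancyState", function(x) {
  v <- x@variants
  if (nrow(v)) v$occupancy <- v$k / x@arraySize else
    v$occupancy <- numeric(0)
  v
})

#' @rdname accessors
#' @export
setMethod("countMatrix", "BaseCounts", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("strainNames", "AlleleFrequencyMatrix", function(x) x@strains)
#' @rdname accessors
#' @export
setMethod("strainNames", "SyntheticDataset", function(x) names(x@baseCounts))
#' @rdname accessors
#' @export
setMethod("siteSet", "AlleleFrequencyMatrix", function(x) x@sites)
#' @rdname accessors
#' @export
setMethod("frequencies", "AlleleFrequencyMatrix", function(x) x@freq)
#' @rdname accessors
#' @export
setMethod("refBases", "AlleleFrequencyMatrix", function(x) x@refBases)
#' @rdname accessors
#' @export
setMethod("windowValues", "CoverageProfile", function(x) x@windowValues)
#' @rdname accessors
#' @export
setMethod("truthTree", "SyntheticDataset", function(x) x@tree)
#' @rdname accessors
#' @export
setMethod("truthStates", "SyntheticDataset", function(x) x@states)
#' @rdname accessors
#' @export
setMethod("truthCopyNumbers", "SyntheticDataset", function(x) x@copyNumbers)
#' @rdname accessors
#' @export
setMethod("hybridFlags", "SyntheticDataset", function(x) x@hybridFlags)
#' @rdname accessors
#' @export
setMethod("referenceUnit", "SyntheticDataset", function(x) x@reference)
#' @rdname accessors
#' @export
setMethod("baseCountList", "SyntheticDataset", function(x) x@baseCounts)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nStrains, "strains,",
      if (is.null(object@tree)) "random topology" else "fixed tree", "\n")
  cat("  array:", object@arraySize, "units x", object@unitLength, "bp\n")
  cat("  mutation rate:", object@mutationRate,
      "/site/blu; homogenization:", object@homogenizationSteps, "steps/blu\n")
  cat("  hybridizations:", length(object@hybridizations),
      "; error rate:", object@errorRate,
      "; genome coverage:", object@genomeCoverage, "x\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "OccupancyState", function(object) {
  v <- object@variants
  cat("OccupancyState for strain", object@strain, "(R =", object@arraySize,
      "units,", object@unitLength, "bp unit)\n")
  cat(" ", nrow(v), "variant alleles;", sum(v$k == object@arraySize),
      "fixed\n")
})

setMethod("show", "BaseCounts", function(object) {
  cat("BaseCounts for strain", object@strain, ":", nrow(object@counts),
      "positions, mean depth", round(mean(rowSums(object@counts)), 2), "\n")
})

setMethod("show", "AlleleFrequencyMatrix", function(object) {
  cat("AlleleFrequencyMatrix:", length(object@strains), "strains x",
      length(object@sites), "polymorphic sites\n")
})

setMethod("show", "CallParams", function(object) {
  cat("CallParams: errorRate", object@errorRate, "| snpThreshold",
      object@snpThreshold, "| minAlleleReads", object@minAlleleReads,
      "| minDepth", object@minDepth, "| alpha", object@alpha, "\n")
})

setMethod("show", "CoverageProfile", function(object) {
  cat("CoverageProfile", if (!is.na(object@strain)) object@strain else "",
      ":", length(object@windowValues), "windows of", object@windowLength,
      "bp over", object@unitLength, "bp\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", length(object@baseCounts), "strains,",
      sum(object@hybridFlags), "hybrids, unit",
      unitLength(object@config), "bp\n")
})
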