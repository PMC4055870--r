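## rDNA copy number from windowed coverage; genome-type classification from
## the pSNP occupancy spectrum.

#' Windowed coverage profile along the rDNA unit
#'
#' Averages per-base depth over consecutive windows (default 20 bp); the
#' final partial window is averaged over its actual width.
#'
#' @param depths per-base depth vector over the whole reference unit.
#' @param windowLength window width, bp.
#' @param strain optional strain identifier.
#' @return a \code{\link{CoverageProfile-class}} object.
#' @examples
#' windowValues(coverageProfile(1:40))   # 10.5, 30.5
#' @export
coverageProfile <- function(depths, windowLength = 20L, strain = NA_character_) {
  if (!length(depths)) stop("empty depth vector")
  if (any(depths < 0)) stop("depths must be >= 0")
  idx <- ceiling(seq_along(depths) / windowLength)
  vals <- as.numeric(tapply(depths, idx, mean))
  new("CoverageProfile", strain = strain,
      windowLength = as.integer(windowLength), windowValues = vals,
      unitLength = length(depths))
}

#' Estimate rDNA copy number from a coverage profile
#'
#' Copy number is the mean window coverage divided by the genome-wide fold
#' coverage (treated as a constant); its standard error is
#' \code{sd(windows) / (sqrt(n windows) * G)} with the sample (n - 1)
#' standard deviation. A single-window profile has no defined SE
#' (\code{NA}).
#'
#' @param profile a \code{\link{CoverageProfile-class}} object.
#' @param genomeCoverage genome-wide fold coverage G (> 0).
#' @return data.frame with strain, mean_unit_coverage, genome_coverage,
#'   copy_number, se.
#' @export
estimateCopyNumber <- function(profile, genomeCoverage) {
  stopifnot(is(profile, "CoverageProfile"))
  if (genomeCoverage <= 0) stop("genomeCoverage must be > 0")
  w <- profile@windowValues
  se <- if (length(w) > 1L) sd(w) / (sqrt(length(w)) * genomeCoverage)
        else NA_real_
  data.frame(strain = profile@strain, mean_unit_coverage = mean(w),
             genome_coverage = genomeCoverage,
             copy_number = mean(w) / genomeCoverage, se = se)
}

#' Occupancy band of a pSNP
#'
#' Low is occupancy at or below 0.10, high at or above 0.90, mid strictly
#' between; the boundaries are assigned outward because the mid band is
#' defined as strictly greater than 10\% and strictly less than 90\%.
#'
#' @param occupancy occupancy value(s) in (0, 1].
#' @param low,high configurable band boundaries.
#' @return character vector over \{"low", "mid", "high"\}.
#' @examples
#' occupancyBand(c(0.05, 0.10, 0.5, 0.90))
#' @export
occupancyBand <- function(occupancy, low = 0.10, high = 0.90) {
  if (any(occupancy <= 0 | occupancy > 1))
    stop("occupancy must lie in (0, 1]")
  ifelse(occupancy <= low, "low", ifelse(occupancy >= high, "high", "mid"))
}

#' Classify a strain's genome type from its pSNP occupancy spectrum
#'
#' Mid-occupancy pSNPs mark genome mosaicism: a hybrid of two divergent
#' parents carries parental SNP differences as pSNPs at occupancies near the
#' mixing proportion. Counting each called site once (summed derived
#' occupancy), pSNP sites are banded by \code{\link{occupancyBand}} and the
#' strain labeled:
#' \itemize{
#'   \item \code{structured_clean} when \code{n_mid <= cleanMaxMid} or the
#'     mid fraction is below \code{cleanMidFraction};
#'   \item \code{mosaic} when \code{n_psnp >= mosaicMinPsnp} and the mid
#'     fraction is at least \code{cleanMidFraction};
#'   \item \code{structured_mosaic} otherwise (few pSNPs but mostly mid);
#'     cases with mid fraction below \code{mosaicMidFraction} additionally
#'     carry \code{borderline = TRUE}.
#' }
#' All thresholds are configurable; the defaults reproduce the worked
#' yeast examples (2 mid of 16 pSNPs is structured clean; a strain whose few
#' pSNPs are mostly mid-occupancy is structured mosaic; many pSNPs with a
#' substantial mid fraction is mosaic).
#'
#' @param calls call data.frame for one strain (as from
#'   \code{\link{callStrain}}).
#' @param lowBand,highBand occupancy band boundaries.
#' @param cleanMaxMid maximum mid-band pSNPs for a clean label.
#' @param cleanMidFraction mid fraction below which the strain is clean.
#' @param mosaicMinPsnp minimum pSNP count for the full mosaic label.
#' @param mosaicMidFraction mid fraction at or above which an intermediate
#'   strain is a confident structured mosaic.
#' @return one-row data.frame: strain, n_snp, n_psnp, n_low, n_mid, n_high,
#'   mid_fraction, label, borderline.
#' @export
classifyGenomeType <- function(calls, lowBand = 0.10, highBand = 0.90,
                               cleanMaxMid = 1L, cleanMidFraction = 0.25,
                               mosaicMinPsnp = 15L, mosaicMidFraction = 0.5) {
  strain <- if (nrow(calls)) {
    if (length(unique(calls$strain)) > 1L)
      stop("calls must come from a single strain")
    calls$strain[1]
  } else NA_character_
  if (nrow(calls)) {
    occ <- tapply(calls$occupancy, calls$pos, sum)
    cls <- tapply(calls$class, calls$pos, `[`, 1L)
    nSnp <- sum(cls == "SNP")
    pOcc <- occ[cls == "pSNP"]
    nPsnp <- length(pOcc)
    bands <- if (nPsnp) occupancyBand(pOcc, lowBand, highBand) else character(0)
  } else {
    nSnp <- 0L; nPsnp <- 0L; bands <- character(0)
  }
  nLow <- sum(bands == "low")
  nMid <- sum(bands == "mid")
  nHigh <- sum(bands == "high")
  midFrac <- nMid / max(nPsnp, 1L)
  borderline <- FALSE
  if (nMid <= cleanMaxMid || midFrac < cleanMidFraction) {
    label <- "structured_clean"
  } else if (nPsnp >= mosaicMinPsnp) {
    label <- "mosaic"
  } else {
    label <- "structured_mosaic"
    borderline <- midFrac < mosaicMidFraction
  }
  data.frame(strain = strain, n_snp = nSnp, n_psnp = nPsnp, n_low = nLow,
             n_mid = nMid, n_high = nHigh, mid_fraction = midFrac,
             label = label, borderline = borderline)
}
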