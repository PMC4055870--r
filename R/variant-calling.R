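## Variant scoring: per-site base counts -> SNP / pSNP calls with occupancy.

## One-sided binomial tail: P(X >= count) with X ~ Binomial(depth, e/3).
.errorTailP <- function(count, depth, errorRate) {
  pbinom(count - 1, depth, errorRate / 3, lower.tail = FALSE)
}

#' Score one site of one strain
#'
#' A non-reference base is admitted as a derived allele when it is supported
#' by at least \code{minAlleleReads} reads and a one-sided binomial test
#' rejects the hypothesis that its count arose from miscalls at rate
#' \code{errorRate / 3}, at level \code{alpha / nSitesTested} (Bonferroni
#' over the sites scanned). A call is emitted when the site has at least one
#' derived allele and depth at least \code{minDepth}; it is classed SNP when
#' the summed derived occupancy reaches \code{snpThreshold}, else pSNP.
#'
#' @param refBase the reference base at the site ("A", "C", "G" or "T").
#' @param counts integer vector of 4 read counts, ordered A, C, G, T.
#' @param params a \code{\link{callParams}} object.
#' @param nSitesTested Bonferroni divisor (number of sites scanned; 1 for a
#'   lone site).
#' @return a list with \code{status} ("called", "no_variant" or
#'   "low_depth"), \code{depth}, \code{class} ("SNP", "pSNP" or \code{NA}),
#'   and \code{derived}, a data.frame of (base, count, occupancy) rows.
#' @examples
#' callSite("A", c(70L, 30L, 0L, 0L), callParams(), nSitesTested = 1)
#' @export
callSite <- function(refBase, counts, params = callParams(),
                     nSitesTested = 1L) {
  stopifnot(is(params, "CallParams"))
  if (!refBase %in% BASES) stop("refBase must be one of A, C, G, T")
  if (length(counts) != 4L || any(counts < 0))
    stop("counts must be 4 non-negative integers (A, C, G, T)")
  depth <- sum(counts)
  noCall <- function(status) list(status = status, depth = depth,
    class = NA_character_,
    derived = data.frame(base = character(0), count = integer(0),
                         occupancy = numeric(0)))
  if (depth < params@minDepth) return(noCall("low_depth"))
  idx <- setdiff(seq_len(4L), match(refBase, BASES))
  cnt <- counts[idx]
  pv <- .errorTailP(cnt, depth, params@errorRate)
  sig <- cnt >= params@minAlleleReads & pv <= params@alpha / nSitesTested
  if (!any(sig)) return(noCall("no_variant"))
  derived <- data.frame(base = BASES[idx][sig], count = as.integer(cnt[sig]),
                        occupancy = cnt[sig] / depth)
  derived <- derived[order(-derived$count, derived$base), , drop = FALSE]
  rownames(derived) <- NULL
  cls <- if (sum(derived$occupancy) >= params@snpThreshold) "SNP" else "pSNP"
  list(status = "called", depth = depth, class = cls, derived = derived)
}

#' Call variants across all sites of one strain
#'
#' Vectorized application of the \code{\link{callSite}} rule to a
#' \code{BaseCounts} table against the reference unit. At most one call is
#' emitted per position; multi-allelic sites keep every significant derived
#' allele in that call (one row each) and are classed by their summed
#' occupancy.
#'
#' @param table a \code{\link{BaseCounts-class}} object.
#' @param reference the rDNA reference unit (character or
#'   \code{DNAStringSet}).
#' @param params a \code{\link{callParams}} object.
#' @param nSitesTested Bonferroni divisor; defaults to the number of
#'   positions in the table.
#' @return data.frame of calls with columns strain, pos, ref, derived,
#'   count, depth, occupancy, class (one row per derived allele; empty with
#'   the same columns when nothing is called).
#' @seealso \code{\link{callSummary}} for per-strain SNP / pSNP totals.
#' @export
callStrain <- function(table, reference, params = callParams(),
                       nSitesTested = NULL) {
  stopifnot(is(table, "BaseCounts"), is(params, "CallParams"))
  refc <- .refChars(reference)
  m <- table@counts
  L <- nrow(m)
  if (L > length(refc)) stop("table positions exceed reference length")
  if (is.null(nSitesTested)) nSitesTested <- L
  refIdx <- match(refc[seq_len(L)], BASES)
  depth <- rowSums(m)

  aCrit <- params@alpha / nSitesTested
  emptyCalls <- data.frame(strain = character(0), pos = integer(0),
    ref = character(0), derived = character(0), count = integer(0),
    depth = integer(0), occupancy = numeric(0), class = character(0))

  rows <- vector("list", 4L)
  for (j in seq_len(4L)) {
    cand <- which(refIdx != j & m[, j] >= params@minAlleleReads &
                  depth >= params@minDepth)
    if (!length(cand)) next
    pv <- .errorTailP(m[cand, j], depth[cand], params@errorRate)
    keep <- cand[pv <= aCrit]
    if (!length(keep)) next
    rows[[j]] <- data.frame(pos = keep, derived = BASES[j],
                            count = as.integer(m[keep, j]),
                            depth = as.integer(depth[keep]),
                            occupancy = m[keep, j] / depth[keep])
  }
  calls <- do.call(rbind, rows)
  if (is.null(calls) || !nrow(calls)) return(emptyCalls)
  calls <- calls[order(calls$pos, -calls$count, calls$derived), , drop = FALSE]
  siteOcc <- tapply(calls$occupancy, calls$pos, sum)
  cls <- ifelse(siteOcc >= params@snpThreshold, "SNP", "pSNP")
  calls$class <- cls[as.character(calls$pos)]
  calls$ref <- refc[calls$pos]
  calls$strain <- table@strain
  rownames(calls) <- NULL
  calls[, c("strain", "pos", "ref", "derived", "count", "depth",
            "occupancy", "class")]
}

#' Per-strain SNP / pSNP summary of a call table
#'
#' Each called position is counted once, classed by its call.
#'
#' @param calls a call data.frame as returned by \code{\link{callStrain}}
#'   (possibly concatenated over strains).
#' @return data.frame with columns strain, n_snp, n_psnp.
#' @export
callSummary <- function(calls) {
  if (!nrow(calls))
    return(data.frame(strain = character(0), n_snp = integer(0),
                      n_psnp = integer(0)))
  per <- unique(calls[, c("strain", "pos", "class")])
  out <- do.call(rbind, lapply(split(per, per$strain), function(d)
    data.frame(strain = d$strain[1],
               n_snp = sum(d$class == "SNP"),
               n_psnp = sum(d$class == "pSNP"))))
  rownames(out) <- NULL
  out
}
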