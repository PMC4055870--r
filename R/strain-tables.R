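## Strain summary tables (per-strain SNP/pSNP counts, copy numbers, genome
## types) and the summary statistics computed from them. Transcriptions of
## the published yeast strain tables ship as TSV fixtures under
## inst/extdata/ (table1_paradoxus.tsv, table2_cerevisiae.tsv).

#' Load and validate a strain summary table
#'
#' Required columns: strain, n_snp, n_psnp, n_total, copy_number,
#' copy_number_se; optional: group, genome_type, modified_genome_type. The
#' row invariant n_total = n_snp + n_psnp is enforced, as is strain
#' uniqueness.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @examples
#' tab <- loadStrainTable(system.file("extdata", "table1_paradoxus.tsv",
#'                                    package = "rDNAphylo"))
#' nrow(tab)  # 26
#' @export
loadStrainTable <- function(path) {
  # na.strings = "": the North American group is coded "NA" in the tables
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "")
  req <- c("strain", "n_snp", "n_psnp", "n_total", "copy_number",
           "copy_number_se")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$strain))
    stop("duplicate strain id(s): ",
         paste(unique(tab$strain[duplicated(tab$strain)]), collapse = ", "))
  bad <- which(tab$n_total != tab$n_snp + tab$n_psnp)
  if (length(bad))
    stop("n_total != n_snp + n_psnp for strain(s): ",
         paste(tab$strain[bad], collapse = ", "))
  tab
}

#' Write a strain summary table
#'
#' @param table a strain summary data.frame.
#' @param path TSV destination.
#' @export
writeStrainTable <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Column sums and per-strain means of polymorphism counts
#'
#' @param table a strain summary table.
#' @return list with sum_snp, sum_psnp, sum_total, mean_psnp_per_strain
#'   (full precision) and mean_psnp_per_strain_2dp (rounded as printed).
#' @export
summarizePolymorphisms <- function(table) {
  if (!nrow(table)) stop("empty strain table")
  m <- sum(table$n_psnp) / nrow(table)
  list(sum_snp = sum(table$n_snp), sum_psnp = sum(table$n_psnp),
       sum_total = sum(table$n_total), mean_psnp_per_strain = m,
       mean_psnp_per_strain_2dp = round(m, 2))
}

#' Two-group contrasts of per-strain pSNP counts
#'
#' \code{psnp_sum}: total pSNPs within the \code{level} group.
#' \code{psnp_mean_ratio}: ratio of group mean pSNP counts,
#' numerator/denominator group means rounded to 2 decimals before division
#' (the printed-table arithmetic); the unrounded ratio is returned
#' alongside. \code{point_biserial_r}: absolute Pearson correlation between
#' per-strain pSNP count and the 0/1 group indicator.
#'
#' @param table a strain summary table.
#' @param grouping name of the grouping column (exactly 2 levels for the
#'   ratio and point-biserial statistics).
#' @param statistic one of "psnp_sum", "psnp_mean_ratio",
#'   "point_biserial_r".
#' @param level group level: the group summed (psnp_sum) or the numerator
#'   group (psnp_mean_ratio).
#' @return psnp_sum / point_biserial_r: a single number;
#'   psnp_mean_ratio: list(ratio, ratio_exact).
#' @export
groupContrast <- function(table, grouping,
                          statistic = c("psnp_sum", "psnp_mean_ratio",
                                        "point_biserial_r"),
                          level = NULL) {
  statistic <- match.arg(statistic)
  if (!grouping %in% names(table)) stop("no column named '", grouping, "'")
  g <- table[[grouping]]
  if (statistic == "psnp_sum") {
    if (is.null(level)) stop("psnp_sum needs a 'level'")
    return(sum(table$n_psnp[g == level]))
  }
  lev <- unique(g)
  if (length(lev) != 2L)
    stop("grouping must have exactly 2 levels for ", statistic)
  if (statistic == "psnp_mean_ratio") {
    if (is.null(level)) stop("psnp_mean_ratio needs a numerator 'level'")
    mNum <- mean(table$n_psnp[g == level])
    mDen <- mean(table$n_psnp[g != level])
    return(list(ratio = round(round(mNum, 2) / round(mDen, 2), 2),
                ratio_exact = mNum / mDen))
  }
  ind <- as.numeric(g == lev[1])
  if (sd(ind) == 0 || sd(table$n_psnp) == 0)
    stop("zero variance: point-biserial correlation undefined")
  abs(cor(table$n_psnp, ind))
}

#' Copy-number summary of a strain table
#'
#' @param table a strain summary table with a copy_number column.
#' @param exclude strain ids to drop before summarizing.
#' @return list with mean (full precision), mean_rounded (integer, as
#'   printed), min / max and the strains attaining them.
#' @export
copyNumberSummary <- function(table, exclude = character(0)) {
  if (!"copy_number" %in% names(table)) stop("no copy_number column")
  unknown <- setdiff(exclude, table$strain)
  if (length(unknown))
    stop("exclusion names unknown strain(s): ",
         paste(unknown, collapse = ", "))
  tab <- table[!table$strain %in% exclude, ]
  m <- mean(tab$copy_number)
  list(mean = m, mean_rounded = round(m),
       min = min(tab$copy_number),
       min_strain = tab$strain[which.min(tab$copy_number)],
       max = max(tab$copy_number),
       max_strain = tab$strain[which.max(tab$copy_number)])
}
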