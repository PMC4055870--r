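## Readers and writers for the pipeline's text formats: base-count TSV,
## calls TSV, frequency-matrix TSV, truth-occupancy TSV, PHYLIP square
## distance matrices. Newick goes through ape, FASTA through Biostrings.

#' Write per-strain base counts to TSV
#'
#' Columns: strain, pos (1-based), A, C, G, T.
#'
#' @param x a \code{BaseCounts} object or a (named) list of them.
#' @param path destination file.
#' @export
writeBaseCounts <- function(x, path) {
  if (is(x, "BaseCounts")) x <- list(x)
  rows <- lapply(x, function(bc) {
    m <- countMatrix(bc)
    data.frame(strain = strainName(bc), pos = seq_len(nrow(m)),
               A = m[, 1], C = m[, 2], G = m[, 3], T = m[, 4])
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read per-strain base counts from TSV
#'
#' @param path file written by \code{\link{writeBaseCounts}} (columns
#'   strain, pos, A, C, G, T; every strain must cover positions 1..L).
#' @return named list of \code{BaseCounts}.
#' @export
readBaseCounts <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("strain", "pos", "A", "C", "G", "T")
  if (!all(req %in% names(tab)))
    stop("base-count TSV needs columns: ", paste(req, collapse = ", "))
  out <- lapply(split(tab, tab$strain), function(d) {
    d <- d[order(d$pos), ]
    if (!identical(d$pos, seq_len(nrow(d))))
      stop("positions of strain ", d$strain[1], " are not contiguous 1..L")
    baseCounts(d$strain[1], as.matrix(d[, BASES]))
  })
  out[unique(tab$strain)]
}

#' Write variant calls to TSV
#' @param calls call data.frame from \code{\link{callStrain}}.
#' @param path destination file.
#' @export
writeCalls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read variant calls from TSV
#' @param path file written by \code{\link{writeCalls}}.
#' @return call data.frame.
#' @export
readCalls <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write an allele-frequency matrix to long TSV
#'
#' Columns: strain, pos, fA, fC, fG, fT.
#'
#' @param matrix an \code{AlleleFrequencyMatrix}.
#' @param path destination file.
#' @export
writeFrequencyMatrix <- function(matrix, path) {
  stopifnot(is(matrix, "AlleleFrequencyMatrix"))
  f <- matrix@freq
  rows <- expand.grid(strain = matrix@strains, pos = matrix@sites,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (b in seq_len(4L)) rows[[paste0("f", BASES[b])]] <- as.vector(f[, , b])
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele-frequency matrix from long TSV
#'
#' @param path file written by \code{\link{writeFrequencyMatrix}}.
#' @param reference optional reference unit used to recover the reference
#'   base of each site; when absent the base with the largest total
#'   frequency at the site is taken as the reference.
#' @return an \code{AlleleFrequencyMatrix}.
#' @export
readFrequencyMatrix <- function(path, reference = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("strain", "pos", paste0("f", BASES))
  if (!all(req %in% names(tab)))
    stop("frequency TSV needs columns: ", paste(req, collapse = ", "))
  strains <- unique(tab$strain)
  sites <- sort(unique(tab$pos))
  freq <- array(0, dim = c(length(strains), length(sites), 4L),
                dimnames = list(strains, sites, BASES))
  si <- match(tab$strain, strains)
  pi <- match(tab$pos, sites)
  for (b in seq_len(4L))
    freq[cbind(si, pi, b)] <- tab[[paste0("f", BASES[b])]]
  refB <- if (!is.null(reference)) {
    .refChars(reference)[sites]
  } else {
    BASES[apply(apply(freq, c(2, 3), sum), 1, which.max)]
  }
  new("AlleleFrequencyMatrix", strains = strains, sites = as.integer(sites),
      refBases = refB, freq = freq)
}

#' Write a PHYLIP square distance matrix
#'
#' First line: the number of taxa. Then one row per taxon: the label padded
#' to width 10, followed by the full row of distances, space-separated.
#'
#' @param d symmetric labeled distance matrix.
#' @param path destination file.
#' @export
writePhylipDist <- function(d, path) {
  .checkDistMatrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path file in the layout of \code{\link{writePhylipDist}} (no row
#'   wrapping).
#' @return symmetric labeled distance matrix.
#' @export
readPhylipDist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  d <- matrix(0, n, n)
  labels <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    labels[i] <- parts[1]
    d[i, ] <- as.numeric(parts[-1])
  }
  dimnames(d) <- list(labels, labels)
  d
}

#' Write truth occupancies of a synthetic dataset to TSV
#'
#' Columns: strain, pos, derived_base, occupancy.
#'
#' @param states named list of \code{OccupancyState}s.
#' @param path destination file.
#' @export
writeOccupancyTruth <- function(states, path) {
  rows <- lapply(states, function(st) {
    v <- variantTable(st)
    if (!nrow(v)) return(NULL)
    data.frame(strain = strainName(st), pos = v$pos, derived_base = v$base,
               occupancy = v$occupancy)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(strain = character(0), pos = integer(0),
               derived_base = character(0), occupancy = numeric(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset (data + truth files) to a directory
#'
#' Writes base_counts.tsv, reference.fasta, truth_tree.nwk,
#' truth_occupancy.tsv and truth_labels.tsv (strain, copy_number, hybrid).
#'
#' @param dataset a \code{SyntheticDataset}.
#' @param dir destination directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBaseCounts(baseCountList(dataset), file.path(dir, "base_counts.tsv"))
  Biostrings::writeXStringSet(referenceUnit(dataset),
                              file.path(dir, "reference.fasta"))
  ape::write.tree(truthTree(dataset), file.path(dir, "truth_tree.nwk"))
  writeOccupancyTruth(truthStates(dataset),
                      file.path(dir, "truth_occupancy.tsv"))
  labels <- data.frame(strain = strainNames(dataset),
                       copy_number = as.integer(truthCopyNumbers(dataset)),
                       hybrid = hybridFlags(dataset))
  write.table(labels, file.path(dir, "truth_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
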