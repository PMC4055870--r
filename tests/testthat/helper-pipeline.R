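# Shared fixtures built in code.

# balanced 8-strain tree, all branches 0.1
balanced8 <- function() {
  paste0("(((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1):0.1,",
         "((e:0.1,f:0.1):0.1,(g:0.1,h:0.1):0.1):0.1);")
}

# high-signal noiseless study conditions for topology-recovery experiments:
# small arrays so new variants start at detectable occupancy (1/20), ~100
# expected variants per branch, error-free deep sequencing
recoveryConfig <- function(seed) {
  simConfig(tree = balanced8(), arraySize = 20L, unitLength = 1500L,
            mutationRate = 0.7, homogenizationSteps = 0, errorRate = 0,
            genomeCoverage = 15, seed = seed)
}

# full pipeline: base counts -> calls -> frequency matrix -> chord -> NJ
recoverTree <- function(ds, params = callParams(errorRate = 0)) {
  calls <- do.call(rbind, lapply(baseCountList(ds), function(b)
    callStrain(b, referenceUnit(ds), params)))
  afm <- buildFrequencyMatrix(calls, strainNames(ds), referenceUnit(ds))
  suppressMessages(neighborJoining(chordDistance(afm)))
}

# an OccupancyState with given positions/occupancies on array of R units
mkState <- function(strain, R, L, pos, k, base = "C") {
  occupancyState(strain, R, L,
                 data.frame(pos = as.integer(pos),
                            base = rep(base, length.out = length(pos)),
                            k = as.integer(k)))
}

# random labeled symmetric "distance" matrix (zero diagonal)
randDist <- function(n, labels = paste0("s", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[lower.tri(d)] <- runif(n * (n - 1) / 2)
  d + t(d)
}

# random valid allele-frequency array (nS x S x 4), rows normalized
randFreqArray <- function(nS, S) {
  f <- array(runif(nS * S * 4), dim = c(nS, S, 4))
  tot <- apply(f, c(1, 2), sum)
  for (b in 1:4) f[, , b] <- f[, , b] / tot
  f
}

table1Path <- function() {
  system.file("extdata", "table1_paradoxus.tsv", package = "rDNAphylo")
}
table2Path <- function() {
  system.file("extdata", "table2_cerevisiae.tsv", package = "rDNAphylo")
}
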