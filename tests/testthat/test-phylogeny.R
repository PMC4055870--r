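test_that("frequency matrix applies the occupancy coding rule", {
  ref <- strrep("A", 200)

  # no calls at all: zero sites
  empty <- data.frame(strain = character(0), pos = integer(0),
                      ref = character(0), derived = character(0),
                      count = integer(0), depth = integer(0),
                      occupancy = numeric(0), class = character(0))
  afm0 <- buildFrequencyMatrix(empty, c("X", "Y"), ref)
  expect_identical(length(siteSet(afm0)), 0L)

  # SNP in X at 100, nothing in Y
  calls <- data.frame(strain = "X", pos = 100L, ref = "A", derived = "C",
                      count = 50L, depth = 50L, occupancy = 1.0,
                      class = "SNP")
  afm <- buildFrequencyMatrix(calls, c("X", "Y"), ref)
  expect_identical(siteSet(afm), 100L)
  expect_equal(as.numeric(frequencies(afm)["X", 1, ]), c(0, 1, 0, 0))
  expect_equal(as.numeric(frequencies(afm)["Y", 1, ]), c(1, 0, 0, 0))

  # pSNP at 7 (A -> G, occ 0.25): remainder on the reference base
  calls2 <- data.frame(strain = "X", pos = 7L, ref = "A", derived = "G",
                       count = 25L, depth = 100L, occupancy = 0.25,
                       class = "pSNP")
  afm2 <- buildFrequencyMatrix(calls2, c("X", "Y"), ref)
  expect_equal(as.numeric(frequencies(afm2)["X", 1, ]), c(0.75, 0, 0.25, 0))
  sums <- apply(frequencies(afm2), c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # occupancy above 1 is rejected
  bad <- data.frame(strain = c("X", "X"), pos = c(7L, 7L), ref = "A",
                    derived = c("G", "C"), count = c(60L, 60L),
                    depth = 100L, occupancy = c(0.6, 0.6), class = "SNP")
  expect_error(buildFrequencyMatrix(bad, c("X", "Y"), ref), "occupancy")
})

test_that("chord distance matches the formula, its bounds, and a brute-force oracle", {
  mk <- function(freq, strains) {
    S <- dim(freq)[2]
    new("AlleleFrequencyMatrix", strains = strains,
        sites = as.integer(seq_len(S)),
        refBases = rep("T", S), freq = freq)
  }
  # identical rows: zero distance; full fixation difference: 1
  f <- array(0, c(2, 3, 4)); f[, , 2] <- 1
  f[1, , 2] <- 0; f[1, , 1] <- 1; f[2, , 2] <- 1
  d <- chordDistance(mk(f, c("x", "y")))
  expect_equal(d["x", "y"], 1)
  fSame <- array(rep(randFreqArray(1, 3), each = 2), c(2, 3, 4))
  expect_equal(max(chordDistance(mk(fSame, c("x", "y")))), 0)

  # hand-evaluated single-site value
  f1 <- array(0, c(2, 1, 4))
  f1[1, 1, ] <- c(1, 0, 0, 0); f1[2, 1, ] <- c(0.5, 0.5, 0, 0)
  expect_equal(chordDistance(mk(f1, c("x", "y")))["x", "y"],
               sqrt(1 - sqrt(0.5)), tolerance = 1e-12)
  expect_equal(round(chordDistance(mk(f1, c("x", "y")))["x", "y"], 5),
               0.54120)

  # brute-force evaluation of the formula, element by element
  set.seed(31)
  for (rep in 1:5) {
    nS <- sample(3:6, 1); S <- sample(2:10, 1)
    f <- randFreqArray(nS, S)
    afm <- mk(f, paste0("s", 1:nS))
    d <- chordDistance(afm)
    for (i in 1:(nS - 1)) for (j in (i + 1):nS) {
      terms <- vapply(seq_len(S), function(s)
        1 - sum(sqrt(f[i, s, ] * f[j, s, ])), numeric(1))
      expect_equal(d[i, j], sqrt(sum(terms) / S), tolerance = 1e-12)
    }
  }
})

test_that("chord distance satisfies the metric axioms on random matrices", {
  set.seed(17)
  for (rep in 1:5) {
    f <- randFreqArray(5, 8)
    afm <- new("AlleleFrequencyMatrix", strains = paste0("s", 1:5),
               sites = 1:8, refBases = rep("A", 8), freq = f)
    d <- chordDistance(afm)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
    for (i in 1:5) for (j in 1:5) for (k in 1:5)
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("neighbor joining is exact on additive distances and scale-equivariant", {
  # n = 3: closed-form branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighborJoining(d3)
  bl <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(bl[["a"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["b"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["c"]], (4 + 5 - 3) / 2)
  expect_error(neighborJoining(d3[1:2, 1:2]), "at least 3")
  dAsym <- d3; dAsym[1, 2] <- 9
  expect_error(neighborJoining(dAsym), "symmetric")

  # additive 5-taxon matrix from a known tree: exact recovery
  set.seed(8)
  for (rep in 1:5) {
    gen <- randomTopology(5)
    dAdd <- ape::cophenetic.phylo(gen)
    est <- neighborJoining(dAdd[gen$tip.label, gen$tip.label])
    expect_equal(splitDistance(est, gen), 0)
    expect_equal(ape::cophenetic.phylo(est)[rownames(dAdd), colnames(dAdd)],
                 dAdd, tolerance = 1e-10)
    # positive rescaling: same topology, branch lengths scaled
    est3 <- neighborJoining(3 * dAdd[gen$tip.label, gen$tip.label])
    expect_equal(splitDistance(est3, est), 0)
    expect_equal(sort(est3$edge.length), sort(3 * est$edge.length),
                 tolerance = 1e-10)
  }
})

test_that("site bootstrap saturates on clean splits and is seed-reproducible", {
  # every site splits the strains identically: all supports 1
  strains <- letters[1:6]
  S <- 12L
  f <- array(0, c(6, S, 4))
  f[1:3, , 1] <- 1          # clade abc reference
  f[4:6, , 2] <- 1          # clade def derived
  afm <- new("AlleleFrequencyMatrix", strains = strains,
             sites = seq_len(S), refBases = rep("A", S), freq = f)
  bs <- bootstrapSupport(afm, nReps = 50, seed = 3)
  expect_true(all(bs$node.label[!is.na(bs$node.label)] == 1.0))

  expect_error(bootstrapSupport(afm, nReps = 0), "nReps")

  # supports live in [0,1] and are bit-for-bit reproducible under a seed
  set.seed(99)
  f2 <- randFreqArray(6, 20)
  afm2 <- new("AlleleFrequencyMatrix", strains = strains, sites = 1:20,
              refBases = rep("A", 20), freq = f2)
  b1 <- bootstrapSupport(afm2, nReps = 30, seed = 7)
  b2 <- bootstrapSupport(afm2, nReps = 30, seed = 7)
  expect_identical(b1$node.label, b2$node.label)
  lab <- b1$node.label[!is.na(b1$node.label)]
  expect_true(all(lab >= 0 & lab <= 1))

  # single-site matrix: computed but flagged degenerate
  afm1 <- new("AlleleFrequencyMatrix", strains = strains, sites = 1L,
              refBases = "A", freq = f[, 1, , drop = FALSE])
  expect_warning(bootstrapSupport(afm1, nReps = 5, seed = 1), "degenerate")
})

test_that("a strong central split gets near-unit bootstrap support", {
  # two 4-strain clades separated by 50 fixed differences plus strain noise
  strains <- letters[1:8]
  S <- 70L
  f <- array(0, c(8, S, 4))
  f[, , 1] <- 1
  for (s in 1:50) { f[5:8, s, 1] <- 0; f[5:8, s, 2] <- 1 }
  set.seed(21)
  for (s in 51:70) {       # scatter strain-specific variants
    i <- sample(8, 1); f[i, s, 1] <- 0.5; f[i, s, 3] <- 0.5
  }
  afm <- new("AlleleFrequencyMatrix", strains = strains, sites = seq_len(S),
             refBases = rep("A", S), freq = f)
  bs <- bootstrapSupport(afm, nReps = 200, seed = 5)
  splits <- rDNAphylo:::.treeSplits(bs)
  central <- paste(sort(c("e", "f", "g", "h")), collapse = "\r")
  expect_true(central %in% splits)
  # support of the edge whose bipartition is the central split
  n <- 8L
  po <- ape::reorder.phylo(bs, "postorder")
  sets <- vector("list", n + bs$Nnode)
  for (i in seq_len(n)) sets[[i]] <- bs$tip.label[i]
  supp <- NA_real_
  clade <- c("e", "f", "g", "h")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
    if (ch > n && (setequal(sets[[ch]], clade) ||
                   setequal(setdiff(bs$tip.label, sets[[ch]]), clade)))
      supp <- bs$node.label[ch - n]
  }
  expect_gte(supp, 0.95)
})

test_that("outgroup rooting preserves bipartitions and splits the pendant edge", {
  set.seed(14)
  tr <- randomTopology(6)
  rooted <- rootWithOutgroup(tr, "s3")
  expect_true(ape::is.rooted(rooted))
  expect_equal(splitDistance(rooted, tr), 0)   # split set unchanged
  expect_error(rootWithOutgroup(tr, "nope"), "not a leaf")

  # rooting a 4-taxon tree on each leaf gives the same unrooted topology
  q <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  q <- ape::unroot(q)
  for (tip in q$tip.label) {
    r <- rootWithOutgroup(q, tip)
    expect_equal(splitDistance(r, q), 0)
    # root children edges have equal length (midpoint insertion)
    rootKids <- which(r$edge[, 1] == length(r$tip.label) + 1L)
    expect_equal(r$edge.length[rootKids[1]], r$edge.length[rootKids[2]])
  }
})

test_that("noiseless high-signal pipeline recovers the generating topology", {
  hits <- vapply(1:10, function(s) {
    ds <- simulateDataset(recoveryConfig(s))
    splitDistance(recoverTree(ds), truthTree(ds)) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
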