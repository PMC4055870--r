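test_that("no mutation means empty occupancy states everywhere", {
  cfg <- simConfig(tree = balanced8(), mutationRate = 0, unitLength = 500L,
                   seed = 11)
  so <- simulateOccupancies(cfg)
  expect_true(all(vapply(so$states, function(s) nrow(variantTable(s)) == 0L,
                         logical(1))))
})

test_that("simulator rejects malformed trees and accepts zero-length branches", {
  cfg <- simConfig(tree = "(a:1,b:1,c:1,d:1);", unitLength = 100L)
  expect_error(simulateOccupancies(cfg), "binary")
  cfg <- simConfig(tree = "((a:1,a:1):1,b:1);", unitLength = 100L)
  expect_error(simulateOccupancies(cfg), "unique")
  # zero-length branch: legal, child state identical to parent's
  cfg <- simConfig(tree = "(x:0.5,y:0);", unitLength = 200L,
                   mutationRate = 0.2, homogenizationSteps = 50, seed = 4)
  so <- simulateOccupancies(cfg)
  expect_identical(nrow(variantTable(so$states$y)), 0L)
})

test_that("without homogenization new variants sit at exactly 1/R", {
  # single informative branch: 2-leaf tree, one branch of length 1
  L <- 1000L
  cfg <- simConfig(tree = "(x:1,y:0);", arraySize = 100L, unitLength = L,
                   mutationRate = 50 / L, homogenizationSteps = 0, seed = 1)
  counts <- vapply(1:200, function(s) {
    cfg@seed <- s
    v <- variantTable(simulateOccupancies(cfg)$states$x)
    expect_true(all(v$occupancy == 1 / 100))
    nrow(v)
  }, numeric(1))
  # Poisson(50) mean over 200 seeds
  expect_lt(abs(mean(counts) - 50), 3)
})

test_that("Moran fixation probability equals the initial occupancy", {
  set.seed(42)
  k <- moranUpdate(rep(1L, 2000), 2L, Inf)
  expect_true(all(k %in% c(0L, 2L)))
  expect_lt(abs(mean(k == 2L) - 0.5), 0.03)
  k10 <- moranUpdate(rep(3L, 2000), 10L, Inf)
  expect_lt(abs(mean(k10 == 10L) - 0.3), 0.03)
})

test_that("hybridization mixes parental arrays with exact expected occupancies", {
  R <- 100L; L <- 60L
  pa <- mkState("A", R, L, pos = 1:20, k = R)          # 20 fixed in A only
  pb <- mkState("B", R, L, pos = 21:40, k = R, base = "G")
  h <- applyHybridization(pa, pb, 0.3, strain = "H")
  v <- variantTable(h)
  expect_identical(nrow(v), 40L)
  expect_equal(mean(v$occupancy[v$pos <= 20]), 0.3)
  expect_equal(mean(v$occupancy[v$pos > 20]), 0.7)
  expect_true(all(v$occupancy > 0.10 & v$occupancy < 0.90))  # all mid pSNPs

  # degenerate mixtures
  h1 <- applyHybridization(pa, pb, 1, strain = "H1")
  expect_equal(variantTable(h1)[c("pos", "base", "k")],
               variantTable(pa)[c("pos", "base", "k")])
  h5 <- applyHybridization(pa, pb, 0.5, strain = "H5")
  expect_true(all(variantTable(h5)$occupancy == 0.5))

  # mismatched references refuse to mix
  pc <- mkState("C", R, 61L, pos = 1, k = 1)
  expect_error(applyHybridization(pa, pc, 0.5), "unit length")
})

test_that("read sampling matches its binomial error model", {
  st0 <- mkState("s", 10L, 50L, pos = integer(0), k = integer(0))

  # depth 0: all counts zero
  bc <- sampleBaseCounts(st0, strrep("A", 50), depth = 0, seed = 1)
  expect_true(all(countMatrix(bc) == 0L))

  # error-free fixed site: every read carries the derived base
  st1 <- mkState("s", 10L, 5L, pos = 3, k = 10)
  bc <- sampleBaseCounts(st1, strrep("A", 5), depth = 50, errorRate = 0,
                         seed = 2)
  m <- countMatrix(bc)
  expect_identical(sum(m[3, c("A", "G", "T")]), 0L)
  expect_gt(m[3, "C"], 0L)

  # occupancy 0.3, eps 0.01, depth 100: derived fraction 0.3*0.99 + 0.7*0.01/3
  st3 <- mkState("s", 10L, 1L, pos = 1, k = 3)
  set.seed(3)
  tot <- 0; der <- 0
  for (r in 1:500) {
    m <- countMatrix(sampleBaseCounts(st3, "A", depth = 100,
                                      errorRate = 0.01))
    tot <- tot + sum(m); der <- der + m[1, "C"]
  }
  expect_lt(abs(der / tot - (0.3 * 0.99 + 0.7 * 0.01 / 3)), 0.01)
})

test_that("base counts at a multi-allelic site are conserved and well mixed", {
  st <- occupancyState("s", 10L, 3L,
    data.frame(pos = c(2L, 2L), base = c("C", "G"), k = c(4L, 3L)))
  bc <- sampleBaseCounts(st, "AAA", depth = 200, errorRate = 0.01, seed = 9)
  m <- countMatrix(bc)
  expect_true(all(rowSums(m) >= 0))
  expect_gt(m[2, "C"], 0); expect_gt(m[2, "G"], 0)
  # ref mass at site 2 is 1 - 0.7
  expect_lt(abs(m[2, "A"] / sum(m[2, ]) - 0.3), 0.15)
})

test_that("simulateDataset is deterministic, flags hybrids, and jitters copy number", {
  cfg <- simConfig(nStrains = 4, unitLength = 300L, seed = 9)
  expect_identical(simulateDataset(cfg), simulateDataset(cfg))

  ds <- simulateDataset(cfg)
  expect_true(all(!hybridFlags(ds)))
  cn <- truthCopyNumbers(ds)
  expect_true(all(cn >= 80L & cn <= 120L))  # +-20% of 100

  cfgH <- simConfig(tree = "((a:0.2,b:0.2):0.2,(c:0.2,d:0.2):0.2);",
                    unitLength = 300L, seed = 2,
                    hybridizations = list(
                      list(child = "b", parentA = "a", parentB = "c",
                           lambda = 0.5)))
  dsH <- simulateDataset(cfgH)
  expect_identical(hybridFlags(dsH)[["b"]], TRUE)
  expect_identical(sum(hybridFlags(dsH)), 1L)

  cfgBad <- simConfig(tree = "((a:1,b:1):1,(c:1,d:1):1);", unitLength = 100L,
                      hybridizations = list(
                        list(child = "z", parentA = "a", parentB = "b",
                             lambda = 0.5)))
  expect_error(simulateDataset(cfgBad), "unknown strain")
})

test_that("occupancies stay in [1/R, 1] on a grid of m/R without drift", {
  for (s in 1:5) {
    cfg <- simConfig(tree = balanced8(), arraySize = 25L, unitLength = 400L,
                     mutationRate = 0.3, homogenizationSteps = 0, seed = s)
    so <- simulateOccupancies(cfg)
    for (st in so$states) {
      v <- variantTable(st)
      if (!nrow(v)) next
      expect_true(all(v$occupancy >= 1 / 25 & v$occupancy <= 1))
      expect_true(all(v$k == round(v$occupancy * 25)))
    }
  }
})
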