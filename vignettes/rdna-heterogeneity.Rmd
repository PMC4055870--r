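---
title: "Methods: intraspecies phylogenetics from rDNA heterogeneity"
author: "rDNAphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intraspecies phylogenetics from rDNA heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rDNAphylo)
```

## The problem

Ribosomal RNA genes sit in tandem arrays of near-identical units — in
*Saccharomyces cerevisiae*, roughly 150 copies of a 9137-bp unit at a single
locus. Concerted evolution (gene conversion and unequal sister-chromatid
exchange) homogenizes the array: a new variant in one unit is, over time,
either amplified to every unit or removed. A variant caught in transit is a
**partial SNP (pSNP)**: it is carried by a fraction of the units — its
**occupancy** — and shows up at intermediate frequency in whole-genome
shotgun reads mapped to the rDNA reference unit. Classically this
within-genome heterogeneity is a nuisance for rDNA-based phylogenetics.
The approach implemented here turns it into signal: each strain's SNPs and
pSNPs are coded as per-site allele-frequency vectors, and strain trees are
estimated from genetic distances between those frequency profiles.

## The pipeline

1. **Variant calling** (`callStrain`). Input is a per-strain, per-site table
   of strand-collapsed base counts against the reference unit. A
   non-reference base is admitted as a derived allele when (i) it has at
   least `minAlleleReads` supporting reads (default 2) and (ii) a one-sided
   binomial test rejects the sequencing-error model
   count ~ Binomial(depth, ε/3) at level α/L (Bonferroni over the L sites
   scanned; α = 0.05, ε = 0.01 by default — with L ≈ 9137 sites an
   uncorrected test would admit hundreds of error sites). Sites below
   `minDepth` (default 10 reads) are no-calls flagged distinctly from "no
   variant". A call's occupancy is the derived read fraction; summed derived
   occupancy at or above `snpThreshold` (default 0.95) makes the call a
   fully resolved SNP, otherwise a pSNP. The boundary between "fully
   resolved" and partial is not sharply defined by read data, so 0.95 is a
   configurable decision, not a reproduction of any published cutoff.

2. **Frequency coding** (`buildFrequencyMatrix`). The site set is the union
   of called positions over all strains. Each strain × site cell is a
   4-vector over (A, C, G, T): occupancy mass on each derived base, the
   remainder on the reference base; strains with no call at an included site
   are a point mass on the reference base. Coding missing coverage as
   reference is a decision — per-site missingness is not representable in a
   frequency matrix — and it biases uncovered sites towards the reference;
   with the default `minDepth` this only affects very low-coverage strains.

3. **Distances** (`chordDistance`). The Cavalli-Sforza–Edwards chord
   distance treats each site as a 4-allele locus:
   D(x,y) = sqrt( (1/L) Σ_s (1 − Σ_b √(f_xsb f_ysb)) ).
   The classical constant prefactor (2√2/π) is omitted: it rescales all
   distances uniformly and cannot change any distance-based topology.
   Byte-compatibility with legacy genetic-distance programs is therefore
   not promised, topology-level agreement is.

4. **Tree estimation** (`neighborJoining`, `bootstrapSupport`,
   `rootWithOutgroup`). Standard Q-criterion neighbor joining (via ape);
   negative estimated branch lengths are clamped to zero with the deficit
   reported. Supports come from resampling *sites* (frequency-matrix
   columns) with replacement — the allele-frequency analog of sequence
   bootstrap — re-running chord + NJ per replicate, and scoring each
   internal edge of the original tree by the fraction of replicates whose
   tree contains the same bipartition. Rooting inserts the root at the
   midpoint of the outgroup's pendant edge.

5. **Tree and matrix comparison** (`splitDistance`,
   `randomSplitDistanceNull`, `mantelTest`). The split distance is the
   fraction of non-trivial bipartitions not shared by the two topologies
   (0 identical, 1 disjoint). Its null is calibrated against uniform random
   labeled topologies on the same leaf set; the reference-vs-random scheme
   is the default, with a random-vs-random alternative, because the
   published description is ambiguous between the two. For a ~27-leaf tree
   the random null sits near 0.99 — almost no splits are shared by chance.
   The Mantel test correlates the lower triangles of two distance matrices
   and permutes rows/columns of one; it is two-sided on |r| (conservative),
   with p-floor 1/(nPerm+1), i.e. 0.001 at the default 999 permutations.

6. **Copy number** (`coverageProfile`, `estimateCopyNumber`). Mean per-base
   depth in 20-bp windows along the unit (final partial window averaged
   over its own width), then mean window coverage divided by genome-wide
   fold coverage G. Per-base depth averaged per window is used instead of
   per-window read counts; the two differ by the constant read length,
   which cancels in the fold-coverage ratio. The standard error
   sd(windows)/(√n·G) treats G as an exact constant.

7. **Genome-type classification** (`classifyGenomeType`). pSNP occupancies
   band into low (≤ 0.10), mid, and high (≥ 0.90); the boundaries go
   outward because the mid band is defined strictly. Mid-occupancy pSNPs
   are the mosaicism indicator: a strain is `structured_clean` when it has
   at most `cleanMaxMid` (1) mid pSNPs or a mid fraction below 0.25;
   `mosaic` when it has at least `mosaicMinPsnp` (15) pSNPs with mid
   fraction ≥ 0.25; `structured_mosaic` otherwise, flagged borderline when
   the mid fraction is below 0.5. The published three-way labels are
   qualitative; this quantitative rule is a package decision engineered to
   reproduce the worked examples (2 mid of 16 pSNPs → structured clean;
   strains whose few pSNPs are mostly mid-occupancy → structured mosaic;
   pSNP-rich strains with substantial mid fractions → mosaic) and every
   threshold is an argument.

## The simulator

`simulateDataset` generates data with the statistical structure the
analysis assumes, plus full truth, so every estimator can be tested for
recovery.

- **Occupancy dynamics.** Concerted evolution is modeled per site as a
  neutral Moran process on the variant's unit count k out of R: each update
  moves k by ±1, each with probability k(R−k)/R², absorbing at 0 (loss) and
  R (fixation — the variant becomes an inherited substitution). This
  abstraction, rather than explicit gene-conversion tracts over unit
  sequences, reproduces the qualitative occupancy dynamics (drift of
  variants towards 0 or 1) with closed-form checkable properties — the
  fixation probability from count k is exactly k/R. Along a branch of
  length b, new variants arise at Poisson(mutationRate · L · b) previously
  untouched sites with initial count 1, then all segregating variants take
  round(h·b) Moran updates. Each site mutates at most once per lineage
  (derived base uniform over the three non-ancestral bases), so tri-allelic
  sites do not arise within a lineage, though the matrix format supports
  them.
- **Hybridization.** A hybrid array takes round(λR) units from parent A and
  the rest from parent B; with deterministic rounding (default) a site
  fixed in A and absent in B yields occupancy exactly ≈ λ, which makes
  expected values exact in tests. A stochastic (hypergeometric) mode is
  available.
- **Read sampling.** Per site, total reads ~ Poisson(depth); each read
  draws a unit from the array's base mix and is miscalled with probability
  ε, uniformly over the other three bases — for a single derived allele at
  occupancy q the derived count is Binomial(total, q(1−ε) + (1−q)ε/3).
- **Copy number and depth.** Array size R is constant during evolution;
  per-strain copy-number variation enters as a final uniform ±20% integer
  jitter, since the estimator, not array-length dynamics, is under test.
  Each strain's rDNA depth is genomeCoverage × its true copy number, which
  makes the coverage-ratio estimator's input self-consistent.
- **Determinism.** One RNG stream, seeded once from `seed`, consumed in a
  documented fixed order; identical configs give identical datasets.

Defaults describe a yeast-like single-locus system: 9137-bp unit, R = 100
units (published per-strain estimates span ~45–354 with means 69 and 99),
3× genome coverage (low-coverage shotgun, hence ~300× over the rDNA),
ε = 0.01, random trees with exponential(mean 0.1) branch lengths, mutation
rate 0.005 per site per branch-length unit and h = 200 Moran updates per
branch-length unit. Homogenization rates in *Saccharomyces* are not
quantified in the literature this package draws on; the default h is chosen
so that simulated strains carry a realistic mix of low-occupancy pSNPs and
occasional fixed variants at these branch lengths, and tests that depend on
the homogenization regime set h explicitly.

**What the simulator does not emulate:** unequal sister-chromatid exchange
with explicit array-length dynamics, selection, rDNA pseudogenes, indels,
mapping and alignment artifacts, GC-dependent coverage bias, or
contamination. Passing recovery tests on simulated data therefore shows the
estimators are correct under the stated model, not that real pileups are
free of upstream artifacts.

## Numerical and design choices

- NJ ties in the Q-criterion are resolved by ape's deterministic scan
  order; negative branch lengths are clamped to 0 (common convention) and
  logged via `message()`.
- Chord terms 1 − Σ√(f_x f_y) can go infinitesimally negative in floating
  point for identical vectors; they are clamped at 0 before the square
  root.
- Bootstrap replicates reuse the raw frequency array (duplicate site
  columns are expected and legal there); supports are matched to edges by
  canonical bipartition keys, replacing any external mapping tool.
- `splitDistance` demands identical leaf sets and names the symmetric
  difference on error; `pruneToCommonLeaves` is the explicit, separate
  pruning step.
- The Mantel permutation count and the bootstrap replicate count trade
  runtime for resolution; the defaults (999, 1000) match common practice.
- Degenerate inputs: zero-length branches are legal no-ops; a single-site
  matrix yields a degenerate-bootstrap warning; a single-window coverage
  profile has `NA` standard error; depth-0 sampling returns all-zero
  counts.

## Test and validation scale

The shipped tests validate each stage against independent oracles: Moran
fixation against the analytic k/R (2000 replicates), chord distance against
brute-force formula evaluation (tolerance 1e−12), NJ against generating
trees of additive matrices (4–8 taxa), split distance against exhaustive
bipartition enumeration (all 5-leaf topology pairs; sampled 6–7-leaf
pairs, cross-checked against normalized Robinson–Foulds), the Mantel test
against its nominal type-I error (500 null pairs at 199 permutations), and
the full pipeline end-to-end on noiseless high-signal simulations (8-strain
balanced tree, 20-unit arrays, 1500-bp units, ~105 expected variants per
branch, 50 seeds) where the truth topology is recovered with split distance
0\. These problem sizes were chosen so the whole suite completes in well
under a minute while keeping every stochastic check's sampling error an
order of magnitude below its tolerance.

## Known limitations

- The variant caller assumes a single global error rate and strand-collapsed
  counts; it does not model mapping quality, strand bias, or contamination.
- The frequency coding cannot represent missing data; uncovered sites are
  reference-coded.
- The genome-type thresholds are calibrated to the published worked
  examples, not learned from data; for other species they should be
  revisited.
- The published split distances for real yeast strain sets (0.52 and 0.65
  against genome-wide SNP trees) require the original read-level datasets
  and genome-wide distance matrices, which are not shipped; the package
  validates the statistic itself (oracle agreement, random null ≈ 0.99)
  rather than those two observed values.
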