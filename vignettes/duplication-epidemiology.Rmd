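---
title: "Genomic epidemiology of EPSPS duplication genotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic epidemiology of EPSPS duplication genotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Glyphosate resistance in kochia (*Bassia scoparia*) is caused by tandem
duplication of the *EPSPS* gene, the target of the herbicide.  The
duplicated locus has a characteristic architecture: repeat units of two
lengths (a long "type I" and a short "type II" segment) interleaved with a
Fhy3/FAR1-like mobile genetic element (MGE).  Because qPCR markers for the
type I and type II junctions only amplify when the MGE sits next to the
respective repeat, a four-marker panel — *EPSPS*, type I, type II, MGE,
each normalized against the single-copy *ALS* gene — fingerprints the
duplication structure of an individual plant.  Individuals can then be
sorted into duplication genotypes whose geography traces where resistance
arose and how it spread; a complementary SSR panel measures neutral
population structure.

`dupepi` reimplements this analysis as a reusable pipeline and pairs it
with a synthetic-data generator, so that every stage is testable without
access to the original data deposit.

# Copy-number quantification (delta-Ct)

Relative copy number per haploid genome is `2^(Ct_ALS - Ct_target)`,
assuming perfect doubling per cycle (efficiency fixed at 2.0; no
standard-curve correction).  Choices that matter:

* **Replicates are averaged on the Ct scale**, not the linear scale,
  before transformation — the convention of the delta-Ct method.
* **No amplification maps to exactly 0 copies**, not missing.  The
  genotype cascade tests "type I and type II > 0", which requires a
  definite zero.  Replicates that failed to amplify are dropped from the
  Ct mean; a marker is 0 only if nothing amplified.
* **Delta-delta-Ct is optional.**  If calibrator individuals with known
  copy numbers are supplied, marker columns are rescaled by
  `known / estimated`; with a single-copy calibrator whose target Ct
  equals its ALS Ct this is a no-op.  Raw delta-Ct is the default because
  the source protocol does not state that a calibrator rescaling was
  applied.

# Duplication-genotype classification

The cascade over a profile `(EPSPS, type I, type II, MGE)`:

1. `EPSPS <= 1.4` -> **S** (wild-type single copy; 1.4 is the published
   threshold for "increased" *EPSPS*, strict inequality);
2. else both repeat junctions `> 0` -> **A**;
3. else `MGE >= 10` -> **B** (10 separates the susceptible 4–6 copy
   background from "increased" MGE);
4. else -> **C**.

Two orderings are deliberate.  S is decided first, so a single-copy
individual with elevated MGE is S (such individuals occur; the MGE can
vary independently of the *EPSPS* locus) and is flagged
`high_MGE_susceptible`.  Repeat-junction presence is decided before the
MGE rule: surveyed all-A populations exist whose MGE mean falls below 10,
and the junction markers are the direct structural evidence; such calls
carry `atypical_low_MGE_A`.  Profiles where exactly one junction amplified
contradict the expectation that both amplify together; they are not
silently called A but fall through to the MGE rule with a
`discordant_repeat_markers` flag.

Thresholds live in `dup_thresholds()`, not in code; defaults are the
published values.

One printed worked-example row ("Wild", Montana) is internally
inconsistent: it reports all individuals as genotype C (each requiring
MGE < 10) alongside a population mean MGE of 16.4, which no set of
C-individuals can produce.  The classifier reproduces every other
pure-proportion row's modal genotype from its printed means; this row is
excluded from that check and asserted inconsistent instead.

# Synthetic data: the stated world

The generator emulates the surveyed design rather than fitting it:

* **qPCR side.**  Class-conditional true copy numbers are calibrated to
  the printed population means: A draws `EPSPS ~ U(4, 12)` with type I
  above type II (`x U(0.9, 1.3)` and `x U(0.3, 0.5)`) and
  `MGE = 2 EPSPS + U(4, 6)`; B draws `EPSPS ~ U(4, 30)` with
  `MGE = 1.5 EPSPS + U(4, 6)` (MGE tracks *EPSPS*, as observed); C draws
  `EPSPS ~ U(2, 8)` with background MGE `U(4, 6)`; S has exactly one
  *EPSPS* copy, no junctions, background MGE.  Only population-level
  means/SEs are published, so these are ranges consistent with those
  means, not fitted distributions.  Ct values invert the delta-Ct
  transform: each replicate draws `Ct_ALS ~ N(22, 0.5)` and markers sit at
  `Ct_ALS - log2(copies)` plus `N(0, 0.15)` technical noise.  The noise
  default keeps classification near-perfect so tests can dial noise up
  deliberately.
* **SSR side.**  A Balding–Nichols island model: per locus, 4–8
  consecutive pentanucleotide repeat-count alleles with flat-Dirichlet
  ancestral frequencies; population frequencies
  `Dirichlet(theta p_anc)`, `theta = (1 - F_ST)/F_ST`; genotypes drawn
  autozygous with probability `F_IS`; cells missing i.i.d.; fragment
  size = integer locus offset + 5 x repeat count + `N(0, 0.3)` bp sizing
  noise.  Defaults (`F_ST = 0.05`, `F_IS = 0.2`, 3% missing, 44
  populations of 9–18 individuals, 10 loci) reflect the weak structure,
  moderate heterozygote deficit and low missingness the survey reports.
  Frequency-level structure is all the downstream stack consumes, which is
  why a coalescent simulator would add nothing here.

What the generator does *not* emulate: linkage between loci (the survey
found none), temporal drift or selection, pollen-versus-seed dispersal
mechanics, stutter or null alleles in fragment data.  A green test
therefore establishes correctness of the statistics on
frequency-structured data, not robustness to electropherogram artefacts.

# Allele binning

Binning fits, per locus, a ladder `offset + k x motif` by grid search over
offsets in `[0, motif)` (0.1 bp grid) minimizing squared residuals, then
assigns each size to its nearest rung; residuals beyond 1.0 bp are
off-ladder and become missing.  Rungs are at exact motif spacing — a
simplification of the flexibin algorithm, which relaxes per-bin widths to
accommodate imperfect repeats; for pentanucleotide loci with 5 bp between
adjacent alleles the fixed ladder is sufficient and easier to reason
about.  Single-peak cells default to homozygotes (the common
fragment-analysis convention, configurable to missing); how the original
analysis handled them is not stated.

# Diversity statistics and exact tests

* Expected heterozygosity is the unbiased estimator
  `(2n/(2n-1)) (1 - sum p^2)` per locus; observed heterozygosity is the
  typed-cell fraction; both are averaged across loci.
* Multilocus `F_IS = 1 - mean(H_O)/mean(H_E)` (ratio of means, not mean of
  ratios); its confidence interval is a percentile bootstrap over
  individuals within the population (1000 replicates).  The divBasic-style
  internals of the original are unstated; this choice is documented and
  cross-checkable through the GENEPOP export.
* Allelic richness is rarefied:
  `E[A(g)] = sum_a [1 - C(N - N_a, g)/C(N, g)]`, with `g` set per locus to
  the minimum typed-copy count across populations so populations are
  comparable.
* The Hardy–Weinberg exact test is seeded Monte Carlo: the statistic is
  the Levene conditional probability of the genotype array given allele
  counts; the null re-pairs the observed alleles; the p-value carries the
  `(hits + 1)/(n_perm + 1)` correction.  The linkage test builds, per
  population, the two-locus table of single-locus genotypes, scores it by
  the G statistic, permutes one locus among individuals, and combines
  populations by Fisher's method (`X^2 = -2 sum log p`, df `2k`).  No
  multiple-testing correction is applied, matching the original reporting.
  Filtering removes loci with more than 10% missing data first, then
  individuals with more than 20% on the reduced matrix — the order the
  survey describes — with strict inequalities at both thresholds.

# Trees and ordination

Prevosti distance between populations is half the mean absolute
allele-frequency difference across the loci typed in both populations
(per-locus renormalization over typed copies; how the original treated
missing data is unstated).  Neighbour-joining is the standard Saitou–Nei
agglomeration; ties in the Q-criterion break deterministically toward the
lowest node-index pair, and negative branch lengths are clamped to zero
without length transfer — the simplest defensible convention.  Bootstrap
supports resample loci with replacement (1000 replicates by default) and
attach bipartition percentages to internal nodes; supports below any
display threshold are still serialized, because filtering is a rendering
concern.  The triangle inequality is not asserted for Prevosti distance.
PCA uses the individuals x alleles 0/1/2 count matrix, column-mean
imputation for missing cells, centering without unit-variance scaling
(the dominant allele-count convention).

# Bayesian clustering and Evanno's delta-K

The sampler is a desk-scale stand-in for the structure program: Gibbs
updates of allele-origin indicators, cluster allele frequencies
(`Dirichlet(lambda = 1)`) and admixture proportions
(`Dirichlet(alpha, ..., alpha)`), with missing alleles skipped.  Two
design points deserve explanation:

* **The likelihood trace is the complete-data log-likelihood**
  `log P(X | Z, P)` at the sampled assignments, and the run summary is
  `L_estimate = mean - var/2` over post-burn-in sweeps.  This is the
  "estimated ln probability of data" that structure reports and on which
  the Evanno method is defined; the observed-data mixture trace is also
  returned for diagnostics.
* **`alpha` is inferred by a Metropolis step** (uniform prior on
  `(0, 10]`, normal proposal, sd 0.05), as in structure, rather than held
  fixed.  With `alpha` fixed at 1 the sampler settles in a washed-out
  admixture mode on weakly structured data and cluster assignments never
  harden; with a small fixed `alpha` chains can irrecoverably empty a
  cluster.  Inference starts at 1.0 and adapts; `infer_alpha = FALSE`
  restores the fixed-`alpha` variant.

The LOCPRIOR model of structure is intentionally out of scope; runs are
aligned clumpp-style by exhaustive label-permutation search maximizing
`G' = 1 - ||Q_a - Q_b P||_F / sqrt(2n)` for `K <= 8` (greedy column
matching beyond), and `evanno()` computes
`delta_K = |L''(K)| / sd_L(K)` over a contiguous K range.

A known limitation, measured rather than hidden: on 3-equidistant-cluster
data of the scale used in the acceptance suite (60 individuals, 10 loci,
`F_ST 0.15`), the likelihood gain from K = 1 to 2 is structurally several
times the gain from 2 to 3, so `delta_K` frequently peaks at K = 2 even
though the sampler itself separates the three clusters cleanly at K = 3
and k-means on the leading principal components recovers them.  This
reflects the well-documented K = 2 bias of the delta-K statistic at
modest data scale; the corresponding acceptance test states the intended
recovery property and is allowed to fail rather than being weakened.

# Numerical conventions

* All Monte Carlo procedures take explicit seeds and are bit-reproducible.
* Degenerate inputs are defined, not crashed on: monomorphic loci give
  HWE p = 1 with a degeneracy flag; all-monomorphic populations report
  `F_IS` as missing; single-locus bootstrap trees warn that supports are
  trivial; zero p-values are clamped to the smallest positive double in
  Fisher's combination with a warning; `sd_L = 0` yields an infinite
  `delta_K` with a warning.
* GENEPOP export uses 3-digit alleles and `000000` for missing; STRUCTURE
  export uses two rows per individual and `-9` — the dominant community
  dialects.  Delimited-file dialect detection is limited to comma/tab;
  anything else must be declared.
* CLI configuration files are JSON rather than TOML, since no TOML parser
  is available in the supported dependency set.
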