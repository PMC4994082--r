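---
title: "Genotyping microsatellites from amplicon reads: methods and design choices"
author: "ampliSTR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping microsatellites from amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: what each stage
computes, which parameters matter and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the method's published description leaves the
details open.

## 1. The genotyping model

A microsatellite (STR) locus is described by a `LocusSpec`: primers, two
constant flanking sequences, a 2–6 bp repeat motif and a plausible
repeat-count range. An amplicon insert is `leftFlank + motif^k + rightFlank`,
and a sequenced read prepends inline site and colony tags plus the forward
primer and appends the reverse primer. Individuals are diploid, so the
calling problem is: given the collapsed unique sequences and their read
depths for one colony at one locus, return an ordered allele pair.

**Half-maximum rule.** The top-depth sequence is allele 1. Every sequence
with depth *strictly greater* than half the top depth is a candidate
("greater than half" is taken literally as `d > max/2`; sequences tied for
the top trivially qualify). One candidate means a homozygote. More than two
candidates are resolved either by taking the next-highest depth (`depth`
strategy; ties among the second-highest broken uniformly at random) or by a
uniform draw over all non-top candidates (`random` strategy). The top allele
is excluded from the random pool because it is always allele 1. The random
strategy is re-drawn ten times into replicate datasets `random000` …
`random009`; `random000` is the canonical analysis dataset. These choices
mirror the workflow the pipeline re-implements; both strategies are kept so
their effect on downstream inference can be measured (`compareDatasets()`
builds the full strategy × prevalence × encoding table).

**Filters** (defaults, all exposed in `RunConfig`):

| stage | parameter | default | rationale |
|---|---|---|---|
| trim | primer mismatches | 2 | tags are too short to absorb mismatches (exact match); primers tolerate 2 substitutions, no indels |
| trim | window, min mean Q | 4, 15 | sliding-window mean-quality truncation; bases at the head of the failing window that individually pass are kept |
| length | min, max | 15, 190 bp | inserts shorter than 15 bp or longer than 190 bp are artifacts |
| length | per-locus cap | known max + 4 repeats | four extra repeat units beyond the longest known sequence |
| depth | pooled min depth | 10 reads | pooling is per locus across the *entire dataset* |
| prevalence | min colonies | 2 | sequences seen in a single colony are unverifiable; 11 reproduces the "min10" variants (alleles in more than 10 colonies) |
| missing | locus, individual | 15%, 35% | loci filtered first, individuals second over retained loci |

Rejected sequences are always written to an audit file; the manual
by-eye inspection step of the original workflow becomes a documented
artifact. Filter order is length → depth → prevalence, and the composition
is monotone (tested).

**Repeat/flank splitting.** `splitTandemRepeat()` re-implements an
etandem-style scorer: candidate runs are found by period-*m* self-match
(*m* = 2…6), scored +1 per base agreeing with the periodic consensus and −1
per mismatch, and adjacent runs are merged across an interruption when the
gap is at most *m*, the phase agrees, and the merged consensus scores higher
— exactly the signature of a substitution inside a repeat. Regions hold an
integral number of motif copies. Tie-breaks: score, then longer region, then
leftmost, then smallest period (a pure dinucleotide run also matches periods
4 and 6 with equal score; the smallest period is the canonical motif). When
a flank happens to end (left) or start (right) with a full copy of the
motif, the repeat/flank boundary is mathematically unidentifiable; the
default locus panel is constructed junction-clean, and because flanks are
constant within a locus any residual boundary shift is uniform across
alleles, so length encoding is unaffected.

**Encodings.** `length` labels an allele by the length of its repeat region
(the fragment-analysis equivalent: same-length alleles merge regardless of
sequence); `unique_id` labels every distinct full sequence. The number of
distinct alleles per locus under `unique_id` is never smaller than under
`length` (pigeonhole; tested), which is the mechanism by which sequence
identity exposes homoplasy.

## 2. Population-genetic estimators

Diversity uses the Nei–Chesser small-sample estimators with ñ the harmonic
mean of per-population sample sizes:

* H_S = (ñ/(ñ−1)) [1 − mean_p Σ_k p²_{kp} − H_O/(2ñ)]
* H_T = 1 − Σ_k p̄²_k + H_S/(ñ·r), with p̄ the unweighted mean frequency
  over the r populations
* H'_T = H_S + (H_T − H_S)·r/(r−1), G_ST = (H_T − H_S)/H_T,
  G'_ST (Hedrick) = G_ST (r−1+H_S) / ((r−1)(1−H_S)),
  D (Jost) = (r/(r−1)) (H_T − H_S)/(1−H_S), N_E = 1/Σ p̄²_k

Multilocus values are unweighted locus averages; monomorphic loci are
flagged and excluded from the ratio statistics. The H_T estimator carries an
O(1/ñ) correction term, so on small constructed samples with exactly equal
population frequencies G_ST is positive at order 1/ñ — the tests use sample
sizes where this remainder is negligible rather than pretending the
estimator is exactly zero.

F-statistics are Weir–Cockerham (1984) multiallelic variance components
(a: among populations, b: among individuals within populations, c: within
individuals), summed over alleles and loci: F_ST = Σa/Σ(a+b+c), F_IS =
Σb/Σ(b+c). They stand in for the AMOVA of the genodive program — both are
method-of-moments decompositions; exact numerical parity with genodive is
not claimed. The unit-test oracle computes the same components through a
nested random-effects ANOVA on allele indicators (mean squares → variance
components), an algebraically equivalent but independently coded route.

**Standardized F'_ST** follows Meirmans: every allele label is recoded to be
population-private while keeping each population's internal genotype
structure, the AMOVA is recomputed, and F'_ST = F_ST/F_ST(max). Its p-value
is inherited from the F_ST permutation test (individuals permuted among
populations, p = (#{perm ≥ obs}+1)/(B+1)); F_IS is tested by permuting
allele copies among individuals within populations.

**Exact tests** are Monte-Carlo conditional-probability tests: per locus the
populations × alleles count table is compared with tables sampled from the
null by Patefield's algorithm (`r2dtable`, margins fixed), p = the
probability of a table at most as probable as the observed one, with the
(k+1)/(B+1) correction so Fisher's combination across loci (χ² with 2L d.f.)
never takes log(0). This replaces the genepop Markov chain; the `steps`
parameter maps to the Monte-Carlo sample count.

**Allelic richness** is rarefied to g = 2 × 24 gene copies by the
combinatorial estimator AR = Σ_i [1 − C(N−N_i, g)/C(N, g)], computed with
log-binomials; populations with N < g are flagged, never extrapolated.

## 3. Bottleneck tests

Following the heterozygosity-excess logic: a recent bottleneck loses rare
alleles faster than heterozygosity, so the observed expected heterozygosity
exceeds the equilibrium expectation *given the observed allele count*. Per
locus, `simulateHeq()` simulates equilibrium samples of the same gene count
under the chosen mutation model, keeps those with exactly the observed
number of alleles, and returns their heterozygosities; θ is first calibrated
by bisection so the mean simulated allele count matches the observed one
(for the infinite-allele model the Ewens closed form E[K] = Σ θ/(θ+i) makes
this calibration exact; when the requested allele count sits above the
attainable mean — all alleles distinct — the θ cap is used and the exact-k
retention filter still applies). The IAM is simulated by the Hoppe-urn
construction, which is the exact sampling law of the coalescent with
infinite-allele mutation; the two-phase model (70% ±1 steps, 30% multistep
with geometric sizes of variance 30 — the conventional parameterization, the
source workflow states only the 70/30 split) uses an explicit Kingman
coalescent with Poisson mutations on branches, implemented in C++. Both the
observed and the simulated heterozygosities use the unbiased estimator
(n/(n−1))(1−Σp̂²); mixing a corrected observed value with uncorrected
simulated ones would shift every standardized difference by a factor n/(n−1)
and mis-calibrate the test. Across loci, excess is tested by a one-tailed
Wilcoxon signed-rank test (exact for ≤ 50 loci; 11 all-positive loci give
p = 1/2¹¹ ≈ 0.000488); fewer than 4 polymorphic loci trigger a power
warning. The graphical mode-shift test bins all allele frequencies into ten
left-open classes (0, 0.1], …, (0.9, 1] — boundary values fall in the lower
class — and calls the spectrum L-shaped iff the lowest class strictly
dominates every other class.

A null-calibration study (200 constant-size equilibrium populations,
48 colonies, 11 loci, 1000 retained simulations per locus) keeps the
Wilcoxon rejection rate at α = 0.05 within [0.02, 0.09]; the test inherits
the mild anti-conservativeness known for the conditional-on-k construction.

## 4. Ordination

`pcaIndividuals()` codes each individual as 0/1/2 counts of every allele,
mean-imputes missing genotypes per column (the standard choice for
covariance PCA on genotype indicators; the handling in the original analysis
software is unpublished), column-centres, and eigendecomposes the covariance
(via SVD; tested against a direct `eigen(cov(x))` oracle at 1e-8).
`pcaPopulations()` does the same on the populations × allele-frequency
matrix. Axis significance shuffles each column independently and counts
permuted eigenvalues reaching the observed one — a documented choice, since
the reference program's permutation scheme is unpublished. Score signs are
fixed by making the largest-magnitude loading positive.

## 5. The synthetic-data generator

`SimConfig()`/`simulateTruth()`/`simulateReadSet()` emulate the study design
the package targets: 7 sites on 3 islands (three on Palau, three on Yap, one
atoll), up to 48 diploid colonies per site (the colony-tag capacity), 11
loci with mostly dinucleotide motifs, and island-model divergence realized
by Balding–Nichols Dirichlet draws, `Dirichlet(ancestral × (1−θ)/θ)`, whose
expected Weir–Cockerham θ equals the target. Genotypes are Hardy–Weinberg
within populations. Defaults, chosen once:

* **Ancestral frequencies** decay geometrically (ratio 0.8) over ~8 core
  alleles plus one flank-SNP variant per locus (same length, different
  sequence — the homoplasy the unique-ID encoding is meant to expose). The
  decay keeps every allele common enough that a prevalence ≥ 2 filter
  virtually never erases a true allele; real loci have rarer alleles, which
  is precisely why the real filter is lossy. In extreme Dirichlet draws an
  allele can still be confined to one colony dataset-wide and is then
  removed — a property of the filter, not a defect; at these defaults it
  affects at most a colony-locus pair or two per dataset.
* **Depth** is negative binomial (mean 50, size 8): skewed per colony-locus,
  P(depth ≤ 1) ≈ 1e−6. No per-amplicon depth statistics are published for
  the emulated study; these are conventions.
* **Allelic balance** Beta(150, 150) applied as a deterministic split of the
  total depth. The noise-free round trip (zero stutter and error recovering
  100% of genotypes through the *entire* pipeline) is a design requirement
  of the generator, and a heterozygote is miscalled whenever its balance
  leaves (1/3, 2/3) — the half-max boundary. Beta(150,150) puts that
  probability at ~3e−9 per call. Real amplicon libraries are more skewed;
  realism lives in the stutter and error knobs, not in the balance.
* **Stutter rate 0.35** (a read keeps its allele with probability 0.65, else
  shifts one repeat unit either way, floored at one repeat). The observed
  stutter:parent ratio is then (s/2)/(1−s) ≈ 0.27, the upper range for long
  dinucleotide repeats — deliberately generous, because under the half-max
  rule multi-candidate (>2 allele) colonies, the calling problem the
  pipeline exists to resolve, essentially only arise via stutter at this
  magnitude (chiefly when a heterozygote's alleles sit two repeat units
  apart and both stutter products coincide in the middle).
* **Point errors** 0.001/base; a tenth of reads carry a 10-base low-quality
  tail (shorter than any reverse primer, so the tail exercises quality
  trimming without eating the insert).

What the generator does **not** emulate: multi-step stutter, chimeras,
paired-end structure (reads are emitted merged), null alleles, contamination
and somatic variation. Its geometric-decay allele-frequency spectra are also
deliberately *more even* than a coalescent-equilibrium spectrum, which is
why the acceptance script's per-site heterozygosity-excess p-values on
simulated data are descriptive rather than a null calibration — observed
heterozygosity genuinely exceeds the IAM equilibrium expectation for the
observed allele counts there. The calibration of the bottleneck test itself
is established separately, on true equilibrium nulls, in the test suite.
Passing tests therefore show the pipeline's logic is correct and its
estimators calibrated on clean island-model data — not that any particular
real library will behave as well.

On these conditions, selecting the second allele by depth rather than at
random yields slightly higher F_ST (+0.004…0.006) and lower F_IS
(−0.012…−0.014) across seeds, because random selection promotes shared
stutter artifacts into within-population diversity; the standardized F'_ST
is left nearly unchanged (the shifts in F_ST and F_ST(max) cancel), so the
package's ordering assertion covers F_ST and F_IS only.

## 6. Determinism and problem sizes

One master seed drives everything; each stage derives a child seed
(`deriveSeed`), and simulation helpers restore the caller's RNG state, so
stages are independently re-runnable and a θ-calibration cache hit cannot
shift downstream streams. The test suite runs the full study design for the
round-trip and ordering checks, 20 genotype-level replicates for F'_ST
recovery, 200 null populations (1000 retained simulations per locus) for the
bottleneck calibration, and 10,000 urn draws for the Ewens check; the
acceptance script uses 499 permutations for the F-statistic tests, 199 for
PCA axes and 1000 bottleneck iterations per locus. Permutation defaults in
the API follow the emulated study's conventions (20,000 permutations,
100,000 exact-test steps, 10,000 bottleneck iterations and PCA
permutations).

## 7. Known limitations

* Variance-component estimates are Weir–Cockerham, not genodive's AMOVA
  implementation; small numerical differences from published genodive values
  are expected (the standardization construction is the same).
* The exact test is Monte-Carlo, not a dememorized Markov chain; p-values
  carry Monte-Carlo error of order 1/√steps.
* No three-level (island > site) hierarchical AMOVA; analyses are two-level,
  plus island-pooled pairwise tests.
* `length`-mode genepop codes are repeat-unit counts, which assumes the
  locus motif length divides the detected repeat region (true for clean
  repeats; near-perfect repeats are rounded).
* The bottleneck machinery tests heterozygosity excess and mode shift only —
  no standardized-differences or sign tests, and no pure stepwise model.
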