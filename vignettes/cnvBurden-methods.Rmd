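---
title: "Rare CNV case/control burden analysis: models and design"
author: "cnvBurden package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare CNV case/control burden analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cnvBurden` implements a complete case/control association analysis of
large, rare copy-number variants (CNVs) called from genotyping-array
intensity data: two-caller consensus calling, sample-level quality
control, a rare-CNV filter cascade with B-allele-frequency (BAF)
validation, covariate-adjusted global burden regressions with gene-set
and constraint partitions, clumped stratified exact locus tests with
permutation-based genomic-inflation control, a deletion-recurrence
permutation test, and carrier-centred clinical analyses. A synthetic
cohort generator with planted effects makes every stage testable without
access to genotype data.

This vignette documents the statistical models, the tunable parameters
and their defaults, the synthetic-data model and what it does and does
not emulate, numerical choices, and known limitations.

# The pipeline

## Consensus calling

Array CNV callers disagree at boundaries and each produces
platform-specific artifacts, so the analysed callset is the
*intersection* of two independent callsets per sample
(`intersectCallsets()`): every same-direction overlapping pair (one call
from each caller) contributes its intersected interval, the probe count
is recomputed over the intersection, and single-caller calls are
dropped. Intersection is the conservative choice: a consensus boundary
is supported by both callers. Overlapping consensus fragments of one
sample are merged when they share at least 1 bp.

## Sample QC

Two screens (`sampleQc()`), mirroring standard array practice:

* **Intensity metrics.** Within each genotyping batch, a sample is an
  outlier for a metric (LRR standard deviation, absolute waviness
  factor, BAF drift) if it lies beyond 3 SDs of the batch mean; an
  outlier on any metric is removed. The pruning is a *single pass*:
  batch statistics are computed once and not recomputed after removals,
  which makes the procedure deterministic and idempotent. Survivors
  must additionally satisfy the hard bounds LRRSD ≤ 0.2, absWF ≤ 0.02,
  BAF drift ≤ 0.001.
* **Raw call load.** A sample is removed if the genomic footprint of
  its raw consensus calls — the length of the *union* of its call
  intervals, not the sum — exceeds 20 Mb, or if it has more than 20
  separate raw calls. "Occupied basepairs" denotes footprint, hence
  union.

## The filter cascade

The analysed callset is large (≥ 15 probes and ≥ 30 kb, both bounds
inclusive) and rare. Every filter is computed on the *full* consensus
callset and appends an audit flag; the analysis-ready set is the calls
with no removal flag (`cascadeSurvivors()`). Because no filter sees the
survivors of another, flag assignment is order-independent and the
audit trail is complete.

* **Region masks** (`applyRegionFilters()`): a call is removed when
  more than 30% of its bases (strictly greater) fall in telomere or
  centromere buffers, polyN reference gaps, segmental duplications, or
  simple-repeat/low-complexity/satellite loci. T-cell-receptor and
  immunoglobulin gene regions and known cell-line artifact loci remove
  on *any* overlap — somatic rearrangement and immortalisation
  artifacts make any overlapping call suspect.
* **Frequency** (`clusterFrequencyFilter()`): same-direction calls are
  single-linkage clustered at ≥ 50% reciprocal overlap — the
  field-standard CNV matching rule — and a call is removed when its
  locus reaches 1% carrier frequency in the combined cohort or in any
  single batch (each with its own denominator; QC-pass samples are the
  denominator), or when it matches an external reference record (same
  direction, ≥ 50% reciprocal overlap) listed at ≥ 1% in any
  population.
* **BAF validation** (`bafValidate()`): probe-level BAF at the call
  site must be consistent with the reported copy state. A hemizygous
  deletion has no heterozygous band, so a deletion is rejected when
  more than 10% of its probes show BAF in (0.25, 0.75). A three-copy
  segment shows bands near 1/3 and 2/3, so a duplication is rejected
  unless at least 60% of its informative probes (BAF in (0.10, 0.90))
  fall inside (0.20, 0.45) ∪ (0.55, 0.80). A call reported at copy
  state 4 or above is tetrasomic: its legitimate bands are 1/4, 1/2 and
  3/4, so the half band is admitted *and* at least 20% of informative
  probes must sit in the quarter bands — which a diploid segment
  lacks, keeping false calls detectable. Calls with fewer than 10
  signal-bearing probes pass with the informational flag
  `BAF_UNTESTED`. All band boundaries and fractions are `filterConfig()`
  parameters.

## Batch-effect inflation control

Small deletions (30–100 kb) are the size class most prone to
batch-specific call pile-ups. `detectInflationLoci()` clusters the
surviving small deletions into loci, forms test units from loci with at
least two carriers, and estimates the permutation genomic inflation
factor (below). While inflation exceeds 1.10, the candidate locus with
the smallest stratified exact p-value is excluded and inflation
re-estimated. A locus is a candidate only if at least 80% of its
carriers come from a single genotyping batch — the batch-effect
signature — and it has at least three carriers: a two-carrier cluster
is no pile-up, and without the floor the loop erodes genuinely null
loci whenever the (noisy, at small unit counts) inflation estimate sits
marginally above the threshold. Singleton loci are excluded from inflation estimation
because a one-carrier exact test has an almost degenerate two-point
p-value distribution and carries no locus-level aggregation signal.
All thresholds are `filterConfig()` parameters.

# Association models

## Global burden regressions

Per-sample burden metrics (`computeBurdenMetrics()`) are deterministic
functions of the surviving calls and the annotation: counts and
affected kilobases by direction, size bin (30–100 kb, 100 kb–1 Mb,
> 1 Mb) and cohort frequency (singleton loci), gene-overlap counts
("coding" means ≥ 1 bp overlap with an annotated gene), counts hitting
genes above pLI thresholds {0.5, 0.9, 0.995} and in curated gene sets
(two neurodevelopmental-disorder lists, haplosensitive,
triplosensitive), and kilobases of evolutionarily constrained sequence
(score track, thresholds configurable because published bin edges for
such figures rarely are printed).

Two regressions per metric:

* `logisticBurdenTest()`: case status ~ covariates + metric; the
  effect is the odds ratio per metric unit with Wald 95% interval and
  two-sided Wald p-value. Wald inference is the convention behind the
  "OR, P" reporting style; separation is flagged with an infinite
  interval rather than an error.
* `linearExcessTest()`: metric ~ covariates + case status; the case
  coefficient is the excess per case (e.g. 0.07 extra calls per case).

The base covariate set is the first five principal components and sex.
Candidates (PCs 6–20, LRRSD) join the model when associated with both
the raw call count (linear) and case status (logistic likelihood-ratio
test — the likelihood ratio is used because a Wald test collapses
under separation) at p < 0.05 (`selectCovariates()`; the screening
threshold is a parameter since "associated" is rarely given a number).
`leaveOneOutBurden()` refits per held-out batch and per dropped
covariate.

## Clumped stratified exact locus tests

Locus tests compare carrier proportions between cases and controls
within four strata (country × sex), because the control cohorts differ
sharply in sex composition and the two countries separate in ancestry.

Genes (or probes, for breakpoint tests) are clumped into units
(`clumpGeneUnits()`, `clumpProbeUnits()`): neighbouring elements merge
when more than half of the calls overlapping either element overlap
both, transitively along genomic order; elements with no calls drop out
and interrupt merging. This prevents a single CNV region from being
counted as many correlated tests.

Each unit is tested with an exact stratified
Cochran–Mantel–Haenszel-type test (`cmhExactTest()`): conditioning on
the per-stratum margins, the total number of case carriers summed over
strata has a null distribution equal to the convolution of per-stratum
central hypergeometrics; the two-sided p-value is the sum of
probabilities of all outcomes no more likely than the observed one (the
minimum-likelihood rule, matching the two-sided Fisher exact
convention, to which the test reduces for a single stratum). The
common odds ratio is the Mantel–Haenszel estimate. Benjamini–Hochberg
adjustment (`bhFdr()`) controls the FDR at 0.05 across units.

## Permutation genomic inflation

Exact p-values for rare carriers are heavily discrete, so the usual
"median χ² over 0.456" inflation factor is biased. Instead
(`permutationLambda()`), each p is converted to a 1-df χ² quantile and
the inflation factor is the median observed quantile divided by the
median, over case/control label permutations *within strata*
(preserving per-stratum case counts), of the permuted median quantile.
Under margin-preserving permutation each unit's conditional null is
unchanged, so permuted p-values are obtained by lookup from the
precomputed null — the estimate costs one convolution per unit
regardless of the permutation count. A fixed seed drives all
permutations.

## Recurrence permutation test

Independent of any single locus reaching significance, an excess of
loci carried by two or more distinct cases indicates dispersed risk
loci. `recurrencePermutationTest()` counts loci (reciprocal-overlap
clusters) with ≥ 2 distinct case carriers and compares against
within-stratum label permutations; p = (1 + #{T_perm ≥ T_obs}) /
(1 + n_perm).

# Downstream carrier analyses

"Deleterious" deletions are deletions of highly loss-of-function
intolerant genes (pLI > 0.995) or of neurodevelopmental (NDD) genes
under either curated definition; deleterious duplications are NDD-gene
duplications (`carrierStatus()`).

* `caseOnlySingleGeneSet()` returns genes hit by ≥ 1 single-gene case
  call (a call overlapping exactly one gene) and no single-gene control
  call; `poissonEnrichment()` gives the exact upper Poisson tail for
  comparing observed de novo or case/control variant counts in that
  set against expectation from exome studies.
* `prsCarrierAssociation()` regresses the within-set-normalized
  polygenic score on carrier status plus the burden covariates — a
  negative carrier shift is the signature of rare-variant/common-variant
  risk trade-off.
* `comorbidityAssociation()` uses the Pearson chi-square without
  continuity correction on the carrier × comorbidity 2 × 2 table,
  falling back to the Fisher exact test only when an expected cell
  count is below 1 (with moderate expected counts and thousands of
  samples the chi-square approximation holds, and the no-correction
  statistic is what such studies print; both methods can be forced).
* `treatmentResponseTest()` compares percent symptom-scale improvement,
  100·(pre − post)/pre, between carriers and non-carriers with a
  pooled-variance t-test (the pooled test is implied whenever reported
  degrees of freedom track the combined sample size; Welch would halve
  them with eight carriers). Degrees of freedom are computed from the
  groups actually analysed.

# The synthetic cohort generator

`simulateStudy()` builds a complete study: sample sheet, toy genome,
two jittered callsets, probe-level BAF/LRR signal and clinical columns,
plus a truth table for tests.

**Study conditions as defaults.** Four genotyping batches, each
case-only or control-only as in array studies assembled from distinct
collections; case collections 63–65% female; Swedish controls 95%
female (a population-cohort inheritance), Norwegian controls balanced,
so controls are ~80% female overall. PC5 is offset by country,
emulating Scandinavian north/south ancestry separation; PC7 carries a
small case loading and, together with LRRSD, modulates the raw call
rate, so the covariate screen has something real to find. Intensity
metrics are log-normal with a 2% planted fraction of pathological
outliers.

**Toy genome.** 5 chromosomes × 30 Mb with 50,000 evenly spaced probes
and 2,000 non-overlapping genes — roughly 1:10 the real array — with
U-shaped pLI (Beta(0.2, 0.2)), random NDD/haplosensitive/triplosensitive
flags, region masks occupying ~20% of the genome, a gene-anchored
constraint-score track, and an external frequency reference listing the
planted common loci above 1%.

**Call model.** Background CNVs are uniform outside masks and planted
loci at 0.7 per sample (sizes log-uniform 50 kb–2 Mb); 25 common loci
(carrier rates 1.5–4%) and 8 rare recurrent loci (~0.4%) are planted;
5% of calls per sample sit fully inside masked regions
(`mask_artifact`), and 5% are "false" calls whose underlying state is
diploid. These rates were fixed once so the consensus rate (~1.4
calls/sample) and the post-cascade rate (~0.6–0.7 calls/sample) match
the regime a well-behaved array study reports. Risk CNVs are planted
retrospectively: with control carrier probability p0 and planted odds
ratio ψ, case carrier probability is p0ψ/(1 − p0 + p0ψ), which makes ψ
the exact generative parameter and parameter recovery a well-posed
oracle. The `excessCallsPerCase` dial is the *total* expected case
excess: extra background Poisson calls supply whatever the carrier
classes do not, so the configured value is the truth the linear model
must recover. Each true CNV enters both callsets with independent
boundary jitter of ±2 probes and is dropped from a callset with the
batch's caller-noise probability (0.05). BAF is emitted per probe from
binomial genotypes at the true copy number (plus N(0, 0.03) noise) over
the call site and a jitter-wide flank; copy-number-0 sites emit a
homozygous-like pattern, a simplification of their unstable signal.

**Clinical model.** Comorbidity flags for cases at realistic base
rates, with the ASD rate in NDD-duplication carriers following a
planted odds ratio (~10, the published carrier contrast); percent
treatment improvement N(47, 28) shifted by −31 points in NDD-deletion
carriers (the SD solves the published t statistic at the published
group sizes); polygenic scores standard normal with a −0.45 SD shift in
deleterious-deletion case carriers.

**What it does not emulate.** Genome-wide raw intensities (signal is
emitted only at call sites), linkage structure and real allele
frequencies, caller-specific breakpoint biases beyond symmetric jitter,
relatedness, and ancestry admixture beyond a single PC offset. Passing
tests therefore demonstrate the statistical machinery and the filter
logic, not robustness to every artifact of real array data.

# Numerical choices

* Coordinates are 1-based inclusive internally (the callers' native
  convention); BED input/output is 0-based half-open; length = end −
  start + 1. Copy state 2 is rejected in call files: a "call" is by
  definition non-diploid.
* Chromosome analysis is restricted to the autosomes supplied in the
  input; no sex-chromosome special-casing is attempted (with strongly
  sex-imbalanced controls, X/Y burden is confounded by design).
* The exact-test convolution works on probability vectors with a
  (1 + 10⁻⁷) tie tolerance in the minimum-likelihood rule, matching
  `fisher.test`.
* Degenerate cases are explicit: an all-zero carrier table gives p = 1
  with an undefined odds ratio; separation flags an infinite Wald
  interval; zero-variance treatment-response groups give t = 0 when
  means agree.
* Simulation-heavy checks run at reduced scale chosen once: null
  calibration uses 200 cohorts of 600/600 on the default toy genome
  with one shared annotation (the genome is a fixed condition, cohorts
  vary); parameter recovery uses 100 cohorts of 2,000/3,500; the filter
  cascade fixture uses one 2,000/2,000 cohort, large enough that a
  19-call single-batch artifact stays below the per-batch 1% frequency
  ceiling, as it did at the emulated study's scale.
* The recovery experiment evaluates the estimators against generative
  truth: the logistic model is fitted on the true carrier covariate and
  the linear model on true per-sample call counts, so the planted
  log-odds-ratio and excess are exactly the estimands. Both fits use the
  full study covariate set (PC1--PC5, PC7, sex, LRRSD): PC7 carries both
  a case loading and a call-rate loading by construction, so omitting it
  biases the excess estimate upward by the confounded path -- exactly the
  situation the covariate screen exists to handle. End-to-end
  recovery through calling and filtering is exercised separately by the
  cascade fixture, where truth labels are compared per call class.
* The batch-artifact fixture plants its risk CNVs with null odds
  ratios. At toy scale a planted true association concentrates in the
  few multi-carrier small-deletion units and dominates the median-based
  inflation estimate, so batch-effect detection is evaluated on an
  association-null background; at the real study's unit count the two
  signals separate on their own.

# Limitations

* The per-batch 1% frequency rule becomes aggressive when a batch is
  small: with a few hundred samples per batch, two or three carriers
  already exceed 1%, so the filter selects against loci whose carriers
  share a batch -- and, because batches are case-only or control-only,
  against loci whose carriers share a case/control label. Downstream
  permutation nulls (the recurrence test, the inflation factor) are then
  slightly conservative relative to label permutation, which does not see
  the selection. At realistic batch sizes (the 1% cap at seven or more
  carriers) the effect is negligible; at the reduced simulation scale it
  is visible as a conservative shift of recurrence p-values and an
  observed-to-permuted quantile ratio slightly below one. The deviation
  is in the safe direction: no test overstates significance.
* The exact test conditions on per-stratum margins; with very few
  carriers its p-values are discrete, which is precisely why inflation
  is estimated by permutation rather than against the theoretical
  χ² median.
* The median-based inflation factor needs a reasonable population of
  multi-carrier units to be stable; with fewer than ~10 units the
  estimate is flagged unreliable.
* Logistic burden models use plain maximum likelihood; no Firth
  correction (separation is flagged instead, which suffices at cohort
  scale).
* The generator's planted effects are marginal, not linked to the PCs;
  confounding by ancestry beyond the PC5/PC7 constructions is not
  simulated.
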