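# cnvBurden

Case/control association analysis of large, rare copy-number variants
(CNVs) called from genotyping-array intensity data — for statistical
geneticists running array-based CNV burden studies in psychiatric or
other complex-trait cohorts.

Rare CNVs (deletions or duplications of at least 15 array probes and
30 kb) are a class of variation whose disease contribution is measured
by comparing carrier burden between cases and controls. The package
implements the full analysis chain:

* **Consensus calling** — the per-sample intersection of two CNV
  callers' callsets, with probe counts recomputed over intersected
  intervals.
* **Sample QC** — per-batch 3-SD outlier pruning on intensity metrics
  (LRRSD, absWF, BAF drift) with hard bounds, and removal of samples
  with > 20 raw calls or > 20 Mb of call footprint.
* **Filter cascade** — size floor; removal of calls with > 30% overlap
  with telomere/centromere buffers, polyN gaps, segmental duplications
  and repeats (any overlap for TCR/Ig and cell-line artifact loci);
  < 1% frequency required internally (combined cohort and every batch)
  and against an external reference at ≥ 50% reciprocal overlap; and
  B-allele-frequency validation of each call's copy state. Every
  filter writes an audit flag; no filter sees another's survivors.
* **Global burden tests** — logistic (case ~ covariates + metric,
  odds ratio per metric unit) and linear (metric ~ covariates + case,
  excess per case) regressions over partitioned burden metrics: by
  direction, size, cohort frequency, gene overlap, pLI threshold,
  neurodevelopmental/dosage-sensitivity gene sets, and constrained
  kilobases; with data-driven covariate screening and leave-one-out
  sensitivity fits.
* **Locus tests** — genes/probes clumped into units by the > 50%
  co-impact rule, an exact stratified Cochran–Mantel–Haenszel test per
  unit (convolved hypergeometric null, two-sided minimum-likelihood
  p), Benjamini–Hochberg FDR, a permutation-based genomic inflation
  factor, iterative exclusion of single-batch inflation loci, and a
  case-recurrence permutation test.
* **Carrier analyses** — case-only single-gene sets with exact Poisson
  enrichment against exome expectations, polygenic-score shifts in
  deleterious-CNV carriers, comorbidity contingency tests, and a
  treatment-response comparison.
* **Synthetic cohorts** — a generator
  (`simulateStudy()`) that builds a complete study (sample sheet, toy
  genome, two jittered callsets, probe-level BAF/LRR signal, clinical
  phenotypes, truth table) with planted odds ratios, so every stage is
  testable end to end.

See `vignettes/cnvBurden-methods.Rmd` for the models, parameter
defaults and design decisions.

## Worked example

```r
library(cnvBurden)

cfg <- simConfig(nCases = 2000, nControls = 2000, seed = 7)
sim <- simulateStudy(cfg)

## sample QC, consensus, filter cascade
qc <- sampleQc(sim$samples)
keep <- sim$samples[!qc$removed, ]
cons <- intersectCallsets(sim$callsA, sim$callsB, sim$probeMap,
                          sim$samples)
cons <- cons[sampleIds(cons) %in% keep$sample_id]
flagged <- filterCascade(cons, keep, sim$annotation$masks,
                         sim$annotation$freqRef, sim$probeMap)
calls <- cascadeSurvivors(flagged)
length(cons) / nrow(sim$samples)    # 1.38 raw consensus calls/sample
length(calls) / nrow(keep)          # 0.67 analysis-ready calls/sample

## burden regression on high-pLI deletion carriage (the generator's
## truth flags; the planted odds ratio is 4.12)
covs <- c("PC1","PC2","PC3","PC4","PC5","PC7","sex","lrrsd")
carrier <- as.numeric(sim$carriers$del_highpli[
  match(keep$sample_id, sim$carriers$sample_id)])
logisticBurdenTest(carrier, keep, covs,
                   metricName = "high-pLI deletion carrier")
#>                      metric    model estimate ci_lo ci_hi  p_value
#> 1 high-pLI deletion carrier logistic     4.32  2.65  7.03 4.41e-09
```

Carrying a deletion of a highly loss-of-function-intolerant gene
multiplies the odds of being a case 4.3-fold (95% CI 2.7–7.0) in this
synthetic cohort — the covariate-adjusted regression recovers the
generator's planted odds ratio of 4.12. (A metric computed from the
called CNVs instead of the truth flags is attenuated toward 1, because
on the gene-dense toy genome many background deletions also touch a
constrained gene; see the methods vignette.)

```r
## clinical contrasts among cases
cases  <- sim$samples[sim$samples$is_case, ]
carr   <- sim$carriers[match(cases$sample_id, sim$carriers$sample_id), ]
comorbidityAssociation(carr$ndd_dup, cases$asd)
#> chi-square 61.2, df 1, p 5.3e-15 (16/32 carriers have ASD vs 176/1968)
treatmentResponseTest(cases$ybocs_pre, cases$ybocs_post, carr$ndd_del)
#> carriers improve 20% vs 45% in non-carriers; t = -5.31, p = 1.2e-07
```

Neurodevelopmental-duplication carriers are strongly enriched for
comorbid autism, and neurodevelopmental-deletion carriers respond
markedly less to treatment — the planted clinical effect sizes
(odds ratio ~10; a 31-point improvement gap).

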