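## Brute-force oracles shared by the unit and acceptance tests.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(IRanges)
})

## per-base scan: bp of [s1,e1] covered by the union of intervals (1-based
## inclusive); only usable for small coordinates
bruteCoveredBp <- function(s1, e1, starts, ends, chrom1 = "c", chroms = "c") {
  covered <- logical(e1 - s1 + 1)
  for (i in seq_along(starts)) {
    if (chroms[i] != chrom1) next
    lo <- max(starts[i], s1); hi <- min(ends[i], e1)
    if (lo <= hi) covered[(lo - s1 + 1):(hi - s1 + 1)] <- TRUE
  }
  sum(covered)
}

## all-pairs single-linkage clustering at reciprocal overlap >= ro
bruteClusters <- function(chrom, start, end, type, ro) {
  n <- length(start)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || chrom[i] != chrom[j] || type[i] != type[j]) next
    ov <- min(end[i], end[j]) - max(start[i], start[j]) + 1
    if (ov <= 0) next
    r <- ov / max(end[i] - start[i] + 1, end[j] - start[j] + 1)
    if (r >= ro) adj[i, j] <- TRUE
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

## full enumeration of the exact stratified test: counts as in
## stratumCounts(); enumerates every table with the observed margins
bruteCmhP <- function(counts) {
  strata <- seq_len(nrow(counts))
  m <- counts[, 1] + counts[, 3]   # carriers
  k <- counts[, 1] + counts[, 2]   # cases
  n <- rowSums(counts)
  ranges <- lapply(strata, function(s)
    max(0, k[s] + m[s] - n[s]):min(k[s], m[s]))
  grid <- expand.grid(ranges)
  pr <- rep(1, nrow(grid))
  for (s in strata)
    pr <- pr * dhyper(grid[[s]], m[s], n[s] - m[s], k[s])
  pr <- pr / sum(pr)
  S <- rowSums(grid)
  S_obs <- sum(counts[, 1])
  p_obs <- sum(pr[S == S_obs])
  sup <- sort(unique(S))
  pmf <- vapply(sup, function(v) sum(pr[S == v]), numeric(1))
  sum(pmf[pmf <= pmf[match(S_obs, sup)] * (1 + 1e-7)])
}

## direct implementation of the step-up FDR formula
bruteBh <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m)) {
      rank_j <- sum(p <= p[j])  # maximal rank of the tied value
      if (p[j] >= p[i]) cand <- min(cand, m * p[j] / rank_j)
    }
    q[i] <- min(cand, 1)
  }
  q
}

## quick constructor for small consensus callsets
mkCalls <- function(chrom, start, end, sample_id, copy_state,
                    n_probes = 20L, ...) {
  CnvCalls(chrom, start, end, sample_id, copy_state,
           rep_len(n_probes, length(chrom)), caller = "consensus", ...)
}

## minimal sample sheet with the columns the pipeline touches
mkSamples <- function(n, cases = n / 2, country = NULL, sex = NULL,
                      dataset = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(country)) country <- rep(c("SWE", "NOR"), length.out = n)
  if (is.null(sex)) sex <- rep(c("M", "F"), length.out = n)
  if (is.null(dataset)) dataset <- rep(c("d1", "d2"), length.out = n)
  df <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                   is_case = seq_len(n) <= cases,
                   dataset = dataset, country = country, sex = sex,
                   lrrsd = exp(rnorm(n, log(0.09), 0.2)),
                   abs_wf = exp(rnorm(n, log(0.005), 0.3)),
                   baf_drift = exp(rnorm(n, log(1.5e-4), 0.4)),
                   stringsAsFactors = FALSE)
  for (i in 1:20) df[[paste0("PC", i)]] <- rnorm(n)
  df
}

## tiny evenly spaced probe grid
mkProbes <- function(chromLen = 1e6, spacing = 1000, chroms = "chr1") {
  pos <- seq(spacing / 2, chromLen, by = spacing)
  gr <- GRanges(rep(chroms, each = length(pos)),
                IRanges(rep(pos, length(chroms)), width = 1))
  mcols(gr)$probe_id <- sprintf("P%05d", seq_along(gr))
  gr
}
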