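#' @importFrom S4Vectors splitAsList
NULL

## Filter-cascade semantics: every filter is computed on the full consensus
## callset (not on survivors of prior filters), all flags are recorded for
## audit, and the analysis-ready set is the calls with zero removal flags.
## Flag assignment is therefore order-independent.

.appendFlags <- function(calls, hit, flag) {
  ff <- filterFlags(calls)
  if (any(hit))
    ff[hit] <- lapply(ff[hit], function(f) unique(c(f, flag)))
  mcols(calls)$filter_flags <- ff
  calls
}

#' Two-caller consensus by interval intersection
#'
#' For each sample, every pair of calls (one from each caller) on the same
#' chromosome with the same CNV direction (both deletions or both
#' duplications) that overlap contributes its intersection; probe counts
#' are recomputed over the intersected interval; calls seen by only one
#' caller are dropped. Overlapping consensus intervals of one sample with
#' the same direction are merged (1 bp overlap suffices).
#'
#' @param callsA,callsB \code{\link{CnvCalls}} from the two callers.
#' @param probes probe-position \code{GRanges} (or a \code{ProbeMap}).
#' @param samples optional sample sheet; calls from samples absent from it
#'   raise an error.
#' @return Consensus \code{\link{CnvCalls}} (caller \code{"consensus"}).
#' @export
intersectCallsets <- function(callsA, callsB, probes, samples = NULL) {
  stopifnot(is(callsA, "CnvCalls"), is(callsB, "CnvCalls"))
  if (is(probes, "ProbeMap")) probes <- probes@probes
  if (!is.null(samples)) {
    unknown <- setdiff(unique(c(sampleIds(callsA), sampleIds(callsB))),
                       samples$sample_id)
    if (length(unknown))
      stop("calls from sample(s) absent from the sample sheet: ",
           paste(unknown, collapse = ", "))
  }
  if (!length(callsA) || !length(callsB))
    return(CnvCalls(caller = "consensus"))
  ov <- findOverlaps(granges(callsA), granges(callsB))
  q <- queryHits(ov); s <- subjectHits(ov)
  keep <- sampleIds(callsA)[q] == sampleIds(callsB)[s] &
    isDeletion(callsA)[q] == isDeletion(callsB)[s]
  q <- q[keep]; s <- s[keep]
  if (!length(q)) return(CnvCalls(caller = "consensus"))
  pint <- pintersect(granges(callsA)[q], granges(callsB)[s])
  mcols(pint) <- NULL
  mcols(pint)$sample_id <- sampleIds(callsA)[q]
  mcols(pint)$copy_state <- copyState(callsA)[q]
  uidA <- mcols(callsA)$uid
  if (!is.null(uidA)) mcols(pint)$uid <- uidA[q]
  ## merge same-sample, same-direction overlapping consensus intervals:
  ## fold (sample, direction) into composite seqnames so one global
  ## reduce() does all groups at once
  chrom <- as.character(seqnames(pint))
  key <- paste(mcols(pint)$sample_id,
               ifelse(mcols(pint)$copy_state < 2L, "del", "dup"),
               chrom, sep = "\r")
  comp <- GRanges(key, IRanges(start(pint), end(pint)))
  red <- GenomicRanges::reduce(comp, min.gapwidth = 0L, with.revmap = TRUE)
  first <- vapply(mcols(red)$revmap, `[`, integer(1), 1L)
  out_chrom <- chrom[first]
  gr_out <- GRanges(out_chrom, IRanges(start(red), end(red)))
  np <- countOverlaps(gr_out, probes)
  ok <- which(np >= 1L)
  cons <- CnvCalls(out_chrom[ok], start(red)[ok], end(red)[ok],
                   mcols(pint)$sample_id[first][ok],
                   mcols(pint)$copy_state[first][ok], np[ok],
                   caller = "consensus",
                   uid = if (is.null(uidA)) NULL
                         else mcols(pint)$uid[first][ok])
  BiocGenerics::sort(cons)
}

#' Flag calls below the analysed size floor
#'
#' Calls with fewer than \code{minProbes} probes or shorter than
#' \code{minLenBp} basepairs are flagged \code{SIZE}; both bounds are
#' inclusive (a 15-probe, 30,000 bp call is kept).
#'
#' @param calls consensus \code{\link{CnvCalls}}.
#' @param cfg a \code{\link{filterConfig}}.
#' @return \code{calls} with updated flags.
#' @export
applySizeFilter <- function(calls, cfg = filterConfig()) {
  hit <- nProbes(calls) < cfg@minProbes |
    width(calls) < cfg@minLenBp
  .appendFlags(calls, hit, "SIZE")
}

#' Flag calls overlapping masked genomic regions
#'
#' A call is flagged with a mask's (uppercased) name when the fraction of
#' its bases covered by the mask exceeds the removal threshold (strictly
#' greater than 30 percent). Masks listed in \code{anyOverlap} (T-cell
#' receptor/immunoglobulin regions and cell-line artifact loci) remove on
#' any overlap instead. All mask flags are recorded even after the first
#' hit, for a full audit.
#'
#' @param calls consensus \code{\link{CnvCalls}}.
#' @param masks named list of \code{\link{RegionSet}} masks.
#' @param cfg a \code{\link{filterConfig}}.
#' @param anyOverlap names of masks using the any-overlap rule.
#' @return \code{calls} with updated flags.
#' @export
applyRegionFilters <- function(calls, masks, cfg = filterConfig(),
                               anyOverlap = c("tcr_ig", "lcl_artifact")) {
  bad <- setdiff(anyOverlap, names(masks))
  if (length(bad))
    stop("unknown mask name(s): ", paste(bad, collapse = ", "))
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!length(m)) next
    hit <- if (nm %in% anyOverlap)
      overlapsAny(granges(calls), granges(m))
    else
      fractionOverlap(calls, m) > cfg@regionOverlapMax
    calls <- .appendFlags(calls, hit, toupper(nm))
  }
  calls
}

#' Cluster calls into CNV loci
#'
#' Same-direction calls are single-linkage clustered at the configured
#' reciprocal overlap (50 percent), the field-standard CNV locus-matching
#' rule.
#'
#' @param calls \code{\link{CnvCalls}}.
#' @param cfg a \code{\link{filterConfig}}.
#' @param samples optional sample sheet for per-dataset carrier counts.
#' @return A list: \code{assign} (cluster id per call) and \code{clusters}
#'   (one row per locus: envelope, type, distinct carrier counts overall
#'   and per dataset, carrier sample ids as a list column).
#' @export
clusterCalls <- function(calls, cfg = filterConfig(), samples = NULL) {
  type <- cnvType(calls)
  cl <- singleLinkageClusters(calls, type, cfg@reciprocalOverlap)
  if (!length(cl))
    return(list(assign = integer(0), clusters = data.frame()))
  ids <- sampleIds(calls)
  ucl <- sort(unique(cl))
  clf <- match(cl, ucl)
  k <- length(ucl)
  first <- match(ucl, cl)
  uu <- !duplicated(paste(clf, ids))  # one row per (cluster, carrier)
  clusters <- data.frame(
    chrom = as.character(seqnames(calls))[first],
    start = as.integer(tapply(start(calls), clf, min)),
    end = as.integer(tapply(end(calls), clf, max)),
    cnv_type = type[first],
    n_calls = tabulate(clf, k),
    n_carriers = tabulate(clf[uu], k),
    cluster_id = ucl,
    stringsAsFactors = FALSE)
  clusters$carriers <- unname(split(ids[uu], factor(clf[uu], seq_len(k))))
  if (!is.null(samples)) {
    dsmap <- samples$dataset[match(ids, samples$sample_id)]
    tab <- table(factor(clf[uu], seq_len(k)), dsmap[uu])
    dataset_tab <- matrix(as.integer(tab), nrow = k,
                          dimnames = list(NULL, colnames(tab)))
    clusters$dataset_carriers <- lapply(seq_len(k), function(i) {
      v <- dataset_tab[i, ]
      v[v > 0]
    })
  }
  rownames(clusters) <- NULL
  list(assign = cl, clusters = clusters)
}

#' Flag common calls by internal and external frequency
#'
#' Calls are clustered into loci (\code{\link{clusterCalls}}); a locus
#' frequency is its distinct carrier count over the relevant denominator.
#' A call is flagged \code{FREQ_INTERNAL} when its locus reaches the
#' frequency ceiling (1 percent) in the full combined case/control cohort
#' or in any single dataset (that dataset's denominator), and
#' \code{FREQ_EXTERNAL} when it matches an external reference record (same
#' direction, at least 50 percent reciprocal overlap) whose listed
#' frequencies reach the ceiling in any population.
#'
#' @param calls consensus \code{\link{CnvCalls}}.
#' @param samples QC-pass sample sheet (the frequency denominators).
#' @param externalRef frequency reference \code{data.frame}
#'   (see \code{\link{readFrequencyReference}}); may be \code{NULL}.
#' @param cfg a \code{\link{filterConfig}}.
#' @return \code{calls} with updated flags.
#' @export
clusterFrequencyFilter <- function(calls, samples, externalRef = NULL,
                                   cfg = filterConfig()) {
  if (!nrow(samples)) stop("empty sample sheet: zero frequency denominator")
  if (!length(calls)) return(calls)
  cc <- clusterCalls(calls, cfg, samples)
  ntot <- nrow(samples)
  ds_n <- table(samples$dataset)
  common <- cc$clusters$n_carriers / ntot >= cfg@freqMax
  for (i in which(!common)) {
    dc <- cc$clusters$dataset_carriers[[i]]
    if (any(as.numeric(dc) / as.numeric(ds_n[names(dc)]) >= cfg@freqMax))
      common[i] <- TRUE
  }
  hit <- common[match(cc$assign, cc$clusters$cluster_id)]
  calls <- .appendFlags(calls, hit, "FREQ_INTERNAL")

  if (!is.null(externalRef) && nrow(externalRef)) {
    freq_cols <- grep("^freq", colnames(externalRef), value = TRUE)
    anyhigh <- apply(externalRef[freq_cols], 1, function(v)
      any(v >= cfg@freqMax, na.rm = TRUE))
    ref <- externalRef[anyhigh, , drop = FALSE]
    if (nrow(ref)) {
      refgr <- GRanges(ref$chrom, IRanges(ref$start, ref$end))
      ov <- findOverlaps(granges(calls), refgr)
      q <- queryHits(ov); s <- subjectHits(ov)
      keep <- cnvType(calls)[q] == ref$cnv_type[s]
      ro <- reciprocalOverlapPairs(granges(calls)[q[keep]],
                                   refgr[s[keep]])
      ext <- rep(FALSE, length(calls))
      ext[q[keep][ro >= cfg@reciprocalOverlap]] <- TRUE
      calls <- .appendFlags(calls, ext, "FREQ_EXTERNAL")
    }
  }
  calls
}

#' Validate calls against probe-level B-allele frequencies
#'
#' A deletion (copy number at most 1) is rejected when more than
#' \code{bafDelHetMax} of its probes show BAF inside the heterozygous
#' diploid band (0.25--0.75): a hemizygous segment has no heterozygotes.
#' A duplication (copy number at least 3) is rejected unless, among probes
#' with BAF inside the informative window (0.10--0.90), at least
#' \code{bafDupBandMin} fall inside the expected three-copy bands near 1/3
#' and 2/3. Calls with fewer than \code{bafMinInformative} signal-bearing
#' probes pass with the flag \code{BAF_UNTESTED}; so do duplications with
#' no informative-window probes.
#'
#' @param calls consensus \code{\link{CnvCalls}}.
#' @param probeMap a signal-bearing \code{\link{ProbeMap}}.
#' @param cfg a \code{\link{filterConfig}}.
#' @param missingSignal \code{"error"} (default) to fail on a call with no
#'   carrier signal, or \code{"untested"} to flag it \code{BAF_UNTESTED}.
#' @return \code{calls} with updated flags and a numeric
#'   \code{baf_score} metadata column (the measured band fraction).
#' @export
bafValidate <- function(calls, probeMap, cfg = filterConfig(),
                        missingSignal = c("error", "untested")) {
  missingSignal <- match.arg(missingSignal)
  if (!length(calls)) return(calls)
  sig <- probeMap@signal
  siggr <- GRanges(sig$chrom, IRanges(sig$pos, width = 1))
  ov <- findOverlaps(granges(calls), siggr)
  q <- queryHits(ov); s <- subjectHits(ov)
  keep <- sampleIds(calls)[q] == sig$sample_id[s]
  q <- q[keep]; s <- s[keep]
  b <- sig$baf[s]

  n <- length(calls)
  hb <- cfg@bafHetBand; lo <- cfg@bafDupBandLo; hi <- cfg@bafDupBandHi
  win <- cfg@bafInformativeWindow
  del <- isDeletion(calls)
  cs <- copyState(calls)
  ## per-call band counts, all vectorized
  het <- b > hb[1] & b < hb[2]
  inwin <- b > win[1] & b < win[2]
  side <- (b > lo[1] & b < lo[2]) | (b > hi[1] & b < hi[2])
  mid <- inwin & abs(b - 0.5) < 0.05
  n_sig <- tabulate(q, n)
  n_het <- tabulate(q[het], n)
  n_win <- tabulate(q[inwin], n)
  n_side <- tabulate(q[side], n)
  n_mid <- tabulate(q[mid], n)

  untested <- n_sig > 0L & n_sig < cfg@bafMinInformative
  tested <- n_sig >= cfg@bafMinInformative
  score <- rep(NA_real_, n)
  reject <- logical(n)
  ## deletions: fraction of probes in the diploid het band
  i <- tested & del
  score[i] <- n_het[i] / n_sig[i]
  reject[i] <- score[i] > cfg@bafDelHetMax
  ## duplications: band fraction among informative-window probes
  i <- tested & !del & n_win == 0L
  untested[i] <- TRUE
  i <- tested & !del & n_win > 0L & cs < 4L
  score[i] <- n_side[i] / n_win[i]
  reject[i] <- score[i] < cfg@bafDupBandMin
  ## tetrasomic pattern: quarter bands plus a legitimate half band;
  ## require the quarter bands too, which a diploid segment lacks
  i <- tested & !del & n_win > 0L & cs >= 4L
  score[i] <- (n_side[i] + n_mid[i]) / n_win[i]
  reject[i] <- score[i] < cfg@bafDupBandMin |
    n_side[i] / n_win[i] < cfg@bafQuadBandMin
  nosig <- n_sig == 0L
  if (any(nosig)) {
    if (missingSignal == "error")
      stop("no carrier signal for call ", which(nosig)[1], " (",
           sampleIds(calls)[which(nosig)[1]], " ",
           as.character(seqnames(calls))[which(nosig)[1]], ":",
           start(calls)[which(nosig)[1]], "-", end(calls)[which(nosig)[1]],
           ")")
    untested[nosig] <- TRUE
  }
  mcols(calls)$baf_score <- score
  calls <- .appendFlags(calls, untested, "BAF_UNTESTED")
  .appendFlags(calls, reject, "BAF_REJECT")
}

#' Run the full CNV filter cascade
#'
#' Applies, on the full consensus callset, the size floor, the region-mask
#' filters, the internal/external frequency filter and BAF validation,
#' recording every flag. \code{BAF_UNTESTED} is informational; all other
#' flags mark removal, and \code{\link{survivingCalls}} returns the
#' analysis-ready set.
#'
#' @param calls consensus \code{\link{CnvCalls}}.
#' @param samples QC-pass sample sheet.
#' @param masks named list of mask \code{\link{RegionSet}}s.
#' @param externalRef external frequency reference (or \code{NULL}).
#' @param probeMap signal-bearing \code{\link{ProbeMap}} (or \code{NULL} to
#'   skip BAF validation).
#' @param cfg a \code{\link{filterConfig}}.
#' @return \code{calls} with all audit flags assigned.
#' @export
filterCascade <- function(calls, samples, masks, externalRef = NULL,
                          probeMap = NULL, cfg = filterConfig()) {
  calls <- applySizeFilter(calls, cfg)
  calls <- applyRegionFilters(calls, masks, cfg)
  calls <- clusterFrequencyFilter(calls, samples, externalRef, cfg)
  if (!is.null(probeMap))
    calls <- bafValidate(calls, probeMap, cfg)
  calls
}

## removal flags; BAF_UNTESTED is informational only
REMOVAL_EXEMPT_FLAGS <- "BAF_UNTESTED"

#' @rdname filterCascade
#' @export
removalFlags <- function(calls) {
  lapply(filterFlags(calls), setdiff, REMOVAL_EXEMPT_FLAGS)
}

#' @rdname filterCascade
#' @details \code{cascadeSurvivors} returns calls whose flags contain no
#'   removal flag (\code{BAF_UNTESTED} alone does not remove).
#' @export
cascadeSurvivors <- function(calls) {
  calls[lengths(removalFlags(calls)) == 0L]
}

#' Detect and exclude batch-effect inflation loci
#'
#' Restricted to small deletions (30--100 kb), the size class prone to
#' batch-specific call pile-ups: calls are clustered into loci, loci with
#' at least two carriers form test units, and the permutation genomic
#' inflation factor (\code{\link{permutationLambda}}) is computed. While
#' the inflation factor exceeds \code{lambdaMax} (1.10), the locus with
#' the smallest stratified exact p-value whose carriers are at least 80
#' percent concentrated in a single dataset (the batch-effect signature)
#' is removed and the inflation factor recomputed; the loop stops when
#' inflation is controlled or no candidate remains.
#'
#' @param calls analysis-ready \code{\link{CnvCalls}} (cascade survivors).
#' @param samples QC-pass sample sheet.
#' @param nPerm permutations per inflation estimate.
#' @param seed integer seed.
#' @param cfg a \code{\link{filterConfig}}.
#' @return A list: \code{removed} (cluster table of excluded loci),
#'   \code{lambdaBefore}, \code{lambdaAfter}, and \code{excludedCalls}
#'   (indices into \code{calls} of the calls at excluded loci).
#' @export
detectInflationLoci <- function(calls, samples, nPerm = 200L, seed = 1L,
                                cfg = filterConfig()) {
  sel <- which(isDeletion(calls) &
               width(calls) >= cfg@smallDelRange[1] &
               width(calls) <= cfg@smallDelRange[2])
  small <- calls[sel]
  empty <- list(removed = data.frame(), lambdaBefore = NA_real_,
                lambdaAfter = NA_real_, excludedCalls = integer(0))
  if (!length(small)) return(empty)
  cc <- clusterCalls(small, cfg, samples)
  cl <- cc$clusters[cc$clusters$n_carriers >= 2L, , drop = FALSE]
  if (!nrow(cl)) return(empty)
  units <- lapply(seq_len(nrow(cl)), function(i)
    list(unit_id = paste0("L", cl$cluster_id[i]),
         carriers = cl$carriers[[i]]))
  lam0 <- permutationLambda(units, samples, nPerm = nPerm, seed = seed)
  lam <- lam0$lambda
  removed <- integer(0)
  active <- seq_len(nrow(cl))
  while (!is.na(lam) && lam > cfg@lambdaMax) {
    cand <- active[vapply(active, function(i) {
      dc <- cl$dataset_carriers[[i]]
      cl$n_carriers[i] >= cfg@inflationMinCarriers &&
        max(as.numeric(dc)) / sum(dc) >= cfg@datasetConcentration
    }, logical(1))]
    if (!length(cand)) break
    pv <- vapply(cand, function(i)
      cmhExactTest(stratumCounts(cl$carriers[[i]], samples))$p_value,
      numeric(1))
    worst <- cand[which.min(pv)]
    removed <- c(removed, worst)
    active <- setdiff(active, worst)
    if (!length(active)) { lam <- NA_real_; break }
    lam <- permutationLambda(units[active], samples, nPerm = nPerm,
                             seed = seed)$lambda
  }
  excl <- sel[cc$assign %in% cl$cluster_id[removed]]
  list(removed = cl[removed, , drop = FALSE], lambdaBefore = lam0$lambda,
       lambdaAfter = lam, excludedCalls = excl)
}
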