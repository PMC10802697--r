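#' @importFrom stats rnorm rpois rbinom runif rbeta rgamma
NULL

#' Synthetic study configuration
#'
#' Holds every parameter of the synthetic cohort generator: cohort
#' composition (case/control counts, genotyping batches that are each
#' case-only or control-only, as in array studies where cases and controls
#' come from different collections), a toy genome (chromosomes, evenly
#' spaced probes, non-overlapping genes with U-shaped pLI, region masks,
#' a constraint track and an external frequency reference), CNV generation
#' rates, planted case/control effects expressed as log odds ratios, and
#' clinical effect sizes.
#'
#' @name SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nCases = "integer", nControls = "integer",
  datasets = "data.frame",
  genome = "list", cnv = "list",
  effects = "numeric", carrierBaseRates = "numeric",
  excessCallsPerCase = "numeric",
  confound = "numeric", outlierFraction = "numeric",
  clinical = "list", seed = "integer"))

.validSimConfig <- function(object) {
  msg <- character()
  ds <- object@datasets
  need <- c("name", "country", "role", "share", "femaleShare",
            "callerNoise", "lrrsdScale")
  if (!all(need %in% colnames(ds)))
    msg <- c(msg, paste("datasets needs columns:", paste(need, collapse = ", ")))
  else {
    for (r in c("case", "control")) {
      sh <- ds$share[ds$role == r]
      if (length(sh) && abs(sum(sh) - 1) > 1e-8)
        msg <- c(msg, paste(r, "dataset shares must sum to 1"))
    }
    if (any(ds$callerNoise < 0 | ds$callerNoise > 1))
      msg <- c(msg, "callerNoise must lie in [0, 1]")
    if (!all(ds$country %in% c("SWE", "NOR")))
      msg <- c(msg, "country must be SWE or NOR")
  }
  if (object@nCases < 0L || object@nControls < 0L ||
      object@nCases + object@nControls <= 0L)
    msg <- c(msg, "need a positive total sample count")
  rates <- c(object@cnv$commonCarrierRate, object@cnv$recurrentCarrierRate,
             object@cnv$falseCallFraction, object@outlierFraction)
  if (any(rates < 0 | rates > 1))
    msg <- c(msg, "rates must lie in [0, 1]")
  if (any(object@carrierBaseRates < 0 | object@carrierBaseRates > 1))
    msg <- c(msg, "carrierBaseRates must lie in [0, 1]")
  if (!all(names(object@effects) %in% names(object@carrierBaseRates)))
    msg <- c(msg, "every effect needs a carrier base rate")
  if (length(msg)) msg else TRUE
}
setValidity("SimConfig", .validSimConfig)

#' Default genotyping-batch layout
#'
#' Four batches mirroring a two-country case/control array study: two
#' case collections and two control cohorts, with Swedish controls heavily
#' female (inherited from a largely female population cohort) and Norwegian
#' controls sex-balanced.
#'
#' @return A \code{data.frame} usable as the \code{datasets} argument of
#'   \code{\link{simConfig}}.
#' @export
defaultDatasets <- function() {
  data.frame(
    name = c("swe_cases", "nor_cases", "swe_controls", "nor_controls"),
    country = c("SWE", "NOR", "SWE", "NOR"),
    role = c("case", "case", "control", "control"),
    share = c(0.72, 0.28, 0.60, 0.40),
    femaleShare = c(0.63, 0.65, 0.95, 0.50),
    callerNoise = 0.05,
    lrrsdScale = 1,
    stringsAsFactors = FALSE)
}

#' Batch-artifact configuration
#'
#' Describes a cluster of spurious small deletion calls confined to one
#' genotyping batch: the classic batch-effect signature that inflates
#' locus-test statistics until the affected loci are excluded.
#'
#' @param dataset name of the affected batch.
#' @param nLoci number of artifact loci.
#' @param nCalls total artifact calls spread over the loci.
#' @param sizeRange artifact call size range in bp (small-deletion regime).
#' @return A list consumed by \code{\link{simConfig}}.
#' @export
batchArtifactConfig <- function(dataset = "swe_cases", nLoci = 3L,
                                nCalls = 19L, sizeRange = c(6e4, 9e4)) {
  list(dataset = dataset, nLoci = as.integer(nLoci),
       nCalls = as.integer(nCalls), sizeRange = sizeRange)
}

#' Build a synthetic study configuration
#'
#' Defaults describe the emulated study: a 5 x 30 Mb toy genome with 50,000
#' evenly spaced probes and 2,000 non-overlapping genes (about 1:10 the real
#' array), case collections 63--65 percent female and controls about 80
#' percent female overall, background and planted common-locus CNV rates
#' calibrated to about 1.4 consensus calls and 0.6--0.7 analysis-ready
#' calls per sample, planted risk-CNV odds ratios of 4.12 for deletions of
#' highly
#' loss-of-function-intolerant genes and about 2.5 for neurodevelopmental
#' (NDD) gene CNVs, a total case excess of 0.07 calls per sample, and the
#' published clinical effect sizes (ASD/duplication odds ratio around 10,
#' a -31 percentage-point treatment-response shift in NDD-deletion
#' carriers, a -0.45 SD polygenic-score shift in deleterious-deletion
#' carriers).
#'
#' @param nCases,nControls cohort sizes.
#' @param datasets batch layout; see \code{\link{defaultDatasets}}.
#' @param genome,cnv,clinical named lists overriding individual defaults.
#' @param effects named log odds ratios for planted carrier classes
#'   (\code{del_highpli}, \code{ndd_del}, \code{ndd_dup}).
#' @param carrierBaseRates control-carrier probability per planted class.
#' @param excessCallsPerCase total expected extra calls per case relative to
#'   controls (the generator's extra background rate is this minus the
#'   carrier-frequency differences implied by \code{effects}).
#' @param confound strengths tying PC7 to case status and PC7/LRRSD to the
#'   raw call rate.
#' @param outlierFraction fraction of samples with pathological intensity
#'   metrics.
#' @param batchArtifact \code{NULL} or \code{\link{batchArtifactConfig}()}.
#' @param seed integer seed; every generator draw derives from it.
#' @return A validated \code{SimConfig}.
#' @export
simConfig <- function(nCases = 600L, nControls = 600L,
                      datasets = defaultDatasets(),
                      genome = list(), cnv = list(), clinical = list(),
                      effects = c(del_highpli = log(4.12),
                                  ndd_del = log(2.54),
                                  ndd_dup = log(2.49)),
                      carrierBaseRates = c(del_highpli = 0.010,
                                           ndd_del = 0.006,
                                           ndd_dup = 0.006),
                      excessCallsPerCase = 0.07,
                      confound = c(pc7Case = 0.15, pc7Calls = 0.10,
                                   lrrsdCalls = 0.15),
                      outlierFraction = 0.02,
                      batchArtifact = NULL,
                      seed = 1L) {
  gdef <- list(nChrom = 5L, chromLenBp = 3e7, nProbes = 50000L,
               nGenes = 2000L, geneLenRange = c(1e4, 4e4), maskScale = 1,
               nCommonLoci = 25L, nRecurrentLoci = 8L,
               nConstraintPerGene = 2L)
  cdef <- list(backgroundRate = 0.7, backgroundSizeRange = c(5e4, 2e6),
               delFraction = 0.5, commonCarrierRate = 0.03,
               recurrentCarrierRate = 0.004, jitterProbes = 2L,
               falseCallFraction = 0.05, maskArtifactRate = 0.05,
               bafSigma = 0.03, batchArtifact = batchArtifact)
  kdef <- list(asdBaseRate = 0.09, adhdBaseRate = 0.12, ticsBaseRate = 0.10,
               sczBaseRate = 0.02, bdBaseRate = 0.03,
               asdDupOR = 10.3, ybocsDelShift = -31,
               ybocsImproveMean = 47, ybocsImproveSd = 28,
               prsDelShift = -0.45)
  gdef[names(genome)] <- genome
  cdef[names(cnv)] <- cnv
  kdef[names(clinical)] <- clinical
  obj <- new("SimConfig", nCases = as.integer(nCases),
             nControls = as.integer(nControls), datasets = datasets,
             genome = gdef, cnv = cdef, effects = effects,
             carrierBaseRates = carrierBaseRates,
             excessCallsPerCase = excessCallsPerCase,
             confound = confound, outlierFraction = outlierFraction,
             clinical = kdef, seed = as.integer(seed))
  validObject(obj)
  obj
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nCases, "cases /", object@nControls,
      "controls in", nrow(object@datasets), "dataset(s);",
      object@genome$nChrom, "x", object@genome$chromLenBp / 1e6,
      "Mb genome,", object@genome$nProbes, "probes,",
      object@genome$nGenes, "genes; seed", object@seed, "\n")
  ef <- object@effects
  if (length(ef))
    cat("  planted OR:", paste(names(ef), sprintf("%.2f", exp(ef)),
                               collapse = ", "),
        "; excess/case", object@excessCallsPerCase, "\n")
  invisible(NULL)
})

## per-dataset sample counts, largest-remainder rounding
.datasetCounts <- function(cfg) {
  ds <- cfg@datasets
  out <- integer(nrow(ds))
  for (r in c("case", "control")) {
    idx <- which(ds$role == r)
    total <- if (r == "case") cfg@nCases else cfg@nControls
    if (!length(idx)) {
      if (total > 0) stop("no dataset declared for role ", r)
      next
    }
    raw <- ds$share[idx] * total
    n <- floor(raw)
    rem <- total - sum(n)
    if (rem > 0) {
      ord <- order(raw - n, decreasing = TRUE)
      n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1L
    }
    if (total > 0 && any(n == 0L))
      stop("dataset '", ds$name[idx[n == 0L]][1],
           "' would receive zero samples")
    out[idx] <- as.integer(n)
  }
  out
}

#' Generate a synthetic cohort sample sheet
#'
#' Samples are assigned to batches by the configured shares; sex follows
#' each batch's female share; PCs are standard normal except PC5, which is
#' offset by country (ancestry separation), and PC7, which carries the
#' configured case-status loading; intensity metrics are log-normal with a
#' planted fraction of pathological outliers; three normalized
#' polygenic-score columns are drawn standard normal.
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @return A sample sheet \code{data.frame} (clinical columns \code{NA}
#'   until \code{\link{generateClinical}}).
#' @export
generateCohort <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed)
  ds <- cfg@datasets
  n_per <- .datasetCounts(cfg)
  n <- sum(n_per)
  dataset <- rep(ds$name, n_per)
  country <- rep(ds$country, n_per)
  is_case <- rep(ds$role == "case", n_per)
  femaleShare <- rep(ds$femaleShare, n_per)
  lrrsdScale <- rep(ds$lrrsdScale, n_per)
  sex <- ifelse(runif(n) < femaleShare, "F", "M")
  pcs <- matrix(rnorm(n * 20L), n, 20L,
                dimnames = list(NULL, paste0("PC", 1:20)))
  pcs[, 5] <- pcs[, 5] + ifelse(country == "NOR", 2.5, 0)
  pcs[, 7] <- pcs[, 7] + cfg@confound[["pc7Case"]] * is_case
  lrrsd <- exp(rnorm(n, log(0.09), 0.20)) * lrrsdScale
  abs_wf <- exp(rnorm(n, log(0.005), 0.30))
  baf_drift <- exp(rnorm(n, log(1.5e-4), 0.40))
  outlier <- runif(n) < cfg@outlierFraction
  lrrsd[outlier] <- lrrsd[outlier] * 3
  abs_wf[outlier] <- abs_wf[outlier] * 5
  baf_drift[outlier] <- baf_drift[outlier] * 10
  out <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    is_case = is_case, dataset = dataset, country = country, sex = sex,
    lrrsd = lrrsd, abs_wf = abs_wf, baf_drift = baf_drift,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pcs))
  out$prs_height <- rnorm(n)
  out$prs_ocd <- rnorm(n)
  out$prs_crossdis <- rnorm(n)
  for (cc in c("asd", "adhd", "tics", "scz", "bd"))
    out[[cc]] <- NA_integer_
  out$ybocs_pre <- NA_real_
  out$ybocs_post <- NA_real_
  out$sim_outlier <- outlier
  out
}

## chromosome arm spans outside the telomere/centromere exclusion zones
.armRanges <- function(cfg) {
  g <- cfg@genome
  len <- g$chromLenBp
  chroms <- paste0("chr", seq_len(g$nChrom))
  centro_lo <- len / 2 - 1e6
  centro_hi <- len / 2 + 1e6
  GRanges(rep(chroms, each = 2),
          IRanges(rep(c(6e5 + 1, centro_hi + 1), g$nChrom),
                  rep(c(centro_lo - 1, len - 6e5), g$nChrom)))
}

## draw n intervals with lengths in lenRange uniformly inside arms,
## rejecting overlap with 'avoid'; returns a GRanges
.placeIntervals <- function(n, lenRange, arms, avoid = NULL,
                            maxTries = 40L) {
  if (n == 0)
    return(GRanges())
  armw <- as.numeric(width(arms))
  placed <- GRanges()
  need <- n
  for (t in seq_len(maxTries)) {
    len <- round(exp(runif(need, log(lenRange[1]), log(lenRange[2]))))
    a <- sample(length(arms), need, replace = TRUE, prob = armw)
    maxoff <- pmax(armw[a] - len, 1)
    s <- start(arms)[a] + floor(runif(need) * maxoff)
    cand <- GRanges(seqnames(arms)[a], IRanges(s, s + len - 1))
    bad <- rep(FALSE, length(cand))
    if (!is.null(avoid) && length(avoid))
      bad <- bad | overlapsAny(cand, avoid)
    if (length(placed))
      bad <- bad | overlapsAny(cand, placed)
    cand <- cand[!bad]
    if (length(cand) > 1)  # drop within-batch mutual overlaps
      cand <- cand[countOverlaps(cand, cand) == 1L]
    placed <- c(placed, cand)
    need <- n - length(placed)
    if (need <= 0) break
  }
  placed[seq_len(min(n, length(placed)))]
}

#' Generate the toy-genome annotation
#'
#' Builds the probe grid, non-overlapping gene models with U-shaped pLI and
#' random gene-set flags, the region masks used by the filter cascade
#' (telomere/centromere buffers, polyN, segmental duplications, repeats,
#' TCR/immunoglobulin regions, cell-line artifact loci), a gene-anchored
#' constraint-score track, the external frequency reference listing the
#' planted common loci at over 1 percent, and the planted common and rare
#' recurrent locus table.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return A list with elements \code{probeMap}, \code{genes},
#'   \code{masks} (named list of \code{RegionSet}), \code{constraint},
#'   \code{freqRef} and \code{loci}.
#' @export
generateAnnotation <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed + 1L)
  g <- cfg@genome
  len <- g$chromLenBp
  chroms <- paste0("chr", seq_len(g$nChrom))

  spacing <- floor(g$nChrom * len / g$nProbes)
  pos <- seq(floor(spacing / 2), len, by = spacing)
  probe_gr <- GRanges(rep(chroms, each = length(pos)),
                      IRanges(rep(pos, g$nChrom), width = 1))
  mcols(probe_gr)$probe_id <- sprintf("P%06d", seq_along(probe_gr))

  ## genes: evenly slotted inside arms, non-overlapping by construction
  arms <- .armRanges(cfg)
  armw <- as.numeric(width(arms))
  gene_per_arm <- floor(g$nGenes * armw / sum(armw))
  gene_per_arm[seq_len(g$nGenes - sum(gene_per_arm))] <-
    gene_per_arm[seq_len(g$nGenes - sum(gene_per_arm))] + 1L
  gl <- list()
  for (i in seq_along(arms)) {
    k <- gene_per_arm[i]
    if (!k) next
    slot <- floor(armw[i] / k)
    glen <- round(runif(k, g$geneLenRange[1],
                        min(g$geneLenRange[2], slot - 100)))
    off <- floor(runif(k) * (slot - glen - 1))
    s <- start(arms)[i] + (seq_len(k) - 1L) * slot + off
    gl[[i]] <- GRanges(seqnames(arms)[i], IRanges(s, s + glen - 1))
  }
  gene_gr <- BiocGenerics::sort(do.call(c, unname(gl[lengths(gl) > 0])))
  ng <- length(gene_gr)
  pli <- rbeta(ng, 0.2, 0.2)
  genes <- RegionSet(as.character(seqnames(gene_gr)), start(gene_gr),
                     end(gene_gr), name = "genes",
                     gene_id = sprintf("G%04d", seq_len(ng)), pli = pli,
                     ndd_kendall = runif(ng) < 0.03,
                     ndd_fu = runif(ng) < 0.035,
                     haplosensitive = runif(ng) < 0.05,
                     triplosensitive = runif(ng) < 0.05)

  ## masks
  ms <- g$maskScale
  masks <- list()
  if (ms > 0) {
    telo <- GRanges(rep(chroms, each = 2),
                    IRanges(rep(c(1, len - 5e5 + 1), g$nChrom),
                            rep(c(5e5, len), g$nChrom)))
    centro <- GRanges(chroms, IRanges(len / 2 - 1e6, len / 2 + 1e6))
    masks$telomere <- new("RegionSet", BiocGenerics::sort(telo),
                          regionName = "telomere")
    masks$centromere <- new("RegionSet", BiocGenerics::sort(centro),
                            regionName = "centromere")
    mask_plan <- list(polyN = list(20, c(5e4, 2e5)),
                      segdup = list(40, c(5e4, 3e5)),
                      repeats = list(60, c(2e4, 1e5)),
                      tcr_ig = list(4, c(1e5, 5e5)),
                      lcl_artifact = list(3, c(1e5, 3e5)))
    avoid <- granges(genes)
    for (nm in names(mask_plan)) {
      k <- max(0L, round(mask_plan[[nm]][[1]] * ms))
      gr <- .placeIntervals(k, mask_plan[[nm]][[2]], arms, avoid)
      masks[[nm]] <- new("RegionSet", BiocGenerics::sort(gr),
                         regionName = nm)
      avoid <- c(avoid, granges(gr))
    }
    mask_bp <- sum(width(GenomicRanges::reduce(
      do.call(c, unname(lapply(masks, granges))))))
    if (mask_bp > 0.9 * g$nChrom * len)
      stop("masks would cover more than 90% of the genome")
  } else {
    for (nm in c("telomere", "centromere", "polyN", "segdup", "repeats",
                 "tcr_ig", "lcl_artifact"))
      masks[[nm]] <- RegionSet(name = nm)
  }
  mask_union <- if (length(masks))
    GenomicRanges::reduce(do.call(c, unname(lapply(masks, granges))))
  else GRanges()

  ## constraint track: conserved elements concentrated inside genes
  ncon <- g$nConstraintPerGene
  con <- list()
  if (ncon > 0) {
    idx <- rep(seq_len(ng), each = ncon)
    clen <- round(runif(length(idx), 1e3, 5e3))
    gs <- start(gene_gr)[idx]
    gw <- width(gene_gr)[idx]
    clen <- pmin(clen, gw)
    cs <- gs + floor(runif(length(idx)) * pmax(gw - clen, 1))
    con$genic <- GRanges(seqnames(gene_gr)[idx],
                         IRanges(cs, cs + clen - 1),
                         score = rgamma(length(idx), 2, scale = 1.5))
  }
  inter <- .placeIntervals(max(1L, ng %/% 4L), c(1e3, 3e3), arms,
                           c(granges(genes), mask_union))
  if (length(inter))
    mcols(inter)$score <- rgamma(length(inter), 2, scale = 1.0)
  con$intergenic <- inter
  con_gr <- do.call(c, unname(con))
  constraint <- RegionSet(as.character(seqnames(con_gr)), start(con_gr),
                          end(con_gr), name = "constraint",
                          score = round(mcols(con_gr)$score, 3))

  ## planted common and rare recurrent loci (outside masks)
  avoid_loci <- mask_union
  common_gr <- .placeIntervals(g$nCommonLoci, c(1e5, 3e5), arms, avoid_loci)
  n_common <- length(common_gr)
  common <- data.frame(
    locus_id = sprintf("CL%02d", seq_len(n_common)),
    chrom = as.character(seqnames(common_gr)),
    start = start(common_gr), end = end(common_gr),
    type = sample(c("del", "dup"), n_common, replace = TRUE),
    rate = runif(n_common, 0.015, 0.04),
    class = "common", stringsAsFactors = FALSE)
  avoid_loci <- c(avoid_loci, granges(common_gr))
  nrec <- g$nRecurrentLoci
  n_small <- ceiling(nrec / 2)
  rec_small <- .placeIntervals(n_small, c(6e4, 9e4), arms, avoid_loci)
  avoid_loci <- c(avoid_loci, granges(rec_small))
  rec_big <- .placeIntervals(nrec - n_small, c(1e5, 5e5), arms, avoid_loci)
  rec_gr <- c(rec_small, rec_big)
  nrec <- length(rec_gr)
  recurrent <- data.frame(
    locus_id = sprintf("RL%02d", seq_len(nrec)),
    chrom = as.character(seqnames(rec_gr)),
    start = start(rec_gr), end = end(rec_gr),
    type = c(rep("del", length(rec_small)),
             sample(c("del", "dup"), length(rec_big), replace = TRUE)),
    rate = cfg@cnv$recurrentCarrierRate,
    class = "recurrent", stringsAsFactors = FALSE)
  loci <- rbind(common, recurrent)

  ## external frequency reference: common loci plus sub-threshold records
  rare_ref <- .placeIntervals(20L, c(5e4, 5e5), arms, NULL)
  freqRef <- rbind(
    data.frame(chrom = common$chrom, start = common$start,
               end = common$end, cnv_type = common$type,
               freq_global = round(pmax(common$rate * runif(n_common, 0.8,
                                                            1.5), 0.012), 4),
               stringsAsFactors = FALSE),
    data.frame(chrom = as.character(seqnames(rare_ref)),
               start = start(rare_ref), end = end(rare_ref),
               cnv_type = sample(c("del", "dup"), length(rare_ref),
                                 replace = TRUE),
               freq_global = round(runif(length(rare_ref), 0.001, 0.009), 4),
               stringsAsFactors = FALSE))
  freqRef$freq_subpop_1 <- round(freqRef$freq_global *
                                   runif(nrow(freqRef), 0.5, 1.5), 4)
  freqRef$freq_subpop_2 <- round(freqRef$freq_global *
                                   runif(nrow(freqRef), 0.5, 1.5), 4)

  list(probeMap = ProbeMap(probe_gr), genes = genes, masks = masks,
       constraint = constraint, freqRef = freqRef, loci = loci,
       arms = arms, spacing = spacing)
}

## carrier probability in cases implied by a control rate p0 and odds ratio
.caseRate <- function(p0, logOR) {
  psi <- exp(logOR)
  p0 * psi / (1 - p0 + p0 * psi)
}

#' Expected case excess implied by a configuration
#'
#' Total expected extra calls per case: the configured
#' \code{excessCallsPerCase} is the generative truth; the planted carrier
#' classes account for \code{sum(p1 - p0)} of it and extra background calls
#' supply the remainder.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return A list with \code{total}, \code{carrierDelta} and
#'   \code{extraBackground} (all expected calls per case).
#' @export
expectedExcess <- function(cfg) {
  p0 <- cfg@carrierBaseRates[names(cfg@effects)]
  p1 <- .caseRate(p0, cfg@effects)
  delta <- sum(p1 - p0)
  extra <- cfg@excessCallsPerCase - delta
  if (extra < -1e-12)
    stop("excessCallsPerCase (", cfg@excessCallsPerCase,
         ") is smaller than the planted carrier excess (",
         round(delta, 4), ")")
  list(total = cfg@excessCallsPerCase, carrierDelta = delta,
       extraBackground = max(extra, 0))
}

#' Generate the two CNV callsets and probe-level signal
#'
#' Places background CNVs uniformly outside the masks at a per-sample
#' Poisson rate (modulated by the configured LRRSD/PC7 call-rate
#' confounds, plus the extra case background implied by
#' \code{\link{expectedExcess}}), carriers at the planted common and rare
#' recurrent loci, risk CNVs (deletions of high-pLI genes, NDD-gene
#' deletions/duplications) with case/control carrier probabilities that
#' make each planted log odds ratio the true generative parameter, the
#' optional single-batch artifact calls, and a configurable fraction of
#' "false" calls whose underlying state is diploid. Every true CNV is
#' emitted into both callsets with independent boundary jitter and dropped
#' from a callset with the batch's caller-noise probability. Probe-level
#' BAF/LRR signal is emitted for each call site (plus a jitter-wide flank)
#' consistent with the true copy state.
#'
#' @param cohort sample sheet from \code{\link{generateCohort}}.
#' @param annot annotation from \code{\link{generateAnnotation}}.
#' @param cfg the \code{\link{simConfig}}.
#' @param signal emit probe-level BAF/LRR signal (skip for experiments
#'   that only consume the truth table and callsets).
#' @return A list with \code{callsA}, \code{callsB} (both
#'   \code{\link{CnvCalls}}), \code{probeMap} (signal-bearing
#'   \code{\link{ProbeMap}}) and a \code{truth} data.frame (one row per
#'   true CNV: interval, reported copy state, true copy number, class,
#'   carrier).
#' @export
generateCnvCalls <- function(cohort, annot, cfg, signal = TRUE) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed + 2L)
  cnvp <- cfg@cnv
  n <- nrow(cohort)
  genes <- annot$genes
  arms <- annot$arms
  mask_union <- GenomicRanges::reduce(
    do.call(c, unname(lapply(annot$masks, granges))))

  truth <- list()

  ## -- background calls (uniform, outside masks) --
  ex <- expectedExcess(cfg)
  zl <- as.numeric(scale(log(cohort$lrrsd)))
  mult <- exp(cfg@confound[["lrrsdCalls"]] * zl +
              cfg@confound[["pc7Calls"]] * cohort$PC7)
  lam <- cnvp$backgroundRate * mult + ex$extraBackground * cohort$is_case
  nbg <- rpois(n, lam)
  if (sum(nbg)) {
    who <- rep(seq_len(n), nbg)
    loci_gr <- if (nrow(annot$loci))
      GRanges(annot$loci$chrom, IRanges(annot$loci$start, annot$loci$end))
    else GRanges()
    gr <- .placeBackground(sum(nbg), cnvp$backgroundSizeRange, arms,
                           mask_union, loci_gr)
    who <- who[seq_along(gr)]
    isdel <- runif(length(gr)) < cnvp$delFraction
    cs <- ifelse(isdel, ifelse(runif(length(gr)) < 0.9, 1L, 0L),
                 ifelse(runif(length(gr)) < 0.9, 3L, 4L))
    false <- runif(length(gr)) < cnvp$falseCallFraction
    truth$background <- data.frame(
      sample_id = cohort$sample_id[who],
      chrom = as.character(seqnames(gr)), start = start(gr), end = end(gr),
      copy_state = cs, true_cn = ifelse(false, 2L, cs),
      class = ifelse(false, "false", "background"),
      stringsAsFactors = FALSE)
  }

  ## -- planted common and recurrent loci --
  loci <- annot$loci
  if (nrow(loci)) {
    rows <- list()
    for (i in seq_len(nrow(loci))) {
      carrier <- which(runif(n) < loci$rate[i])
      if (!length(carrier)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = cohort$sample_id[carrier],
        chrom = loci$chrom[i], start = loci$start[i], end = loci$end[i],
        copy_state = ifelse(loci$type[i] == "del", 1L, 3L),
        true_cn = ifelse(loci$type[i] == "del", 1L, 3L),
        class = loci$class[i], stringsAsFactors = FALSE)
    }
    if (length(rows)) truth$loci <- do.call(rbind, rows)
  }

  ## -- mask-artifact calls: placed fully inside a masked interval --
  if (cnvp$maskArtifactRate > 0 && length(mask_union)) {
    big <- mask_union[width(mask_union) >= 5e4]
    if (length(big)) {
      nart <- rpois(n, cnvp$maskArtifactRate)
      who <- rep(seq_len(n), nart)
      if (length(who)) {
        mi <- sample(length(big), length(who), replace = TRUE,
                     prob = as.numeric(width(big)))
        mlen <- width(big)[mi]
        alen <- pmax(45000, floor(mlen * runif(length(who), 0.6, 1)))
        alen <- pmin(alen, mlen)
        off <- floor(runif(length(who)) * (mlen - alen + 1))
        isdel <- runif(length(who)) < 0.5
        truth$mask_artifact <- data.frame(
          sample_id = cohort$sample_id[who],
          chrom = as.character(seqnames(big))[mi],
          start = start(big)[mi] + off,
          end = start(big)[mi] + off + alen - 1,
          copy_state = ifelse(isdel, 1L, 3L),
          true_cn = ifelse(isdel, 1L, 3L),
          class = "mask_artifact", stringsAsFactors = FALSE)
      }
    }
  }

  ## -- planted risk CNVs --
  pli <- mcols(genes)$pli
  ndd <- mcols(genes)$ndd_kendall | mcols(genes)$ndd_fu
  eligible <- list(del_highpli = which(pli > 0.995),
                   ndd_del = which(ndd), ndd_dup = which(ndd))
  for (m in names(cfg@effects)) {
    p0 <- cfg@carrierBaseRates[[m]]
    if (p0 <= 0) next
    p1 <- .caseRate(p0, cfg@effects[[m]])
    el <- eligible[[m]]
    if (!length(el))
      stop("planted effect '", m, "' has no eligible genes")
    pcar <- ifelse(cohort$is_case, p1, p0)
    carrier <- which(runif(n) < pcar)
    if (!length(carrier)) next
    gidx <- el[sample.int(length(el), length(carrier), replace = TRUE)]
    gs <- start(genes)[gidx]; ge <- end(genes)[gidx]
    pad <- pmax(1e4, ceiling((6e4 - (ge - gs + 1)) / 2))
    cs <- if (grepl("dup", m)) 3L else 1L
    truth[[m]] <- data.frame(
      sample_id = cohort$sample_id[carrier],
      chrom = as.character(seqnames(genes))[gidx],
      start = pmax(gs - pad, 1), end = ge + pad,
      copy_state = cs, true_cn = cs, class = paste0("risk_", m),
      stringsAsFactors = FALSE)
  }

  ## -- single-batch artifact calls --
  ba <- cnvp$batchArtifact
  if (!is.null(ba)) {
    in_ds <- which(cohort$dataset == ba$dataset)
    if (!length(in_ds))
      stop("batch artifact dataset '", ba$dataset, "' has no samples")
    loci_gr <- if (nrow(annot$loci))
      GRanges(annot$loci$chrom, IRanges(annot$loci$start, annot$loci$end))
    else GRanges()
    art_gr <- .placeIntervals(ba$nLoci, ba$sizeRange, arms,
                              c(mask_union, loci_gr))
    per <- rep(ba$nCalls %/% ba$nLoci, ba$nLoci)
    extra <- ba$nCalls - sum(per)
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    rows <- list()
    for (i in seq_along(art_gr)) {
      carrier <- sample(in_ds, min(per[i], length(in_ds)))
      rows[[i]] <- data.frame(
        sample_id = cohort$sample_id[carrier],
        chrom = as.character(seqnames(art_gr))[i],
        start = start(art_gr)[i], end = end(art_gr)[i],
        copy_state = 1L, true_cn = 1L, class = "artifact",
        stringsAsFactors = FALSE)
    }
    truth$artifact <- do.call(rbind, rows)
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  if (is.null(truth) || !nrow(truth)) {
    pm <- annot$probeMap
    return(list(callsA = CnvCalls(caller = "A"),
                callsB = CnvCalls(caller = "B"),
                probeMap = pm,
                truth = data.frame()))
  }
  truth$uid <- sprintf("C%06d", seq_len(nrow(truth)))

  ## -- emit the two jittered callsets --
  probes <- annot$probeMap@probes
  spacing <- annot$spacing
  noise <- cfg@datasets$callerNoise[
    match(cohort$dataset[match(truth$sample_id, cohort$sample_id)],
          cfg@datasets$name)]
  J <- cnvp$jitterProbes
  mk_callset <- function(label) {
    keep <- runif(nrow(truth)) >= noise
    tt <- truth[keep, , drop = FALSE]
    if (!nrow(tt))
      return(CnvCalls(caller = label))
    j1 <- sample(seq(-J, J), nrow(tt), replace = TRUE) * spacing
    j2 <- sample(seq(-J, J), nrow(tt), replace = TRUE) * spacing
    s <- pmax(tt$start + j1, 1)
    e <- tt$end + j2
    bad <- e - s + 1 < 2 * spacing
    s[bad] <- tt$start[bad]; e[bad] <- tt$end[bad]
    gr <- GRanges(tt$chrom, IRanges(s, e))
    np <- countOverlaps(gr, probes)
    ok <- np >= 1L
    CnvCalls(tt$chrom[ok], s[ok], e[ok], tt$sample_id[ok],
             tt$copy_state[ok], np[ok], caller = label, uid = tt$uid[ok])
  }
  callsA <- mk_callset("A")
  callsB <- mk_callset("B")

  if (!signal)
    return(list(callsA = callsA, callsB = callsB,
                probeMap = annot$probeMap, truth = truth))

  ## -- probe-level signal at call sites (+ jitter-wide flank) --
  flank <- J * spacing
  site <- GRanges(truth$chrom, IRanges(pmax(truth$start - flank, 1),
                                       truth$end + flank))
  ov <- findOverlaps(site, probes)
  ci <- queryHits(ov); pi <- subjectHits(ov)
  ppos <- start(probes)[pi]
  inside <- ppos >= truth$start[ci] & ppos <= truth$end[ci]
  cn <- ifelse(inside, truth$true_cn[ci], 2L)
  nb <- length(cn)
  geno <- rbinom(nb, pmax(cn, 1L), 0.5)
  baf_mean <- ifelse(cn == 0L, rbinom(nb, 1L, 0.5),
                     geno / pmax(cn, 1L))
  baf <- pmin(pmax(baf_mean + rnorm(nb, 0, cnvp$bafSigma), 0), 1)
  lrr_mu <- c(`0` = -3.5, `1` = -0.6, `2` = 0, `3` = 0.4, `4` = 0.75)
  lrr <- lrr_mu[as.character(cn)] + rnorm(nb, 0, 0.2)
  sig <- data.frame(sample_id = truth$sample_id[ci],
                    probe_id = mcols(probes)$probe_id[pi],
                    chrom = as.character(seqnames(probes))[pi],
                    pos = ppos, lrr = round(lrr, 4), baf = round(baf, 4),
                    stringsAsFactors = FALSE)
  dup <- duplicated(paste(sig$sample_id, sig$probe_id))
  sig <- sig[!dup, , drop = FALSE]

  list(callsA = callsA, callsB = callsB,
       probeMap = ProbeMap(probes, sig), truth = truth)
}

## background placement with mask-fraction rejection (a handful of rounds;
## accepted calls overlap the mask union by at most the removal threshold)
.placeBackground <- function(nn, sizeRange, arms, mask_union,
                             avoid = GRanges()) {
  armw <- as.numeric(width(arms))
  out <- NULL
  need <- nn
  for (t in 1:20) {
    len <- round(exp(runif(need, log(sizeRange[1]), log(sizeRange[2]))))
    a <- sample(length(arms), need, replace = TRUE, prob = armw)
    maxoff <- pmax(armw[a] - len, 1)
    s <- start(arms)[a] + floor(runif(need) * maxoff)
    cand <- GRanges(seqnames(arms)[a], IRanges(s, s + len - 1))
    frac <- if (length(mask_union))
      coveredBp(cand, mask_union) / as.numeric(width(cand))
    else numeric(length(cand))
    bad <- frac > 0.25
    if (length(avoid)) bad <- bad | overlapsAny(cand, avoid)
    ok <- cand[!bad]
    out <- if (is.null(out)) ok else c(out, ok)
    need <- nn - length(out)
    if (need <= 0) break
  }
  out[seq_len(min(nn, length(out)))]
}

#' Truth-based carrier flags
#'
#' @param truth truth table from \code{\link{generateCnvCalls}}.
#' @param samples the sample sheet.
#' @return A \code{data.frame} with logical columns \code{del_highpli},
#'   \code{ndd_del}, \code{ndd_dup} and \code{deleterious_del}
#'   (high-pLI or NDD deletion).
#' @export
truthCarrierFlags <- function(truth, samples) {
  has <- function(cls) samples$sample_id %in%
    truth$sample_id[truth$class == cls]
  data.frame(sample_id = samples$sample_id,
             del_highpli = has("risk_del_highpli"),
             ndd_del = has("risk_ndd_del"),
             ndd_dup = has("risk_ndd_dup"),
             deleterious_del = has("risk_del_highpli") | has("risk_ndd_del"),
             stringsAsFactors = FALSE)
}

#' Fill in clinical phenotypes
#'
#' Comorbidity flags are drawn for cases with the configured base rates;
#' the ASD rate in NDD-duplication carriers follows the planted odds ratio.
#' YBOCS (symptom-severity) scores are drawn so that percent improvement
#' under treatment is shifted by \code{ybocsDelShift} percentage points in
#' NDD-deletion carriers. The cross-disorder polygenic score is shifted by
#' \code{prsDelShift} SD in case carriers of deleterious deletions.
#'
#' @param cohort sample sheet.
#' @param carriers carrier flags (see \code{\link{truthCarrierFlags}}).
#' @param cfg the \code{\link{simConfig}}.
#' @return The cohort with clinical columns filled for cases.
#' @export
generateClinical <- function(cohort, carriers, cfg) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed + 3L)
  k <- cfg@clinical
  idx <- match(cohort$sample_id, carriers$sample_id)
  ndd_dup <- carriers$ndd_dup[idx]
  ndd_del <- carriers$ndd_del[idx]
  del_bad <- carriers$deleterious_del[idx]
  case <- cohort$is_case
  ncase <- sum(case)
  if (k$asdBaseRate > 0 && ncase > 0 && ncase * k$asdBaseRate < 1)
    stop("requested ASD prevalence incompatible with cohort size")
  p_asd <- ifelse(ndd_dup, .caseRate(k$asdBaseRate, log(k$asdDupOR)),
                  k$asdBaseRate)
  draw <- function(p) ifelse(case, as.integer(runif(nrow(cohort)) < p), NA)
  cohort$asd <- draw(p_asd)
  cohort$adhd <- draw(k$adhdBaseRate)
  cohort$tics <- draw(k$ticsBaseRate)
  cohort$scz <- draw(k$sczBaseRate)
  cohort$bd <- draw(k$bdBaseRate)
  pre <- pmin(pmax(round(rnorm(nrow(cohort), 25, 5)), 10), 40)
  imp <- rnorm(nrow(cohort), k$ybocsImproveMean, k$ybocsImproveSd) +
    k$ybocsDelShift * ndd_del
  imp <- pmin(imp, 100)
  post <- pmin(pmax(round(pre * (1 - imp / 100)), 0), 40)
  cohort$ybocs_pre <- ifelse(case, pre, NA_real_)
  cohort$ybocs_post <- ifelse(case, post, NA_real_)
  cohort$prs_crossdis <- cohort$prs_crossdis +
    k$prsDelShift * (case & del_bad)
  cohort
}

#' Simulate a complete study
#'
#' Runs \code{\link{generateCohort}}, \code{\link{generateAnnotation}},
#' \code{\link{generateCnvCalls}} and \code{\link{generateClinical}} and
#' optionally writes every input file of the pipeline (sample sheet, two
#' call files, mask BEDs, gene/constraint/frequency tables) plus the truth
#' table to a directory.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param dir optional output directory.
#' @return A list: \code{samples}, \code{annotation}, \code{callsA},
#'   \code{callsB}, \code{probeMap}, \code{truth}, \code{carriers}.
#' @export
simulateStudy <- function(cfg, dir = NULL) {
  cohort <- generateCohort(cfg)
  annot <- generateAnnotation(cfg)
  calls <- generateCnvCalls(cohort, annot, cfg)
  carriers <- truthCarrierFlags(calls$truth, cohort)
  cohort <- generateClinical(cohort, carriers, cfg)
  out <- list(samples = cohort, annotation = annot,
              callsA = calls$callsA, callsB = calls$callsB,
              probeMap = calls$probeMap, truth = calls$truth,
              carriers = carriers)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeSampleSheet(cohort, file.path(dir, "samples.tsv"))
    writeCnvCalls(calls$callsA, file.path(dir, "calls_A.tsv"))
    writeCnvCalls(calls$callsB, file.path(dir, "calls_B.tsv"))
    for (nm in names(annot$masks))
      writeBedRegions(annot$masks[[nm]],
                      file.path(dir, paste0("mask_", nm, ".bed")))
    writeGeneAnnotation(annot$genes, file.path(dir, "genes.tsv"))
    write.table(as.data.frame(annot$constraint)[
      c("seqnames", "start", "end", "score")],
      file.path(dir, "constraint.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = c("chrom", "start", "end", "score"))
    write.table(annot$freqRef, file.path(dir, "freq_reference.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(calls$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
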