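#' @importFrom stats dhyper qchisq median
NULL

STRATUM_LEVELS <- c("SWE.M", "SWE.F", "NOR.M", "NOR.F")

#' Analysis stratum of each sample
#'
#' The four case/control comparison groups: Swedish male, Swedish female,
#' Norwegian male, Norwegian female.
#'
#' @param samples sample sheet with \code{country} and \code{sex}.
#' @return A factor with the four stratum levels.
#' @export
stratumOf <- function(samples) {
  factor(paste(samples$country, samples$sex, sep = "."),
         levels = STRATUM_LEVELS)
}

#' Per-stratum 2x2 carrier/case counts
#'
#' @param carriers character vector of carrier sample ids (a sample counts
#'   at most once).
#' @param samples sample sheet.
#' @return Integer matrix, one row per stratum, columns
#'   \code{case_carrier}, \code{case_non}, \code{control_carrier},
#'   \code{control_non}.
#' @export
stratumCounts <- function(carriers, samples) {
  carriers <- unique(carriers)
  st <- stratumOf(samples)
  isc <- samples$is_case
  carr <- samples$sample_id %in% carriers
  out <- matrix(0L, nlevels(st), 4L,
                dimnames = list(levels(st),
                                c("case_carrier", "case_non",
                                  "control_carrier", "control_non")))
  for (s in levels(st)) {
    i <- st == s
    out[s, ] <- c(sum(carr & isc & i), sum(!carr & isc & i),
                  sum(carr & !isc & i), sum(!carr & !isc & i))
  }
  out
}

## exact conditional null of S = total case carriers over strata:
## convolution of per-stratum central hypergeometric pmfs.
## counts: matrix as produced by stratumCounts.
.cmhNullPmf <- function(counts) {
  pmf <- 1
  for (s in seq_len(nrow(counts))) {
    a <- counts[s, 1]; b <- counts[s, 2]
    c_ <- counts[s, 3]; d <- counts[s, 4]
    m <- a + c_          # carriers in stratum
    k <- a + b           # cases in stratum
    n <- a + b + c_ + d
    if (m == 0L || k == 0L || n == 0L) next
    hi <- min(m, k)
    ps <- dhyper(0:hi, m, n - m, k)
    new <- numeric(length(pmf) + hi)
    for (x in 0:hi)
      new[seq_along(pmf) + x] <- new[seq_along(pmf) + x] + pmf * ps[x + 1]
    pmf <- new
  }
  if (length(pmf) == 1L) pmf <- c(1)
  pmf / sum(pmf)
}

## two-sided minimum-likelihood p for each possible S under pmf
.minlikeP <- function(pmf) {
  vapply(seq_along(pmf), function(i)
    sum(pmf[pmf <= pmf[i] * (1 + 1e-7)]), numeric(1))
}

#' Stratified exact Cochran-Mantel-Haenszel test
#'
#' Exact conditional test of carrier status against case status across
#' strata with fixed per-stratum margins. The statistic is the total
#' number of case carriers summed over strata; its null distribution is
#' the convolution of per-stratum central hypergeometric distributions,
#' and the two-sided p-value follows the minimum-likelihood rule (the sum
#' of probabilities of all outcomes no more likely than the observed one),
#' matching the convention of the two-sided Fisher exact test. The
#' reported common odds ratio is the Mantel-Haenszel estimate.
#'
#' @param counts per-stratum counts from \code{\link{stratumCounts}}.
#' @return A list: \code{p_value}, \code{odds_ratio} (possibly infinite),
#'   \code{S_obs}, and \code{degenerate} (no carriers at all: p = 1, odds
#'   ratio undefined).
#' @export
cmhExactTest <- function(counts) {
  a <- counts[, 1]; b <- counts[, 2]; c_ <- counts[, 3]; d <- counts[, 4]
  if (sum(a + c_) == 0L)
    return(list(p_value = 1, odds_ratio = NA_real_, S_obs = 0L,
                degenerate = TRUE))
  pmf <- .cmhNullPmf(counts)
  S <- sum(a)
  pv <- .minlikeP(pmf)
  n <- a + b + c_ + d
  num <- sum(ifelse(n > 0, a * d / n, 0))
  den <- sum(ifelse(n > 0, b * c_ / n, 0))
  or <- if (den == 0 && num == 0) NA_real_
        else if (den == 0) Inf else num / den
  list(p_value = min(pv[S + 1L], 1), odds_ratio = or, S_obs = S,
       degenerate = FALSE)
}

## >50% co-impact clumping shared by gene- and probe-based units.
## elements: GRanges ordered along the genome; callsets: list of integer
## call-id vectors per element. Adjacent elements (consecutive in the
## given order, same chrom, adjacency allowed by `adjacent`) merge iff
## |calls hitting both| / |calls hitting either| > 0.5, transitively.
.clumpElements <- function(elements, callsets, adjacent) {
  n <- length(callsets)
  grp <- integer(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (i > 1L && adjacent[i - 1L]) {
      A <- callsets[[i - 1L]]; B <- callsets[[i]]
      u <- length(union(A, B))
      if (u > 0 && length(intersect(A, B)) / u > 0.5) {
        grp[i] <- grp[i - 1L]
        next
      }
    }
    g <- g + 1L
    grp[i] <- g
  }
  grp
}

.unitsFromGroups <- function(elements, callsets, grp, calls, kind,
                             member_ids, samples) {
  keep_grp <- unique(grp[lengths(callsets) > 0L])
  units <- lapply(keep_grp, function(gg) {
    ii <- which(grp == gg)
    cid <- sort(unique(unlist(callsets[ii])))
    carriers <- unique(sampleIds(calls)[cid])
    list(unit_id = NA_character_, kind = kind,
         chrom = as.character(seqnames(elements))[ii[1]],
         start = min(start(elements)[ii]), end = max(end(elements)[ii]),
         members = member_ids[ii], carriers = carriers,
         n_calls = length(cid))
  })
  for (i in seq_along(units))
    units[[i]]$unit_id <- sprintf("%s_%03d", kind, i)
  units
}

#' Clump genes into association test units
#'
#' One pass per CNV direction. Neighboring genes along a chromosome merge
#' into a single unit when more than half of the calls overlapping either
#' gene overlap both; merging is transitive along genomic order. Genes
#' with no overlapping call are dropped (and interrupt merging). Each
#' unit's carriers are the distinct samples with a call overlapping any
#' member gene.
#'
#' @param calls analysis-ready \code{\link{CnvCalls}}.
#' @param genes gene \code{\link{RegionSet}}.
#' @param type \code{"del"} or \code{"dup"}.
#' @return A list of test units (see \code{\link{assocTests}}).
#' @export
clumpGeneUnits <- function(calls, genes, type = c("del", "dup")) {
  type <- match.arg(type)
  calls_t <- calls[cnvType(calls) == type]
  ord <- order(as.integer(seqnames(genes)), start(genes), end(genes))
  genes <- genes[ord]
  ov <- findOverlaps(granges(genes), granges(calls_t))
  callsets <- vector("list", length(genes))
  for (i in seq_along(callsets)) callsets[[i]] <- integer()
  spl <- split(subjectHits(ov), queryHits(ov))
  callsets[as.integer(names(spl))] <- spl
  chrom <- as.character(seqnames(genes))
  adjacent <- chrom[-1] == chrom[-length(chrom)]
  grp <- .clumpElements(genes, callsets, adjacent)
  .unitsFromGroups(granges(genes), callsets, grp, calls_t,
                   paste0("gene_", type), mcols(genes)$gene_id, NULL)
}

#' Clump probes into breakpoint test units
#'
#' Same rule as \code{\link{clumpGeneUnits}} with array probes as the
#' elements: consecutive probes merge when more than half of the calls
#' covering either also cover both, so units delimit shared breakpoints.
#' Probes covered by no call are dropped and interrupt merging.
#'
#' @param calls analysis-ready \code{\link{CnvCalls}}.
#' @param probes probe \code{GRanges} (or \code{\link{ProbeMap}}).
#' @param type \code{"del"} or \code{"dup"}.
#' @return A list of test units.
#' @export
clumpProbeUnits <- function(calls, probes, type = c("del", "dup")) {
  type <- match.arg(type)
  if (is(probes, "ProbeMap")) probes <- probes@probes
  calls_t <- calls[cnvType(calls) == type]
  ov <- findOverlaps(probes, granges(calls_t))
  cov_idx <- sort(unique(queryHits(ov)))
  if (!length(cov_idx)) return(list())
  sub <- probes[cov_idx]
  spl <- split(subjectHits(ov), queryHits(ov))
  callsets <- unname(spl[as.character(cov_idx)])
  ## adjacency requires consecutive position in the full probe grid
  chrom <- as.character(seqnames(sub))
  adjacent <- diff(cov_idx) == 1L & chrom[-1] == chrom[-length(chrom)]
  grp <- .clumpElements(sub, callsets, adjacent)
  ids <- mcols(sub)$probe_id
  if (is.null(ids)) ids <- as.character(cov_idx)
  .unitsFromGroups(granges(sub), callsets, grp, calls_t,
                   paste0("probe_", type), ids, NULL)
}

#' Benjamini-Hochberg q-values
#'
#' @param p numeric p-values in \eqn{[0, 1]} (no missing values).
#' @return q-values: \eqn{q_i = \min_{j: p_{(j)} \ge p_{(i)}} m p_{(j)}/j},
#'   capped at 1.
#' @export
bhFdr <- function(p) {
  if (any(is.na(p))) stop("p-values must not be missing")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run stratified exact tests over units with FDR control
#'
#' @param units list of test units from \code{\link{clumpGeneUnits}} or
#'   \code{\link{clumpProbeUnits}}.
#' @param samples QC-pass sample sheet.
#' @return A \code{data.frame}: one row per unit with envelope, members,
#'   carrier counts by class, Mantel-Haenszel odds ratio, exact p and BH q.
#' @export
assocTests <- function(units, samples) {
  if (!length(units))
    return(data.frame(unit_id = character(), p_value = numeric(),
                      q_value = numeric()))
  rows <- lapply(units, function(u) {
    cnt <- stratumCounts(u$carriers, samples)
    res <- cmhExactTest(cnt)
    data.frame(unit_id = u$unit_id, kind = u$kind, chrom = u$chrom,
               start = u$start, end = u$end,
               members = paste(u$members, collapse = ","),
               n_case_carriers = sum(cnt[, "case_carrier"]),
               n_control_carriers = sum(cnt[, "control_carrier"]),
               odds_ratio = res$odds_ratio, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bhFdr(out$p_value)
  out
}

## permute case/control labels within each stratum, preserving per-stratum
## case counts; returns a logical matrix samples x nPerm
.permuteLabels <- function(samples, nPerm) {
  st <- stratumOf(samples)
  isc <- samples$is_case
  out <- matrix(FALSE, nrow(samples), nPerm)
  for (s in levels(st)) {
    idx <- which(st == s)
    k <- sum(isc[idx])
    if (!length(idx) || k == 0L) next
    for (b in seq_len(nPerm))
      out[idx[sample.int(length(idx), k)], b] <- TRUE
  }
  out
}

#' Permutation-based genomic inflation factor
#'
#' Each unit's exact p-value is converted to a 1-df chi-square quantile;
#' the inflation factor is the median observed quantile divided by the
#' median (over case/control label permutations within strata) of the
#' permuted median quantile. Normalizing by the permutation median rather
#' than the theoretical 0.456 accommodates the heavy discreteness of
#' rare-carrier exact p-values. Under margin-preserving permutation each
#' unit's conditional null distribution is unchanged, so permuted p-values
#' are obtained by lookup, making the estimate cheap and exact.
#'
#' @param units list of test units (each with a \code{carriers} element).
#' @param samples QC-pass sample sheet.
#' @param nPerm number of label permutations (at least 100 for reporting).
#' @param seed integer seed for reproducible permutations.
#' @return A list: \code{lambda}, \code{xObserved} (per-unit quantiles),
#'   \code{permMedians}, and \code{reliable} (\code{FALSE} with a warning
#'   when fewer than 10 units are available).
#' @export
permutationLambda <- function(units, samples, nPerm = 200L, seed = 1L) {
  reliable <- TRUE
  if (length(units) < 10L) {
    warning("fewer than 10 units: inflation estimate is unreliable")
    reliable <- FALSE
  }
  if (!length(units))
    return(list(lambda = NA_real_, xObserved = numeric(0),
                permMedians = numeric(0), reliable = FALSE))
  set.seed(seed)
  carrier_idx <- lapply(units, function(u)
    which(samples$sample_id %in% unique(u$carriers)))
  pLookup <- lapply(units, function(u)
    .minlikeP(.cmhNullPmf(stratumCounts(u$carriers, samples))))
  isc <- samples$is_case
  S_obs <- vapply(carrier_idx, function(ii) sum(isc[ii]), integer(1))
  p_obs <- vapply(seq_along(units), function(i)
    min(pLookup[[i]][S_obs[i] + 1L], 1), numeric(1))
  x_obs <- qchisq(1 - p_obs, df = 1)
  perm <- .permuteLabels(samples, nPerm)
  med_perm <- vapply(seq_len(nPerm), function(b) {
    pb <- perm[, b]
    xp <- vapply(seq_along(units), function(i) {
      S <- sum(pb[carrier_idx[[i]]])
      qchisq(1 - min(pLookup[[i]][S + 1L], 1), df = 1)
    }, numeric(1))
    median(xp)
  }, numeric(1))
  denom <- median(med_perm)
  lambda <- if (is.na(denom) || denom <= 0) NA_real_
            else median(x_obs) / denom
  list(lambda = lambda, xObserved = x_obs, permMedians = med_perm,
       reliable = reliable)
}

#' Case-recurrence permutation test
#'
#' Tests whether cases show an excess of CNV loci carried by at least two
#' distinct cases, beyond what case/control label permutation within
#' strata predicts. The statistic is the number of loci (reciprocal
#' overlap clusters) with two or more distinct case carriers of the given
#' direction; the p-value is \eqn{(1 + \#\{T_{perm} \ge T_{obs}\}) /
#' (1 + n_{perm})}.
#'
#' @param calls analysis-ready \code{\link{CnvCalls}}.
#' @param samples QC-pass sample sheet.
#' @param type \code{"del"} or \code{"dup"}.
#' @param nPerm number of permutations (at least 1,000 for reporting).
#' @param seed integer seed.
#' @param cfg \code{\link{filterConfig}} (for the clustering rule).
#' @return A list: \code{p_value}, \code{T_obs}, \code{T_perm}.
#' @export
recurrencePermutationTest <- function(calls, samples, type = c("del", "dup"),
                                      nPerm = 1000L, seed = 1L,
                                      cfg = filterConfig()) {
  type <- match.arg(type)
  calls_t <- calls[cnvType(calls) == type]
  if (!length(calls_t))
    return(list(p_value = 1, T_obs = 0L, T_perm = integer(0)))
  set.seed(seed)
  cc <- clusterCalls(calls_t, cfg)
  carrier_idx <- lapply(cc$clusters$carriers, function(ids)
    which(samples$sample_id %in% ids))
  isc <- samples$is_case
  T_obs <- sum(vapply(carrier_idx, function(ii) sum(isc[ii]),
                      integer(1)) >= 2L)
  perm <- .permuteLabels(samples, nPerm)
  T_perm <- vapply(seq_len(nPerm), function(b) {
    pb <- perm[, b]
    sum(vapply(carrier_idx, function(ii) sum(pb[ii]), integer(1)) >= 2L)
  }, integer(1))
  p <- (1 + sum(T_perm >= T_obs)) / (1 + nPerm)
  list(p_value = p, T_obs = T_obs, T_perm = T_perm)
}
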