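#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges granges seqnames start end width
#' @importFrom BiocGenerics sort
#' @importFrom GenomeInfoDb sortSeqlevels
NULL

VALID_COPY_STATES <- c(0L, 1L, 3L, 4L)
CALLER_LEVELS <- c("A", "B", "consensus")

#' CNV call set
#'
#' A \code{CnvCalls} object is a \code{GRanges} holding one CNV call per row,
#' in 1-based inclusive coordinates (the native convention of array CNV
#' callers), with the per-call metadata the pipeline requires: carrier sample,
#' integer copy state (2, the diploid state, is disallowed -- a call is by
#' definition non-diploid), supporting probe count, caller provenance and a
#' set of audit filter flags.
#'
#' @slot .Data inherited \code{GRanges} representation.
#' @name CnvCalls-class
#' @aliases CnvCalls-class
#' @exportClass CnvCalls
setClass("CnvCalls", contains = "GRanges")

.validCnvCalls <- function(object) {
  msg <- character()
  mc <- mcols(object)
  need <- c("sample_id", "copy_state", "n_probes", "caller", "filter_flags")
  missing_cols <- setdiff(need, colnames(mc))
  if (length(missing_cols))
    return(paste("missing metadata column(s):",
                 paste(missing_cols, collapse = ", ")))
  if (length(object)) {
    if (!all(mc$copy_state %in% VALID_COPY_STATES))
      msg <- c(msg, "copy_state must be one of 0, 1, 3, 4 (2 is not a call)")
    if (!all(mc$n_probes >= 1L))
      msg <- c(msg, "n_probes must be >= 1")
    if (!all(mc$caller %in% CALLER_LEVELS))
      msg <- c(msg, "caller must be one of 'A', 'B', 'consensus'")
    if (!is(mc$filter_flags, "CharacterList"))
      msg <- c(msg, "filter_flags must be a CharacterList")
    if (any(width(object) < 1L))
      msg <- c(msg, "calls must satisfy start <= end (length >= 1 bp)")
  }
  if (length(msg)) msg else TRUE
}
setValidity("CnvCalls", .validCnvCalls)

#' Construct a CnvCalls object
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 1-based inclusive coordinates.
#' @param sample_id carrier sample identifier per call.
#' @param copy_state integer copy state in \{0, 1, 3, 4\}.
#' @param n_probes number of array probes supporting the call.
#' @param caller provenance label: \code{"A"}, \code{"B"} or
#'   \code{"consensus"}.
#' @param filter_flags optional \code{CharacterList} of audit flags.
#' @param uid optional stable per-call identifier (kept through consensus).
#' @return A \code{CnvCalls} object.
#' @export
CnvCalls <- function(chrom = character(), start = integer(), end = integer(),
                     sample_id = character(), copy_state = integer(),
                     n_probes = integer(), caller = "consensus",
                     filter_flags = NULL, uid = NULL) {
  n <- length(chrom)
  if (is.null(filter_flags))
    filter_flags <- CharacterList(rep(list(character()), n))
  gr <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)))
  mcols(gr) <- DataFrame(
    sample_id = as.character(sample_id),
    copy_state = as.integer(copy_state),
    n_probes = as.integer(n_probes),
    caller = rep_len(as.character(caller), n),
    filter_flags = filter_flags
  )
  if (!is.null(uid)) mcols(gr)$uid <- uid
  new("CnvCalls", sortSeqlevels(gr))
}

#' Named set of genomic regions
#'
#' A \code{RegionSet} is a sorted \code{GRanges} (1-based inclusive) carrying
#' a name and optional per-interval payload columns (e.g. \code{gene_id},
#' \code{pli}, gene-set membership flags, \code{score}). On construction,
#' overlapping or abutting intervals with identical payload are merged, so a
#' \code{RegionSet} used as a mask is always a disjoint union.
#'
#' @name RegionSet-class
#' @exportClass RegionSet
setClass("RegionSet", contains = "GRanges",
         representation(regionName = "character"))

.validRegionSet <- function(object) {
  msg <- character()
  if (length(object@regionName) != 1L)
    msg <- c(msg, "regionName must be a single string")
  if (length(object)) {
    if (is.unsorted(order(as.integer(seqnames(object)), start(object))) &&
        !identical(order(as.integer(seqnames(object)), start(object)),
                   seq_along(object)))
      msg <- c(msg, "intervals must be sorted by (chrom, start)")
    pli <- mcols(object)$pli
    if (!is.null(pli) && any(!is.na(pli) & (pli < 0 | pli > 1)))
      msg <- c(msg, "pli must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
}
setValidity("RegionSet", .validRegionSet)

#' Construct a RegionSet
#'
#' @param chrom,start,end interval coordinates, 1-based inclusive.
#' @param name name of the set (e.g. \code{"segdup"}, \code{"genes"}).
#' @param ... payload vectors of the same length as \code{chrom}
#'   (e.g. \code{gene_id}, \code{pli}, \code{score}).
#' @return A sorted \code{RegionSet} with same-payload intervals merged.
#' @export
RegionSet <- function(chrom = character(), start = integer(),
                      end = integer(), name = "regions", ...) {
  payload <- list(...)
  if (length(chrom) && any(end < start))
    stop("RegionSet: start must be <= end")
  gr <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)))
  gr <- sortSeqlevels(gr)
  if (length(payload))
    mcols(gr) <- DataFrame(payload)
  gr <- .mergeSamePayload(gr)
  new("RegionSet", gr, regionName = as.character(name))
}

## merge overlapping/abutting intervals whose payload rows are identical
.mergeSamePayload <- function(gr) {
  if (!length(gr)) return(BiocGenerics::sort(gr))
  mc <- mcols(gr)
  if (!ncol(mc)) {
    out <- GenomicRanges::reduce(BiocGenerics::sort(gr))
    return(out)
  }
  key <- do.call(paste, c(lapply(seq_len(ncol(mc)), function(j)
    as.character(mc[[j]])), sep = "\r"))
  o <- order(as.integer(seqnames(gr)), start(gr), end(gr))
  gr <- gr[o]; key <- key[o]
  ## same-key overlapping/abutting rows are rare: find them via a single
  ## overlap query and merge with union-find
  ov <- findOverlaps(granges(gr), granges(gr), maxgap = 0L)
  q <- queryHits(ov); s <- subjectHits(ov)
  keep <- q < s & key[q] == key[s]
  if (!any(keep)) return(gr)
  q <- q[keep]; s <- s[keep]
  parent <- seq_along(gr)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(q)) {
    a <- find(q[k]); b <- find(s[k])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_along(gr), find, integer(1))
  first <- !duplicated(comp)
  newstart <- tapply(start(gr), comp, min)[as.character(comp[first])]
  newend <- tapply(end(gr), comp, max)[as.character(comp[first])]
  out <- GRanges(seqnames(gr)[first],
                 IRanges(as.integer(newstart), as.integer(newend)))
  mcols(out) <- mc[o, , drop = FALSE][first, , drop = FALSE]
  BiocGenerics::sort(out)
}

#' Array probe map with per-sample signal at call sites
#'
#' Probe genomic positions (strictly increasing within each chromosome) plus
#' per-(sample, probe) Log R Ratio and B-allele-frequency values, emitted by
#' the synthetic generator at CNV call sites and consumed by BAF validation.
#'
#' @slot probes \code{GRanges} of width-1 probe positions with a
#'   \code{probe_id} column.
#' @slot signal \code{data.frame} with columns \code{sample_id},
#'   \code{probe_id}, \code{chrom}, \code{pos}, \code{lrr}, \code{baf}.
#' @name ProbeMap-class
#' @exportClass ProbeMap
setClass("ProbeMap",
         representation(probes = "GRanges", signal = "data.frame"))

.validProbeMap <- function(object) {
  msg <- character()
  pr <- object@probes
  if (length(pr)) {
    byc <- split(start(pr), as.character(seqnames(pr)))
    if (!all(vapply(byc, function(p) all(diff(p) > 0), logical(1))))
      msg <- c(msg, "probe positions must be strictly increasing per chrom")
  }
  sig <- object@signal
  if (nrow(sig)) {
    if (!all(c("sample_id", "probe_id", "chrom", "pos", "lrr", "baf") %in%
             colnames(sig)))
      msg <- c(msg, "signal must have sample_id, probe_id, chrom, pos, lrr, baf")
    else if (any(sig$baf < 0 | sig$baf > 1, na.rm = TRUE))
      msg <- c(msg, "baf must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
}
setValidity("ProbeMap", .validProbeMap)

#' @param probes \code{GRanges} of probe positions (width 1, \code{probe_id}).
#' @param signal per-(sample, probe) signal \code{data.frame}; may be empty.
#' @rdname ProbeMap-class
#' @export
ProbeMap <- function(probes,
                     signal = data.frame(sample_id = character(),
                                         probe_id = character(),
                                         chrom = character(),
                                         pos = integer(),
                                         lrr = numeric(),
                                         baf = numeric())) {
  new("ProbeMap", probes = BiocGenerics::sort(probes), signal = signal)
}

#' CNV filter cascade configuration
#'
#' Thresholds of the rare-CNV filter cascade. Defaults follow the analysed
#' callset definition (at least 15 probes and 30 kb), the strict 30-percent
#' mask-overlap removal rule, the 1-percent internal/external frequency
#' ceiling with 50-percent reciprocal-overlap locus matching, and the
#' BAF-validation band parameters.
#'
#' @export
setClass("FilterConfig", representation(
  minProbes = "integer", minLenBp = "integer",
  regionOverlapMax = "numeric", freqMax = "numeric",
  reciprocalOverlap = "numeric",
  bafHetBand = "numeric", bafDelHetMax = "numeric",
  bafDupBandLo = "numeric", bafDupBandHi = "numeric",
  bafDupBandMin = "numeric", bafQuadBandMin = "numeric",
  bafMinInformative = "integer",
  bafInformativeWindow = "numeric",
  smallDelRange = "numeric", lambdaMax = "numeric",
  datasetConcentration = "numeric", inflationMinCarriers = "integer"
))

.validFilterConfig <- function(object) {
  msg <- character()
  for (s in c("regionOverlapMax", "freqMax", "reciprocalOverlap")) {
    v <- slot(object, s)
    if (!(v > 0 && v < 1)) msg <- c(msg, paste(s, "must lie in (0, 1)"))
  }
  if (length(msg)) msg else TRUE
}
setValidity("FilterConfig", .validFilterConfig)

#' @param minProbes,minLenBp analysed-call size floor (15 probes, 30 kb).
#' @param regionOverlapMax mask-overlap fraction above which a call is
#'   removed (strictly greater than 0.30 by default).
#' @param freqMax frequency at or above which a locus is considered common
#'   (0.01).
#' @param reciprocalOverlap reciprocal-overlap threshold for locus
#'   clustering and external-reference matching (0.50).
#' @param bafHetBand BAF interval treated as a heterozygous diploid band.
#' @param bafDelHetMax maximum tolerated het-band fraction for a deletion.
#' @param bafDupBandLo,bafDupBandHi expected duplication BAF bands (near 1/3
#'   and 2/3).
#' @param bafDupBandMin minimum fraction of informative probes inside the
#'   duplication bands.
#' @param bafQuadBandMin for calls reported at copy state 4 or above,
#'   minimum fraction of informative probes inside the quarter bands
#'   (which a diploid segment lacks).
#' @param bafMinInformative minimum probes with signal needed to test a call.
#' @param bafInformativeWindow BAF window defining informative (non-homozygous)
#'   probes for duplication validation.
#' @param smallDelRange size range (bp) of the "small deletion" class screened
#'   for batch-effect inflation.
#' @param lambdaMax genomic-inflation ceiling for iterative locus exclusion.
#' @param datasetConcentration single-dataset carrier concentration that marks
#'   a locus as a batch-effect candidate.
#' @param inflationMinCarriers minimum carriers a locus needs to qualify as
#'   a batch-effect exclusion candidate (a two-carrier cluster is not a
#'   pile-up).
#' @return A \code{FilterConfig} object.
#' @rdname FilterConfig-class
#' @export
filterConfig <- function(minProbes = 15L, minLenBp = 30000L,
                         regionOverlapMax = 0.30, freqMax = 0.01,
                         reciprocalOverlap = 0.50,
                         bafHetBand = c(0.25, 0.75), bafDelHetMax = 0.10,
                         bafDupBandLo = c(0.20, 0.45),
                         bafDupBandHi = c(0.55, 0.80),
                         bafDupBandMin = 0.60, bafQuadBandMin = 0.20,
                         bafMinInformative = 10L,
                         bafInformativeWindow = c(0.10, 0.90),
                         smallDelRange = c(30000, 100000),
                         lambdaMax = 1.10, datasetConcentration = 0.80,
                         inflationMinCarriers = 3L) {
  new("FilterConfig", minProbes = as.integer(minProbes),
      minLenBp = as.integer(minLenBp),
      regionOverlapMax = regionOverlapMax, freqMax = freqMax,
      reciprocalOverlap = reciprocalOverlap,
      bafHetBand = bafHetBand, bafDelHetMax = bafDelHetMax,
      bafDupBandLo = bafDupBandLo, bafDupBandHi = bafDupBandHi,
      bafDupBandMin = bafDupBandMin, bafQuadBandMin = bafQuadBandMin,
      bafMinInformative = as.integer(bafMinInformative),
      bafInformativeWindow = bafInformativeWindow,
      smallDelRange = smallDelRange, lambdaMax = lambdaMax,
      datasetConcentration = datasetConcentration,
      inflationMinCarriers = as.integer(inflationMinCarriers))
}

## ---- accessors ----

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @describeIn CnvCalls-class carrier sample id per call.
#' @param x a \code{CnvCalls} object.
#' @export
setMethod("sampleIds", "CnvCalls", function(x) mcols(x)$sample_id)

#' @export
setGeneric("copyState", function(x) standardGeneric("copyState"))
#' @describeIn CnvCalls-class integer copy state per call.
#' @export
setMethod("copyState", "CnvCalls", function(x) mcols(x)$copy_state)

#' @export
setGeneric("nProbes", function(x) standardGeneric("nProbes"))
#' @describeIn CnvCalls-class supporting probe count per call.
#' @export
setMethod("nProbes", "CnvCalls", function(x) mcols(x)$n_probes)

#' @export
setGeneric("callerLabel", function(x) standardGeneric("callerLabel"))
#' @describeIn CnvCalls-class caller provenance per call.
#' @export
setMethod("callerLabel", "CnvCalls", function(x) mcols(x)$caller)

#' @export
setGeneric("filterFlags", function(x) standardGeneric("filterFlags"))
#' @describeIn CnvCalls-class audit filter flags per call.
#' @export
setMethod("filterFlags", "CnvCalls", function(x) mcols(x)$filter_flags)

#' @export
setGeneric("filterFlags<-", function(x, value) standardGeneric("filterFlags<-"))
#' @describeIn CnvCalls-class replace the audit flags.
#' @param value a \code{CharacterList} parallel to \code{x}.
#' @export
setMethod("filterFlags<-", "CnvCalls", function(x, value) {
  mcols(x)$filter_flags <- value
  validObject(x)
  x
})

#' @export
setGeneric("cnvType", function(x) standardGeneric("cnvType"))
#' @describeIn CnvCalls-class \code{"del"} for copy state below 2,
#'   \code{"dup"} above 2.
#' @export
setMethod("cnvType", "CnvCalls", function(x)
  ifelse(mcols(x)$copy_state < 2L, "del", "dup"))

#' @export
setGeneric("isDeletion", function(x) standardGeneric("isDeletion"))
#' @describeIn CnvCalls-class logical, copy state below 2.
#' @export
setMethod("isDeletion", "CnvCalls", function(x) mcols(x)$copy_state < 2L)

#' @export
setGeneric("regionName", function(x) standardGeneric("regionName"))
#' @describeIn RegionSet-class the set's name.
#' @param x a \code{RegionSet}.
#' @export
setMethod("regionName", "RegionSet", function(x) x@regionName)

#' Calls carrying no removal flag
#'
#' @param x a \code{CnvCalls} object after the filter cascade.
#' @return The subset of \code{x} whose \code{filter_flags} are empty.
#' @export
survivingCalls <- function(x) {
  stopifnot(is(x, "CnvCalls"))
  x[lengths(filterFlags(x)) == 0L]
}

## ---- show methods ----

setMethod("show", "CnvCalls", function(object) {
  n <- length(object)
  cat("CnvCalls with", n, "call(s) from",
      length(unique(sampleIds(object))), "sample(s)\n")
  if (n) {
    tp <- table(cnvType(object))
    cat("  deletions:", sum(isDeletion(object)),
        " duplications:", n - sum(isDeletion(object)), "\n")
    cat("  flagged for removal:", sum(lengths(filterFlags(object)) > 0L), "\n")
  }
  invisible(NULL)
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet '", object@regionName, "': ", length(object),
      " interval(s), ", sum(width(object)), " bp\n", sep = "")
  invisible(NULL)
})

setMethod("show", "ProbeMap", function(object) {
  cat("ProbeMap:", length(object@probes), "probes,",
      nrow(object@signal), "signal records\n")
  invisible(NULL)
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig: >=", object@minProbes, "probes, >=", object@minLenBp,
      "bp; mask overlap >", object@regionOverlapMax,
      "; frequency <", object@freqMax,
      "; reciprocal overlap >=", object@reciprocalOverlap, "\n")
  invisible(NULL)
})
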