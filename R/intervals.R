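#' @importFrom GenomicRanges findOverlaps countOverlaps pintersect reduce
#'   GRanges
#' @importFrom IRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits
NULL

## Internal interval arithmetic. All coordinates 1-based inclusive;
## length = end - start + 1 = width().

## bp of each query range covered by the union of subject ranges
coveredBp <- function(query, subject) {
  subject <- GenomicRanges::reduce(granges(subject))
  ov <- findOverlaps(granges(query), subject)
  if (!length(ov)) return(numeric(length(query)))
  w <- width(pintersect(granges(query)[queryHits(ov)],
                        subject[subjectHits(ov)]))
  out <- numeric(length(query))
  agg <- tapply(w, queryHits(ov), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Fraction of a call covered by a mask
#'
#' For each call, the number of basepairs covered by the union of the mask's
#' intervals, divided by the call length.
#'
#' @param calls a \code{CnvCalls} object (or any \code{GRanges}).
#' @param mask a \code{RegionSet} (or any \code{GRanges}).
#' @return Numeric vector in \eqn{[0, 1]}, one value per call.
#' @examples
#' calls <- CnvCalls("chr1", 1, 1000, "S1", 1L, 20L)
#' mask <- RegionSet(c("chr1", "chr1"), c(1, 151), c(200, 400), name = "m")
#' fractionOverlap(calls, mask)  # 400/1000
#' @export
fractionOverlap <- function(calls, mask) {
  coveredBp(calls, mask) / as.numeric(width(calls))
}

## reciprocal overlap of parallel range vectors: min(ov/len1, ov/len2);
## 0 when on different chromosomes or disjoint
reciprocalOverlapPairs <- function(gr1, gr2) {
  same <- as.character(seqnames(gr1)) == as.character(seqnames(gr2))
  ov <- pmin(end(gr1), end(gr2)) - pmax(start(gr1), start(gr2)) + 1
  ov <- pmax(ov, 0) * same
  ov / pmax(width(gr1), width(gr2))
}

## per-sample union bp of a set of ranges, returned as a named numeric;
## one global reduce() over (sample, chrom) composite seqnames
unionBpBySample <- function(calls) {
  if (!length(calls)) return(numeric(0))
  ids <- sampleIds(calls)
  comp <- GRanges(paste(ids, as.character(seqnames(calls)), sep = "\r"),
                  IRanges(start(calls), end(calls)))
  red <- GenomicRanges::reduce(comp)
  sid <- sub("\r.*$", "", as.character(seqnames(red)))
  out <- tapply(width(red), sid, sum)
  setNames(as.numeric(out), names(out))
}

## single-linkage connected components of same-type calls linked by
## reciprocal overlap >= ro. Returns an integer cluster id per call.
singleLinkageClusters <- function(gr, type, ro) {
  n <- length(gr)
  if (!n) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ov <- findOverlaps(granges(gr), granges(gr))
  q <- queryHits(ov); s <- subjectHits(ov)
  keep <- q < s & type[q] == type[s]
  q <- q[keep]; s <- s[keep]
  if (length(q)) {
    rr <- reciprocalOverlapPairs(granges(gr)[q], granges(gr)[s])
    link <- rr >= ro
    for (k in which(link)) {
      a <- find(q[k]); b <- find(s[k])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
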