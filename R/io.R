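#' @importFrom utils read.delim write.table
NULL

## File dialects.
##  * CNV call files: caller-native tab format, 1-based inclusive:
##      chrom start end copy_state n_probes sample_id
##  * Region files: BED, 0-based half-open, chrom/start/end plus optional
##    named payload columns behind a single '#'-prefixed header line.
##  * Annotation/frequency/sample-sheet files: headered TSV, coordinates
##    1-based inclusive.

#' Read a CNV call file
#'
#' Reads a caller-style tab-delimited call file (columns \code{chrom},
#' \code{start}, \code{end}, \code{copy_state}, \code{n_probes},
#' \code{sample_id}; 1-based inclusive coordinates) and validates every row.
#'
#' @param path file path.
#' @param caller provenance label to stamp on the calls
#'   (\code{"A"}, \code{"B"} or \code{"consensus"}).
#' @return A \code{\link{CnvCalls}} object (empty for an empty file).
#' @export
readCnvCalls <- function(path, caller = "consensus") {
  stopifnot(file.exists(path))
  caller <- match.arg(caller, CALLER_LEVELS)
  df <- tryCatch(
    read.delim(path, header = TRUE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e)))
  if (!nrow(df)) return(CnvCalls(caller = caller))
  need <- c("chrom", "start", "end", "copy_state", "n_probes", "sample_id")
  if (!all(need %in% colnames(df)))
    stop("call file must have columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(df$start) | is.na(df$end) | df$start > df$end)
  if (length(bad))
    stop("malformed interval at row ", bad[1], " of '", path, "'")
  bad <- which(!(df$copy_state %in% VALID_COPY_STATES))
  if (length(bad))
    stop("unknown copy state '", df$copy_state[bad[1]], "' at row ", bad[1])
  bad <- which(is.na(df$n_probes) | df$n_probes < 1)
  if (length(bad))
    stop("invalid probe count at row ", bad[1])
  CnvCalls(df$chrom, df$start, df$end, df$sample_id,
           df$copy_state, df$n_probes, caller = caller)
}

#' Write a CNV call file
#'
#' Inverse of \code{\link{readCnvCalls}}; \code{read(write(x))} returns
#' the identical call list.
#'
#' @param calls a \code{CnvCalls} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCnvCalls <- function(calls, path) {
  stopifnot(is(calls, "CnvCalls"))
  df <- data.frame(chrom = as.character(seqnames(calls)),
                   start = start(calls), end = end(calls),
                   copy_state = copyState(calls),
                   n_probes = nProbes(calls),
                   sample_id = sampleIds(calls))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED region file into a RegionSet
#'
#' BED coordinates (0-based half-open) are converted to the internal
#' 1-based inclusive convention. Optional payload columns may follow the
#' three coordinate columns, named by a leading \code{#}-prefixed header
#' line. Overlapping or abutting intervals with identical payload are merged
#' and the result is sorted, so re-reading a written file is idempotent.
#'
#' @param path BED file path.
#' @param name name for the resulting \code{\link{RegionSet}}.
#' @return A \code{RegionSet}.
#' @export
readBedRegions <- function(path, name = basename(path)) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  cols <- NULL
  if (length(first) && startsWith(first, "#"))
    cols <- strsplit(sub("^#", "", first), "\t")[[1]]
  df <- tryCatch(
    read.delim(path, header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      stop("cannot parse '", path, "': ", conditionMessage(e))
    })
  if (is.null(df) || !nrow(df)) return(RegionSet(name = name))
  if (is.null(cols)) cols <- c("chrom", "start", "end",
                               paste0("payload", seq_len(ncol(df) - 3L)))
  colnames(df) <- cols[seq_len(ncol(df))]
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("invalid BED interval (start >= end) at row ", bad[1],
         " of '", path, "'")
  payload <- df[setdiff(colnames(df), c("chrom", "start", "end"))]
  do.call(RegionSet, c(list(chrom = df$chrom, start = df$start + 1L,
                            end = df$end, name = name),
                       as.list(payload)))
}

#' Write a RegionSet as BED
#'
#' @param regions a \code{RegionSet}.
#' @param path output path (0-based half-open coordinates on disk).
#' @return \code{path}, invisibly.
#' @export
writeBedRegions <- function(regions, path) {
  stopifnot(is(regions, "RegionSet"))
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L, end = end(regions))
  mc <- mcols(regions)
  if (ncol(mc)) df <- cbind(df, as.data.frame(mc))
  header <- paste0("#", paste(colnames(df), collapse = "\t"))
  writeLines(header, path)
  suppressWarnings(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a sample sheet
#'
#' Headered TSV with one row per sample: \code{sample_id}, \code{is_case},
#' \code{dataset}, \code{country}, \code{sex}, intensity metrics
#' (\code{lrrsd}, \code{abs_wf}, \code{baf_drift}), principal components
#' \code{PC1}..\code{PC20}, polygenic-score columns (\code{prs_*}) and
#' clinical columns.
#'
#' @param path file path.
#' @return A \code{data.frame}.
#' @export
readSampleSheet <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "is_case", "dataset", "country", "sex",
            "lrrsd", "abs_wf", "baf_drift")
  if (!all(need %in% colnames(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  df$is_case <- as.logical(df$is_case)
  if (any(df$lrrsd < 0 | df$abs_wf < 0 | df$baf_drift < 0, na.rm = TRUE))
    stop("intensity metrics must be non-negative")
  df
}

#' @rdname readSampleSheet
#' @param samples sample \code{data.frame} to write.
#' @export
writeSampleSheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation
#'
#' Headered TSV with columns \code{gene_id}, \code{chrom}, \code{start},
#' \code{end} (1-based inclusive), \code{pli} and 0/1 gene-set flags
#' (\code{ndd_kendall}, \code{ndd_fu}, \code{haplosensitive},
#' \code{triplosensitive}).
#'
#' @param path file path.
#' @return A \code{RegionSet} named \code{"genes"} with payload columns.
#' @export
readGeneAnnotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "pli")
  if (!all(need %in% colnames(df)))
    stop("gene annotation must have columns: ", paste(need, collapse = ", "))
  flags <- intersect(c("ndd_kendall", "ndd_fu", "haplosensitive",
                       "triplosensitive"), colnames(df))
  args <- c(list(chrom = df$chrom, start = df$start, end = df$end,
                 name = "genes", gene_id = df$gene_id, pli = df$pli),
            lapply(df[flags], function(v) as.integer(v) > 0L))
  names(args)[-(1:6)] <- flags
  do.call(RegionSet, args)
}

#' @rdname readGeneAnnotation
#' @param genes gene \code{RegionSet} to write.
#' @export
writeGeneAnnotation <- function(genes, path) {
  df <- data.frame(gene_id = mcols(genes)$gene_id,
                   chrom = as.character(seqnames(genes)),
                   start = start(genes), end = end(genes),
                   pli = mcols(genes)$pli)
  for (f in c("ndd_kendall", "ndd_fu", "haplosensitive", "triplosensitive"))
    if (!is.null(mcols(genes)[[f]])) df[[f]] <- as.integer(mcols(genes)[[f]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-base constraint score track
#'
#' Headered TSV with \code{chrom}, \code{start}, \code{end} (1-based
#' inclusive) and \code{score} (e.g. a phyloP-like conservation score).
#'
#' @param path file path.
#' @return A \code{RegionSet} named \code{"constraint"} with a \code{score}
#'   payload column.
#' @export
readConstraintTrack <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  RegionSet(df$chrom, df$start, df$end, name = "constraint",
            score = df$score)
}

#' Read an external CNV frequency reference
#'
#' Headered TSV with \code{chrom}, \code{start}, \code{end} (1-based
#' inclusive), \code{cnv_type} (\code{del}/\code{dup}) and one or more
#' frequency columns (\code{freq_global}, \code{freq_subpop_*}).
#'
#' @param path file path.
#' @return A \code{data.frame}.
#' @export
readFrequencyReference <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "cnv_type")
  if (!all(need %in% colnames(df)))
    stop("frequency reference must have columns: ",
         paste(need, collapse = ", "))
  if (!any(startsWith(colnames(df), "freq")))
    stop("frequency reference must have at least one freq* column")
  df
}
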