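#' @importFrom stats sd
NULL

## Sample-level QC on intensity metrics and raw call load.
## Outlier pruning is a single pass: dataset means/SDs are computed once on
## the incoming samples and never recomputed after removals, which makes
## the procedure deterministic and idempotent on its own output.

QC_HARD_BOUNDS <- c(lrrsd = 0.2, abs_wf = 0.02, baf_drift = 0.001)
QC_METRIC_REASON <- c(lrrsd = "LRRSD_OUTLIER", abs_wf = "WF_OUTLIER",
                      baf_drift = "DRIFT_OUTLIER")

#' Prune intensity-metric outliers
#'
#' Within each dataset, a sample is marked an outlier for a metric (LRRSD,
#' absolute waviness factor, BAF drift) if it falls beyond 3 SDs of the
#' dataset mean; a sample is removed if it is an outlier for any metric.
#' Surviving samples must additionally satisfy the hard bounds
#' LRRSD <= 0.2, absWF <= 0.02 and BAF drift <= 0.001; any survivor
#' violating a bound is removed with the corresponding reason.
#'
#' @param samples sample sheet with \code{dataset}, \code{lrrsd},
#'   \code{abs_wf}, \code{baf_drift}.
#' @param nSd outlier threshold in dataset SD units (3).
#' @return A QC report \code{data.frame}: \code{sample_id},
#'   \code{removed}, \code{reasons} (comma-joined), and the per-dataset
#'   metric means/SDs as an attribute \code{"dataset_stats"}.
#' @export
pruneIntensityOutliers <- function(samples, nSd = 3) {
  small <- names(which(table(samples$dataset) < 2L))
  if (length(small))
    stop("dataset(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  metrics <- names(QC_METRIC_REASON)
  reasons <- vector("list", nrow(samples))
  for (i in seq_along(reasons)) reasons[[i]] <- character()
  stats_rows <- list()
  for (d in unique(samples$dataset)) {
    idx <- which(samples$dataset == d)
    for (m in metrics) {
      x <- samples[[m]][idx]
      mu <- mean(x); s <- sd(x)
      stats_rows[[paste(d, m)]] <- data.frame(
        dataset = d, metric = m, mean = mu, sd = s)
      out <- abs(x - mu) > nSd * s
      for (j in idx[out])
        reasons[[j]] <- c(reasons[[j]], QC_METRIC_REASON[[m]])
    }
  }
  ## hard bounds apply to the survivors of the SD pruning
  survivor <- lengths(reasons) == 0L
  for (m in metrics) {
    viol <- survivor & samples[[m]] > QC_HARD_BOUNDS[[m]]
    for (j in which(viol))
      reasons[[j]] <- c(reasons[[j]], QC_METRIC_REASON[[m]])
  }
  out <- data.frame(sample_id = samples$sample_id,
                    removed = lengths(reasons) > 0L,
                    reasons = vapply(reasons, function(r)
                      paste(unique(r), collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  attr(out, "dataset_stats") <- do.call(rbind, stats_rows)
  out
}

#' Prune samples with excessive raw call load
#'
#' A sample is removed if the genomic footprint of its raw calls (the
#' length of the union of its call intervals, not the sum) exceeds 20 Mb,
#' or if it has more than 20 separate raw calls. Both thresholds are
#' strict inequalities.
#'
#' @param samples sample sheet.
#' @param rawCalls raw (pre-filter) consensus \code{\link{CnvCalls}}.
#' @param maxBp,maxCalls removal thresholds.
#' @return QC report \code{data.frame} with \code{sample_id},
#'   \code{removed}, \code{reasons}, \code{call_count}, \code{union_bp}.
#' @export
pruneCallOutliers <- function(samples, rawCalls, maxBp = 2e7,
                              maxCalls = 20L) {
  stopifnot(is(rawCalls, "CnvCalls"))
  ubp <- unionBpBySample(rawCalls)
  cnt <- table(sampleIds(rawCalls))
  union_bp <- as.numeric(ubp[samples$sample_id])
  union_bp[is.na(union_bp)] <- 0
  call_count <- as.integer(cnt[samples$sample_id])
  call_count[is.na(call_count)] <- 0L
  reasons <- character(nrow(samples))
  reasons[union_bp > maxBp] <- "CALL_BP"
  many <- call_count > maxCalls
  reasons[many] <- ifelse(nzchar(reasons[many]),
                          paste(reasons[many], "CALL_COUNT", sep = ","),
                          "CALL_COUNT")
  data.frame(sample_id = samples$sample_id,
             removed = nzchar(reasons), reasons = reasons,
             call_count = call_count, union_bp = union_bp,
             stringsAsFactors = FALSE)
}

#' Combined sample QC
#'
#' Runs \code{\link{pruneIntensityOutliers}} then
#' \code{\link{pruneCallOutliers}} and merges the reports.
#'
#' @param samples sample sheet.
#' @param rawCalls raw consensus calls (optional; intensity-only QC if
#'   missing).
#' @return A merged QC report; kept samples are those with
#'   \code{removed == FALSE}.
#' @export
sampleQc <- function(samples, rawCalls = NULL) {
  rep1 <- pruneIntensityOutliers(samples)
  if (is.null(rawCalls)) return(rep1)
  rep2 <- pruneCallOutliers(samples, rawCalls)
  reasons <- ifelse(nzchar(rep1$reasons) & nzchar(rep2$reasons),
                    paste(rep1$reasons, rep2$reasons, sep = ","),
                    paste0(rep1$reasons, rep2$reasons))
  out <- data.frame(sample_id = samples$sample_id,
                    removed = rep1$removed | rep2$removed,
                    reasons = reasons,
                    call_count = rep2$call_count,
                    union_bp = rep2$union_bp,
                    stringsAsFactors = FALSE)
  attr(out, "dataset_stats") <- attr(rep1, "dataset_stats")
  out
}

#' @rdname sampleQc
#' @param qcReport a report from \code{\link{sampleQc}}.
#' @return For \code{keptSampleIds}: character vector of surviving ids.
#' @export
keptSampleIds <- function(qcReport) qcReport$sample_id[!qcReport$removed]
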