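#' @importFrom stats glm lm binomial coef vcov pnorm pt qnorm as.formula
NULL

## Per-sample burden metrics are deterministic functions of a sample's
## surviving calls plus the annotation; every regression below consumes
## them as plain numeric columns.

#' Compute per-sample burden metrics
#'
#' Emits the partitioned burden table: call counts (all, deletions,
#' duplications), affected basepairs per 100 kb, distinct gene counts
#' (1 bp overlap defines "coding"), counts of calls hitting genes above
#' each pLI threshold and in each gene set, size-bin counts, singleton
#' (single-carrier locus) counts, a coding/noncoding split, and kilobases
#' of constrained sequence deleted/duplicated above each constraint-score
#' threshold.
#'
#' @param calls analysis-ready \code{\link{CnvCalls}} (cascade survivors).
#' @param samples QC-pass sample sheet (defines the rows; samples without
#'   calls get zeros).
#' @param genes gene \code{\link{RegionSet}} with \code{pli} and gene-set
#'   flag payloads.
#' @param constraint constraint-score \code{\link{RegionSet}} (or
#'   \code{NULL} to skip constrained-kb metrics).
#' @param clusters optional precomputed \code{\link{clusterCalls}} result
#'   for the singleton metric.
#' @param pliThresholds pLI thresholds (0.5, 0.9, 0.995).
#' @param constraintThresholds score thresholds for constrained-kb metrics.
#' @param cfg \code{\link{filterConfig}} (clustering rule for singletons).
#' @return A \code{data.frame}, one row per sample, \code{sample_id} plus
#'   one column per metric.
#' @export
computeBurdenMetrics <- function(calls, samples, genes, constraint = NULL,
                                 clusters = NULL,
                                 pliThresholds = c(0.5, 0.9, 0.995),
                                 constraintThresholds = c(2, 4),
                                 cfg = filterConfig()) {
  if (is.null(genes)) stop("gene annotation is required")
  n <- nrow(samples)
  sidx <- match(sampleIds(calls), samples$sample_id)
  if (any(is.na(sidx)))
    stop("calls from samples absent from the sample sheet")
  del <- isDeletion(calls)
  w <- as.numeric(width(calls))

  acc <- function(sel, val = NULL) {
    ## sum val (default: count) over calls, per sample
    v <- if (is.null(val)) rep(1, length(calls)) else val
    out <- numeric(n)
    if (any(sel)) {
      agg <- tapply(v[sel], sidx[sel], sum)
      out[as.integer(names(agg))] <- as.numeric(agg)
    }
    out
  }

  out <- data.frame(sample_id = samples$sample_id,
                    stringsAsFactors = FALSE)
  out$count_all <- acc(rep(TRUE, length(calls)))
  out$count_del <- acc(del)
  out$count_dup <- acc(!del)
  out$bp_del_per100kb <- acc(del, w) / 1e5
  out$bp_dup_per100kb <- acc(!del, w) / 1e5

  ## distinct genes overlapped (>= 1 bp)
  ov <- findOverlaps(granges(calls), granges(genes))
  q <- queryHits(ov); g <- subjectHits(ov)
  geneCount <- function(sel) {
    out <- numeric(n)
    k <- sel[q]
    if (any(k)) {
      key <- paste(sidx[q][k], g[k])
      first <- !duplicated(key)
      agg <- tapply(rep(1, sum(first)), sidx[q][k][first], sum)
      out[as.integer(names(agg))] <- as.numeric(agg)
    }
    out
  }
  out$genes_del <- geneCount(del)
  out$genes_dup <- geneCount(!del)

  ## per-call gene-overlap summaries
  coding <- rep(FALSE, length(calls))
  coding[unique(q)] <- TRUE
  out$count_coding_del <- acc(del & coding)
  out$count_coding_dup <- acc(!del & coding)
  out$count_noncoding_del <- acc(del & !coding)
  out$count_noncoding_dup <- acc(!del & !coding)

  pli <- mcols(genes)$pli
  for (t in pliThresholds) {
    hit <- rep(FALSE, length(calls))
    hit[unique(q[pli[g] > t])] <- TRUE
    out[[sprintf("count_del_pli_gt%s", t)]] <- acc(del & hit)
    out[[sprintf("count_dup_pli_gt%s", t)]] <- acc(!del & hit)
  }
  for (set in c("ndd_kendall", "ndd_fu", "haplosensitive",
                "triplosensitive")) {
    fl <- mcols(genes)[[set]]
    if (is.null(fl)) next
    hit <- rep(FALSE, length(calls))
    hit[unique(q[fl[g]])] <- TRUE
    out[[paste0("count_del_", set)]] <- acc(del & hit)
    out[[paste0("count_dup_", set)]] <- acc(!del & hit)
  }

  ## size bins
  out$count_30_100kb <- acc(w >= 3e4 & w <= 1e5)
  out$count_100kb_1mb <- acc(w > 1e5 & w <= 1e6)
  out$count_gt1mb <- acc(w > 1e6)

  ## singletons: calls at loci with exactly one carrier
  if (length(calls)) {
    if (is.null(clusters)) clusters <- clusterCalls(calls, cfg)
    singleton_cluster <-
      clusters$clusters$cluster_id[clusters$clusters$n_carriers == 1L]
    out$count_singleton <- acc(clusters$assign %in% singleton_cluster)
    out$count_singleton_del <- acc(del & clusters$assign %in%
                                     singleton_cluster)
  } else {
    out$count_singleton <- numeric(n)
    out$count_singleton_del <- numeric(n)
  }

  ## constrained kilobases
  if (!is.null(constraint) && length(constraint)) {
    sc <- mcols(constraint)$score
    for (t in constraintThresholds) {
      keep <- constraint[!is.na(sc) & sc >= t]
      bp <- coveredBp(calls, keep)
      out[[sprintf("constrained_kb_del_ge%s", t)]] <- acc(del, bp) / 1e3
      out[[sprintf("constrained_kb_dup_ge%s", t)]] <- acc(!del, bp) / 1e3
    }
  }
  out
}

## covariate design data: numeric PCs/metrics plus sex coded as a factor
.covariateData <- function(samples, covariates) {
  df <- data.frame(row.names = seq_len(nrow(samples)))
  for (cv in covariates) {
    if (cv == "sex") df$sex <- factor(samples$sex, levels = c("F", "M"))
    else df[[cv]] <- samples[[cv]]
  }
  df
}

BASE_COVARIATES <- c("PC1", "PC2", "PC3", "PC4", "PC5", "sex")

#' Screen additional covariates for the burden models
#'
#' The base model holds the major principal components (PC1--PC5) and sex.
#' A candidate (PCs 6--20, LRRSD) joins the model when it is associated
#' (p < \code{alpha}) with both the raw CNV call count (linear regression)
#' and case status (logistic regression).
#'
#' @param samples sample sheet.
#' @param rawCallCounts raw (pre-filter) per-sample call counts, aligned
#'   to \code{samples}.
#' @param candidates candidate column names.
#' @param base always-included covariates.
#' @param alpha screening threshold.
#' @return Character vector: \code{base} plus the selected candidates.
#' @export
selectCovariates <- function(samples, rawCallCounts,
                             candidates = c(paste0("PC", 6:20), "lrrsd"),
                             base = BASE_COVARIATES, alpha = 0.05) {
  sel <- character()
  for (cv in candidates) {
    x <- samples[[cv]]
    if (is.null(x)) next
    if (length(unique(x)) < 2L) {
      warning("candidate '", cv, "' is constant; skipped")
      next
    }
    p1 <- summary(lm(rawCallCounts ~ x))$coefficients["x", 4]
    ## likelihood-ratio test: robust to separation (a candidate that
    ## predicts case status perfectly must still be selected)
    fit <- suppressWarnings(glm(samples$is_case ~ x, family = binomial()))
    p2 <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                        lower.tail = FALSE)
    if (p1 < alpha && p2 < alpha) sel <- c(sel, cv)
  }
  c(base, sel)
}

.fitSummary <- function(fit, term, level = 0.95) {
  est <- coef(fit)[[term]]
  se <- sqrt(diag(vcov(fit))[[term]])
  z <- qnorm(1 - (1 - level) / 2)
  p <- 2 * pnorm(-abs(est / se))
  list(estimate = est, se = se, lo = est - z * se, hi = est + z * se,
       p = p)
}

#' Covariate-adjusted logistic burden test
#'
#' Maximum-likelihood logistic regression of case status on the covariates
#' plus the burden metric; the reported effect is the odds ratio per
#' metric unit with a Wald 95 percent interval and two-sided Wald p-value.
#' Complete or quasi-complete separation is reported with an
#' infinite-interval flag instead of failing.
#'
#' @param metric numeric per-sample burden metric, aligned to
#'   \code{samples}.
#' @param samples QC-pass sample sheet.
#' @param covariates covariate column names (\code{"sex"} allowed).
#' @param metricName label for the output row.
#' @return A one-row \code{data.frame}: metric, model, estimate (odds
#'   ratio), \code{ci_lo}, \code{ci_hi}, \code{p_value}, sample counts,
#'   covariates used and a \code{separation} flag.
#' @export
logisticBurdenTest <- function(metric, samples, covariates = BASE_COVARIATES,
                               metricName = "burden") {
  if (any(!is.finite(metric))) stop("metric must be finite for all samples")
  y <- samples$is_case
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  df <- .covariateData(samples, covariates)
  df$..metric <- metric
  df$..y <- y
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(..y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- .fitSummary(fit, "..metric")
  if (!sep && s$se > 20) sep <- TRUE
  data.frame(metric = metricName, model = "logistic",
             estimate = exp(s$estimate),
             ci_lo = if (sep) 0 else exp(s$lo),
             ci_hi = if (sep) Inf else exp(s$hi),
             p_value = s$p, n_cases = sum(y), n_controls = sum(!y),
             covariates = paste(covariates, collapse = "+"),
             separation = sep, stringsAsFactors = FALSE)
}

#' Linear excess-rate test
#'
#' Ordinary least squares with the burden metric as the outcome and case
#' status as the critical predictor, adjusting for the same covariates as
#' the logistic model; the estimate is the excess metric per case with a
#' 95 percent interval.
#'
#' @inheritParams logisticBurdenTest
#' @return A one-row \code{data.frame} as in
#'   \code{\link{logisticBurdenTest}} with \code{model = "linear"}.
#' @export
linearExcessTest <- function(metric, samples, covariates = BASE_COVARIATES,
                             metricName = "burden") {
  if (any(!is.finite(metric))) stop("metric must be finite for all samples")
  df <- .covariateData(samples, covariates)
  df$..case <- as.numeric(samples$is_case)
  df$..metric <- metric
  fit <- lm(..metric ~ ., data = df)
  alias <- is.na(coef(fit))
  if (any(alias))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(which(alias)), collapse = ", "))
  est <- coef(fit)[["..case"]]
  se <- sqrt(diag(vcov(fit))[["..case"]])
  dfres <- fit$df.residual
  tcrit <- stats::qt(0.975, dfres)
  p <- 2 * pt(-abs(est / se), dfres)
  data.frame(metric = metricName, model = "linear", estimate = est,
             ci_lo = est - tcrit * se, ci_hi = est + tcrit * se,
             p_value = p, n_cases = sum(samples$is_case),
             n_controls = sum(!samples$is_case),
             covariates = paste(covariates, collapse = "+"),
             separation = FALSE, stringsAsFactors = FALSE)
}

#' Leave-one-out burden sensitivity analysis
#'
#' Refits the burden model once per held-out dataset (on the remaining
#' samples) and once per dropped covariate (on all samples), to show that
#' a result is not driven by a single input dataset or covariate.
#'
#' @inheritParams logisticBurdenTest
#' @param model \code{"logistic"} or \code{"linear"}.
#' @return A \code{data.frame} of burden-result rows with columns
#'   \code{held_out} (\code{dataset:x} or \code{covariate:x}); held-out
#'   fits whose outcome collapses to one class are flagged and skipped.
#' @export
leaveOneOutBurden <- function(metric, samples, covariates = BASE_COVARIATES,
                              model = c("logistic", "linear"),
                              metricName = "burden") {
  model <- match.arg(model)
  fitfun <- if (model == "logistic") logisticBurdenTest else linearExcessTest
  datasets <- unique(samples$dataset)
  if (length(datasets) < 2L) stop("leave-one-out needs at least 2 datasets")
  rows <- list()
  for (d in datasets) {
    keep <- samples$dataset != d
    if (length(unique(samples$is_case[keep])) < 2L) {
      rows[[paste0("dataset:", d)]] <- data.frame(
        metric = metricName, model = model, estimate = NA_real_,
        ci_lo = NA_real_, ci_hi = NA_real_, p_value = NA_real_,
        n_cases = sum(samples$is_case[keep]),
        n_controls = sum(!samples$is_case[keep]),
        covariates = paste(covariates, collapse = "+"),
        separation = NA, held_out = paste0("dataset:", d),
        note = "single outcome class", stringsAsFactors = FALSE)
      next
    }
    r <- fitfun(metric[keep], samples[keep, , drop = FALSE], covariates,
                metricName)
    r$held_out <- paste0("dataset:", d)
    r$note <- ""
    rows[[r$held_out]] <- r
  }
  for (cv in covariates) {
    r <- fitfun(metric, samples, setdiff(covariates, cv), metricName)
    r$held_out <- paste0("covariate:", cv)
    r$note <- ""
    rows[[r$held_out]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
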