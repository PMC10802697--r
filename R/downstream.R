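#' @importFrom stats ppois chisq.test fisher.test t.test lm sd
NULL

#' Deleterious-CNV carrier status
#'
#' Derives, deterministically from the surviving calls and the gene
#' annotation, the carrier flags used in the downstream analyses:
#' deletions of highly loss-of-function-intolerant genes (pLI above the
#' threshold) and deletions/duplications of neurodevelopmental (NDD)
#' genes under each curated definition. Raising the pLI threshold never
#' adds carriers.
#'
#' @param calls analysis-ready \code{\link{CnvCalls}}.
#' @param genes gene \code{\link{RegionSet}} with \code{pli},
#'   \code{ndd_kendall}, \code{ndd_fu} payloads.
#' @param samples sample sheet (defines the rows).
#' @param pliThreshold pLI cutoff for the high-pLI deletion flag (0.995).
#' @return A \code{data.frame}: \code{sample_id}, logical
#'   \code{del_highpli}, \code{ndd_del_kendall}, \code{ndd_dup_kendall},
#'   \code{ndd_del_fu}, \code{ndd_dup_fu}, \code{ndd_del}, \code{ndd_dup}
#'   (either definition), \code{deleterious_del}, \code{deleterious_dup}.
#' @export
carrierStatus <- function(calls, genes, samples, pliThreshold = 0.995) {
  ov <- findOverlaps(granges(calls), granges(genes))
  q <- queryHits(ov); g <- subjectHits(ov)
  del <- isDeletion(calls)
  ids <- sampleIds(calls)
  flag <- function(callSel, geneSel) {
    hit <- unique(q[callSel[q] & geneSel[g]])
    samples$sample_id %in% ids[hit]
  }
  pli <- mcols(genes)$pli
  kend <- mcols(genes)$ndd_kendall
  fu <- mcols(genes)$ndd_fu
  out <- data.frame(
    sample_id = samples$sample_id,
    del_highpli = flag(del, pli > pliThreshold),
    ndd_del_kendall = flag(del, kend),
    ndd_dup_kendall = flag(!del, kend),
    ndd_del_fu = flag(del, fu),
    ndd_dup_fu = flag(!del, fu),
    stringsAsFactors = FALSE)
  out$ndd_del <- out$ndd_del_kendall | out$ndd_del_fu
  out$ndd_dup <- out$ndd_dup_kendall | out$ndd_dup_fu
  out$deleterious_del <- out$del_highpli | out$ndd_del
  out$deleterious_dup <- out$ndd_dup
  out
}

#' Genes hit only by single-gene case CNVs
#'
#' A call is "single-gene" if it overlaps exactly one annotated gene.
#' Returns the genes hit by at least one single-gene case call and by no
#' single-gene control call -- the case-only set compared against exome
#' summary statistics.
#'
#' @param calls analysis-ready \code{\link{CnvCalls}}.
#' @param genes gene \code{\link{RegionSet}}.
#' @param samples sample sheet (for case status).
#' @return Character vector of gene ids.
#' @export
caseOnlySingleGeneSet <- function(calls, genes, samples) {
  ov <- findOverlaps(granges(calls), granges(genes))
  q <- queryHits(ov); g <- subjectHits(ov)
  ngene <- tabulate(q, nbins = length(calls))
  single <- ngene == 1L
  isc <- samples$is_case[match(sampleIds(calls), samples$sample_id)]
  keep <- single[q]
  gcase <- unique(g[keep & isc[q]])
  gctrl <- unique(g[keep & !isc[q]])
  mcols(genes)$gene_id[setdiff(gcase, gctrl)]
}

#' One-sided Poisson enrichment p-value
#'
#' Exact upper-tail probability \eqn{P(X \ge observed)} for
#' \eqn{X \sim Poisson(expected)}.
#'
#' @param observed non-negative integer count.
#' @param expected positive expectation.
#' @return The one-sided p-value.
#' @examples
#' poissonEnrichment(9, 3.94)    # ~0.02
#' poissonEnrichment(26, 17.30)  # ~0.03
#' @export
poissonEnrichment <- function(observed, expected) {
  if (expected <= 0) stop("expected must be positive")
  if (observed < 0 || observed != round(observed))
    stop("observed must be a non-negative integer")
  if (observed == 0) return(1)
  ppois(observed - 1, expected, lower.tail = FALSE)
}

#' Polygenic-score vs carrier-status regression
#'
#' Linear regression of the (within-analysis-set normalized) polygenic
#' score on carrier status plus the global-burden covariates; the
#' estimate is the carrier mean shift in SD units.
#'
#' @param prs numeric polygenic-score column, aligned to \code{samples}.
#' @param carrier logical carrier flag, aligned to \code{samples}.
#' @param samples the analysis set.
#' @param covariates covariate columns (see
#'   \code{\link{logisticBurdenTest}}).
#' @return A one-row \code{data.frame}: estimate, \code{ci_lo},
#'   \code{ci_hi}, \code{p_value}, carrier count and a \code{skipped}
#'   flag (no carriers in the analysis set).
#' @export
prsCarrierAssociation <- function(prs, carrier, samples,
                                  covariates = BASE_COVARIATES) {
  if (sd(prs) == 0) stop("PRS column is constant; cannot normalize")
  prs <- as.numeric(scale(prs))
  if (!any(carrier))
    return(data.frame(estimate = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, p_value = NA_real_,
                      n_carriers = 0L, skipped = TRUE))
  df <- .covariateData(samples, covariates)
  df$..carrier <- as.numeric(carrier)
  df$..prs <- prs
  fit <- lm(..prs ~ ., data = df)
  est <- coef(fit)[["..carrier"]]
  se <- sqrt(diag(vcov(fit))[["..carrier"]])
  dfres <- fit$df.residual
  p <- 2 * pt(-abs(est / se), dfres)
  tcrit <- stats::qt(0.975, dfres)
  data.frame(estimate = est, ci_lo = est - tcrit * se,
             ci_hi = est + tcrit * se, p_value = p,
             n_carriers = sum(carrier), skipped = FALSE)
}

#' Carrier/comorbidity contingency test
#'
#' Builds the 2x2 carrier-by-comorbidity table and applies the Pearson
#' chi-square without continuity correction, falling back to the two-sided
#' Fisher exact test when the table is too sparse for the chi-square
#' approximation (an expected cell count below 1).
#'
#' @param carrier logical carrier flag.
#' @param comorbid logical (or 0/1) comorbidity flag; missing values drop
#'   the sample.
#' @param method \code{"auto"} (default sparsity switch), or force
#'   \code{"chisq"} / \code{"fisher"}.
#' @return A list: \code{method} (\code{"chisq"}/\code{"fisher"}),
#'   \code{statistic} (chi-square) or \code{odds_ratio} (Fisher),
#'   \code{df}, \code{p_value} and \code{table}.
#' @export
comorbidityAssociation <- function(carrier, comorbid,
                                   method = c("auto", "chisq", "fisher")) {
  method <- match.arg(method)
  keep <- !is.na(carrier) & !is.na(comorbid)
  carrier <- as.logical(carrier[keep])
  comorbid <- as.logical(comorbid[keep])
  if (!length(carrier)) stop("empty contingency table")
  tab <- table(factor(comorbid, c(TRUE, FALSE)),
               factor(carrier, c(TRUE, FALSE)),
               dnn = c("comorbid", "carrier"))
  if (sum(tab) == 0) stop("empty contingency table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_chisq <- switch(method, chisq = TRUE, fisher = FALSE,
                      auto = all(expected >= 1))
  if (use_chisq) {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(method = "chisq", statistic = unname(ct$statistic),
         df = unname(ct$parameter), p_value = ct$p.value, table = tab)
  } else {
    ft <- fisher.test(tab)
    list(method = "fisher", odds_ratio = unname(ft$estimate),
         df = 1L, p_value = ft$p.value, table = tab)
  }
}

#' Treatment-response comparison between carriers and non-carriers
#'
#' Percent improvement is \eqn{100 (pre - post) / pre} on the
#' symptom-severity scale; carriers and non-carriers are compared with a
#' two-sided pooled-variance t-test.
#'
#' @param pre,post pre- and post-treatment scores (pre must be positive;
#'   samples with missing scores are dropped).
#' @param carrier logical carrier flag.
#' @return A list: \code{t}, \code{df}, \code{p_value},
#'   \code{mean_carrier}, \code{mean_noncarrier}, \code{n_carrier},
#'   \code{n_noncarrier}, \code{skipped} (a group has fewer than 2
#'   samples).
#' @export
treatmentResponseTest <- function(pre, post, carrier) {
  keep <- !is.na(pre) & !is.na(post) & !is.na(carrier)
  pre <- pre[keep]; post <- post[keep]; carrier <- as.logical(carrier[keep])
  if (any(pre <= 0)) stop("pre-treatment score must be positive")
  imp <- 100 * (pre - post) / pre
  n1 <- sum(carrier); n0 <- sum(!carrier)
  if (n1 < 2L || n0 < 2L)
    return(list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                mean_carrier = if (n1) mean(imp[carrier]) else NA_real_,
                mean_noncarrier = if (n0) mean(imp[!carrier]) else NA_real_,
                n_carrier = n1, n_noncarrier = n0, skipped = TRUE))
  if (sd(imp[carrier]) == 0 && sd(imp[!carrier]) == 0) {
    ## degenerate zero-variance groups: equal means give t = 0
    eq <- mean(imp[carrier]) == mean(imp[!carrier])
    return(list(t = if (eq) 0 else sign(mean(imp[carrier]) -
                                          mean(imp[!carrier])) * Inf,
                df = n1 + n0 - 2L, p_value = if (eq) 1 else 0,
                mean_carrier = mean(imp[carrier]),
                mean_noncarrier = mean(imp[!carrier]),
                n_carrier = n1, n_noncarrier = n0, skipped = FALSE))
  }
  tt <- t.test(imp[carrier], imp[!carrier], var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_carrier = mean(imp[carrier]),
       mean_noncarrier = mean(imp[!carrier]),
       n_carrier = n1, n_noncarrier = n0, skipped = FALSE)
}

#' Read exome-study gene-level summary statistics
#'
#' Headered TSV with \code{gene_id}, expected and observed de novo
#' damaging counts and case/control loss-of-function counts, used for the
#' Poisson enrichment comparison of the case-only CNV gene set.
#'
#' @param path file path.
#' @return A \code{data.frame}.
#' @export
readExomeSummary <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "dn_expected", "dn_observed")
  if (!all(need %in% colnames(df)))
    stop("exome summary must have columns: ", paste(need, collapse = ", "))
  if (any(df$dn_expected <= 0)) stop("expected values must be positive")
  df
}
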