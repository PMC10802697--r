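mkGenes <- function() {
  RegionSet(rep("chr1", 3), c(100000, 400000, 800000),
            c(150000, 450000, 900000), name = "genes",
            gene_id = c("G1", "G2", "G3"), pli = c(0.999, 0.3, 0.7),
            ndd_kendall = c(FALSE, TRUE, FALSE),
            ndd_fu = c(FALSE, FALSE, FALSE),
            haplosensitive = c(TRUE, FALSE, FALSE),
            triplosensitive = c(FALSE, FALSE, FALSE))
}

test_that("burden metrics follow directly from calls and annotation", {
  s <- mkSamples(3, dataset = "d1")
  genes <- mkGenes()
  ## S0001: one 250 kb deletion covering the pLI=0.999 gene
  calls <- mkCalls("chr1", 50000, 299999, "S0001", 1L)
  bm <- computeBurdenMetrics(calls, s, genes)
  r <- bm[bm$sample_id == "S0001", ]
  expect_equal(r$count_del, 1)
  expect_equal(r$bp_del_per100kb, 2.5)
  expect_equal(r$genes_del, 1)
  expect_equal(r$count_del_pli_gt0.995, 1)
  expect_equal(r$count_coding_del, 1)
  expect_equal(r$count_noncoding_del, 0)
  expect_equal(r$count_100kb_1mb, 1)
  expect_equal(r$count_singleton, 1)
  ## samples without calls have all-zero metrics
  z <- bm[bm$sample_id == "S0002", ]
  expect_true(all(z[, -1] == 0))
  ## coding + noncoding counts sum to the total, exactly
  expect_equal(bm$count_coding_del + bm$count_noncoding_del, bm$count_del)
})

test_that("gene-count metrics match a brute-force overlap scan", {
  set.seed(12)
  s <- mkSamples(6, dataset = "d1")
  genes <- mkGenes()
  n <- 15
  st <- sample(seq(1, 9.5e5, by = 5e3), n)
  calls <- mkCalls(rep("chr1", n), st, st + sample(c(4e4, 2e5), n, TRUE),
                   sample(s$sample_id, n, replace = TRUE),
                   sample(c(1L, 3L), n, replace = TRUE))
  bm <- computeBurdenMetrics(calls, s, genes)
  for (i in seq_len(nrow(s))) {
    sel <- sampleIds(calls) == s$sample_id[i] & isDeletion(calls)
    hit <- rep(FALSE, 3)
    for (g in 1:3)
      for (j in which(sel))
        if (start(calls)[j] <= end(genes)[g] &&
            end(calls)[j] >= start(genes)[g]) hit[g] <- TRUE
    expect_equal(bm$genes_del[i], sum(hit))
  }
})

test_that("constrained-kb metrics sum covered bases above threshold", {
  s <- mkSamples(2, dataset = "d1")
  constraint <- RegionSet(rep("chr1", 3), c(100000, 110000, 200000),
                          c(104999, 112999, 204999), name = "constraint",
                          score = c(3, 1, 5))
  calls <- mkCalls("chr1", 95000, 210000, "S0001", 1L)
  bm <- computeBurdenMetrics(calls, s, mkGenes(), constraint)
  expect_equal(bm$constrained_kb_del_ge2[1], 10)   # 5 kb + 5 kb
  expect_equal(bm$constrained_kb_del_ge4[1], 5)    # score-5 element only
})

test_that("covariate screening requires both associations", {
  set.seed(8)
  n <- 400
  s <- mkSamples(n, dataset = "d1")
  raw <- rpois(n, 1.5)
  ## perfect association with case status and with the raw count
  s$PC6 <- as.numeric(s$is_case) + rnorm(n, 0, 0.1)
  raw2 <- raw + round(2 * s$PC6)
  sel <- selectCovariates(s, raw2, candidates = c("PC6", "PC8"))
  expect_true("PC6" %in% sel)
  expect_false("PC8" %in% sel)
  expect_true(all(c("PC1", "PC5", "sex") %in% sel))
  s$PC9 <- 1
  expect_warning(selectCovariates(s, raw, candidates = "PC9"), "constant")
})

test_that("a null candidate is excluded at close to the nominal rate", {
  set.seed(15)
  n <- 250
  kept <- 0L
  for (r in 1:100) {
    s <- mkSamples(n, dataset = "d1", seed = 1000 + r)
    raw <- rpois(n, 1.5)
    sel <- selectCovariates(s, raw, candidates = "PC6")
    if (!("PC6" %in% sel)) kept <- kept + 1L
  }
  expect_gte(kept, 90L)  # ~99.75% expected under the double screen
})

test_that("the confounded mimic cohort reproduces the printed model", {
  set.seed(4)
  n <- 1500
  s <- mkSamples(n, cases = 0, dataset = rep(c("a", "b"), each = n / 2))
  ## case status depends on PC7; raw counts depend on PC7 and LRRSD;
  ## LRRSD differs by case collection
  s$is_case <- runif(n) < plogis(-0.2 + 0.8 * s$PC7)
  s$lrrsd <- exp(rnorm(n, log(0.09) + 0.25 * s$is_case, 0.15))
  raw <- rpois(n, exp(0.3 + 0.25 * s$PC7 + 3 * (s$lrrsd - 0.09)))
  sel <- selectCovariates(s, raw)
  expect_setequal(sel, c("PC1", "PC2", "PC3", "PC4", "PC5", "sex",
                         "PC7", "lrrsd"))
})

test_that("logistic burden test handles null, separation and 2x2 cases", {
  n <- 200
  s <- mkSamples(n, cases = n / 2, dataset = "d1")
  ## perfectly balanced metric: OR exactly 1
  metric <- rep(c(0, 1), n / 2)
  r <- logisticBurdenTest(metric, s, covariates = character(0))
  expect_equal(r$estimate, 1, tolerance = 1e-6)
  ## metric equal to the case indicator: separation flagged
  r2 <- logisticBurdenTest(as.numeric(s$is_case), s,
                           covariates = character(0))
  expect_true(r2$separation)
  expect_equal(r2$ci_hi, Inf)
  ## binary carrier metric without covariates equals the 2x2 odds ratio
  set.seed(2)
  carrier <- rbinom(n, 1, ifelse(s$is_case, 0.3, 0.15))
  r3 <- logisticBurdenTest(carrier, s, covariates = character(0))
  tab <- table(carrier, s$is_case)
  or <- (tab["1", "TRUE"] * tab["0", "FALSE"]) /
    (tab["0", "TRUE"] * tab["1", "FALSE"])
  expect_equal(r3$estimate, or, tolerance = 1e-4)
  expect_error(logisticBurdenTest(metric, within(s, is_case <- TRUE),
                                  character(0)), "single class")
})

test_that("linear excess test estimates the case shift", {
  n <- 300
  s <- mkSamples(n, cases = n / 2, dataset = "d1")
  metric <- rep(c(2, 3), n / 2)  # identical distribution in both groups
  metric[s$is_case] <- metric[s$is_case]
  r <- linearExcessTest(metric, s, covariates = character(0))
  expect_equal(r$estimate, 0, tolerance = 1e-10)
  ## adding a covariate orthogonal to case and metric leaves the
  ## estimate unchanged
  set.seed(3)
  z <- rnorm(n)
  z <- residuals(lm(z ~ as.numeric(s$is_case) + metric))
  s$PC6 <- z
  r2 <- linearExcessTest(metric, s, covariates = "PC6")
  expect_equal(r2$estimate, r$estimate, tolerance = 1e-8)
  ## collinear design errors with the offending column named
  s$PC7 <- as.numeric(s$is_case)
  expect_error(linearExcessTest(metric, s, covariates = "PC7"),
               "collinear")
})

test_that("planted case excess is recovered within sampling error", {
  set.seed(77)
  n <- 4000
  s <- mkSamples(n, cases = n / 2, dataset = "d1")
  metric <- rpois(n, 1.4 + 0.07 * s$is_case)
  r <- linearExcessTest(metric, s, covariates = character(0))
  se <- (r$ci_hi - r$ci_lo) / (2 * 1.96)
  expect_lt(abs(r$estimate - 0.07), 3 * se)
})

test_that("leave-one-out reproduces the full fit on exchangeable data", {
  n <- 400
  s <- mkSamples(n, cases = 0, dataset = rep(c("a", "b"), n / 2))
  ## identical datasets by construction: alternate assignment
  set.seed(6)
  s$is_case <- rep(rbinom(n / 2, 1, 0.5), each = 2) == 1
  metric <- rep(rpois(n / 2, 1.5), each = 2)
  full <- linearExcessTest(metric, s, covariates = character(0))
  loo <- leaveOneOutBurden(metric, s, covariates = character(0),
                           model = "linear")
  ds_rows <- loo[startsWith(loo$held_out, "dataset:"), ]
  expect_equal(ds_rows$estimate, rep(full$estimate, 2), tolerance = 1e-8)
  expect_error(leaveOneOutBurden(metric, within(s, dataset <- "a"),
                                 character(0), "linear"), "2 datasets")
  ## a held-out fit with one outcome class is flagged and skipped
  s2 <- s; s2$is_case[s2$dataset == "b"] <- TRUE
  s2$is_case[s2$dataset == "a"] <- rep(c(TRUE, FALSE), n / 4)
  loo2 <- leaveOneOutBurden(metric, s2, character(0), "logistic")
  row_a <- loo2[loo2$held_out == "dataset:a", ]
  expect_equal(row_a$note, "single outcome class")
  expect_true(is.na(row_a$estimate))
})
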