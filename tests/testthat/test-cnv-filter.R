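probes1 <- mkProbes(2e6, 1000)   # chr1, probe every kb

test_that("consensus is the per-sample same-direction intersection", {
  A <- mkCalls("chr1", 100000, 200000, "S1", 1L)
  B <- mkCalls("chr1", 150000, 260000, "S1", 1L)
  cons <- intersectCallsets(A, B, probes1)
  expect_equal(c(start(cons), end(cons)), c(150000L, 200000L))
  expect_equal(nProbes(cons), sum(start(probes1) >= 150000 &
                                  start(probes1) <= 200000))
  expect_equal(callerLabel(cons), "consensus")

  ## identical callsets reproduce the input (up to probe recount)
  X <- mkCalls(c("chr1", "chr1"), c(5e4, 9e5), c(1e5, 1e6),
               c("S1", "S2"), c(1L, 3L))
  cons2 <- intersectCallsets(X, X, probes1)
  expect_equal(granges(cons2), granges(BiocGenerics::sort(X)),
               ignore_attr = TRUE)

  ## a deletion present in one callset only is dropped
  expect_length(intersectCallsets(A, mkCalls(character(0), integer(0),
                                             integer(0), character(0),
                                             integer(0), integer(0)),
                                  probes1), 0)
  ## opposite directions never pair
  expect_length(intersectCallsets(A, mkCalls("chr1", 150000, 260000,
                                             "S1", 3L), probes1), 0)
  ## different samples never pair
  expect_length(intersectCallsets(A, mkCalls("chr1", 150000, 260000,
                                             "S2", 1L), probes1), 0)
  ## unknown sample triggers an error when a sheet is supplied
  expect_error(intersectCallsets(A, B, probes1, mkSamples(4)),
               "absent from the sample sheet")
})

test_that("size filter bounds are inclusive", {
  cfg <- filterConfig()
  calls <- CnvCalls(rep("chr1", 3), c(1e5, 2e5, 3e5),
                    c(1e5 + 49999, 2e5 + 29998, 3e5 + 29999),
                    c("S1", "S2", "S3"), 1L, c(14L, 20L, 15L))
  out <- applySizeFilter(calls, cfg)
  fl <- filterFlags(out)
  expect_equal(unlist(fl[1]), "SIZE")   # 14 probes
  expect_equal(unlist(fl[2]), "SIZE")   # 29,999 bp
  expect_length(unlist(fl[3]), 0)       # 15 probes, 30,000 bp
})

test_that("mask filters apply the strict 30% and any-overlap rules", {
  cfg <- filterConfig()
  masks <- list(
    segdup = RegionSet("chr1", 1e5, 1e5 + 29999, name = "segdup"),
    tcr_ig = RegionSet("chr1", 5e5, 6e5, name = "tcr_ig"),
    lcl_artifact = RegionSet(name = "lcl_artifact"))
  ## overlap exactly 0.30 with segdup -> kept
  c1 <- mkCalls("chr1", 1e5, 1e5 + 99999, "S1", 1L)
  ## 1 bp overlap with the Ig region -> removed
  c2 <- mkCalls("chr1", 4e5, 5e5, "S1", 1L)
  ## disjoint from everything
  c3 <- mkCalls("chr1", 1e6, 1.1e6, "S1", 1L)
  calls <- suppressWarnings(c(c1, c2, c3))
  out <- applyRegionFilters(calls, masks, cfg)
  fl <- filterFlags(out)
  expect_length(unlist(fl[1]), 0)
  expect_equal(unlist(fl[2]), "TCR_IG")
  expect_length(unlist(fl[3]), 0)
  expect_error(applyRegionFilters(calls, masks["segdup"], cfg),
               "unknown mask")
})

test_that("region flags match a brute-force recomputation", {
  set.seed(11)
  for (rep_i in 1:10) {
    nm <- sample(2:5, 1)
    ms <- sample(1:8000, nm); me <- ms + sample(200:1500, nm, replace = TRUE)
    masks <- list(segdup = RegionSet(rep("chr1", nm), ms, me,
                                     name = "segdup"),
                  tcr_ig = RegionSet(name = "tcr_ig"),
                  lcl_artifact = RegionSet(name = "lcl_artifact"))
    nc <- 8
    cs <- sample(1:9000, nc); ce <- cs + sample(100:2500, nc, replace = TRUE)
    calls <- mkCalls(rep("chr1", nc), cs, ce, sprintf("S%d", 1:nc), 1L)
    out <- applyRegionFilters(calls, masks, filterConfig())
    for (i in seq_len(nc)) {
      frac <- bruteCoveredBp(cs[i], ce[i], ms, me, "c", rep("c", nm)) /
        (ce[i] - cs[i] + 1)
      expect_equal("SEGDUP" %in% unlist(filterFlags(out)[i]), frac > 0.30)
    }
  }
})

test_that("locus clustering matches all-pairs single linkage", {
  set.seed(23)
  for (rep_i in 1:8) {
    n <- sample(6:14, 1)
    st <- sample(seq(1, 3e5, by = 1e3), n)
    en <- st + sample(c(3e4, 5e4, 8e4), n, replace = TRUE)
    ty <- sample(c(1L, 3L), n, replace = TRUE)
    calls <- mkCalls(rep("chr1", n), st, en, sprintf("S%02d", 1:n), ty)
    got <- clusterCalls(calls)$assign
    want <- bruteClusters(rep("chr1", n), st, en,
                          ifelse(ty < 2, "del", "dup"), 0.5)
    ## same partition up to label renaming
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("frequency filter removes common loci, keeps singletons", {
  n <- 1000
  s <- mkSamples(n, dataset = "d1")
  ## one singleton + one locus carried by 15 distinct samples (1.5%)
  calls <- mkCalls(rep("chr1", 16),
                   c(1e6, rep(5e5, 15)), c(1.2e6, rep(5.6e5, 15)),
                   c("S0001", sprintf("S%04d", 101:115)), 1L)
  out <- clusterFrequencyFilter(calls, s, NULL, filterConfig())
  fl <- filterFlags(out)
  expect_length(unlist(fl[1]), 0)
  expect_true(all(vapply(fl[-1], function(f) "FREQ_INTERNAL" %in% f,
                         logical(1))))

  ## external reference matching: same type and >= 50% reciprocal overlap
  ref <- data.frame(chrom = "chr1", start = 1.0e6, end = 1.21e6,
                    cnv_type = c("del"), freq_global = 0.02)
  out2 <- clusterFrequencyFilter(calls, s, ref, filterConfig())
  expect_true("FREQ_EXTERNAL" %in% unlist(filterFlags(out2)[1]))
  ref$cnv_type <- "dup"
  out3 <- clusterFrequencyFilter(calls, s, ref, filterConfig())
  expect_false("FREQ_EXTERNAL" %in% unlist(filterFlags(out3)[1]))
  ref$cnv_type <- "del"; ref$freq_global <- 0.005
  out4 <- clusterFrequencyFilter(calls, s, ref, filterConfig())
  expect_false("FREQ_EXTERNAL" %in% unlist(filterFlags(out4)[1]))

  expect_error(clusterFrequencyFilter(calls, s[0, ], NULL),
               "denominator")
})

mkSignal <- function(sample_id, chrom, positions, baf) {
  data.frame(sample_id = sample_id, probe_id = sprintf("P%05d",
                                                       seq_along(positions)),
             chrom = chrom, pos = positions, lrr = 0, baf = baf,
             stringsAsFactors = FALSE)
}

test_that("BAF validation accepts clean patterns and rejects diploid ones", {
  cfg <- filterConfig()
  pos <- seq(100500, 119500, by = 1000)  # 20 probes inside the call
  call <- mkCalls("chr1", 100000, 120000, "S1", 1L)
  ## clean hemizygous: BAF at 0/1
  pm <- ProbeMap(probes1, mkSignal("S1", "chr1", pos,
                                   rep(c(0.01, 0.99), 10)))
  out <- bafValidate(call, pm, cfg)
  expect_length(unlist(filterFlags(out)), 0)
  ## 40% of probes near 0.5 -> diploid het band -> reject
  baf <- rep(c(0.01, 0.99), 10); baf[1:8] <- 0.5
  pm2 <- ProbeMap(probes1, mkSignal("S1", "chr1", pos, baf))
  out2 <- bafValidate(call, pm2, cfg)
  expect_true("BAF_REJECT" %in% unlist(filterFlags(out2)))
  ## clean trisomic duplication: bands at 1/3, 2/3 among 0/1 homs
  dup <- mkCalls("chr1", 100000, 120000, "S1", 3L)
  pm3 <- ProbeMap(probes1, mkSignal("S1", "chr1", pos,
                                    rep(c(0, 1/3, 2/3, 1), 5)))
  out3 <- bafValidate(dup, pm3, cfg)
  expect_length(unlist(filterFlags(out3)), 0)
  ## diploid segment mislabelled as duplication -> reject
  pm4 <- ProbeMap(probes1, mkSignal("S1", "chr1", pos,
                                    rep(c(0, 0.5, 0.5, 1), 5)))
  out4 <- bafValidate(dup, pm4, cfg)
  expect_true("BAF_REJECT" %in% unlist(filterFlags(out4)))
  ## too few informative probes -> BAF_UNTESTED, not removed
  pm5 <- ProbeMap(probes1, mkSignal("S1", "chr1", pos[1:5], rep(0, 5)))
  out5 <- bafValidate(call, pm5, cfg)
  expect_equal(unlist(filterFlags(out5)), "BAF_UNTESTED")
  expect_length(cascadeSurvivors(out5), 1)
  ## missing carrier signal is an error naming the call
  pm6 <- ProbeMap(probes1, mkSignal("OTHER", "chr1", pos, rep(0, 20)))
  expect_error(bafValidate(call, pm6, cfg), "S1 chr1:100000-120000")
  expect_equal(unlist(filterFlags(bafValidate(call, pm6, cfg,
                                              missingSignal = "untested"))),
               "BAF_UNTESTED")
})

test_that("BAF validation calibrates on simulated copy states", {
  set.seed(5)
  nrep <- 150
  pos <- seq(100500, 129500, by = 1000)  # 30 probes
  accept_cn3 <- 0L; reject_diploid <- 0L
  for (r in seq_len(nrep)) {
    geno3 <- rbinom(30, 3, 0.5) / 3
    baf3 <- pmin(pmax(geno3 + rnorm(30, 0, 0.03), 0), 1)
    dup <- mkCalls("chr1", 100000, 130000, "S1", 3L)
    pm <- ProbeMap(probes1, mkSignal("S1", "chr1", pos, baf3))
    f <- unlist(filterFlags(bafValidate(dup, pm)))
    if (!("BAF_REJECT" %in% f)) accept_cn3 <- accept_cn3 + 1L
    geno2 <- rbinom(30, 2, 0.5) / 2
    baf2 <- pmin(pmax(geno2 + rnorm(30, 0, 0.03), 0), 1)
    pm2 <- ProbeMap(probes1, mkSignal("S1", "chr1", pos, baf2))
    f2 <- unlist(filterFlags(bafValidate(dup, pm2)))
    if ("BAF_REJECT" %in% f2) reject_diploid <- reject_diploid + 1L
  }
  expect_gte(accept_cn3 / nrep, 0.95)
  expect_gte(reject_diploid / nrep, 0.90)
})

test_that("cascade flags are order-independent and survivors unflagged", {
  set.seed(3)
  n <- 40
  s <- mkSamples(n, dataset = "d1")
  st <- sample(seq(2e5, 1.5e6, by = 1e4), n)
  calls <- mkCalls(rep("chr1", n), st, st + 5e4,
                   s$sample_id[seq_len(n)], 1L)
  masks <- list(segdup = RegionSet("chr1", 3e5, 5e5, name = "segdup"),
                tcr_ig = RegionSet(name = "tcr_ig"),
                lcl_artifact = RegionSet(name = "lcl_artifact"))
  a <- applyRegionFilters(applySizeFilter(calls), masks)
  b <- applySizeFilter(applyRegionFilters(calls, masks))
  expect_equal(lapply(filterFlags(a), sort), lapply(filterFlags(b), sort))
  surv <- cascadeSurvivors(a)
  expect_true(all(lengths(removalFlags(surv)) == 0))
})
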