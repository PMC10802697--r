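test_that("stratum counts partition every sample exactly once", {
  s <- mkSamples(40)
  cnt <- stratumCounts(s$sample_id[c(1, 5, 9)], s)
  expect_equal(sum(cnt), 40L)
  expect_equal(sum(cnt[, c("case_carrier", "control_carrier")]), 3L)
  ## a sample contributes at most once
  cnt2 <- stratumCounts(rep(s$sample_id[1], 5), s)
  expect_equal(sum(cnt2[, c("case_carrier", "control_carrier")]), 1L)
})

test_that("exact CMH equals Fisher's two-sided test on one stratum", {
  set.seed(31)
  for (r in 1:300) {
    m <- matrix(c(rpois(2, 3), rpois(2, 8)) + c(0, 0, 1, 1), 2)
    counts <- matrix(c(m[1, 1], m[1, 2], m[2, 1], m[2, 2]), 1,
                     dimnames = list("SWE.M",
                                     c("case_carrier", "case_non",
                                       "control_carrier", "control_non")))
    got <- cmhExactTest(counts)
    want <- fisher.test(matrix(c(m[1, 1], m[2, 1], m[1, 2], m[2, 2]), 2))
    expect_equal(got$p_value, want$p.value, tolerance = 1e-9)
  }
})

test_that("exact CMH equals full enumeration on multi-stratum tables", {
  set.seed(32)
  for (r in 1:40) {
    counts <- matrix(0L, 4, 4, dimnames = list(
      c("SWE.M", "SWE.F", "NOR.M", "NOR.F"),
      c("case_carrier", "case_non", "control_carrier", "control_non")))
    for (s in 1:4) {
      n <- sample(6:15, 1); k <- sample(2:(n - 2), 1)
      m <- sample(0:4, 1)
      a <- if (m) rhyper(1, m, n - m, k) else 0L
      counts[s, ] <- c(a, k - a, m - a, n - k - (m - a))
    }
    got <- cmhExactTest(counts)$p_value
    expect_equal(got, bruteCmhP(counts), tolerance = 1e-9)
  }
})

test_that("exact CMH is invariant to stratum order and joint label swaps", {
  counts <- matrix(c(3, 17, 1, 29,
                     2, 28, 2, 38,
                     1, 9, 0, 10,
                     0, 20, 1, 19), 4, 4, byrow = TRUE,
                   dimnames = list(NULL, c("case_carrier", "case_non",
                                           "control_carrier",
                                           "control_non")))
  p0 <- cmhExactTest(counts)$p_value
  expect_equal(cmhExactTest(counts[c(3, 1, 4, 2), ])$p_value, p0)
  swapped <- counts[, c(4, 3, 2, 1)]
  colnames(swapped) <- colnames(counts)
  expect_equal(cmhExactTest(swapped)$p_value, p0)
  ## all-zero carriers: degenerate
  z <- counts; z[, c(1, 3)] <- 0L
  res <- cmhExactTest(z)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
  ## equal carrier proportions in every stratum: p close to 1, OR ~ 1
  eq <- matrix(c(5, 45, 5, 45), 4, 4, byrow = TRUE,
               dimnames = dimnames(counts))
  res_eq <- cmhExactTest(eq)
  expect_gt(res_eq$p_value, 0.99)
  expect_equal(res_eq$odds_ratio, 1, tolerance = 1e-9)
})

test_that("gene clumping follows the >50% co-impact rule", {
  genes <- RegionSet(rep("chr1", 3), c(1e5, 3e5, 6e5),
                     c(2e5, 4e5, 7e5), name = "genes",
                     gene_id = c("G1", "G2", "G3"),
                     pli = c(0.1, 0.1, 0.1))
  ## every call spans G1 and G2; none touches G3
  calls <- mkCalls(rep("chr1", 4), rep(9e4, 4), rep(4.5e5, 4),
                   sprintf("S%d", 1:4), 1L)
  units <- clumpGeneUnits(calls, genes, "del")
  expect_length(units, 1)
  expect_setequal(units[[1]]$members, c("G1", "G2"))
  expect_length(units[[1]]$carriers, 4)

  ## two genes never co-hit stay separate units
  calls2 <- mkCalls(rep("chr1", 4), c(9e4, 9e4, 5.5e5, 5.5e5),
                    c(2.5e5, 2.5e5, 7.5e5, 7.5e5),
                    sprintf("S%d", 1:4), 1L)
  units2 <- clumpGeneUnits(calls2, genes, "del")
  expect_length(units2, 2)
  expect_equal(sort(vapply(units2, function(u) u$members[1],
                           character(1))), c("G1", "G3"))
})

test_that("clumping agrees with brute-force evaluation of the rule", {
  set.seed(41)
  for (rep_i in 1:10) {
    ng <- 6
    gs <- seq(1e5, by = 2e5, length.out = ng)
    genes <- RegionSet(rep("chr1", ng), gs, gs + 1e5, name = "genes",
                       gene_id = sprintf("G%d", 1:ng), pli = 0.1)
    nc <- 12
    cs <- sample(seq(5e4, 1.3e6, by = 2.5e4), nc)
    calls <- mkCalls(rep("chr1", nc), cs,
                     cs + sample(c(1.2e5, 3e5), nc, TRUE),
                     sprintf("S%02d", 1:nc), 1L)
    units <- clumpGeneUnits(calls, genes, "del")
    ## brute force: per-gene call sets, then transitive adjacent merging
    sets <- lapply(1:ng, function(g)
      which(start(calls) <= end(genes)[g] & end(calls) >= start(genes)[g]))
    grp <- seq_len(ng)
    for (g in 2:ng) {
      u <- union(sets[[g - 1]], sets[[g]])
      b <- intersect(sets[[g - 1]], sets[[g]])
      if (length(u) && length(b) / length(u) > 0.5)
        grp[grp == grp[g]] <- grp[g - 1]
    }
    want <- table(grp[lengths(sets) > 0])
    got <- vapply(units, function(u) length(u$members), integer(1))
    expect_equal(sort(unname(got)), sort(as.integer(want)))
  }
})

test_that("probe clumping separates disjoint breakpoint clusters", {
  probes <- mkProbes(2e6, 1000)
  ## calls sharing identical breakpoints form one unit
  calls <- mkCalls(rep("chr1", 3), rep(100000, 3), rep(120000, 3),
                   sprintf("S%d", 1:3), 1L)
  units <- clumpProbeUnits(calls, probes, "del")
  expect_length(units, 1)
  expect_equal(length(units[[1]]$members),
               sum(start(probes) >= 1e5 & start(probes) <= 1.2e5))
  ## two disjoint call clusters give two units
  calls2 <- suppressWarnings(c(calls,
    mkCalls(rep("chr1", 2), rep(5e5, 2), rep(5.4e5, 2),
            c("S7", "S8"), 1L)))
  units2 <- clumpProbeUnits(calls2, probes, "del")
  expect_length(units2, 2)
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bhFdr(0.04), 0.04)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_error(bhFdr(c(0.1, NA)), "missing")
  expect_error(bhFdr(c(0.1, 1.2)), "0, 1")
  set.seed(51)
  for (r in 1:20) {
    p <- round(runif(sample(3:12, 1)), 3)
    expect_equal(bhFdr(p), bruteBh(p))
  }
})

test_that("assocTests produces monotone q-values and correct counts", {
  set.seed(61)
  s <- mkSamples(200)
  genes <- RegionSet(rep("chr1", 4), seq(1e5, by = 3e5, length.out = 4),
                     seq(1e5, by = 3e5, length.out = 4) + 1e5,
                     name = "genes", gene_id = sprintf("G%d", 1:4),
                     pli = 0.1)
  nc <- 30
  gidx <- sample(1:4, nc, replace = TRUE)
  calls <- mkCalls(rep("chr1", nc), start(genes)[gidx] - 1e4,
                   end(genes)[gidx] + 1e4,
                   sample(s$sample_id, nc, replace = TRUE), 1L)
  units <- clumpGeneUnits(calls, genes, "del")
  res <- assocTests(units, s)
  expect_true(all(res$q_value >= res$p_value))
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
  ## carrier counts sum to the distinct (sample, unit) incidences
  incid <- sum(vapply(units, function(u) length(unique(u$carriers)),
                      integer(1)))
  expect_equal(sum(res$n_case_carriers + res$n_control_carriers), incid)
})

test_that("permutation lambda is calibrated and self-consistent", {
  set.seed(71)
  s <- mkSamples(600)
  ## 40 multi-carrier units with label-independent carriers
  units <- lapply(1:40, function(i)
    list(unit_id = paste0("U", i),
         carriers = sample(s$sample_id, sample(3:8, 1))))
  suppressWarnings({
    lam <- permutationLambda(units, s, nPerm = 200L, seed = 5L)
  })
  expect_true(lam$reliable)
  expect_gt(lam$lambda, 0.85)
  expect_lt(lam$lambda, 1.15)
  ## identical permutations with the same seed
  lam2 <- permutationLambda(units, s, nPerm = 200L, seed = 5L)
  expect_equal(lam$lambda, lam2$lambda)
  expect_warning(permutationLambda(units[1:3], s, nPerm = 50L, seed = 1L),
                 "unreliable")
})

test_that("recurrence test is exact on edge cases and detects planting", {
  s <- mkSamples(400)
  empty <- CnvCalls()
  r0 <- recurrencePermutationTest(empty, s, "del", nPerm = 99L, seed = 1L)
  expect_equal(r0$T_obs, 0L)
  expect_equal(r0$p_value, 1)
  ## planted case-pair loci (two case carriers each) exceed what label
  ## permutation predicts; background loci carry random labels
  set.seed(9)
  cases <- s$sample_id[s$is_case]
  planted <- mkCalls(rep("chr1", 20),
                     rep(seq(1e5, by = 1e6, length.out = 10), each = 2),
                     rep(seq(1e5, by = 1e6, length.out = 10), each = 2) + 5e4,
                     cases[1:20], 1L)
  bg <- mkCalls(rep("chr2", 20),
                rep(seq(1e5, by = 1e6, length.out = 10), each = 2),
                rep(seq(1e5, by = 1e6, length.out = 10), each = 2) + 5e4,
                sample(s$sample_id, 20), 1L)
  calls <- suppressWarnings(c(planted, bg))
  r1 <- recurrencePermutationTest(calls, s, "del", nPerm = 199L, seed = 2L)
  expect_gte(r1$T_obs, 10L)
  expect_lt(r1$p_value, 0.05)
})
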