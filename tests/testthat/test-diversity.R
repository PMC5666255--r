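test_that("segregating sites counts variable unambiguous columns", {
  alnI <- HaploAlignment(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_equal(segregatingSites(alnI), 0L)
  expect_equal(segregatingSites(toyAlignment()), 2L)
  expect_error(segregatingSites(HaploAlignment(c(a = "ACGT"))),
               "sample-size")
  # complete deletion drops a column with an N before counting
  alnN <- HaploAlignment(c(a = "ACGT", b = "NCGA", c = "TCGA"))
  expect_equal(segregatingSites(alnN), 1L)
  expect_equal(segregatingSites(alnN, deletion = "pairwise"), 2L)
})

test_that("haplotype diversity follows Nei's unbiased formula", {
  expect_equal(haplotypeDiversity(5), 0)
  expect_equal(haplotypeDiversity(c(1, 1)), 1)
  expect_equal(haplotypeDiversity(c(3, 1)), 0.5)
  expect_equal(haplotypeDiversity(c(3, 1), corrected = FALSE), 6 / 16)
  expect_error(haplotypeDiversity(1), "sample-size")
  # invariant to relabeling; splitting a class increases H at fixed n
  set.seed(21)
  for (r in 1:20) {
    cnt <- rpois(5, 4) + 1L
    expect_equal(haplotypeDiversity(cnt), haplotypeDiversity(rev(cnt)))
    big <- which.max(cnt)
    if (cnt[big] >= 2) {
      split <- c(cnt[-big], cnt[big] - 1L, 1L)
      expect_gte(haplotypeDiversity(split), haplotypeDiversity(cnt))
    }
  }
})

test_that("pairwise diversity matches hand-enumerated values", {
  alnI <- HaploAlignment(c(a = "ACGT", b = "ACGT"))
  pdI <- pairwiseDiversity(alnI)
  expect_equal(pdI$Pi_bar, 0)
  expect_equal(pdI$pi, 0)

  pd <- pairwiseDiversity(toyAlignment())
  expect_equal(pd$Pi_bar, 7 / 6)
  expect_equal(pd$pi, 7 / 60)

  two <- HaploAlignment(c(a = paste(rep("A", 554), collapse = ""),
                          b = paste(c(rep("A", 553), "T"), collapse = "")))
  pd2 <- pairwiseDiversity(two)
  expect_equal(pd2$Pi_bar, 1)
  expect_equal(pd2$pi, 1 / 554)
})

test_that("Watterson's theta uses the harmonic-number scaling", {
  expect_equal(wattersonTheta(0, 10), 0)
  expect_equal(wattersonTheta(2, 4), 2 / (1 + 1 / 2 + 1 / 3))
  expect_error(wattersonTheta(3, 1), "sample-size")
  # internal consistency at study scale: theta_w between the bounds
  # implied by S and the harmonic number
  a1 <- sum(1 / (1:363))
  expect_equal(wattersonTheta(59, 364), 59 / a1)
})

test_that("private haplotypes and ratios follow the endemism definition", {
  m <- toyMeta(paste0("s", 1:10),
               rep(c("g1", "g2"), each = 5),
               region = rep(c("EA", "WS"), each = 5))
  # disjoint haplotype sets of sizes 3 and 2
  seqs <- c(s1 = "AAAA", s2 = "AAAT", s3 = "AATT", s4 = "AAAA",
            s5 = "AAAT", s6 = "GGGG", s7 = "GGGT", s8 = "GGGG",
            s9 = "GGGT", s10 = "GGGG")
  tab <- collapseHaplotypes(HaploAlignment(seqs, m), "population")
  ph <- privateHaplotypes(tab)
  expect_equal(ph$PH, c(3L, 2L))
  expect_equal(ph$PH_ratio, c(1, 1))

  # one shared haplotype only -> PH = 0 everywhere
  shared <- setNames(rep("ACGT", 10), paste0("s", 1:10))
  tabS <- collapseHaplotypes(HaploAlignment(shared, m), "population")
  expect_equal(privateHaplotypes(tabS)$PH, c(0L, 0L))

  # group with k = 4 of which 2 private -> ratio 0.5
  seqs2 <- c(s1 = "AAAA", s2 = "AAAT", s3 = "AATT", s4 = "ATTT",
             s5 = "AAAA", s6 = "AAAA", s7 = "AAAT", s8 = "GGGG",
             s9 = "GGGT", s10 = "GGGG")
  tab2 <- collapseHaplotypes(HaploAlignment(seqs2, m), "population")
  ph2 <- privateHaplotypes(tab2)
  g1 <- ph2[ph2$group == "g1", ]
  expect_equal(g1$k, 4L)
  expect_equal(g1$PH, 2L)
  expect_equal(g1$PH_ratio, 0.5)

  expect_error(privateHaplotypes(collapseHaplotypes(
    HaploAlignment(shared))), "grouping error")
})

test_that("sum of private haplotypes is bounded by the pooled count", {
  set.seed(22)
  for (r in 1:5) {
    sim <- simulateCoalescent(n = 30, theta = 3, model = "island",
                              demes = 3L, nPerDeme = c(10, 10, 10),
                              M = 2, L = 100)
    tab <- collapseHaplotypes(simAlignment(sim), "population")
    ph <- privateHaplotypes(tab)
    expect_lte(sum(ph$PH), nHaplotypes(tab))
    shared <- sum(rowSums(haplotypeCounts(tab) > 0) > 1)
    expect_equal(sum(ph$PH) == nHaplotypes(tab), shared == 0)
  }
})

test_that("diversity summary table is coherent across groups", {
  set.seed(23)
  sim <- simulateCoalescent(n = 24, theta = 4, model = "island",
                            demes = 2L, nPerDeme = c(12, 12), M = 1,
                            L = 120)
  div <- diversitySummary(simAlignment(sim), "population")
  expect_equal(div$group, c("deme1", "deme2", "all"))
  expect_equal(div$n, c(12L, 12L, 24L))
  expect_true(all(div$H >= 0 & div$H <= 1))
  expect_true(all(div$pi >= 0))
  expect_equal(div$pi, div$Pi_bar / 120)
  # the pooled haplotype count never exceeds the per-group sum
  expect_lte(div$k[3], div$k[1] + div$k[2])
  f <- tempfile(fileext = ".csv")
  out <- writeDiversitySummary(div, f)
  expect_equal(out$H, round(div$H, 5))
})
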