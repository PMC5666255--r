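makePopAln <- function(seqs, pops, regions = NULL) {
  ids <- names(seqs)
  if (is.null(regions)) regions <- rep("EA", length(ids))
  HaploAlignment(seqs, toyMeta(ids, pops, region = regions))
}

test_that("AMOVA reproduces the hand-computed variance partition", {
  # Pop1 = {A, A}, Pop2 = {A, B}, d(A,B) = 1:
  # SSD_total = 0.75, SSD_within = 0.5, equal mean squares -> PhiST = 0
  aln <- makePopAln(c(a1 = "AAAA", a2 = "AAAA", b1 = "AAAA",
                      b2 = "AAAT"),
                    c("p1", "p1", "p2", "p2"))
  am <- amova(aln, nPerm = 200, seed = 1)
  expect_equal(sum(am@table$SS), 0.75)
  expect_equal(am@table$SS[am@table$level == "within_populations"], 0.5)
  expect_equal(am@phi[["PhiST"]], 0)
  expect_equal(sum(am@table$df), 3L)

  # two populations fixed for different haplotypes: PhiST = 1
  aln2 <- makePopAln(setNames(rep(c("AAAA", "AAAT"), each = 8),
                              paste0("s", 1:16)),
                     rep(c("p1", "p2"), each = 8))
  am2 <- amova(aln2, nPerm = 200, seed = 1)
  expect_equal(am2@phi[["PhiST"]], 1)
  wp <- am2@table$percent[am2@table$level == "within_populations"]
  expect_equal(wp, 0)

  # identical composition in every population: PhiST <= 0, p high
  aln3 <- makePopAln(setNames(rep(c("AAAA", "AAAT"), 6), paste0("s", 1:12)),
                     rep(c("p1", "p2"), each = 6))
  am3 <- amova(aln3, nPerm = 200, seed = 1)
  expect_lte(am3@phi[["PhiST"]], 0)
  expect_gt(am3@p[["PhiST"]], 0.2)

  expect_error(amova(aln, nPerm = 0), "parameter error")
  one <- makePopAln(c(a = "AAAA", b = "AAAT"), c("p1", "p1"))
  expect_error(amova(one), "grouping error")
})

test_that("statistics are invariant to within-population relabeling and
           to duplicating every individual", {
  set.seed(60)
  sim <- simulateCoalescent(n = 24, theta = 3, model = "island",
                            demes = 2L, nPerDeme = c(12, 12), M = 0.5,
                            L = 200)
  aln <- simAlignment(sim)
  am <- amova(aln, nPerm = 10, seed = 2)
  # shuffle ids within each population (labels follow the samples)
  meta <- as.data.frame(alnMetadata(aln))
  perm <- unlist(lapply(split(meta$sample_id, meta$population), sample))
  am2 <- amova(aln[perm], nPerm = 10, seed = 2)
  expect_equal(am2@phi, am@phi)
  expect_equal(am2@table$sigma2, am@table$sigma2)

  # duplicate every individual: point estimates unchanged
  seqs <- as.character(alnSequences(aln))
  dup <- c(seqs, setNames(seqs, paste0(names(seqs), "_d")))
  popd <- rep(meta$population, 2)
  alnD <- makePopAln(dup, popd)
  amD <- amova(alnD, nPerm = 10, seed = 2)
  # the df-corrected (unbiased) variance components shift slightly when
  # every individual is duplicated; the point estimate is only
  # asymptotically invariant
  expect_equal(amD@phi[["PhiST"]], am@phi[["PhiST"]], tolerance = 0.05)
})

test_that("two-level AMOVA on a pair equals the pairwise Phi-ST entry", {
  set.seed(61)
  sim <- simulateCoalescent(n = 30, theta = 4, model = "island",
                            demes = 3L, nPerDeme = c(10, 10, 10), M = 1,
                            L = 150)
  aln <- simAlignment(sim)
  pw <- pairwisePhiST(aln, nPerm = 50, seed = 3)
  meta <- as.data.frame(alnMetadata(aln))
  keep <- meta$sample_id[meta$population %in% c("deme1", "deme3")]
  amp <- amova(aln[keep], nPerm = 50, seed = 3)
  expect_equal(pw$phist["deme1", "deme3"], amp@phi[["PhiST"]],
               tolerance = 1e-12)
  expect_equal(diag(pw$phist), setNames(rep(0, 3), rownames(pw$phist)))
  expect_true(all(pw$p >= 0 & pw$p <= 1, na.rm = TRUE))
  # undersized population flagged undefined
  small <- c(keep, meta$sample_id[meta$population == "deme2"][1])
  pws <- pairwisePhiST(aln[small], nPerm = 20, seed = 1)
  expect_true(is.na(pws$phist["deme1", "deme2"]))
})

test_that("three-level AMOVA partitions coherently and agrees with a
           PERMANOVA cross-check on the SS decomposition", {
  set.seed(62)
  sim <- simulateCoalescent(n = 40, theta = 4, model = "island",
                            demes = 4L, nPerDeme = rep(10, 4), M = 0.5,
                            L = 600)
  aln <- simAlignment(sim)
  meta <- as.data.frame(alnMetadata(aln))
  grp <- ifelse(meta$population %in% c("deme1", "deme2"), "g1", "g2")
  names(grp) <- meta$sample_id
  am <- amova(aln, groups = grp, nPerm = 50, seed = 4)
  expect_equal(sum(am@table$percent), 100, tolerance = 1e-6)
  expect_equal(sum(am@table$df), length(aln) - 1L)
  expect_length(am@phi, 3L)

  # vegan::adonis2 on sqrt distances partitions the same total SS
  d <- pairwiseDifferences(aln)
  dd <- stats::as.dist(sqrt(d))
  pop <- meta$population
  adn <- vegan::adonis2(dd ~ pop, permutations = 2)
  expect_equal(sum(am@table$SS), adn$SumOfSqs[nrow(adn)],
               tolerance = 1e-9)
  am2 <- amova(aln, nPerm = 5, seed = 1)
  expect_equal(am2@table$SS[am2@table$level == "within_populations"],
               adn$SumOfSqs[2], tolerance = 1e-9)
})
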