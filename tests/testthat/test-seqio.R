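test_that("FASTA reading parses, uppercases, maps U to T and validates", {
  p <- writeFasta(c(s1 = "ACGT", s2 = "ACGA"))
  aln <- readAlignment(p)
  expect_s4_class(aln, "HaploAlignment")
  expect_equal(length(aln), 2L)
  expect_equal(alignmentLength(aln), 4L)
  expect_equal(names(aln), c("s1", "s2"))

  p2 <- writeFasta(c(a = "acgu"))
  expect_equal(as.character(alnSequences(readAlignment(p2))[[1]]), "ACGT")

  # wrapped FASTA reads identically to single-line
  long <- paste(rep("ACGT", 30), collapse = "")
  pw <- writeFasta(c(x = long), width = 17)
  expect_equal(as.character(alnSequences(readAlignment(pw))[[1]]), long)

  expect_error(readAlignment(writeFasta(c(a = "ACGT", b = "ACGTA"))),
               "alignment error")
  pe <- tempfile(); writeLines(character(0), pe)
  expect_error(readAlignment(pe), "input error")
  expect_error(readAlignment(writeFasta(c(ok = "ACGT", bad = "ACXT"))),
               "bad")
})

test_that("metadata reading enforces the declared schema", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,population,region,subregion,lat,lon,depth_m",
               "s1,TA_deep,EA,TA,-66.5,140.0,430"), p)
  m <- readSampleMetadata(p)
  expect_equal(m$region, "EA")
  expect_equal(m$depth_m, 430)

  p2 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,population", "s1,x"), p2)
  expect_error(readSampleMetadata(p2), "missing column")

  p3 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,population,region,subregion,lat,lon,depth_m",
               "s1,x,EA,XX,0,0,10"), p3)
  expect_error(readSampleMetadata(p3), "subregion")

  # unknown region caught by the alignment container
  expect_error(HaploAlignment(c(s1 = "ACGT"),
                              toyMeta("s1", "x", region = "ZZ")),
               "region")
})

test_that("haplotype collapsing follows the ambiguity policy", {
  aln <- HaploAlignment(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGA"))
  tab <- collapseHaplotypes(aln)
  expect_equal(nHaplotypes(tab), 2L)
  expect_equal(as.integer(haplotypeCounts(tab)), c(2L, 1L))
  expect_equal(names(haplotypeSequences(tab)), c("H1", "H2"))

  alnN <- HaploAlignment(c(s1 = "ACGT", s2 = "ACGN"))
  expect_equal(nHaplotypes(collapseHaplotypes(alnN)), 1L)
  expect_equal(nHaplotypes(collapseHaplotypes(alnN, policy = "strict")), 2L)

  tab4 <- collapseHaplotypes(toyAlignment())
  expect_equal(nHaplotypes(tab4), 3L)
  expect_equal(as.integer(haplotypeCounts(tab4)), c(2L, 1L, 1L))

  # metadata-bearing alignments group by the requested column
  aln2 <- HaploAlignment(c(s1 = "ACGT", s2 = "ACGA"),
                         toyMeta(c("s1", "s2"), c("p1", "p2")))
  tab2 <- collapseHaplotypes(aln2, "population")
  expect_equal(colnames(haplotypeCounts(tab2)), c("p1", "p2"))
  # metadata that fails to cover every record is rejected up front
  expect_error(HaploAlignment(c(s1 = "ACGT", s2 = "ACGA"),
                              toyMeta("s1", "p1")),
               "match")
})

test_that("collapsing conserves n over groupings and policies", {
  set.seed(30)
  for (r in 1:5) {
    sim <- simulateCoalescent(25, theta = 4, L = 80)
    aln <- simAlignment(sim)
    for (pol in c("wildcard", "strict")) {
      tab <- collapseHaplotypes(aln, "population", pol)
      expect_equal(sum(haplotypeCounts(tab)), length(aln))
    }
  }
})

test_that("pairwise differences match hand enumeration and invariants", {
  aln <- HaploAlignment(c(a = "ACGT", b = "ACGA"))
  d <- pairwiseDifferences(aln)
  expect_equal(d["a", "b"], 1)
  expect_equal(pairwiseDifferences(aln, mode = "p_distance")["a", "b"],
               0.25)

  d4 <- pairwiseDifferences(toyAlignment())
  expect_equal(d4["s1", "s2"], 1)
  expect_equal(d4["s1", "s3"], 2)
  expect_equal(d4["s1", "s4"], 0)
  expect_equal(d4["s2", "s3"], 1)
  expect_equal(d4["s2", "s4"], 1)
  expect_equal(d4["s3", "s4"], 2)
  expect_true(isSymmetric(unname(d4)))
  expect_equal(diag(d4), setNames(rep(0, 4), names(toyAlignment())))

  # identical rows give the zero matrix
  alnI <- HaploAlignment(c(x = "ACGT", y = "ACGT", z = "ACGT"))
  expect_true(all(pairwiseDifferences(alnI) == 0))

  # permuting records permutes the matrix conformally
  perm <- c("s3", "s1", "s4", "s2")
  dp <- pairwiseDifferences(toyAlignment()[perm])
  expect_equal(dp, d4[perm, perm], ignore_attr = TRUE)

  # gap-free alignments: p * L equals the count matrix exactly
  set.seed(31)
  sim <- simulateCoalescent(12, theta = 3, L = 60)
  cnt <- pairwiseDifferences(simAlignment(sim))
  p <- pairwiseDifferences(simAlignment(sim), mode = "p_distance")
  expect_equal(p * 60, cnt, ignore_attr = TRUE)

  expect_error(pairwiseDifferences(HaploAlignment(c(a = "ACGT"))),
               "sample-size")
  expect_error(pairwiseDifferences(HaploAlignment(c(a = "NNNN",
                                                    b = "ACGT"))),
               "undefined-distance")
})

test_that("tabular writers round-trip ids and counts", {
  tab <- collapseHaplotypes(toyAlignment())
  f <- tempfile(fileext = ".csv")
  writeHaplotypeTable(tab, f)
  back <- read.csv(f, check.names = FALSE)
  expect_equal(back$haplotype_id, c("H1", "H2", "H3"))
  expect_equal(back$all, c(2L, 1L, 1L))

  d <- pairwiseDifferences(toyAlignment())
  f2 <- tempfile(fileext = ".csv")
  writeDistanceMatrix(d, f2)
  back2 <- read.csv(f2, check.names = FALSE)
  expect_equal(back2$id, names(toyAlignment()))
  expect_equal(back2$s3[1], 2)
})
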