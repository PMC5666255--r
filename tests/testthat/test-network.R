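test_that("parsimony probabilities: production equals the dense-grid
           oracle and limits behave", {
  for (L in c(100, 554)) {
    prod <- vapply(1:15, parsimonyProbability, 0, L = L)
    orac <- vapply(1:15, parsimonyProbabilityOracle, 0, L = L)
    expect_equal(prod, orac, tolerance = 1e-6)
    expect_true(all(diff(prod) < 0))   # harder with more steps
  }
  # nested criteria: a stricter alpha never allows more steps
  for (L in c(100, 554, 1000))
    expect_lte(connectionLimit(L, 0.95), connectionLimit(L, 0.90))
  # vacuous probability bound connects everything
  expect_equal(connectionLimit(10, 1e-9), 10L)
  # frozen regression constant from the oracle at study scale
  expect_equal(connectionLimit(554, 0.95), 8L)
  expect_error(connectionLimit(554, 1.2), "parameter error")
})

test_that("network construction contracts: singletons, single steps,
           forced paths", {
  one <- collapseHaplotypes(HaploAlignment(c(a = "ACGT", b = "ACGT")))
  net1 <- buildNetwork(one, limit = 5)
  expect_equal(nrow(net1@nodes), 1L)
  expect_equal(igraph::ecount(net1@graph), 0L)
  expect_equal(ancestralHaplotype(net1), "H1")

  two <- collapseHaplotypes(HaploAlignment(c(a = "ACGT", b = "ACGA")))
  net2 <- buildNetwork(two, limit = 5)
  expect_equal(nrow(net2@nodes), 2L)
  expect_equal(igraph::ecount(net2@graph), 1L)
  expect_equal(sum(net2@nodes$inferred), 0L)

  # 3 steps apart with limit >= 3: exactly 2 inferred intermediates
  tab <- collapseHaplotypes(HaploAlignment(
    c(x1 = "AAAA", x2 = "AAAA", x3 = "AAAA", x4 = "AAAA", x5 = "AAAA",
      y1 = "TTTA")))
  net3 <- buildNetwork(tab, limit = 5)
  expect_equal(sum(net3@nodes$inferred), 2L)
  expect_equal(igraph::ecount(net3@graph), 3L)
  # every edge spans exactly one mutational step
  ed <- igraph::as_data_frame(net3@graph, what = "edges")
  seqOf <- setNames(net3@nodes$sequence, net3@nodes$id)
  for (e in seq_len(nrow(ed))) {
    a <- strsplit(seqOf[[ed$from[e]]], "")[[1]]
    b <- strsplit(seqOf[[ed$to[e]]], "")[[1]]
    expect_equal(sum(a != b), 1L)
    expect_equal(which(a != b), ed$site[e])
  }
  # intermediates mutate sites in ascending order from the frequent end
  expect_equal(ed$site, c(1L, 2L, 3L))

  # beyond the limit the pair stays unconnected
  netL <- buildNetwork(tab, limit = 2)
  expect_equal(igraph::ecount(netL@graph), 0L)
  expect_equal(igraph::count_components(netL@graph), 2L)
})

test_that("networks are forests and conserve observed frequencies", {
  set.seed(70)
  for (r in 1:6) {
    sim <- simulateCoalescent(40, model = "sudden", theta0 = 0.05,
                              theta1 = 15, tau = 3, L = 300)
    tab <- collapseHaplotypes(simAlignment(sim))
    net <- buildNetwork(tab, limit = 10)
    g <- net@graph
    expect_equal(igraph::ecount(g),
                 igraph::vcount(g) - igraph::count_components(g))
    expect_equal(sum(net@nodes$freq), 40)
    infDeg <- igraph::degree(g)[net@nodes$inferred]
    if (length(infDeg)) expect_true(all(infDeg >= 2))
  }
})

test_that("ancestral designation prefers frequent, connected haplotypes", {
  # star: center frequency 10, tips frequency 1
  seqs <- c(setNames(rep("AAAAA", 10), paste0("c", 1:10)),
            t1 = "TAAAA", t2 = "ATAAA", t3 = "AATAA")
  net <- buildNetwork(collapseHaplotypes(HaploAlignment(seqs)), limit = 3)
  expect_equal(ancestralHaplotype(net), "H1")
  expect_false(net@ancestralTied)

  # equal frequency, equal degree: lower id wins and the tie is flagged
  two <- buildNetwork(collapseHaplotypes(HaploAlignment(
    c(a = "ACGT", b = "ACGA"))), limit = 5)
  expect_equal(ancestralHaplotype(two), "H1")
  expect_true(two@ancestralTied)
})

test_that("the designated ancestor usually is the simulated root under
           star-like expansion", {
  set.seed(71)
  hits <- 0L
  nrep <- 100L
  for (r in seq_len(nrep)) {
    sim <- simulateCoalescent(50, model = "sudden", theta0 = 0.01,
                              theta1 = 20, tau = 3)
    net <- buildNetwork(collapseHaplotypes(simAlignment(sim)),
                        limit = 10)
    anc <- ancestralHaplotype(net)
    ancSeq <- net@nodes$sequence[net@nodes$id == anc]
    if (identical(ancSeq, simRootHaplotype(sim))) hits <- hits + 1L
  }
  expect_gte(hits, 60L)
})

test_that("GraphML and CSV exports carry the node annotations", {
  tab <- collapseHaplotypes(HaploAlignment(
    c(a = "AAAA", b = "AAAT", c = "AAAT")))
  net <- buildNetwork(tab, limit = 5)
  paths <- writeNetworkGraphML(net, tempfile())
  expect_true(all(file.exists(paths)))
  nodes <- read.csv(paths[["nodes"]])
  expect_equal(sort(nodes$id), c("H1", "H2"))
  gml <- readLines(paths[["graphml"]])
  expect_true(any(grepl("graphml", gml)))
})
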