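# Statistical-parsimony haplotype network with a 95% connection limit.

# Parsimony probability that two sequences of length L observed to
# differ at j sites are connected without superimposed change: every
# one of the j differing sites arose by exactly one mutation (no
# multiple hits at the variable sites).  Under a Jukes-Cantor site
# model with expected per-site mutation count lambda along the path,
# P(site differs) = q = 3/4 (1 - exp(-4 lambda/3)) and P(exactly one
# mutation, hence a difference) = lambda exp(-lambda); averaging over
# the posterior of q given (j, L) with a uniform prior on q in (0, 3/4):
#   P_j = Int w(q) [lam(q) e^-lam(q) / q]^j dq / Int w(q) dq
# with binomial weight w(q) = q^j (1-q)^(L-j).
.parsimonyIntegrands <- function(j, L) {
  lam <- function(q) -0.75 * log1p(-4 * q / 3)
  list(num = function(q) {
         l <- lam(q)
         exp(j * (log(l) - l) + (L - j) * log1p(-q))
       },
       den = function(q) exp(j * log(q) + (L - j) * log1p(-q)))
}

# the posterior is sharply peaked near j/L; split the quadrature there
.parsimonyCuts <- function(j, L) {
  qhat <- (j + 1) / (L + 2)
  sort(unique(pmin(pmax(c(0, qhat / 5, qhat * 5, 0.75), 0), 0.75)))
}

#' Parsimony connection probability (production routine)
#'
#' Probability, under the statistical-parsimony criterion, that two
#' haplotypes observed to differ at \code{j} of \code{L} sites are
#' connected without superimposed (multiple-hit) change.  Evaluated by
#' adaptive quadrature; [parsimonyProbabilityOracle()] is the slow dense
#' Riemann-grid reference.
#'
#' @param j Number of observed differences (>= 1).
#' @param L Sequence length.
#' @return Probability in (0, 1).
#' @export
parsimonyProbability <- function(j, L) {
  f <- .parsimonyIntegrands(j, L)
  cuts <- .parsimonyCuts(j, L)
  piece <- function(fun) sum(vapply(seq_len(length(cuts) - 1L),
    function(i) stats::integrate(fun, cuts[i], cuts[i + 1L],
                                 rel.tol = 1e-10,
                                 subdivisions = 500L)$value, 0))
  piece(f$num) / piece(f$den)
}

#' Parsimony connection probability (dense-grid oracle)
#'
#' Same quantity as [parsimonyProbability()], computed by midpoint
#' Riemann summation on a dense fixed grid; kept as an independent
#' reference implementation.
#'
#' @inheritParams parsimonyProbability
#' @param gridN Number of grid cells (default 2e5).
#' @return Probability in (0, 1).
#' @export
parsimonyProbabilityOracle <- function(j, L, gridN = 2e5) {
  f <- .parsimonyIntegrands(j, L)
  h <- 0.75 / gridN
  q <- (seq_len(gridN) - 0.5) * h
  sum(f$num(q)) / sum(f$den(q))
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps j such that the parsimony
#' probability for haplotypes j steps apart is >= alpha (the classic
#' "95\% connection limit" at alpha = 0.95).
#'
#' @param L Alignment length (>= 1).
#' @param alpha Required parsimony probability, in (0, 1); default 0.95.
#' @return Integer number of steps (capped at L).
#' @export
connectionLimit <- function(L, alpha = 0.95) {
  if (alpha <= 0 || alpha >= 1)
    stop("parameter error: alpha must be in (0, 1)")
  if (L < 1) stop("parameter error: L must be >= 1")
  j <- 0L
  while (j < L && parsimonyProbability(j + 1L, L) >= alpha)
    j <- j + 1L
  j
}

# Hamming distance between two character vectors over sites unambiguous
# in both; also returns the differing site indices (ascending)
.hapDiffSites <- function(a, b, okA, okB) {
  both <- okA & okB
  which(both & a != b)
}

#' Build a statistical-parsimony haplotype network
#'
#' Haplotype pairs are connected in non-decreasing mutational-distance
#' order (ties broken by higher pair frequency, then id order); a
#' connection at distance d > 1 inserts d - 1 inferred intermediate
#' nodes, mutations applied in ascending site index starting from the
#' higher-frequency endpoint.  Connections beyond the limit, and
#' connections that would only add a cycle between already-connected
#' nodes, are skipped, so the result is a forest (number of edges =
#' number of nodes - number of components).
#'
#' @param table A [HaplotypeTable-class].
#' @param limit Connection limit in steps (default: the 95\% limit for
#'   the alignment length via [connectionLimit()]).
#' @return A [HaplotypeNetwork-class].
#' @export
buildNetwork <- function(table, limit = NULL) {
  haps <- haplotypeSequences(table)
  counts <- haplotypeCounts(table)
  K <- length(haps)
  L <- if (K > 0) Biostrings::width(haps)[1L] else 0L
  if (is.null(limit)) limit <- connectionLimit(L)
  ids <- names(haps)
  freq <- rowSums(counts)
  cm <- as.matrix(haps)
  ok <- matrix(cm %in% c("A", "C", "G", "T"), nrow = K)
  # candidate pairs with distances
  pairs <- NULL
  if (K > 1L) {
    combs <- utils::combn(K, 2L)
    dist <- integer(ncol(combs))
    for (c0 in seq_len(ncol(combs))) {
      a <- combs[1L, c0]; b <- combs[2L, c0]
      dist[c0] <- length(.hapDiffSites(cm[a, ], cm[b, ], ok[a, ], ok[b, ]))
    }
    ordKey <- order(dist,
                    -pmax(freq[combs[1L, ]], freq[combs[2L, ]]),
                    -(freq[combs[1L, ]] + freq[combs[2L, ]]),
                    combs[1L, ], combs[2L, ])
    pairs <- data.frame(a = combs[1L, ordKey], b = combs[2L, ordKey],
                        d = dist[ordKey])
  }
  # node store (observed + inferred)
  nodeId <- ids
  nodeSeq <- apply(cm, 1L, paste, collapse = "")
  nodeFreq <- freq
  inferred <- rep(FALSE, K)
  comp <- seq_len(K)              # union-find
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  edges <- data.frame(from = character(0), to = character(0),
                      site = integer(0))
  nInf <- 0L
  if (!is.null(pairs)) for (r in seq_len(nrow(pairs))) {
    d <- pairs$d[r]
    if (d == 0L || d > limit) next
    a <- pairs$a[r]; b <- pairs$b[r]
    if (find(a) == find(b)) next      # cycle-skipping (forest output)
    # start chain at the higher-frequency endpoint (tie: lower id)
    if (freq[b] > freq[a]) { tmp <- a; a <- b; b <- tmp }
    sitesMut <- .hapDiffSites(cm[a, ], cm[b, ], ok[a, ], ok[b, ])
    cur <- a
    curSeq <- strsplit(nodeSeq[a], "")[[1]]
    for (sidx in seq_along(sitesMut)) {
      s <- sitesMut[sidx]
      curSeq[s] <- cm[b, s]
      if (sidx < length(sitesMut)) {
        nInf <- nInf + 1L
        newId <- paste0("i", nInf)
        nodeId <- c(nodeId, newId)
        nodeSeq <- c(nodeSeq, paste(curSeq, collapse = ""))
        nodeFreq <- c(nodeFreq, 0)
        inferred <- c(inferred, TRUE)
        comp <- c(comp, length(comp) + 1L)
        nxt <- length(nodeId)
      } else nxt <- b
      edges <- rbind(edges, data.frame(from = nodeId[cur],
                                       to = nodeId[nxt],
                                       site = s))
      comp[find(nxt)] <- find(cur)
      cur <- nxt
    }
  }
  nodes <- data.frame(id = nodeId, sequence = nodeSeq,
                      freq = as.numeric(nodeFreq), inferred = inferred,
                      stringsAsFactors = FALSE)
  grpCounts <- matrix(0, nrow = length(nodeId), ncol = ncol(counts),
                      dimnames = list(nodeId, colnames(counts)))
  grpCounts[seq_len(K), ] <- counts
  nodes <- cbind(nodes, as.data.frame(grpCounts))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  net <- new("HaplotypeNetwork", graph = g, nodes = nodes,
             connectionLimit = as.integer(limit), ancestral = "",
             ancestralByComponent = character(0), ancestralTied = FALSE)
  .designateAncestral(net)
}

# outgroup-weight designation: per component, the observed node
# maximizing (relative frequency) x (relative degree); ties -> higher
# frequency, then id order
.designateAncestral <- function(net) {
  g <- net@graph
  memb <- igraph::components(g)$membership
  deg <- igraph::degree(g)
  nodes <- net@nodes
  anc <- character(0)
  tied <- FALSE
  compSizes <- table(memb)
  for (cp in as.integer(names(compSizes))) {
    ix <- which(memb == cp & !nodes$inferred)
    if (!length(ix)) next
    fr <- nodes$freq[ix]
    dg <- deg[ix]
    score <- (fr / max(sum(fr), 1)) * ((dg + 1) / sum(dg + 1))
    topScore <- max(score)
    top <- ix[score >= topScore - 1e-12]
    if (length(top) > 1L) {
      tied <- TRUE
      fmax <- max(nodes$freq[top])
      top <- top[nodes$freq[top] == fmax]
      if (length(top) > 1L) top <- top[order(.hapNum(nodes$id[top]))]
    }
    anc[as.character(cp)] <- nodes$id[top[1L]]
  }
  # main designation: largest component (ties: lowest component index)
  obsSizes <- tapply(!nodes$inferred, memb, sum)
  main <- names(sort(-obsSizes))[1L]
  net@ancestral <- if (length(anc)) anc[[main]] else ""
  net@ancestralByComponent <- anc
  net@ancestralTied <- tied
  net
}

.hapNum <- function(id) suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", id)))

#' Designated ancestral haplotype of a network
#'
#' @param net A [HaplotypeNetwork-class].
#' @param byComponent Return the per-component vector instead of the
#'   main (largest-component) designation.
#' @return Haplotype id (character), or named character vector.
#' @export
ancestralHaplotype <- function(net, byComponent = FALSE) {
  if (byComponent) net@ancestralByComponent else net@ancestral
}

#' Write a haplotype network as GraphML plus node/edge CSV tables
#'
#' @param net A [HaplotypeNetwork-class].
#' @param prefix Output prefix; writes \code{<prefix>.graphml},
#'   \code{<prefix>_nodes.csv}, \code{<prefix>_edges.csv}.
#' @return Invisibly, the written paths.
#' @export
writeNetworkGraphML <- function(net, prefix) {
  g <- net@graph
  igraph::V(g)$ancestral <- igraph::V(g)$name == net@ancestral
  gml <- paste0(prefix, ".graphml")
  igraph::write_graph(g, gml, format = "graphml")
  ncsv <- paste0(prefix, "_nodes.csv")
  utils::write.csv(net@nodes, ncsv, row.names = FALSE)
  ecsv <- paste0(prefix, "_edges.csv")
  ed <- igraph::as_data_frame(g, what = "edges")
  utils::write.csv(ed, ecsv, row.names = FALSE)
  invisible(c(graphml = gml, nodes = ncsv, edges = ecsv))
}
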