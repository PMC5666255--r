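# Coalescent simulator: constant size, sudden expansion, exponential
# growth, island migration, and the two-phase spatial (infinite-island)
# expansion.  Time is measured in units of N generations for the present
# (reference) population, so that theta = 2*N*u per locus, pairwise
# coalescence happens at rate 1 and mutations fall at rate theta/2 per
# lineage per unit time; E[pairwise differences] = theta at equilibrium.

# --- genealogy -------------------------------------------------------------

# Unstructured coalescent under a piecewise/continuous size history.
# relSize(t) gives population size relative to the reference at time t
# (backwards); for sudden expansion the switch is at T = tau/theta1.
# Returns parent pointers and node times (leaves 1..n, internal nodes
# n+1..2n-1 in chronological order).
.simTree <- function(n, model = "constant", theta0 = NULL, theta1 = NULL,
                     tau = NULL, g = 0) {
  nNode <- 2L * n - 1L
  parent <- integer(nNode)
  times <- numeric(nNode)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    rate <- k * (k - 1) / 2
    if (model == "constant") {
      t <- t + stats::rexp(1, rate)
    } else if (model == "sudden") {
      # size 1 (theta1-scale) until T, then theta0/theta1
      T0 <- tau / theta1
      w <- stats::rexp(1, rate)
      if (t + w < T0) {
        t <- t + w
      } else {
        rel <- theta0 / theta1
        if (rel <= 0) {          # instantaneous ancestral coalescence
          t <- max(t, T0)
        } else {
          t <- max(t, T0) + stats::rexp(1, rate / rel)
        }
      }
    } else if (model == "growth") {
      # backwards size exp(-g t): rate(t) = rate * exp(g t)
      if (g == 0) {
        t <- t + stats::rexp(1, rate)
      } else {
        u <- stats::runif(1)
        # solve int_t^{t+w} rate*exp(g s) ds = -log(u)
        t <- log(exp(g * t) - g * log(u) / rate) / g
      }
    } else stop("unknown demographic model: ", model)
    pair <- sample(active, 2L)
    parent[pair] <- nxt
    times[nxt] <- t
    active <- c(setdiff(active, pair), nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, times = times, n = n)
}

# Structured coalescent: either a finite island model at equilibrium
# (model "island": demes, M) or the two-phase spatial expansion (model
# "spatial": all samples in one deme of an effectively infinite island
# system until T = tau/theta, then one ancestral deme of the same size).
.simTreeStructured <- function(nPerDeme, M, model = "island",
                               tau = NULL, theta = NULL) {
  n <- sum(nPerDeme)
  nNode <- 2L * n - 1L
  parent <- integer(nNode)
  times <- numeric(nNode)
  deme <- rep(seq_along(nPerDeme), nPerDeme)
  active <- seq_len(n)
  demeOf <- deme
  nDemes <- length(nPerDeme)
  freshDeme <- nDemes   # counter for never-occupied demes (spatial mode)
  t <- 0
  nxt <- n + 1L
  collapsed <- FALSE
  T0 <- if (identical(model, "spatial")) tau / theta else Inf
  while (length(active) > 1L) {
    k <- length(active)
    if (collapsed) {
      t <- t + stats::rexp(1, k * (k - 1) / 2)
      pair <- sample(active, 2L)
    } else {
      tab <- table(demeOf[active])
      coalRate <- sum(tab * (tab - 1) / 2)
      migRate <- k * M / 2
      total <- coalRate + migRate
      if (total <= 0 && is.infinite(T0))
        stop("island model deadlock: no coalescence or migration possible")
      w <- if (total > 0) stats::rexp(1, total) else Inf
      if (t + w >= T0) {         # spatial expansion: ancestral collapse
        t <- T0
        collapsed <- TRUE
        next
      }
      t <- t + w
      if (stats::runif(1) < migRate / total) {
        lin <- active[sample.int(k, 1L)]
        if (identical(model, "spatial")) {
          freshDeme <- freshDeme + 1L   # infinite islands: empty target
          demeOf[lin] <- freshDeme
        } else {
          demeOf[lin] <- sample(setdiff(seq_len(nDemes), demeOf[lin]), 1L)
        }
        next
      }
      # coalescence: pick a deme weighted by its pair count
      dlab <- as.integer(names(tab))
      d <- dlab[sample.int(length(dlab), 1L,
                           prob = tab * (tab - 1) / 2)]
      pair <- sample(active[demeOf[active] == d], 2L)
    }
    parent[pair] <- nxt
    times[nxt] <- t
    demeOf[nxt] <- demeOf[pair[1L]]
    active <- c(setdiff(active, pair), nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, times = times, n = n, deme = deme)
}

# branch lengths (length of branch above each non-root node)
.branchLengths <- function(tree) {
  nNode <- length(tree$parent)
  has <- tree$parent != 0L
  bl <- numeric(nNode)
  bl[has] <- tree$times[tree$parent[has]] - tree$times[has]
  bl
}

# leaves under each node, as an index list
.leafSets <- function(tree) {
  n <- tree$n
  nNode <- length(tree$parent)
  sets <- vector("list", nNode)
  for (i in seq_len(n)) sets[[i]] <- i
  for (v in seq_len(nNode - 1L)) {
    p <- tree$parent[v]
    if (p > 0L) sets[[p]] <- c(sets[[p]], sets[[v]])
  }
  sets
}

# Place mutations: returns per-mutation branch (node below) given theta
# (mutation rate theta/2 per lineage per unit time).
.dropMutations <- function(tree, theta) {
  bl <- .branchLengths(tree)
  tot <- sum(bl)
  nmut <- stats::rpois(1, theta / 2 * tot)
  if (nmut == 0L) return(integer(0))
  sample.int(length(bl), nmut, replace = TRUE, prob = bl)
}

# Fast summary path (infinite sites): S, Pi_bar, K_hap without building
# sequences.  Used by the simulation-based neutrality tests.
.simStats <- function(n, theta, model = "constant", theta0 = NULL,
                      theta1 = NULL, tau = NULL, g = 0) {
  tree <- .simTree(n, model, theta0, theta1, tau, g)
  muts <- .dropMutations(tree, theta)
  if (length(muts) == 0L)
    return(list(S = 0L, Pi_bar = 0, K = 1L))
  sets <- .leafSets(tree)
  key <- character(n)
  cnt <- integer(length(muts))
  for (m in seq_along(muts)) {
    lv <- sets[[muts[m]]]
    cnt[m] <- length(lv)
    key[lv] <- paste(key[lv], m)
  }
  seg <- cnt > 0L & cnt < n
  Pi <- sum(cnt[seg] * (n - cnt[seg])) / (n * (n - 1) / 2)
  list(S = sum(seg), Pi_bar = Pi, K = length(unique(key)))
}

# Histogram-only simulation path (infinite sites): the mismatch
# distribution needs only pairwise mutation-count distances, so skip
# sequence construction entirely.  Used by the parametric bootstrap.
.simMismatch <- function(n, model = c("sudden", "spatial", "constant"),
                         theta = NULL, theta0 = NULL, theta1 = NULL,
                         tau = NULL, M = NULL) {
  model <- match.arg(model)
  tree <- switch(model,
    sudden = .simTree(n, "sudden", theta0 = theta0, theta1 = theta1,
                      tau = tau),
    spatial = .simTreeStructured(n, M, "spatial", tau = tau,
                                 theta = theta),
    constant = .simTree(n, "constant"))
  mutTheta <- switch(model, sudden = theta1, spatial = theta,
                     constant = theta)
  muts <- .dropMutations(tree, mutTheta)
  nPairs <- n * (n - 1) / 2
  if (length(muts) == 0L) {
    counts <- setNames(nPairs, "0")
    return(list(counts = counts, n_pairs = nPairs,
                relative = counts / nPairs))
  }
  sets <- .leafSets(tree)
  X <- matrix(0L, nrow = n, ncol = length(muts))
  for (m in seq_along(muts)) X[sets[[muts[m]]], m] <- 1L
  cc <- rowSums(X)
  d <- outer(cc, cc, "+") - 2 * tcrossprod(X)
  v <- d[upper.tri(d)]
  dmax <- max(v)
  counts <- tabulate(v + 1L, nbins = dmax + 1L)
  names(counts) <- 0:dmax
  list(counts = counts, n_pairs = nPairs, relative = counts / nPairs)
}

.BASES <- c("A", "C", "G", "T")
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# one mutated base given current base, transition/transversion ratio
.mutateBase <- function(base, tstv) {
  if (stats::runif(1) < tstv / (tstv + 1)) return(.TRANSITION[[base]])
  tv <- setdiff(.BASES, c(base, .TRANSITION[[base]]))
  tv[sample.int(2L, 1L)]
}

# Build sequences from a tree + mutation placement.  Infinite-sites mode
# assigns each mutation its own site (no collisions); finite-sites mode
# draws sites with replacement and applies changes in time order down
# the tree (HKY-like transition bias).
.buildAlignment <- function(tree, muts, L, sites = "infinite",
                            tstv = 3.99) {
  n <- tree$n
  nNode <- length(tree$parent)
  children <- split(seq_len(nNode - 1L), tree$parent[-nNode])
  mutsByBranch <- split(seq_along(muts), muts)
  root <- nNode
  rootSeq <- rep("A", L)
  seqMat <- matrix(NA_character_, nrow = n, ncol = L)
  if (sites == "infinite") {
    if (length(muts) > L)
      stop(sprintf(
        "infinite-sites overflow: %d mutations exceed %d sites",
        length(muts), L))
    site <- if (length(muts)) sample.int(L, length(muts)) else integer(0)
  } else {
    site <- if (length(muts)) sample.int(L, length(muts),
                                         replace = TRUE) else integer(0)
  }
  # mutation times (uniform on the branch) order application within a path
  mutTime <- numeric(length(muts))
  if (length(muts)) {
    bl <- .branchLengths(tree)
    top <- tree$times[tree$parent[muts]]
    mutTime <- top - stats::runif(length(muts)) * bl[muts]
  }
  # explicit stack (avoids deep recursion on large n); mutations on a
  # branch are applied oldest first so finite-sites multiple hits stack
  # correctly
  stack <- list(list(node = root, seqv = rootSeq))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    seqv <- fr$seqv
    mb <- mutsByBranch[[as.character(fr$node)]]
    if (!is.null(mb)) {
      for (m in mb[order(-mutTime[mb])]) seqv[site[m]] <-
          .mutateBase(seqv[site[m]], tstv)
    }
    if (fr$node <= n) {
      seqMat[fr$node, ] <- seqv
    } else {
      for (ch in children[[as.character(fr$node)]])
        stack[[length(stack) + 1L]] <- list(node = ch, seqv = seqv)
    }
  }
  list(seqs = apply(seqMat, 1L, paste, collapse = ""),
       root = paste(rootSeq, collapse = ""))
}

#' Simulate a COI-like alignment under a coalescent model
#'
#' Supported histories: \code{"constant"} size; \code{"sudden"}
#' expansion (size switches from the theta1 scale to the theta0 scale at
#' time tau/theta1 back, tau in mutational units as in the mismatch
#' model); \code{"growth"} (exponential, rate \code{g} per coalescent
#' time unit); \code{"island"} (finite island model, \code{demes} demes
#' of scaled size \code{theta} with per-lineage migration rate M/2);
#' \code{"spatial"} (infinite-island spatial expansion: one sampled deme,
#' migrants lost to empty demes, ancestral collapse at tau/theta).
#'
#' @param n Sample size (ignored for island model when \code{nPerDeme}
#'   given).
#' @param theta Scaled mutation parameter per locus (2Nu); for the
#'   sudden model the post-expansion \code{theta1} takes this role.
#' @param model Demographic model (see above).
#' @param theta0,theta1,tau Sudden-expansion parameters.
#' @param g Exponential growth rate (model "growth").
#' @param M Scaled migration rate (models "island"/"spatial").
#' @param demes,nPerDeme Island-model layout; \code{nPerDeme} is a
#'   vector of per-deme sample sizes.
#' @param L Number of sites (default 554).
#' @param sites "infinite" (each mutation a new site) or "finite"
#'   (HKY-like transition-biased finite-sites model).
#' @param tstv Transition/transversion ratio for finite-sites mutations
#'   (default 3.99).
#' @param seed Optional integer seed (deterministic output).
#' @param populationLabels Optional deme -> population label vector.
#' @return A [SimulatedDataset-class].
#' @examples
#' sim <- simulateCoalescent(10, theta = 5, seed = 1)
#' simAlignment(sim)
#' @export
simulateCoalescent <- function(n = NULL, theta = NULL,
                               model = c("constant", "sudden", "growth",
                                         "island", "spatial"),
                               theta0 = NULL, theta1 = NULL, tau = NULL,
                               g = 0, M = 0, demes = 1L, nPerDeme = NULL,
                               L = 554L, sites = c("infinite", "finite"),
                               tstv = 3.99, seed = NULL,
                               populationLabels = NULL) {
  model <- match.arg(model)
  sites <- match.arg(sites)
  if (!is.null(seed)) set.seed(seed)
  # parameter validation before any sampling
  if (model %in% c("constant", "growth") &&
      (is.null(theta) || theta < 0))
    stop("parameter error: theta must be a non-negative number")
  if (model == "sudden") {
    if (is.null(theta1) && !is.null(theta)) theta1 <- theta
    if (is.null(theta0) || is.null(theta1) || is.null(tau) ||
        theta0 < 0 || theta1 <= 0 || tau < 0)
      stop("parameter error: sudden expansion needs theta0 >= 0, theta1 > 0, tau >= 0")
  }
  if (model == "spatial" &&
      (is.null(theta) || theta <= 0 || is.null(tau) || tau < 0 || M < 0))
    stop("parameter error: spatial expansion needs theta > 0, tau >= 0, M >= 0")
  if (model == "island") {
    if (is.null(nPerDeme)) nPerDeme <- rep(n %/% demes, demes)
    if (any(nPerDeme < 0) || sum(nPerDeme) < 1 || M < 0 ||
        is.null(theta) || theta < 0)
      stop("parameter error: invalid island-model specification")
  }
  if (is.null(n)) n <- sum(nPerDeme)
  if (n < 1) stop("parameter error: need n >= 1")
  if (tstv <= 0) stop("parameter error: tstv must be > 0")
  if (n == 1L) {
    aln <- HaploAlignment(setNames(paste(rep("A", L), collapse = ""), "t1"),
                          .demeMeta("t1", 1L, populationLabels))
    return(new("SimulatedDataset", alignment = aln,
               trueParams = list(model = model, theta = theta, L = L,
                                 seed = seed),
               rootHaplotype = paste(rep("A", L), collapse = "")))
  }
  if (model %in% c("island", "spatial")) {
    if (model == "spatial") nPerDeme <- n
    tree <- .simTreeStructured(nPerDeme, M, model, tau, theta)
    mutTheta <- theta
    deme <- tree$deme
  } else {
    tree <- .simTree(n, model, theta0, theta1, tau, g)
    mutTheta <- if (model == "sudden") theta1 else theta
    deme <- rep(1L, n)
  }
  muts <- .dropMutations(tree, mutTheta)
  built <- .buildAlignment(tree, muts, L, sites, tstv)
  ids <- paste0("t", seq_len(n))
  aln <- HaploAlignment(setNames(built$seqs, ids),
                        .demeMeta(ids, deme, populationLabels))
  new("SimulatedDataset", alignment = aln,
      trueParams = list(model = model, theta = theta, theta0 = theta0,
                        theta1 = theta1, tau = tau, g = g, M = M,
                        L = L, sites = sites, tstv = tstv, seed = seed),
      rootHaplotype = built$root)
}

.demeMeta <- function(ids, deme, populationLabels = NULL) {
  pop <- if (is.null(populationLabels)) paste0("deme", deme)
         else populationLabels[deme]
  data.frame(sample_id = ids, population = pop,
             region = rep(.REGIONS[1L], length(ids)),
             subregion = "", lat = NA_real_, lon = NA_real_,
             depth_m = NA_real_)
}

#' @rdname SimulatedDataset-class
#' @param x A \code{SimulatedDataset}.
#' @export
setGeneric("simAlignment", function(x) standardGeneric("simAlignment"))
#' @rdname SimulatedDataset-class
#' @export
setMethod("simAlignment", "SimulatedDataset", function(x) x@alignment)

#' @rdname SimulatedDataset-class
#' @export
setGeneric("simTrueParams", function(x) standardGeneric("simTrueParams"))
#' @rdname SimulatedDataset-class
#' @export
setMethod("simTrueParams", "SimulatedDataset", function(x) x@trueParams)

#' @rdname SimulatedDataset-class
#' @export
setGeneric("simRootHaplotype", function(x) standardGeneric("simRootHaplotype"))
#' @rdname SimulatedDataset-class
#' @export
setMethod("simRootHaplotype", "SimulatedDataset", function(x) x@rootHaplotype)

#' Simulate a four-region study-like dataset
#'
#' Emulates the structure of the sea-spider COI study data: 364
#' sequences of 554 bp across four Southern Ocean regions with
#' contrasting histories -- EA (n=227) and AP (n=95) as old, diverse
#' sudden expansions; WS (n=29) as a recent low-diversity expansion; AI
#' (n=13) as a small founder-style sample -- with parameters chosen so
#' the pooled number of haplotypes is of the order of 85.
#'
#' @param seed Integer seed; the same seed gives byte-identical output.
#' @return A [SimulatedDataset-class] with region metadata.
#' @export
makeStudyLikeDataset <- function(seed) {
  set.seed(seed)
  cfg <- list(
    EA = list(n = 227L, tau = 3.4, theta0 = 0.005, theta1 = 29.4),
    AP = list(n = 95L,  tau = 4.7, theta0 = 0.002, theta1 = 16.6),
    WS = list(n = 29L,  tau = 0.9, theta0 = 0.001, theta1 = 0.95),
    AI = list(n = 13L,  tau = 1.3, theta0 = 0.02,  theta1 = 3.5))
  seqs <- character(0)
  meta <- NULL
  roots <- character(0)
  for (rg in names(cfg)) {
    p <- cfg[[rg]]
    sim <- simulateCoalescent(p$n, model = "sudden", theta0 = p$theta0,
                              theta1 = p$theta1, tau = p$tau, L = 554L,
                              sites = "finite")
    s <- as.character(alnSequences(simAlignment(sim)))
    names(s) <- paste0(rg, "_", seq_along(s))
    seqs <- c(seqs, s)
    meta <- rbind(meta, data.frame(
      sample_id = names(s), population = rg, region = rg,
      subregion = "", lat = NA_real_, lon = NA_real_,
      depth_m = NA_real_))
    roots[rg] <- simRootHaplotype(sim)
  }
  aln <- HaploAlignment(seqs, meta)
  new("SimulatedDataset", alignment = aln,
      trueParams = list(model = "study_like", regions = cfg, seed = seed,
                        L = 554L),
      rootHaplotype = roots[["EA"]])
}

#' Write a simulated dataset to FASTA + metadata CSV + parameter JSON
#'
#' @param sim A [SimulatedDataset-class].
#' @param prefix Output path prefix; writes \code{<prefix>.fasta},
#'   \code{<prefix>_meta.csv} and \code{<prefix>_params.json}.
#' @return Invisibly, the three paths.
#' @export
writeSimulatedDataset <- function(sim, prefix) {
  aln <- simAlignment(sim)
  fa <- paste0(prefix, ".fasta")
  Biostrings::writeXStringSet(alnSequences(aln), fa)
  mcsv <- paste0(prefix, "_meta.csv")
  utils::write.csv(as.data.frame(alnMetadata(aln)), mcsv,
                   row.names = FALSE)
  js <- paste0(prefix, "_params.json")
  writeLines(jsonlite::toJSON(simTrueParams(sim), auto_unbox = TRUE,
                              null = "null", digits = NA), js)
  invisible(c(fasta = fa, meta = mcsv, params = js))
}
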