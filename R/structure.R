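# Distance-based AMOVA, pairwise Phi-ST, permutation significance.

# Resolve a per-sample label vector: metadata column name or explicit
# vector (recycled by sample id when named).
.resolveLabels <- function(aln, x) {
  if (is.null(x)) return(NULL)
  if (length(x) == 1L && is.character(x) &&
      x %in% c("population", "region", "subregion"))
    return(.groupLabels(aln, x))
  if (!is.null(names(x))) return(setNames(as.character(x[names(aln)]),
                                          names(aln)))
  if (length(x) != length(aln))
    stop("grouping error: label vector length must match sample count")
  setNames(as.character(x), names(aln))
}

# squared-distance matrix for the AMOVA metric: pairwise difference
# counts play the role of squared Euclidean distances (sequence-level
# Phi statistics); "haplotype" scores 0/1 (conventional frequency Fst)
.amovaD2 <- function(aln, metric) {
  if (metric == "difference")
    pairwiseDifferences(aln, mode = "count", deletion = "pairwise")
  else {
    tab <- collapseHaplotypes(aln, policy = "strict")
    hap <- rep(names(tab@members), lengths(tab@members))
    names(hap) <- unlist(tab@members)
    hap <- hap[names(aln)]
    outer(hap, hap, "!=") * 1
  }
}

# sum of squared distances within each level-1 cell, divided by cell size
.ssWithin <- function(d2, lab) {
  s <- 0
  for (g in unique(lab)) {
    idx <- which(lab == g)
    if (length(idx) > 1L)
      s <- s + sum(d2[idx, idx]) / 2 / length(idx)
  }
  s
}

.amovaComponents <- function(d2, pop, grp = NULL) {
  n <- length(pop)
  sizes <- table(pop)
  P <- length(sizes)
  ssTotal <- sum(d2) / 2 / n
  ssWP <- .ssWithin(d2, pop)
  if (is.null(grp)) {
    dfA <- P - 1L
    dfW <- n - P
    ssAP <- ssTotal - ssWP
    msA <- ssAP / dfA
    msW <- ssWP / dfW
    nc <- (n - sum(sizes^2) / n) / dfA
    s2w <- msW
    s2a <- (msA - msW) / nc
    tot <- s2a + s2w
    list(table = data.frame(
           level = c("among_populations", "within_populations"),
           df = c(dfA, dfW), SS = c(ssAP, ssWP),
           sigma2 = c(s2a, s2w),
           percent = 100 * c(s2a, s2w) / tot),
         phi = c(PhiST = s2a / tot))
  } else {
    G <- length(unique(grp))
    ssWG <- .ssWithin(d2, grp)          # pairs within groups
    ssAPWG <- ssWG - ssWP
    ssAG <- ssTotal - ssWG
    dfAG <- G - 1L
    dfAP <- P - G
    dfW <- n - P
    npg <- tapply(pop, grp, function(x) {
      tb <- table(x); sum(tb^2) / length(x)
    })
    ngs <- table(grp)
    A <- sum(tapply(seq_along(pop), grp, function(ix) {
      tb <- table(pop[ix]); sum(tb^2) / length(ix)
    }))
    SP <- sum(sizes^2)
    SG <- sum(ngs^2)
    n1 <- (n - A) / dfAP
    n2 <- (A - SP / n) / dfAG
    n3 <- (n - SG / n) / dfAG
    msW <- ssWP / dfW
    msAP <- ssAPWG / dfAP
    msAG <- ssAG / dfAG
    s2c <- msW
    s2b <- (msAP - s2c) / n1
    s2a <- (msAG - s2c - n2 * s2b) / n3
    tot <- s2a + s2b + s2c
    list(table = data.frame(
           level = c("among_groups", "among_populations_within_groups",
                     "within_populations"),
           df = c(dfAG, dfAP, dfW), SS = c(ssAG, ssAPWG, ssWP),
           sigma2 = c(s2a, s2b, s2c),
           percent = 100 * c(s2a, s2b, s2c) / tot),
         phi = c(PhiST = (s2a + s2b) / tot,
                 PhiCT = s2a / tot,
                 PhiSC = s2b / (s2b + s2c)))
  }
}

#' Analysis of molecular variance (AMOVA)
#'
#' Excoffier-style hierarchical partition of molecular variance using
#' pairwise mutational-difference counts as squared distances (the
#' sequence-level Phi-statistic design; a frequency-only 0/1 haplotype
#' metric is available behind \code{metric = "haplotype"}).  Significance
#' by permutation: individuals among populations for PhiST, individuals
#' among populations within groups for PhiSC, whole populations among
#' groups for PhiCT; p-values use the (r+1)/(B+1) corrected estimator.
#' Negative variance components are reported as computed unless
#' \code{floorNegative}.
#'
#' @param aln A [HaploAlignment-class].
#' @param populations Per-sample population labels: a metadata column
#'   name ("population", "region", "subregion") or a vector (named by
#'   sample id, or in alignment order).  Default "population".
#' @param groups Optional higher-level labels in the same forms, turning
#'   the analysis into the three-level design.
#' @param nPerm Number of permutations (>= 1; default 1000; the
#'   publication-scale counts are 2000 for a regional AMOVA and 10000
#'   for pairwise tests).
#' @param seed Optional integer seed.
#' @param metric "difference" (default) or "haplotype".
#' @param floorNegative Truncate negative variance components at 0.
#' @return An [AmovaResult-class].
#' @export
amova <- function(aln, populations = "population", groups = NULL,
                  nPerm = 1000L, seed = NULL,
                  metric = c("difference", "haplotype"),
                  floorNegative = FALSE) {
  metric <- match.arg(metric)
  if (nPerm < 1) stop("parameter error: need nPerm >= 1")
  pop <- .resolveLabels(aln, populations)
  grp <- .resolveLabels(aln, groups)
  if (length(unique(pop)) < 2L)
    stop("grouping error: need >= 2 populations")
  if (any(table(pop) < 1L))
    stop("grouping error: empty population")
  if (!is.null(seed)) set.seed(seed)
  d2 <- .amovaD2(aln, metric)
  obs <- .amovaComponents(d2, pop, grp)
  n <- length(pop)
  # permutation nulls
  permGE <- setNames(integer(length(obs$phi)), names(obs$phi))
  for (b in seq_len(nPerm)) {
    sh <- sample.int(n)
    popP <- pop[sh]
    if (is.null(grp)) {
      st <- .amovaComponents(d2, popP)$phi
      permGE["PhiST"] <- permGE["PhiST"] + (st["PhiST"] >= obs$phi["PhiST"])
    } else {
      # PhiST: individuals anywhere; PhiSC: individuals within groups;
      # PhiCT: populations among groups
      stST <- .amovaComponents(d2, popP, grp[sh])$phi["PhiST"]
      permGE["PhiST"] <- permGE["PhiST"] + (stST >= obs$phi["PhiST"])
      popW <- pop
      for (g in unique(grp)) {
        ix <- which(grp == g)
        popW[ix] <- pop[ix][sample.int(length(ix))]
      }
      stSC <- .amovaComponents(d2, popW, grp)$phi["PhiSC"]
      permGE["PhiSC"] <- permGE["PhiSC"] + (stSC >= obs$phi["PhiSC"])
      popNames <- unique(pop)
      g2p <- tapply(grp, pop, function(x) x[1L])[popNames]
      newG <- sample(g2p)
      grpP <- setNames(newG[match(pop, popNames)], names(pop))
      stCT <- .amovaComponents(d2, pop, grpP)$phi["PhiCT"]
      permGE["PhiCT"] <- permGE["PhiCT"] + (stCT >= obs$phi["PhiCT"])
    }
  }
  p <- (permGE + 1) / (nPerm + 1)
  tab <- obs$table
  phi <- obs$phi
  if (floorNegative) {
    tab$sigma2 <- pmax(tab$sigma2, 0)
    tab$percent <- 100 * tab$sigma2 / sum(tab$sigma2)
    phi <- pmax(phi, 0)
  }
  new("AmovaResult", table = tab, phi = phi, p = p[names(phi)],
      nPerm = as.integer(nPerm),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Pairwise Phi-ST matrix with permutation p-values
#'
#' Two-level AMOVA applied to every pair of populations; one-sided
#' p-values by permuting individuals between the two populations,
#' (r+1)/(B+1)-corrected.  Pairs involving a population with fewer than
#' 2 samples are flagged undefined (NA cells).
#'
#' @inheritParams amova
#' @return List with \code{phist} (symmetric matrix, zero diagonal),
#'   \code{p} (p-value matrix), \code{p_adjusted} (sequential-Bonferroni
#'   a.k.a. Holm, over the lower triangle) and \code{n_perm}.
#' @export
pairwisePhiST <- function(aln, populations = "population",
                          nPerm = 1000L, seed = NULL,
                          metric = c("difference", "haplotype")) {
  metric <- match.arg(metric)
  if (nPerm < 1) stop("parameter error: need nPerm >= 1")
  pop <- .resolveLabels(aln, populations)
  pops <- sort(unique(pop))
  if (length(pops) < 2L) stop("grouping error: need >= 2 populations")
  if (!is.null(seed)) set.seed(seed)
  d2full <- .amovaD2(aln, metric)
  K <- length(pops)
  phist <- matrix(0, K, K, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  diag(pmat) <- NA
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    ia <- which(pop == pops[a]); ib <- which(pop == pops[b])
    if (length(ia) < 2L || length(ib) < 2L) {
      phist[a, b] <- phist[b, a] <- NA_real_
      next
    }
    idx <- c(ia, ib)
    d2 <- d2full[idx, idx]
    lab <- rep(c("a", "b"), c(length(ia), length(ib)))
    obs <- .amovaComponents(d2, lab)$phi[["PhiST"]]
    r <- 0L
    for (pm in seq_len(nPerm)) {
      st <- .amovaComponents(d2, lab[sample.int(length(lab))])$phi[["PhiST"]]
      if (st >= obs) r <- r + 1L
    }
    phist[a, b] <- phist[b, a] <- obs
    pmat[a, b] <- pmat[b, a] <- (r + 1) / (nPerm + 1)
  }
  lowp <- pmat[lower.tri(pmat)]
  adj <- stats::p.adjust(lowp, method = "holm")
  padj <- pmat
  padj[lower.tri(padj)] <- adj
  padj[upper.tri(padj)] <- t(padj)[upper.tri(padj)]
  list(phist = phist, p = pmat, p_adjusted = padj,
       n_perm = as.integer(nPerm))
}
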