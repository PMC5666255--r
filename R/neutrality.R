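# Tajima's D and Fu's Fs, with coalescent-simulation significance.

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log unsigned Stirling numbers of the first kind |s(n, k)|, k = 1..n,
# by the log-space recurrence |s(n+1,k)| = n|s(n,k)| + |s(n,k-1)|
# (cached per n: the n = 364 table is reused heavily in simulations)
.stirlingCache <- new.env(parent = emptyenv())
.logStirlingFirst <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirlingCache[[key]])) return(.stirlingCache[[key]])
  ls <- 0                      # n = 1: |s(1,1)| = 1
  if (n > 1L) {
    for (m in seq_len(n - 1L)) {
      new <- numeric(m + 1L)
      new[1L] <- log(m) + ls[1L]                      # k = 1
      if (m > 1L)
        for (k in 2:m) new[k] <- .logsumexp(c(log(m) + ls[k], ls[k - 1L]))
      new[m + 1L] <- 0                                 # |s(n,n)| = 1
      ls <- new
    }
  }
  .stirlingCache[[key]] <- ls
  ls
}

#' Ewens sampling distribution of the number of alleles
#'
#' P(K = k | theta, n) = |s1(n,k)| theta^k / (theta (theta+1) ...
#' (theta+n-1)), with |s1| the unsigned Stirling numbers of the first
#' kind, computed in log space.
#'
#' @param n Sample size.
#' @param theta Scaled mutation parameter (> 0).
#' @return Numeric vector of probabilities for k = 1..n (sums to 1).
#' @export
ewensDistribution <- function(n, theta) {
  if (theta <= 0) stop("domain error: theta must be > 0")
  ls <- .logStirlingFirst(n)
  k <- seq_len(n)
  lp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1L)))
  exp(lp)
}

.tajimaFromStats <- function(S, Pi_bar, n) {
  if (n < 4) stop("sample-size error: Tajima's D needs n >= 4")
  if (S < 1)
    stop("statistic-undefined error: Tajima's D undefined when S = 0")
  a1 <- .a1(n); a2 <- .a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (Pi_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Tajima's D
#'
#' D = (Pi_bar - S/a1) / sqrt(e1 S + e2 S(S-1)), contrasting the
#' pairwise (Pi) and Watterson (S/a1) estimators of theta; negative
#' values signal an excess of rare variants as after a population
#' expansion.  Both S and Pi use the complete-deletion site set so the
#' two estimators share one alignment.
#'
#' @param aln A [HaploAlignment-class] with n >= 4 and at least one
#'   segregating site.
#' @return The D statistic.
#' @export
tajimasD <- function(aln) {
  n <- length(aln)
  S <- segregatingSites(aln)
  Pi <- pairwiseDiversity(aln)$Pi_bar
  .tajimaFromStats(S, Pi, n)
}

.fsFromStats <- function(Pi_bar, K, n) {
  if (Pi_bar <= 0)
    stop("statistic-undefined error: Fu's Fs undefined when Pi_bar = 0")
  ls <- .logStirlingFirst(n)
  k <- seq_len(n)
  lp <- ls + k * log(Pi_bar) - sum(log(Pi_bar + 0:(n - 1L)))
  lS <- .logsumexp(lp[k >= K])           # log S' = log P(K >= K_obs)
  lC <- .logsumexp(lp[k < K])            # log (1 - S')
  if (K <= 1L || !is.finite(lC))
    stop("overflow-guard error: S' = 1 boundary (K_obs at minimum)")
  if (!is.finite(lS))
    stop("overflow-guard error: S' = 0 boundary")
  lS - lC
}

#' Fu's Fs
#'
#' Fs = ln(S'/(1-S')) with S' = P(K >= K_obs) under the Ewens sampling
#' distribution at theta = Pi_bar (Tajima's estimator).  Large negative
#' values indicate an excess of haplotypes relative to the pairwise
#' diversity, the classic signature of recent demographic expansion.
#'
#' @param aln A [HaploAlignment-class] with n >= 2 and Pi_bar > 0.
#' @param policy Haplotype-collapse policy used for K (default
#'   "wildcard").
#' @return The Fs statistic.
#' @export
fusFs <- function(aln, policy = "wildcard") {
  n <- length(aln)
  if (n < 2) stop("sample-size error: need n >= 2")
  Pi <- pairwiseDiversity(aln)$Pi_bar
  K <- nHaplotypes(collapseHaplotypes(aln, policy = policy))
  .fsFromStats(Pi, K, n)
}

#' Simulation-based neutrality test
#'
#' Computes Tajima's D and Fu's Fs on the alignment, then simulates
#' \code{nSims} constant-size coalescent samples at theta = Pi_bar
#' (matching the conditioning used by Fu 1997) and reports left-tail
#' p-values p = (r+1)/(B+1) where r = number of simulated statistics <=
#' the observed one (negative values signal expansion).  Replicates on
#' which a statistic is undefined (S = 0 for D, Pi = 0 for Fs) are
#' dropped and counted; more than 10\% drops raises a warning flag in
#' the result.  By Fu's convention Fs is deemed significant at the 0.05
#' level when p(Fs) < 0.02; the result reports this alongside the raw
#' p-values.
#'
#' @param aln A [HaploAlignment-class].
#' @param nSims Number of null replicates (>= 100; default 1000, raise
#'   to 10000 for publication-scale runs).
#' @param seed Optional integer seed.
#' @param thetaHat Override the simulation theta (default: observed
#'   Pi_bar).
#' @param keepNull Also return the simulated null statistic draws.
#' @return List with D, Fs, p_D, p_Fs, significant_Fs_005 (Fu's
#'   convention), n_sims, dropped counts, seed and a warning flag (plus
#'   \code{null_D}, \code{null_Fs} when \code{keepNull}).
#' @export
neutralityTest <- function(aln, nSims = 1000L, seed = NULL,
                           thetaHat = NULL, keepNull = FALSE) {
  if (nSims < 100) stop("parameter error: need nSims >= 100")
  if (!is.null(seed)) set.seed(seed)
  n <- length(aln)
  S <- segregatingSites(aln)
  Pi <- pairwiseDiversity(aln)$Pi_bar
  K <- nHaplotypes(collapseHaplotypes(aln))
  D <- .tajimaFromStats(S, Pi, n)
  Fs <- .fsFromStats(Pi, K, n)
  theta <- if (is.null(thetaHat)) Pi else thetaHat
  simD <- rep(NA_real_, nSims); simFs <- rep(NA_real_, nSims)
  for (b in seq_len(nSims)) {
    st <- .simStats(n, theta)
    if (st$S >= 1L) simD[b] <- .tajimaFromStats(st$S, st$Pi_bar, n)
    if (st$Pi_bar > 0 && st$K > 1L)
      simFs[b] <- .fsFromStats(st$Pi_bar, st$K, n)
  }
  dropD <- sum(is.na(simD)); dropFs <- sum(is.na(simFs))
  simD <- simD[!is.na(simD)]; simFs <- simFs[!is.na(simFs)]
  pD <- (sum(simD <= D) + 1) / (length(simD) + 1)
  pFs <- (sum(simFs <= Fs) + 1) / (length(simFs) + 1)
  warn <- max(dropD, dropFs) > 0.1 * nSims
  if (warn)
    warning("more than 10% of null replicates dropped (statistic undefined)")
  out <- list(D = D, Fs = Fs, p_D = pD, p_Fs = pFs,
              significant_Fs_005 = pFs < 0.02,
              n_sims = as.integer(nSims), dropped_D = dropD,
              dropped_Fs = dropFs, seed = seed, warning_dropped = warn)
  if (keepNull) { out$null_D <- simD; out$null_Fs <- simFs }
  out
}
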