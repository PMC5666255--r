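# Mismatch distributions: observed histograms, sudden-demographic and
# spatial (infinite-island) expansion models, least-squares fitting,
# SSD/raggedness goodness-of-fit with parametric bootstrap.

#' Observed mismatch distribution
#'
#' Histogram of pairwise nucleotide-difference counts over all unordered
#' sequence pairs (complete-deletion site set by default, so its mean
#' equals Pi_bar from [pairwiseDiversity()] exactly).
#'
#' @param aln A [HaploAlignment-class] with n >= 2.
#' @param deletion "complete" (default) or "pairwise".
#' @return List with \code{counts} (named vector over difference classes
#'   0..d_max), \code{n_pairs} and \code{relative} (frequencies summing
#'   to 1).
#' @export
observedMismatch <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  d <- pairwiseDifferences(aln, mode = "count", deletion = deletion)
  v <- d[upper.tri(d)]
  dmax <- max(v)
  counts <- tabulate(v + 1L, nbins = dmax + 1L)
  names(counts) <- 0:dmax
  list(counts = counts, n_pairs = length(v),
       relative = counts / length(v))
}

# stationary mismatch F_hat_i(theta) = theta^i / (theta+1)^(i+1)
.Fhat <- function(theta, i) {
  if (theta == 0) return(as.numeric(i == 0))
  exp(i * log(theta) - (i + 1) * log(theta + 1))
}

#' Expected mismatch distribution under sudden demographic expansion
#'
#' The classic sudden-expansion (bottleneck-to-expansion) model: a
#' population at equilibrium scaled size theta0 grew instantaneously to
#' theta1 at tau mutational time units before present.
#' F_i = Fhat_i(theta1) + exp(-tau(theta1+1)/theta1) *
#' sum_{j<=i} tau^(i-j)/(i-j)! (Fhat_j(theta0) - Fhat_j(theta1)), with
#' Fhat_i(theta) = theta^i/(theta+1)^(i+1).
#'
#' @param tau Expansion time in mutational units (>= 0).
#' @param theta0,theta1 Pre-/post-expansion scaled sizes (>= 0;
#'   theta1 = 0 handled by its analytic limit).
#' @param dMax Largest difference class returned.
#' @param normalize Renormalize the truncated vector to sum to 1
#'   (default TRUE; FALSE returns the raw model probabilities, whose
#'   partial sums are bounded by 1).
#' @return Numeric vector over classes 0..dMax.
#' @export
expectedSudden <- function(tau, theta0, theta1, dMax,
                           normalize = TRUE) {
  if (tau < 0 || theta0 < 0 || theta1 < 0)
    stop("domain error: parameters must be non-negative")
  i <- 0:dMax
  .FhatVec <- function(theta) {
    if (theta == 0) as.numeric(i == 0)
    else exp(i * log(theta) - (i + 1) * log(theta + 1))
  }
  if (theta1 == 0) {
    F <- if (tau == 0) .FhatVec(theta0)
         else as.numeric(i == 0)   # analytic limit: coalescence at once
  } else {
    F1 <- .FhatVec(theta1)
    F0 <- .FhatVec(theta0)
    delta <- F0 - F1
    # damped Poisson-kernel convolution, damping folded into the kernel
    # in log space to stay finite for large tau
    lw <- ifelse(i == 0 & tau == 0, 0, i * log(tau)) - lgamma(i + 1) -
      tau * (theta1 + 1) / theta1
    w <- exp(lw)
    shift <- outer(i, i, "-")
    W <- matrix(0, dMax + 1L, dMax + 1L)
    keep <- shift >= 0
    W[keep] <- w[shift[keep] + 1L]
    F <- F1 + as.numeric(W %*% delta)
  }
  F[F < 0] <- 0   # tiny negative round-off
  if (normalize) {
    s <- sum(F)
    if (s <= 0) stop("numerical error: model mass vanished on 0..dMax")
    F <- F / s
  }
  F
}

#' Expected mismatch distribution under spatial (infinite-island)
#' expansion
#'
#' A single sampled deme of scaled size theta inside an effectively
#' infinite island system that expanded spatially tau mutational units
#' ago from one ancestral deme of the same size.  Looking backwards, a
#' pair of lineages in the sampled deme either coalesces before a
#' migration separates them (rate 1 vs total separation rate M), or
#' survives the recent epoch and coalesces in the ancestral deme; the
#' resulting mismatch is a continuous mixture of Poisson layers over the
#' stationary distribution, evaluated by numerical integration.
#'
#' @param tau Expansion time in mutational units (>= 0).
#' @param theta Scaled deme (and ancestral) size (> 0, or 0 for the
#'   monomorphic limit).
#' @param M Scaled migration rate (>= 0).
#' @param dMax Largest difference class returned.
#' @param normalize Renormalize over 0..dMax (default TRUE).
#' @return Numeric vector over classes 0..dMax.
#' @export
expectedSpatial <- function(tau, theta, M, dMax, normalize = TRUE) {
  if (tau < 0 || theta < 0 || M < 0)
    stop("domain error: parameters must be non-negative")
  i <- 0:dMax
  if (theta == 0) {
    F <- as.numeric(i == 0)
  } else {
    T0 <- tau / theta
    upper <- min(T0, 750 / (1 + M))
    recent <- vapply(i, function(j) {
      if (upper <= 0) return(0)
      val <- tryCatch(stats::integrate(
        function(t) exp(-(1 + M) * t) * stats::dpois(j, theta * t),
        lower = 0, upper = upper, rel.tol = 1e-9,
        subdivisions = 400L)$value,
        error = function(e)
          stop("numerical error: mismatch integral failed (j=", j, "): ",
               conditionMessage(e), call. = FALSE))
      val
    }, 0)
    surv <- 1 - (1 - exp(-(1 + M) * T0)) / (1 + M)
    Fst <- vapply(i, function(j) .Fhat(theta, j), 0)
    anc <- vapply(i, function(ii) {
      k <- 0:ii
      sum(Fst[k + 1L] * stats::dpois(ii - k, tau))
    }, 0)
    F <- recent + surv * anc
  }
  F[F < 0] <- 0
  if (normalize) {
    s <- sum(F)
    if (s <= 0) stop("numerical error: model mass vanished on 0..dMax")
    F <- F / s
  }
  F
}

#' Harpending's raggedness index
#'
#' r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2 over a normalized distribution
#' x_0..x_d with x_{d+1} = 0.  Smooth unimodal (expansion-like)
#' distributions give small r; ragged multimodal (stationary)
#' distributions give large r.
#'
#' @param x Normalized frequencies over difference classes 0..d.
#' @return The raggedness index.
#' @examples
#' raggedness(c(1))                 # single spike: 1
#' raggedness(rep(0.1, 10))         # uniform: 0.01
#' @export
raggedness <- function(x) {
  if (abs(sum(x) - 1) > 1e-8)
    stop("domain error: raggedness requires a normalized distribution")
  xx <- c(x, 0)
  sum(diff(xx)^2)
}

.ssdObjective <- function(obsRel, model, dMax) {
  pad <- c(obsRel, rep(0, dMax + 1L - length(obsRel)))
  function(par) {
    expd <- tryCatch(
      if (model == "demographic")
        expectedSudden(par[1L], par[2L], par[3L], dMax)
      else expectedSpatial(par[1L], par[2L], par[3L], dMax),
      error = function(e) NULL)
    if (is.null(expd) || anyNA(expd)) return(1e6)
    sum((pad - expd)^2)
  }
}

.FIT_BOUNDS <- list(
  demographic = list(lower = c(tau = 0, theta0 = 0, theta1 = 0),
                     upper = c(tau = 50, theta0 = 1e5, theta1 = 1e5)),
  spatial     = list(lower = c(tau = 0, theta = 0, M = 0),
                     upper = c(tau = 50, theta = 1e5, M = 1e4)))

#' Fit an expansion model to a mismatch distribution
#'
#' Minimizes the sum of squared deviations (SSD) between the observed
#' relative mismatch frequencies and the model distribution, by bounded
#' multi-start L-BFGS-B (8 starts: tau at the method-of-moments mean
#' difference and half of it; theta0 in {0.01, 1} and theta1 in
#' {10, 100} for the demographic model, theta in {0.01, 1} and M in
#' {0.5, 10} for the spatial model; box bounds tau in [0, 50], thetas in
#' [0, 1e5], M in [0, 1e4]).  Estimates on the upper box bound are
#' flagged as effectively infinite.
#'
#' @param hist Output of [observedMismatch()] (or a
#'   [HaploAlignment-class], converted internally).
#' @param model "demographic" or "spatial".
#' @param starts Optional matrix/data.frame of custom start points (one
#'   row per start, columns in parameter order); default is the 8-start
#'   grid above.  Bootstrap refits warm-start from the parent estimate.
#' @return A [MismatchFit-class] (bootstrap slots unset; see
#'   [bootstrapGof()]).
#' @export
fitExpansion <- function(hist, model = c("demographic", "spatial"),
                         starts = NULL) {
  model <- match.arg(model)
  if (is(hist, "HaploAlignment")) hist <- observedMismatch(hist)
  obsRel <- hist$relative
  if (sum(obsRel > 0) < 2L)
    stop("identifiability error: mismatch histogram is degenerate (< 2 classes with mass)")
  dMax <- (length(obsRel) - 1L) + 5L   # observed support + 5, renormalized
  obj <- .ssdObjective(obsRel, model, dMax)
  if (is.null(starts)) {
    meanDiff <- sum((seq_along(obsRel) - 1) * obsRel)
    tauStarts <- unique(pmin(pmax(c(meanDiff, meanDiff / 2), 0.1), 49))
    starts <- if (model == "demographic")
      expand.grid(tau = tauStarts, theta0 = c(0.01, 1),
                  theta1 = c(10, 100))
    else
      expand.grid(tau = tauStarts, theta = c(0.01, 1), M = c(0.5, 10))
  }
  bounds <- .FIT_BOUNDS[[model]]
  best <- NULL
  trace <- character(0)
  for (s in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[s, ]), bounds$lower), bounds$upper)
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(parscale = pmax(p0, 0.1),
                                  maxit = 500L)),
      error = function(e) { trace <<- c(trace, conditionMessage(e)); NULL })
    if (is.null(res)) next
    # never return uphill from the start point
    if (obj(p0) < res$value) res <- list(par = p0, value = obj(p0))
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("fit error: optimizer failed from every start; trace: ",
         paste(trace, collapse = " | "))
  par <- setNames(best$par, names(bounds$lower))
  expd <- if (model == "demographic")
    expectedSudden(par[1L], par[2L], par[3L], dMax)
  else expectedSpatial(par[1L], par[2L], par[3L], dMax)
  obsPad <- c(obsRel, rep(0, dMax + 1L - length(obsRel)))
  new("MismatchFit", model = model, estimate = par,
      expected = expd, observed = obsPad,
      SSD = best$value, RAG = raggedness(obsRel),
      pSSD = NA_real_, pRAG = NA_real_,
      ci = matrix(numeric(0), nrow = 0, ncol = 2),
      boundary = par >= bounds$upper - 1e-6,
      B = 0L, seed = NA_integer_, nPairs = hist$n_pairs)
}

#' Parametric-bootstrap goodness of fit for a mismatch model
#'
#' Simulates B coalescent datasets under the fitted parameters (sudden
#' expansion for the demographic model, infinite-island history for the
#' spatial model) with the same sample size and locus length, refits
#' each, and reports p(SSD) = proportion of replicates whose refitted
#' SSD is >= the observed SSD (analogously for raggedness) using the raw
#' B-denominator proportion, plus 5--95 percentile confidence intervals
#' of the refitted parameters.  Replicates whose refit fails (e.g.
#' monomorphic simulated data) are dropped and counted; > 10\% drops
#' raises a warning.
#'
#' @param fit A [MismatchFit-class] from [fitExpansion()].
#' @param n Sample size to simulate (match the data the fit came from).
#' @param L Locus length in bp (default 554).
#' @param B Bootstrap replicates (>= 100; default 1000, raise to 10000
#'   for publication-scale runs).
#' @param seed Optional integer seed.
#' @return The fit with \code{pSSD}, \code{pRAG}, \code{ci}, \code{B}
#'   and \code{seed} filled in.
#' @export
bootstrapGof <- function(fit, n, L = 554L, B = 1000L, seed = NULL) {
  if (B < 100) stop("parameter error: need B >= 100")
  if (!is.null(seed)) set.seed(seed)
  est <- fit@estimate
  simOne <- function() {
    if (fit@model == "demographic")
      .simMismatch(n, model = "sudden", theta0 = est[["theta0"]],
                   theta1 = max(est[["theta1"]], 1e-8),
                   tau = est[["tau"]])
    else
      .simMismatch(n, model = "spatial",
                   theta = max(est[["theta"]], 1e-8),
                   tau = est[["tau"]], M = est[["M"]])
  }
  # refits warm-start from the parent estimate plus two spread starts
  warm <- rbind(est,
                est * c(0.5, 1, 1) + c(0, 0, 10),
                est * c(2, 1, 1) * c(1, 0, 1) + c(0, 0.5, 0))
  ssd <- rag <- rep(NA_real_, B)
  pars <- matrix(NA_real_, nrow = B, ncol = length(est),
                 dimnames = list(NULL, names(est)))
  for (b in seq_len(B)) {
    rep <- tryCatch({
      h <- simOne()
      f <- fitExpansion(h, fit@model, starts = warm)
      list(ssd = f@SSD, rag = f@RAG, par = f@estimate)
    }, error = function(e) NULL)
    if (!is.null(rep)) {
      ssd[b] <- rep$ssd; rag[b] <- rep$rag; pars[b, ] <- rep$par
    }
  }
  keep <- !is.na(ssd)
  nFail <- sum(!keep)
  if (nFail > 0.1 * B)
    warning(sprintf("%d/%d bootstrap refits failed", nFail, B))
  fit@pSSD <- mean(ssd[keep] >= fit@SSD)
  fit@pRAG <- mean(rag[keep] >= fit@RAG)
  fit@ci <- t(apply(pars[keep, , drop = FALSE], 2L, stats::quantile,
                    probs = c(0.05, 0.95), names = FALSE))
  colnames(fit@ci) <- c("lower5", "upper95")
  fit@B <- as.integer(sum(keep))
  fit@seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  fit
}
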