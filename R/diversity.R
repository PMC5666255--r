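# Per-group diversity statistics: S, H, Pi, pi, Watterson's theta,
# private haplotypes.

#' Number of segregating (polymorphic) sites
#'
#' Counts alignment columns with at least two distinct unambiguous
#' states, after applying the deletion policy (default: complete
#' deletion, i.e. columns containing any N/'-' are excluded so S shares
#' the site set of the other diversity statistics).
#'
#' @param aln A [HaploAlignment-class] with n >= 2.
#' @param deletion "complete" (default) or "pairwise" (all columns kept;
#'   ambiguous cells ignored within each column).
#' @return Integer count of segregating sites.
#' @export
segregatingSites <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (length(aln) < 2L) stop("sample-size error: need n >= 2")
  cm <- .charMatrix(aln)
  if (deletion == "complete")
    cm <- cm[, .completeColumns(cm), drop = FALSE]
  ok <- .validMask(cm)
  nState <- vapply(seq_len(ncol(cm)), function(j) {
    length(unique(cm[ok[, j], j]))
  }, integer(1))
  sum(nState >= 2L)
}

#' Haplotype (gene) diversity
#'
#' Nei's unbiased gene diversity H = n/(n-1) * (1 - sum p_i^2): the
#' probability that two sequences drawn without replacement carry
#' different haplotypes.
#'
#' @param counts Vector of haplotype frequencies (or a
#'   [HaplotypeTable-class], pooled over groups).
#' @param corrected Apply the n/(n-1) small-sample correction (default
#'   TRUE).
#' @return H in [0, 1].
#' @examples
#' haplotypeDiversity(c(3, 1))  # 0.5
#' @export
haplotypeDiversity <- function(counts, corrected = TRUE) {
  if (is(counts, "HaplotypeTable")) counts <- rowSums(haplotypeCounts(counts))
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("sample-size error: need n >= 2")
  h <- 1 - sum((counts / n)^2)
  if (corrected) h <- h * n / (n - 1)
  h
}

#' Mean pairwise differences and nucleotide diversity
#'
#' Pi_bar is the mean, over all n(n-1)/2 sequence pairs, of the count of
#' nucleotide differences; pi divides by the effective sequence length
#' (retained columns under complete deletion; per-pair complete sites
#' averaged over pairs under pairwise deletion, which keeps
#' pi = Pi_bar / L exact for gap-free data).
#'
#' @param aln A [HaploAlignment-class] with n >= 2.
#' @param deletion "complete" (default) or "pairwise".
#' @return Named list with \code{Pi_bar}, \code{pi} and
#'   \code{L_effective}.
#' @export
pairwiseDiversity <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  d <- pairwiseDifferences(aln, mode = "count", deletion = deletion)
  ut <- upper.tri(d)
  Pi_bar <- mean(d[ut])
  Leff <- if (deletion == "complete")
    sum(.completeColumns(.charMatrix(aln)))
  else mean(attr(d, "pairComplete")[ut])
  list(Pi_bar = Pi_bar, pi = Pi_bar / Leff, L_effective = Leff)
}

#' Watterson's theta from segregating sites
#'
#' theta_W = S / a1 with a1 = sum_{i=1}^{n-1} 1/i (per-sequence, i.e.
#' per-locus scale).
#'
#' @param S Number of segregating sites.
#' @param n Sample size (>= 2).
#' @return theta_W.
#' @export
wattersonTheta <- function(S, n) {
  if (n < 2) stop("sample-size error: need n >= 2")
  S / sum(1 / seq_len(n - 1))
}

# harmonic-number helpers shared with the neutrality module
.a1 <- function(n) sum(1 / seq_len(n - 1))
.a2 <- function(n) sum(1 / seq_len(n - 1)^2)

#' Private haplotypes per group
#'
#' A haplotype is private to group g when its frequency is non-zero only
#' in g.  The ratio divides by the number of haplotypes observed in the
#' group.
#'
#' @param table A [HaplotypeTable-class] with >= 2 groups.
#' @return data.frame with columns group, k (haplotypes observed), PH,
#'   PH_ratio.
#' @export
privateHaplotypes <- function(table) {
  counts <- haplotypeCounts(table)
  if (ncol(counts) < 2L)
    stop("grouping error: private haplotypes need >= 2 groups")
  presence <- counts > 0
  private <- rowSums(presence) == 1L
  k <- colSums(presence)
  PH <- colSums(presence & private)
  data.frame(group = colnames(counts), k = as.integer(k),
             PH = as.integer(PH), PH_ratio = PH / k,
             row.names = NULL)
}

#' Per-group diversity summary table
#'
#' One row per group plus a pooled "all" row, with n, k (haplotypes), PH,
#' PH/k, H, S, Pi_bar and pi — the standard regional-diversity layout
#' for mitochondrial phylogeography — plus Watterson's theta.
#'
#' @param aln A [HaploAlignment-class] with metadata.
#' @param grouping Metadata column to group by (default "region").
#' @param policy Haplotype-collapse ambiguity policy.
#' @return data.frame; values unrounded (round at write-out).
#' @export
diversitySummary <- function(aln, grouping = "region",
                             policy = "wildcard") {
  lab <- .groupLabels(aln, grouping)
  tab <- collapseHaplotypes(aln, grouping, policy)
  counts <- haplotypeCounts(tab)
  groups <- colnames(counts)
  ph <- if (length(groups) > 1L) privateHaplotypes(tab) else NULL
  # k and H per group come from the pooled collapse so they are
  # consistent with the private-haplotype accounting
  oneRow <- function(sub, name, cvec) {
    n <- length(sub)
    S <- segregatingSites(sub)
    pd <- pairwiseDiversity(sub)
    data.frame(group = name, n = n, k = sum(cvec > 0),
               PH = NA_integer_, PH_ratio = NA_real_,
               H = haplotypeDiversity(cvec),
               S = S, Pi_bar = pd$Pi_bar, pi = pd$pi,
               theta_w = wattersonTheta(S, n))
  }
  rows <- lapply(groups, function(g) {
    r <- oneRow(aln[names(lab)[lab == g]], g, counts[, g])
    if (!is.null(ph)) {
      r$PH <- ph$PH[ph$group == g]
      r$PH_ratio <- ph$PH_ratio[ph$group == g]
    }
    r
  })
  all <- oneRow(aln, "all", rowSums(counts))
  out <- rbind(do.call(rbind, rows), all)
  rownames(out) <- NULL
  out
}

#' Write a diversity summary CSV (values rounded to 5 decimals)
#'
#' @param x Output of [diversitySummary()].
#' @param path Output CSV path.
#' @export
writeDiversitySummary <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], round, digits = 5)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(x)
}
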