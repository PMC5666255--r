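#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.REGIONS <- c("EA", "AP", "WS", "AI")
.SUBREGIONS <- c("TA", "RS", "DS", "BR", "BI", "SSI", "")

#' HaploAlignment: a rectangular nucleotide alignment with sample metadata
#'
#' Container for an intraspecific alignment (one sequence per individual,
#' all the same length) plus an optional per-sample metadata table giving
#' population, region, subregion and collection coordinates.  All
#' downstream statistics (diversity, neutrality, mismatch, AMOVA,
#' networks) consume this class.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of equal-width sequences; names
#'   are the unique sample identifiers.
#' @slot meta A [S4Vectors::DataFrame] with one row per sequence and
#'   columns \code{sample_id}, \code{population}, \code{region},
#'   \code{subregion}, \code{lat}, \code{lon}, \code{depth_m}.  May have
#'   zero rows when no metadata were supplied.
#'
#' @seealso [readAlignment()], [collapseHaplotypes()]
#' @exportClass HaploAlignment
setClass("HaploAlignment",
  representation(seqs = "DNAStringSet", meta = "DataFrame"))

setValidity("HaploAlignment", function(object) {
  msg <- character()
  n <- length(object@seqs)
  if (n < 1L) msg <- c(msg, "alignment must contain at least one sequence")
  ids <- names(object@seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    msg <- c(msg, "all sequences must carry non-empty ids")
  else if (anyDuplicated(ids))
    msg <- c(msg, "sequence ids must be unique")
  w <- Biostrings::width(object@seqs)
  if (n >= 1L && length(unique(w)) > 1L)
    msg <- c(msg, sprintf("unequal sequence lengths: %s",
                          paste(unique(w), collapse = ", ")))
  if (n >= 1L && any(w == 0L)) msg <- c(msg, "empty sequences not allowed")
  if (nrow(object@meta) > 0L) {
    need <- c("sample_id", "population", "region", "subregion",
              "lat", "lon", "depth_m")
    miss <- setdiff(need, colnames(object@meta))
    if (length(miss))
      msg <- c(msg, paste("metadata missing columns:",
                          paste(miss, collapse = ", ")))
    else {
      if (!setequal(object@meta$sample_id, ids) ||
          nrow(object@meta) != n)
        msg <- c(msg, "metadata sample_ids must match alignment ids 1:1")
      bad <- setdiff(unique(object@meta$region), .REGIONS)
      if (length(bad))
        msg <- c(msg, sprintf("unknown region label(s): %s (allowed: %s)",
                              paste(bad, collapse = ", "),
                              paste(.REGIONS, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' HaplotypeTable: distinct sequences with per-group frequency counts
#'
#' @slot haplotypes A [Biostrings::DNAStringSet] of representative
#'   sequences, one per haplotype, named \code{H1}, \code{H2}, ... in
#'   order of first appearance.
#' @slot counts Integer matrix, haplotype x group; column sums are the
#'   group sample sizes.
#' @slot grouping Which metadata column defined the columns.
#' @slot policy Ambiguity policy used when collapsing ("wildcard" or
#'   "strict").
#' @slot members List mapping haplotype id to the sample ids it contains.
#'
#' @seealso [collapseHaplotypes()]
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
  representation(haplotypes = "DNAStringSet", counts = "matrix",
                 grouping = "character", policy = "character",
                 members = "list"))

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  if (length(object@haplotypes) != nrow(object@counts))
    msg <- c(msg, "counts must have one row per haplotype")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (any(rowSums(object@counts) == 0))
    msg <- c(msg, "every haplotype must be observed at least once")
  if (length(msg)) msg else TRUE
})

#' MismatchFit: a fitted pairwise-difference expansion model
#'
#' Result of fitting the sudden-demographic or spatial (infinite-island)
#' expansion model to an observed mismatch distribution by least squares,
#' optionally with parametric-bootstrap goodness-of-fit p-values and
#' percentile confidence intervals.
#'
#' @slot model "demographic" or "spatial".
#' @slot estimate Named numeric: \code{tau}, \code{theta0}, \code{theta1}
#'   (demographic) or \code{tau}, \code{theta}, \code{M} (spatial).
#' @slot expected Expected relative mismatch distribution at the optimum.
#' @slot observed Observed relative mismatch distribution.
#' @slot SSD Sum of squared deviations at the optimum.
#' @slot RAG Harpending's raggedness of the observed distribution.
#' @slot pSSD,pRAG Parametric-bootstrap p-values (NA until
#'   [bootstrapGof()] is run).
#' @slot ci Matrix of 5--95\% percentile intervals per parameter (0 rows
#'   until bootstrapped).
#' @slot boundary Logical per parameter: estimate hit its upper box bound
#'   (reported "inf"-style).
#' @slot B Bootstrap replicate count (0 until bootstrapped).
#' @slot seed Seed used for the bootstrap.
#' @slot nPairs Number of sequence pairs behind the observed histogram.
#'
#' @seealso [fitExpansion()], [bootstrapGof()]
#' @exportClass MismatchFit
setClass("MismatchFit",
  representation(model = "character", estimate = "numeric",
                 expected = "numeric", observed = "numeric",
                 SSD = "numeric", RAG = "numeric",
                 pSSD = "numeric", pRAG = "numeric",
                 ci = "matrix", boundary = "logical",
                 B = "integer", seed = "integer", nPairs = "numeric"))

setValidity("MismatchFit", function(object) {
  msg <- character()
  if (!object@model %in% c("demographic", "spatial"))
    msg <- c(msg, "model must be 'demographic' or 'spatial'")
  if (any(object@estimate < 0))
    msg <- c(msg, "all expansion parameters must be non-negative")
  if (object@SSD < 0) msg <- c(msg, "SSD must be non-negative")
  if (length(msg)) msg else TRUE
})

#' AmovaResult: hierarchical analysis of molecular variance
#'
#' @slot table data.frame with one row per level (among groups / among
#'   populations within groups / among populations / within populations):
#'   df, sum of squares, variance component sigma2, percent variation.
#' @slot phi Named numeric Phi-statistics (PhiST, and PhiCT/PhiSC for the
#'   three-level design).
#' @slot p Named numeric permutation p-values for the Phi-statistics.
#' @slot nPerm Number of permutations.
#' @slot seed Seed used for permutations.
#'
#' @seealso [amova()], [pairwisePhiST()]
#' @exportClass AmovaResult
setClass("AmovaResult",
  representation(table = "data.frame", phi = "numeric", p = "numeric",
                 nPerm = "integer", seed = "integer"))

#' HaplotypeNetwork: statistical-parsimony haplotype graph
#'
#' Observed haplotypes plus inferred (unsampled) single-step
#' intermediates, every edge spanning exactly one mutational step, built
#' under a parsimony connection limit.
#'
#' @slot graph An [igraph::igraph] with vertex attributes \code{name},
#'   \code{sequence}, \code{freq}, \code{inferred}, per-group counts, and
#'   edge attribute \code{site} (1-based mutated alignment column).
#' @slot nodes data.frame mirror of the vertex table.
#' @slot connectionLimit Maximum parsimonious number of steps used.
#' @slot ancestral Id of the designated ancestral haplotype in the
#'   largest component ("" when the network is empty).
#' @slot ancestralByComponent Named character, one designated ancestor
#'   per connected component.
#' @slot ancestralTied TRUE when the top outgroup-weight score was tied.
#'
#' @seealso [buildNetwork()], [ancestralHaplotype()]
#' @exportClass HaplotypeNetwork
setClass("HaplotypeNetwork",
  representation(graph = "ANY", nodes = "data.frame",
                 connectionLimit = "integer", ancestral = "character",
                 ancestralByComponent = "character",
                 ancestralTied = "logical"))

#' SimulatedDataset: output of the coalescent simulator
#'
#' @slot alignment A [HaploAlignment] (simulated sequences + deme
#'   metadata).
#' @slot trueParams List echoing the simulation parameters.
#' @slot rootHaplotype Character; the sequence at the genealogy root.
#'
#' @seealso [simulateCoalescent()], [makeStudyLikeDataset()]
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
  representation(alignment = "HaploAlignment", trueParams = "list",
                 rootHaplotype = "character"))
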