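# Accessors and show() methods.

#' @rdname HaploAlignment-class
#' @param object,x A \code{HaploAlignment}.
#' @export
setGeneric("alnSequences", function(x) standardGeneric("alnSequences"))
#' @rdname HaploAlignment-class
#' @export
setMethod("alnSequences", "HaploAlignment", function(x) x@seqs)

#' @rdname HaploAlignment-class
#' @export
setGeneric("alnMetadata", function(x) standardGeneric("alnMetadata"))
#' @rdname HaploAlignment-class
#' @export
setMethod("alnMetadata", "HaploAlignment", function(x) x@meta)

#' @rdname HaploAlignment-class
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))
#' @rdname HaploAlignment-class
#' @export
setMethod("alignmentLength", "HaploAlignment",
          function(x) unique(Biostrings::width(x@seqs))[1L])

#' @rdname HaploAlignment-class
#' @export
setMethod("length", "HaploAlignment", function(x) length(x@seqs))

#' @rdname HaploAlignment-class
#' @export
setMethod("names", "HaploAlignment", function(x) names(x@seqs))

#' Subset a HaploAlignment by index, id or logical mask
#'
#' @param x A \code{HaploAlignment}.
#' @param i Index vector (numeric, logical, or character sample ids).
#' @param j,drop,... Ignored.
#' @return A \code{HaploAlignment} with the selected samples (metadata
#'   subset along).
#' @export
setMethod("[", "HaploAlignment", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  seqs <- x@seqs[i]
  meta <- x@meta
  if (nrow(meta) > 0L)
    meta <- meta[match(names(seqs), meta$sample_id), , drop = FALSE]
  new("HaploAlignment", seqs = seqs, meta = meta)
})

setMethod("show", "HaploAlignment", function(object) {
  cat(sprintf("HaploAlignment: %d sequences x %d bp\n",
              length(object@seqs), alignmentLength(object)))
  if (nrow(object@meta) > 0L) {
    tab <- table(object@meta$region)
    cat("  regions:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  } else cat("  (no sample metadata)\n")
})

#' @rdname HaplotypeTable-class
#' @param x,object A \code{HaplotypeTable}.
#' @export
setGeneric("haplotypeCounts", function(x) standardGeneric("haplotypeCounts"))
#' @rdname HaplotypeTable-class
#' @export
setMethod("haplotypeCounts", "HaplotypeTable", function(x) x@counts)

#' @rdname HaplotypeTable-class
#' @export
setGeneric("haplotypeSequences",
           function(x) standardGeneric("haplotypeSequences"))
#' @rdname HaplotypeTable-class
#' @export
setMethod("haplotypeSequences", "HaplotypeTable", function(x) x@haplotypes)

#' @rdname HaplotypeTable-class
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))
#' @rdname HaplotypeTable-class
#' @export
setMethod("nHaplotypes", "HaplotypeTable", function(x) length(x@haplotypes))

setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf(
    "HaplotypeTable: %d haplotypes, %d samples, grouped by %s (%s policy)\n",
    nHaplotypes(object), sum(object@counts), object@grouping, object@policy))
  cat("  groups:", paste(sprintf("%s (n=%d)", colnames(object@counts),
                                 colSums(object@counts)), collapse = ", "),
      "\n")
})

setMethod("show", "MismatchFit", function(object) {
  cat(sprintf("MismatchFit (%s expansion model)\n", object@model))
  est <- object@estimate
  lab <- vapply(seq_along(est), function(i) {
    v <- if (object@boundary[i]) "inf" else format(est[i], digits = 4)
    paste0(names(est)[i], "=", v)
  }, character(1))
  cat("  estimate:", paste(lab, collapse = ", "), "\n")
  cat(sprintf("  SSD = %.5g  RAG = %.5g\n", object@SSD, object@RAG))
  if (object@B > 0L)
    cat(sprintf("  bootstrap (B=%d): p(SSD) = %.3f, p(RAG) = %.3f\n",
                object@B, object@pSSD, object@pRAG))
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (squared pairwise-difference distances)\n")
  print(object@table, row.names = FALSE)
  for (s in names(object@phi))
    cat(sprintf("  %s = %.5f  (p = %.4g, %d permutations)\n",
                s, object@phi[s], object@p[s], object@nPerm))
})

setMethod("show", "HaplotypeNetwork", function(object) {
  inf <- sum(object@nodes$inferred)
  cat(sprintf(
    "HaplotypeNetwork: %d observed + %d inferred nodes, %d edges, %d component(s)\n",
    nrow(object@nodes) - inf, inf, igraph::ecount(object@graph),
    igraph::count_components(object@graph)))
  cat(sprintf("  connection limit: %d steps; ancestral: %s%s\n",
              object@connectionLimit, object@ancestral,
              if (object@ancestralTied) " (tied)" else ""))
})

setMethod("show", "SimulatedDataset", function(object) {
  p <- object@trueParams
  cat(sprintf("SimulatedDataset: %d sequences x %d bp (%s model)\n",
              length(object@alignment), alignmentLength(object@alignment),
              p$model %||% "constant"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
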