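# Alignment / metadata input, haplotype collapsing, pairwise distances.

.ALLOWED <- c("A", "C", "G", "T", "N", "-")

#' Construct a HaploAlignment from sequences and optional metadata
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet] of
#'   aligned sequences (equal length, alphabet A/C/G/T/N/-).
#' @param meta Optional data.frame of sample metadata (see
#'   [readSampleMetadata()] for the expected columns).
#' @return A [HaploAlignment-class] object.
#' @export
HaploAlignment <- function(seqs, meta = NULL) {
  if (is.character(seqs)) {
    if (is.null(names(seqs)))
      names(seqs) <- paste0("s", seq_along(seqs))
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  if (is.null(meta)) {
    meta <- S4Vectors::DataFrame(sample_id = character(0),
                                 population = character(0),
                                 region = character(0),
                                 subregion = character(0),
                                 lat = numeric(0), lon = numeric(0),
                                 depth_m = numeric(0))
  } else if (!is(meta, "DataFrame")) {
    meta <- S4Vectors::DataFrame(meta)
  }
  new("HaploAlignment", seqs = seqs, meta = meta)
}

#' Read an aligned FASTA file
#'
#' Reads a (wrapped or single-line) FASTA alignment, uppercases, maps U
#' to T, and validates that all sequences have identical length and use
#' only A/C/G/T/N/-.
#'
#' @param path Path to the FASTA file.
#' @param meta Optional metadata data.frame (or path to a metadata CSV)
#'   whose \code{sample_id} column must match the FASTA ids exactly.
#' @return A [HaploAlignment-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "ACGA"), fa)
#' aln <- readAlignment(fa)
#' alignmentLength(aln)  # 4
#' @export
readAlignment <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("input error: unparseable FASTA: ",
                         conditionMessage(e), call. = FALSE))
  if (length(raw) == 0L) stop("input error: FASTA file contains no records")
  txt <- toupper(as.character(raw))
  txt <- gsub("U", "T", txt, fixed = TRUE)
  # name offending record before any other validation
  for (i in seq_along(txt)) {
    bad <- setdiff(unique(strsplit(txt[i], "")[[1]]), .ALLOWED)
    if (length(bad))
      stop(sprintf("input error: record '%s' contains invalid character(s): %s",
                   names(raw)[i], paste(bad, collapse = ", ")))
  }
  if (length(unique(nchar(txt))) > 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(unique(nchar(txt)), collapse = ", "), ")")
  names(txt) <- sub("\\s.*$", "", names(raw))  # id = first token
  if (is.character(meta) && length(meta) == 1L)
    meta <- readSampleMetadata(meta)
  HaploAlignment(txt, meta)
}

#' Read a sample-metadata CSV
#'
#' Expected header: \code{sample_id,population,region,subregion,lat,lon,
#' depth_m} (UTF-8, comma-separated, '.' decimal).  Region labels must be
#' one of EA, AP, WS, AI; subregion one of TA, RS, DS, BR, BI, SSI or
#' empty.
#'
#' @param path Path to the CSV file.
#' @return A data.frame.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character"))
  need <- c("sample_id", "population", "region", "subregion",
            "lat", "lon", "depth_m")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("input error: metadata missing column(s): ",
         paste(miss, collapse = ", "))
  df$subregion[is.na(df$subregion)] <- ""
  bad <- setdiff(unique(df$subregion), .SUBREGIONS)
  if (length(bad))
    stop("input error: unknown subregion label(s): ",
         paste(bad, collapse = ", "))
  df
}

# internal: character matrix (rows = samples) and unambiguous-site mask
.charMatrix <- function(aln) {
  m <- as.matrix(alnSequences(aln))
  rownames(m) <- names(aln)
  m
}

.validMask <- function(cm) matrix(cm %in% c("A", "C", "G", "T"),
                                  nrow = nrow(cm))

# columns unambiguous in every sample (complete-deletion site set)
.completeColumns <- function(cm) colSums(!.validMask(cm)) == 0L

.groupLabels <- function(aln, grouping) {
  meta <- alnMetadata(aln)
  if (nrow(meta) == 0L)
    return(setNames(rep("all", length(aln)), names(aln)))
  grouping <- match.arg(grouping, c("population", "region", "subregion"))
  lab <- meta[[grouping]][match(names(aln), meta$sample_id)]
  if (anyNA(lab))
    stop("mapping error: record(s) without metadata: ",
         paste(names(aln)[is.na(lab)], collapse = ", "))
  setNames(as.character(lab), names(aln))
}

#' Collapse aligned sequences into haplotypes
#'
#' Two sequences share a haplotype when they are identical at every site
#' that is unambiguous (not N, not '-') in both.  Under the default
#' \code{"wildcard"} policy N and '-' act as wildcards: a sequence joins
#' the first previously seen haplotype whose representative (first
#' member, in input order) it is compatible with.  Under \code{"strict"}
#' only exactly identical strings share a haplotype.  Haplotype ids are
#' "H" + 1-based order of first appearance.
#'
#' @param aln A [HaploAlignment-class].
#' @param grouping Metadata column defining the count columns
#'   ("population", "region" or "subregion"); ignored when the alignment
#'   carries no metadata (single "all" group).
#' @param policy "wildcard" (default) or "strict".
#' @return A [HaplotypeTable-class].
#' @examples
#' aln <- HaploAlignment(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGA"))
#' nHaplotypes(collapseHaplotypes(aln))  # 2
#' @export
collapseHaplotypes <- function(aln, grouping = "population",
                               policy = c("wildcard", "strict")) {
  policy <- match.arg(policy)
  lab <- .groupLabels(aln, grouping)
  seqs <- as.character(alnSequences(aln))
  n <- length(seqs)
  reps <- character(0)        # representative strings
  assign <- integer(n)
  if (policy == "strict") {
    assign <- match(seqs, unique(seqs))
    reps <- unique(seqs)
  } else {
    repMat <- list()
    cm <- .charMatrix(aln)
    ok <- .validMask(cm)
    for (i in seq_len(n)) {
      hit <- 0L
      for (h in seq_along(repMat)) {
        r <- repMat[[h]]
        both <- ok[i, ] & r$ok
        if (all(cm[i, both] == r$chars[both])) { hit <- h; break }
      }
      if (hit == 0L) {
        repMat[[length(repMat) + 1L]] <- list(chars = cm[i, ], ok = ok[i, ])
        hit <- length(repMat)
        reps <- c(reps, seqs[i])
      }
      assign[i] <- hit
    }
  }
  K <- length(reps)
  groups <- sort(unique(lab))
  counts <- matrix(0L, nrow = K, ncol = length(groups),
                   dimnames = list(paste0("H", seq_len(K)), groups))
  for (i in seq_len(n))
    counts[assign[i], lab[i]] <- counts[assign[i], lab[i]] + 1L
  members <- split(names(aln), paste0("H", assign))
  members <- members[paste0("H", seq_len(K))]
  hap <- Biostrings::DNAStringSet(setNames(reps, paste0("H", seq_len(K))))
  new("HaplotypeTable", haplotypes = hap, counts = counts,
      grouping = if (nrow(alnMetadata(aln)) > 0L) grouping else "all",
      policy = policy, members = members)
}

#' Pairwise sequence differences
#'
#' Counts of mismatching sites (or their proportion) over
#' pairwise-complete sites, computed with \code{ape::dist.dna}.  Under
#' \code{deletion = "complete"} all columns containing any N/'-' are
#' dropped first so every statistic shares one site set; under
#' \code{"pairwise"} sites are excluded per pair.
#'
#' @param aln A [HaploAlignment-class] with at least 2 sequences.
#' @param mode "count" (integer mutational differences) or "p_distance".
#' @param deletion "pairwise" (default) or "complete".
#' @return A symmetric numeric matrix with sample ids as dimnames and
#'   attribute \code{"pairComplete"} (matrix of per-pair complete-site
#'   counts).
#' @export
pairwiseDifferences <- function(aln, mode = c("count", "p_distance"),
                                deletion = c("pairwise", "complete")) {
  mode <- match.arg(mode)
  deletion <- match.arg(deletion)
  if (length(aln) < 2L) stop("sample-size error: need at least 2 sequences")
  cm <- .charMatrix(aln)
  if (deletion == "complete") {
    keep <- .completeColumns(cm)
    cm <- cm[, keep, drop = FALSE]
    if (ncol(cm) == 0L)
      stop("undefined-distance error: no complete columns remain")
  }
  ok <- .validMask(cm)
  pairComplete <- ok %*% t(ok)
  if (any(pairComplete[upper.tri(pairComplete)] == 0))
    stop("undefined-distance error: a pair shares no unambiguous site")
  bin <- ape::as.DNAbin(tolower(cm))
  cnt <- as.matrix(ape::dist.dna(bin, model = "N",
                                 pairwise.deletion = TRUE))
  d <- if (mode == "count") cnt else cnt / pairComplete
  dimnames(d) <- list(names(aln), names(aln))
  diag(d) <- 0
  attr(d, "pairComplete") <- pairComplete
  d
}

#' Optionally Jukes--Cantor-correct a p-distance matrix
#'
#' @param p A p-distance matrix from [pairwiseDifferences()].
#' @return The JC69-corrected distance matrix.
#' @export
jukesCantor <- function(p) {
  if (any(p >= 0.75)) stop("domain error: p-distance >= 3/4 not correctable")
  d <- -0.75 * log(1 - 4 * p / 3)
  attr(d, "pairComplete") <- attr(p, "pairComplete")
  d
}

#' Write a haplotype table to CSV
#'
#' Columns: haplotype_id, sequence, one count column per group.
#'
#' @param x A [HaplotypeTable-class].
#' @param path Output CSV path.
#' @return Invisibly, the data.frame written.
#' @export
writeHaplotypeTable <- function(x, path) {
  df <- data.frame(haplotype_id = names(haplotypeSequences(x)),
                   sequence = as.character(haplotypeSequences(x)),
                   as.data.frame(haplotypeCounts(x)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a distance matrix as square CSV (id header row and column)
#'
#' @param d Matrix from [pairwiseDifferences()].
#' @param path Output CSV path.
#' @export
writeDistanceMatrix <- function(d, path) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
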