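# Shared fixtures, built in code.

# the 4-sequence toy used throughout: S = 2, Pi_bar = 7/6, K_hap = 3
toyAlignment <- function() {
  HaploAlignment(c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAT",
                   s3 = "AAAAAAAATT", s4 = "AAAAAAAAAA"))
}

toyMeta <- function(ids, population, region = "EA", subregion = "") {
  data.frame(sample_id = ids, population = population, region = region,
             subregion = subregion, lat = NA_real_, lon = NA_real_,
             depth_m = NA_real_)
}

writeFasta <- function(seqs, width = NULL) {
  path <- tempfile(fileext = ".fasta")
  lines <- character(0)
  for (nm in names(seqs)) {
    lines <- c(lines, paste0(">", nm))
    s <- seqs[[nm]]
    if (is.null(width)) lines <- c(lines, s)
    else lines <- c(lines,
                    substring(s, seq(1, nchar(s), width),
                              pmin(seq(1, nchar(s), width) + width - 1,
                                   nchar(s))))
  }
  writeLines(lines, path)
  path
}

# brute-force Fu's Fs oracle for tiny n: exact Stirling numbers by the
# integer recurrence, Ewens probabilities summed directly, all
# quantities recomputed from the raw sequences with naive loops
bruteFs <- function(seqs) {
  n <- length(seqs)
  d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(seqs[i], "")[[1]]; b <- strsplit(seqs[j], "")[[1]]
    d <- d + sum(a != b)
  }
  Pi <- d / (n * (n - 1) / 2)
  K <- length(unique(seqs))
  # exact unsigned Stirling numbers of the first kind
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1     # s(0,0)
  for (m in 1:n) for (k in 1:m)
    s[m + 1, k + 1] <- (m - 1) * s[m, k + 1] + s[m, k]
  denom <- prod(Pi + 0:(n - 1))
  pk <- vapply(1:n, function(k) s[n + 1, k + 1] * Pi^k / denom, 0)
  Sp <- sum(pk[1:n >= K])
  log(Sp / (1 - Sp))
}
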