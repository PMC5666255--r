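# Whole-study orchestration: diversity -> neutrality -> mismatch ->
# structure -> network -> dating from one configuration, with per-stage
# seed derivation, error isolation and a run log.

# one global seed deterministically derives per-stage seeds so a stage
# can be re-run in isolation (simple string hash, kept below 2^31)
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)) * 257)
  as.integer((seed + h) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Executes diversity, neutrality, mismatch (+ goodness of fit),
#' structure (AMOVA + pairwise Phi-ST), network and dating on one
#' alignment, writing CSV/GraphML outputs and a run log.  A failing
#' stage is recorded and skipped, and stages depending on it (dating
#' depends on mismatch) are skipped as dependents.  Identical config +
#' seed gives identical outputs.
#'
#' @param aln A [HaploAlignment-class] with metadata, or a FASTA path.
#' @param meta Metadata data.frame or CSV path (when \code{aln} is a
#'   path).
#' @param outDir Output directory (created if needed).
#' @param grouping Metadata column for per-group analyses (default
#'   "region").
#' @param seed Global integer seed; per-stage seeds are derived from it.
#' @param nPerm Permutations for structure tests.
#' @param nSims Replicates for neutrality null simulations.
#' @param B Bootstrap replicates for mismatch goodness of fit.
#' @param mu,correction Dating parameters (see [expansionTime()]).
#' @param alpha Parsimony connection probability for the network.
#' @param mismatchModel "demographic", "spatial" or "both".
#' @param skip Character vector of stage names to skip (among
#'   "diversity", "neutrality", "mismatch", "structure", "network",
#'   "dating").
#' @return Invisibly, a list with per-stage results, \code{errors},
#'   \code{skipped} and the log lines.
#' @export
runPipeline <- function(aln, meta = NULL, outDir = tempfile("run"),
                        grouping = "region", seed = 1L,
                        nPerm = 1000L, nSims = 1000L, B = 200L,
                        mu = DEFAULT_MU, correction = 10,
                        alpha = 0.95, mismatchModel = "demographic",
                        skip = character(0)) {
  if (is.character(aln)) aln <- readAlignment(aln, meta)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  results <- list()
  errors <- list()
  skipped <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  say("pipeline start: n=%d, L=%d, grouping=%s, seed=%d",
      length(aln), alignmentLength(aln), grouping, seed)
  say("parameters: nPerm=%d nSims=%d B=%d mu=%g correction=%g alpha=%g model=%s",
      nPerm, nSims, B, mu, correction, alpha, mismatchModel)
  lab <- .groupLabels(aln, grouping)
  groups <- sort(unique(lab))
  stage <- function(name, deps, fun) {
    if (name %in% skip) {
      skipped <<- c(skipped, name)
      say("stage %s: skipped (requested)", name)
      return(invisible(NULL))
    }
    bad <- intersect(deps, c(names(errors), skipped))
    if (length(bad)) {
      skipped <<- c(skipped, name)
      say("stage %s: skipped (dependency %s unavailable)", name,
          paste(bad, collapse = ","))
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(.stageSeed(seed, name)), error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
      say("stage %s: ERROR (%s) [%.2fs]", name, conditionMessage(res), dt)
    } else {
      results[[name]] <<- res
      say("stage %s: done [%.2fs]", name, dt)
    }
  }
  stage("diversity", NULL, function(sd) {
    div <- diversitySummary(aln, grouping)
    writeDiversitySummary(div, file.path(outDir, "diversity.csv"))
    div
  })
  stage("neutrality", NULL, function(sd) {
    set.seed(sd)
    rows <- lapply(c(groups, "all"), function(g) {
      sub <- if (g == "all") aln else aln[names(lab)[lab == g]]
      r <- tryCatch(neutralityTest(sub, nSims = nSims),
                    error = function(e) NULL)
      if (is.null(r)) data.frame(group = g, D = NA, Fs = NA,
                                 p_D = NA, p_Fs = NA)
      else data.frame(group = g, D = r$D, Fs = r$Fs, p_D = r$p_D,
                      p_Fs = r$p_Fs)
    })
    out <- do.call(rbind, rows)
    utils::write.csv(out, file.path(outDir, "neutrality.csv"),
                     row.names = FALSE)
    out
  })
  stage("mismatch", NULL, function(sd) {
    set.seed(sd)
    models <- if (mismatchModel == "both") c("demographic", "spatial")
              else mismatchModel
    fits <- list()
    for (g in c(groups, "all")) {
      sub <- if (g == "all") aln else aln[names(lab)[lab == g]]
      for (m in models) {
        f <- tryCatch({
          f0 <- fitExpansion(observedMismatch(sub), m)
          bootstrapGof(f0, n = length(sub), L = alignmentLength(sub),
                       B = B, seed = .stageSeed(sd, paste0(g, m)))
        }, error = function(e) NULL)
        if (!is.null(f)) fits[[paste(g, m, sep = ".")]] <- f
      }
    }
    tab <- do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      est <- f@estimate
      data.frame(fit = nm, model = f@model,
                 tau = est[["tau"]],
                 par2 = est[[2L]], par3 = est[[3L]],
                 SSD = f@SSD, p_SSD = f@pSSD,
                 RAG = f@RAG, p_RAG = f@pRAG)
    }))
    utils::write.csv(tab, file.path(outDir, "mismatch.csv"),
                     row.names = FALSE)
    fits
  })
  stage("structure", NULL, function(sd) {
    am <- amova(aln, populations = grouping, nPerm = nPerm, seed = sd)
    utils::write.csv(am@table, file.path(outDir, "amova.csv"),
                     row.names = FALSE)
    pw <- pairwisePhiST(aln, populations = grouping, nPerm = nPerm,
                        seed = .stageSeed(sd, "pairwise"))
    writeDistanceMatrix(pw$phist, file.path(outDir, "pairwise_phist.csv"))
    writeDistanceMatrix(pw$p, file.path(outDir, "pairwise_p.csv"))
    list(amova = am, pairwise = pw)
  })
  stage("network", NULL, function(sd) {
    tab <- collapseHaplotypes(aln, grouping)
    writeHaplotypeTable(tab, file.path(outDir, "haplotypes.csv"))
    net <- buildNetwork(tab,
                        limit = connectionLimit(alignmentLength(aln),
                                                alpha))
    writeNetworkGraphML(net, file.path(outDir, "network"))
    net
  })
  stage("dating", "mismatch", function(sd) {
    fits <- results$mismatch
    demFits <- fits[vapply(fits, function(f) f@model == "demographic",
                           logical(1))]
    if (!length(demFits)) demFits <- fits
    dt <- datingTable(demFits, mu = mu, L = alignmentLength(aln),
                      correction = correction)
    utils::write.csv(dt, file.path(outDir, "dating.csv"),
                     row.names = FALSE)
    dt
  })
  say("pipeline end: %d stage(s) ok, %d error(s), %d skipped",
      length(results), length(errors), length(skipped))
  writeLines(log, file.path(outDir, "run.log"))
  invisible(list(results = results, errors = errors, skipped = skipped,
                 log = log, outDir = outDir))
}
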