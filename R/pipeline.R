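# Orchestration: run the full per-dataset analysis and emit a study row
# with the same schema as the packaged 81-study summary table, so that
# simulated studies can be fed straight into the summary statistics.
# There is no separate shell executable: runStudy() is the entry point and
# scripts can wrap it with Rscript where a batch interface is wanted.

.presetReps <- function(preset) {
  if (preset == "paper")
    list(ild = 999L, ird = 99L, resamples = 100L, gerPerms = 10000L)
  else
    list(ild = 49L, ird = 49L, resamples = 25L, gerPerms = 1000L)
}

#' Run the complete partition analysis for one dataset
#'
#' Executes curation, the three partition searches, ensemble homoplasy
#' indices, the ILD test, all four IRD variants, the jackknife
#' partition-versus-entire test and (when ranges are given) stratigraphic
#' congruence for both partitions' trees. Every stage gets a seed derived
#' from the master seed; stage failures are caught and recorded so a
#' partial row is still returned.
#'
#' @param cm a \linkS4class{CharacterMatrix}, or NULL if \code{nexus} given.
#' @param scheme a \linkS4class{PartitionScheme}, or charset names via
#'   \code{cranio}/\code{post} when reading from \code{nexus}.
#' @param nexus optional path to a NEXUS file to read.
#' @param cranio,post charset names used with \code{nexus}.
#' @param ranges optional stratigraphic range table (or CSV path).
#' @param outgroup outgroup taxon for rooting trees in the stratigraphic
#'   stage.
#' @param preset \code{"paper"} (999/99 replicates, 100 resamples) or
#'   \code{"desk"} (49/49/25) -- sets both the search effort and the
#'   replicate counts; individual counts can be overridden.
#' @param config optional explicit \linkS4class{SearchConfig}.
#' @param ildReplicates,irdReplicates,nResamples optional overrides.
#' @param curate apply the 40% missing-data curation first.
#' @param seed master seed.
#' @return list with \code{row} (one-row data.frame, fixture schema),
#'   \code{details} (full result objects) and \code{errors}.
#' @export
runStudy <- function(cm = NULL, scheme = NULL, nexus = NULL,
                     cranio = "cranio", post = "post", ranges = NULL,
                     outgroup = NULL, preset = c("desk", "paper"),
                     config = NULL, ildReplicates = NULL,
                     irdReplicates = NULL, nResamples = NULL,
                     curate = TRUE, seed = 1L) {
  preset <- match.arg(preset)
  reps <- .presetReps(preset)
  if (is.null(config)) config <- searchConfig(preset = preset)
  ildReplicates <- ildReplicates %||% reps$ild
  irdReplicates <- irdReplicates %||% reps$ird
  nResamples <- nResamples %||% reps$resamples
  if (!is.null(nexus)) {
    cm <- readNexus(nexus)
    scheme <- buildPartitionScheme(cm, cranio, post)
  }
  if (is.character(ranges)) ranges <- readStratRanges(ranges)
  stopifnot(is(cm, "CharacterMatrix"), is(scheme, "PartitionScheme"))
  set.seed(seed)
  seeds <- .deriveSeeds(10L)
  errors <- character(0)
  t0 <- proc.time()[["elapsed"]]
  nTaxaOrig <- nTaxa(cm)

  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      errors[[length(errors) + 1L]] <<- paste0(label, ": ", conditionMessage(e))
      NULL
    })
  }

  cur <- NULL
  if (curate) {
    cur <- stage("curate", curateMatrix(cm, scheme))
    if (!is.null(cur)) { cm <- cur$matrix; scheme <- cur$scheme }
  }
  idx <- .partitionIndices(scheme)
  miss <- missingPercent(cm, scheme)

  tsC <- stage("search_cranio", heuristicSearch(cm, idx$cranio, config, seeds[1]))
  tsP <- stage("search_post", heuristicSearch(cm, idx$post, config, seeds[2]))
  ciC <- if (!is.null(tsC)) stage("ci_cranio", ensembleIndices(tsC, cm, idx$cranio))
  ciP <- if (!is.null(tsP)) stage("ci_post", ensembleIndices(tsP, cm, idx$post))

  ild <- stage("ild", ildTest(cm, scheme, config, ildReplicates, seed = seeds[3]))
  irdNM <- stage("ird_nnd_matching",
                 irdTest(cm, scheme, config, "matching", "NND",
                         irdReplicates, seed = seeds[4]))
  irdNR <- stage("ird_nnd_rf",
                 irdTest(cm, scheme, config, "RF", "NND",
                         irdReplicates, seed = seeds[5]))
  irdMM <- stage("ird_mr_matching",
                 irdTest(cm, scheme, config, "matching", "MR",
                         irdReplicates, seed = seeds[6]))
  irdMR <- stage("ird_mr_rf",
                 irdTest(cm, scheme, config, "RF", "MR",
                         irdReplicates, seed = seeds[7]))
  sim <- stage("partition_vs_entire",
               partitionVsEntireTest(cm, scheme, config, nResamples,
                                     seed = seeds[8]))
  strat <- NULL
  if (!is.null(ranges) && !is.null(tsC) && !is.null(tsP)) {
    strat <- stage("stratigraphy", list(
      cranio = stratCongruence(tsC, ranges, outgroup, reps$gerPerms, seeds[9]),
      post = stratCongruence(tsP, ranges, outgroup, reps$gerPerms, seeds[10])))
  }

  pv <- function(x) if (is.null(x)) NA_real_ else pValue(x)
  row <- data.frame(
    ref = "simulated", ref_no = NA_integer_, clade = NA_character_,
    n_cranio_chars = length(idx$cranio), n_post_chars = length(idx$post),
    n_taxa = nTaxa(cm), n_taxa_removed = nTaxaOrig - nTaxa(cm),
    p_ild = pv(ild), p_ird_nnd_rf = pv(irdNR), p_ird_mr_rf = pv(irdMR),
    p_ird_nnd_matching = pv(irdNM), p_ird_mr_matching = pv(irdMM),
    missing_cranio_pct = miss[["cranio"]], missing_post_pct = miss[["post"]],
    missing_total_pct = miss[["total"]],
    ci_cranio = if (is.null(ciC)) NA_real_ else ciC@CI,
    ri_cranio = if (is.null(ciC)) NA_real_ else ciC@RI,
    ci_post = if (is.null(ciP)) NA_real_ else ciP@CI,
    ri_post = if (is.null(ciP)) NA_real_ else ciP@RI,
    winner = if (is.null(sim)) NA_character_ else sim@winner,
    winner_p = if (is.null(sim)) NA_real_ else sim@pPairedWilcoxon,
    seed = seed, runtime_s = proc.time()[["elapsed"]] - t0,
    stringsAsFactors = FALSE)

  list(row = row,
       details = list(curation = if (!is.null(cur)) cur$report,
                      treesCranio = tsC, treesPost = tsP,
                      indicesCranio = ciC, indicesPost = ciP,
                      ild = ild,
                      ird = list(nnd_matching = irdNM, nnd_rf = irdNR,
                                 mr_matching = irdMM, mr_rf = irdMR),
                      similarity = sim, stratigraphy = strat,
                      seeds = seeds, preset = preset),
       errors = errors)
}

#' Serialize a study row to JSON
#'
#' @param study result of [runStudy()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStudyRow <- function(study, path) {
  jsonlite::write_json(study$row, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
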