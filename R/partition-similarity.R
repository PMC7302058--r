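# The jackknife test of whether craniodental or postcranial characters
# yield trees closer to those from the entire matrix. Character numbers are
# equalized: with n the size of the smaller partition, each resample draws
# n characters from the larger partition (the smaller is used in full) and
# n characters from the entire matrix (n/2 from each partition, the odd
# extra character alternating sides), so every inferred tree set rests on
# exactly n characters.

#' Jackknife samples for one resampling round
#'
#' Draws the three character samples for resample \code{resampleIndex}
#' from the current RNG stream: the smaller partition in full, the larger
#' partition subsampled to the smaller's size \code{n}, and an
#' entire-matrix sample of \code{n} characters split evenly between the
#' partitions (when \code{n} is odd, the extra character comes from the
#' craniodental side on odd resample indices and the postcranial side on
#' even ones).
#'
#' @param scheme a \linkS4class{PartitionScheme}.
#' @param resampleIndex 1-based resample number (drives the alternation).
#' @return list of integer index vectors \code{cranio}, \code{post},
#'   \code{entire}.
#' @export
jackknifeResampleSets <- function(scheme, resampleIndex) {
  idx <- .partitionIndices(scheme)
  n <- min(length(idx$cranio), length(idx$post))
  if (n < 2L) stop("smaller partition must have at least 2 characters")
  sampleTo <- function(v, k) if (length(v) > k) sort(sample(v, k)) else v
  cr <- sampleTo(idx$cranio, n)
  po <- sampleTo(idx$post, n)
  half <- n %/% 2L
  extra <- n %% 2L
  nc <- half + if (extra && resampleIndex %% 2L == 1L) 1L else 0L
  np <- n - nc
  entire <- sort(c(sample(idx$cranio, nc), sample(idx$post, np)))
  list(cranio = cr, post = po, entire = entire)
}

#' Which partition yields trees closest to the entire matrix?
#'
#' For each of \code{nResamples} resampling rounds, heuristic searches are
#' run on the three jackknife samples (craniodental, postcranial,
#' entire-matrix) and the mean nearest-neighbour matching distances from
#' each partition's trees to the entire-matrix trees are recorded. The
#' winner is the side with the smaller mean distance across resamples
#' (medians are also reported). A paired Wilcoxon signed-rank test on the
#' resample pairs gives the headline p-value; the unpaired Mann-Whitney
#' test is reported alongside.
#'
#' @param cm a curated \linkS4class{CharacterMatrix}.
#' @param scheme a \linkS4class{PartitionScheme}.
#' @param config a \linkS4class{SearchConfig}.
#' @param nResamples resampling rounds (p-values are NA below 2).
#' @param seed master seed.
#' @return a \linkS4class{SimilarityResult}.
#' @export
partitionVsEntireTest <- function(cm, scheme, config = searchConfig(),
                                  nResamples = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- .deriveSeeds(nResamples)
  dC <- numeric(nResamples)
  dP <- numeric(nResamples)
  idx <- .partitionIndices(scheme)
  n <- min(length(idx$cranio), length(idx$post))
  for (r in seq_len(nResamples)) {
    set.seed(seeds[r])
    sets <- jackknifeResampleSets(scheme, r)
    sub <- .deriveSeeds(4L)
    tsC <- heuristicSearch(cm, sets$cranio, config, seed = sub[1])
    tsP <- heuristicSearch(cm, sets$post, config, seed = sub[2])
    tsE <- heuristicSearch(cm, sets$entire, config, seed = sub[3])
    dC[r] <- meanNND(tsC, tsE, metric = "matching", cap = config@nndTreeCap,
                     seed = sub[4])
    dP[r] <- meanNND(tsP, tsE, metric = "matching", cap = config@nndTreeCap,
                     seed = sub[4])
  }
  means <- c(cranio = mean(dC), post = mean(dP))
  medians <- c(cranio = median(dC), post = median(dP))
  winner <- if (means[["cranio"]] < means[["post"]]) "Cranio"
            else if (means[["post"]] < means[["cranio"]]) "Post" else "Tie"
  pw <- pm <- NA_real_
  if (nResamples >= 2L && any(dC != dP)) {
    pw <- suppressWarnings(wilcox.test(dC, dP, paired = TRUE,
                                       exact = FALSE)$p.value)
    pm <- suppressWarnings(wilcox.test(dC, dP, exact = FALSE)$p.value)
  }
  new("SimilarityResult",
      pairs = data.frame(resample = seq_len(nResamples),
                         d_cranio = dC, d_post = dP),
      n = as.integer(n), nResamples = as.integer(nResamples),
      means = means, medians = medians, winner = winner,
      pPairedWilcoxon = pw, pMannWhitney = pm,
      seed = as.integer(seed %||% NA_integer_))
}
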