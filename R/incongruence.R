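# ILD and IRD permutation tests between the craniodental and postcranial
# character partitions. Both tests compare an observed incongruence
# statistic with its distribution over random bipartitions of the pooled
# characters in the original proportions; p-values follow the add-one rule
# (1 + #{null >= observed}) / (R + 1), ties counting toward rejection.

.deriveSeeds <- function(n) sample.int(2147483646L, n)

.partitionIndices <- function(scheme) {
  list(cranio = which(scheme@labels == "craniodental"),
       post = which(scheme@labels == "postcranial"))
}

#' Incongruence length difference
#'
#' Extra parsimony steps required when two partitions are analysed
#' together rather than separately: \code{L_AB - (L_A + L_B)}. Non-negative
#' whenever all three lengths are optimal; a negative value (a sign of a
#' failed search) raises a warning.
#'
#' @param lAB optimal length of the combined matrix, in steps.
#' @param lA,lB optimal lengths of the two partitions analysed alone.
#' @return the ILD in steps.
#' @examples
#' ildStatistic(328, 172, 146)  # 10
#' @export
ildStatistic <- function(lAB, lA, lB) {
  out <- lAB - lA - lB
  if (any(out < 0))
    warning("negative ILD: one of the searches was not optimal")
  out
}

#' Random bipartition of a character set
#'
#' Uniform split of \code{chars} into disjoint sets of sizes
#' \code{sizeA} and \code{length(chars) - sizeA}, drawn without
#' replacement from the current RNG stream.
#'
#' @param chars integer vector of character indices.
#' @param sizeA size of the first set; must be in \code{1..length(chars)-1}.
#' @return list with integer vectors \code{A} and \code{B}.
#' @export
randomBipartition <- function(chars, sizeA) {
  if (sizeA < 1L || sizeA >= length(chars))
    stop("sizeA must leave both sides non-empty")
  a <- sort(sample(chars, sizeA))
  list(A = a, B = sort(setdiff(chars, a)))
}

.addOneP <- function(null, observed) (1 + sum(null >= observed)) / (length(null) + 1)

#' ILD permutation test
#'
#' Observed ILD from three heuristic searches (craniodental, postcranial,
#' combined); the null distribution re-searches \code{replicates} random
#' bipartitions of the pooled craniodental + postcranial characters in the
#' original proportions (characters labelled "other" never enter). The
#' combined-matrix length is shared by every replicate. Minimum attainable
#' p with 999 replicates is 0.001.
#'
#' @param cm a curated \linkS4class{CharacterMatrix}.
#' @param scheme a \linkS4class{PartitionScheme}.
#' @param config a \linkS4class{SearchConfig}.
#' @param replicates random bipartitions for the null.
#' @param seed master seed; per-search seeds are derived from it.
#' @return an \linkS4class{IncongruenceResult}.
#' @export
ildTest <- function(cm, scheme, config = searchConfig(), replicates = 999L,
                    seed = NULL) {
  idx <- .partitionIndices(scheme)
  if (!sum(.informativeFlags(cm, idx$cranio)) ||
      !sum(.informativeFlags(cm, idx$post)))
    stop("both partitions need at least one informative character")
  if (!is.null(seed)) set.seed(seed)
  # three independent seeds per replicate: bipartition draw and the two
  # searches (coupling them correlates addition order with set content)
  seeds <- .deriveSeeds(3L + 3L * replicates)
  pool <- c(idx$cranio, idx$post)
  # only lengths are needed: store a single tree and skip collapsing
  config <- searchConfig(nadd = config@nadd, hold = config@hold,
                         maxtrees = 1L, swapmax = config@swapmax,
                         nndTreeCap = config@nndTreeCap,
                         collapseZero = FALSE)
  lA <- score(heuristicSearch(cm, idx$cranio, config, seed = seeds[1]))
  lB <- score(heuristicSearch(cm, idx$post, config, seed = seeds[2]))
  lAB <- score(heuristicSearch(cm, pool, config, seed = seeds[3]))
  obs <- ildStatistic(lAB, lA, lB)
  null <- numeric(replicates)
  for (r in seq_len(replicates)) {
    s3 <- seeds[3L + 3L * r - (2:0)]
    set.seed(s3[1])
    bp <- randomBipartition(pool, length(idx$cranio))
    la <- score(heuristicSearch(cm, bp$A, config, seed = s3[2]))
    lb <- score(heuristicSearch(cm, bp$B, config, seed = s3[3]))
    null[r] <- lAB - la - lb
  }
  new("IncongruenceResult", method = "ILD", metric = "steps", mode = "",
      observed = as.numeric(obs), null = null, pValue = .addOneP(null, obs),
      replicates = as.integer(replicates),
      seed = as.integer(seed %||% NA_integer_),
      sizes = c(length(idx$cranio), length(idx$post)))
}

#' IRD incongruence statistic between two tree sets
#'
#' In NND mode, the symmetrized mean nearest-neighbour distance between
#' the sets (capped at \code{cap} trees per set); in MR mode, the distance
#' between the two majority-rule (plus compatible groupings) consensus
#' trees. For singleton tree sets both modes reduce to the plain pairwise
#' distance.
#'
#' @param tsA,tsB \linkS4class{TreeSet}s on a common leaf set.
#' @param metric \code{"matching"} or \code{"RF"}.
#' @param mode \code{"NND"} or \code{"MR"}.
#' @param cap tree cap per set for NND mode.
#' @param seed optional seed for NND subsampling.
#' @return the incongruence statistic.
#' @export
irdStatistic <- function(tsA, tsB, metric = c("matching", "RF"),
                         mode = c("NND", "MR"), cap = 1000L, seed = NULL) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (!length(.asTreeList(tsA)) || !length(.asTreeList(tsB)))
    stop("empty tree set")
  if (mode == "NND") {
    meanNND(tsA, tsB, metric = metric, cap = cap, seed = seed)
  } else {
    ca <- majorityRuleConsensus(tsA)
    cb <- majorityRuleConsensus(tsB)
    if (metric == "RF") rfDistance(ca, cb) else matchingDistance(ca, cb)
  }
}

#' IRD permutation test
#'
#' Like the ILD test but with a tree-to-tree distance as the incongruence
#' statistic: the observed value compares the optimal tree sets of the two
#' partitions; the null re-searches random bipartitions. Minimum
#' attainable p with 99 replicates is 0.01.
#'
#' @inheritParams ildTest
#' @param metric \code{"matching"} or \code{"RF"}.
#' @param mode \code{"NND"} (mean nearest-neighbour distances) or
#'   \code{"MR"} (distance between majority-rule-plus-compatible trees).
#' @return an \linkS4class{IncongruenceResult}.
#' @export
irdTest <- function(cm, scheme, config = searchConfig(),
                    metric = c("matching", "RF"), mode = c("NND", "MR"),
                    replicates = 99L, seed = NULL) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  idx <- .partitionIndices(scheme)
  if (!sum(.informativeFlags(cm, idx$cranio)) ||
      !sum(.informativeFlags(cm, idx$post)))
    stop("both partitions need at least one informative character")
  if (!is.null(seed)) set.seed(seed)
  seeds <- .deriveSeeds(3L + 4L * replicates)
  pool <- c(idx$cranio, idx$post)
  tsA <- heuristicSearch(cm, idx$cranio, config, seed = seeds[1])
  tsB <- heuristicSearch(cm, idx$post, config, seed = seeds[2])
  obs <- irdStatistic(tsA, tsB, metric, mode, cap = config@nndTreeCap,
                      seed = seeds[3])
  null <- numeric(replicates)
  for (r in seq_len(replicates)) {
    s4 <- seeds[3L + 4L * r - (3:0)]
    set.seed(s4[1])
    bp <- randomBipartition(pool, length(idx$cranio))
    ta <- heuristicSearch(cm, bp$A, config, seed = s4[2])
    tb <- heuristicSearch(cm, bp$B, config, seed = s4[3])
    null[r] <- irdStatistic(ta, tb, metric, mode, cap = config@nndTreeCap,
                            seed = s4[4])
  }
  new("IncongruenceResult", method = "IRD", metric = metric, mode = mode,
      observed = as.numeric(obs), null = null, pValue = .addOneP(null, obs),
      replicates = as.integer(replicates),
      seed = as.integer(seed %||% NA_integer_),
      sizes = c(length(idx$cranio), length(idx$post)))
}
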