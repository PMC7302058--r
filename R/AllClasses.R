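#' @import methods
#' @importFrom stats median rank cor pchisq wilcox.test binom.test lm resid
#'   rexp rgamma runif rbinom setNames complete.cases
#' @importFrom utils read.csv write.csv head combn
#' @useDynLib partcong, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Discrete morphological character matrix
#'
#' Taxa-by-characters container for categorical (cladistic) data. Each cell
#' is either observed (a non-empty set of integer state codes, a singleton
#' for a fixed score and a larger set for polymorphic/uncertain scores),
#' missing (\code{"?"}) or inapplicable (\code{"-"}). State sets are stored
#' as bitmasks (bit \code{k} set means state \code{k} is scored), so each
#' character may use at most 30 states. Missing and inapplicable cells are
#' stored distinctly -- the curation rules count both -- but are treated
#' identically (fully ambiguous) in parsimony scoring.
#'
#' @slot masks integer matrix (taxa x characters) of state-set bitmasks;
#'   0 for missing/inapplicable cells.
#' @slot special integer matrix of the same shape: 0 observed, 1 missing,
#'   2 inapplicable.
#' @slot alphabet integer vector, number of states available per character.
#' @slot charsets named list of integer index vectors (NEXUS CHARSETs).
#' @export
setClass("CharacterMatrix",
  representation(masks = "matrix", special = "matrix",
                 alphabet = "integer", charsets = "list"))

setValidity("CharacterMatrix", function(object) {
  m <- object@masks; s <- object@special
  if (!is.integer(m) || !is.integer(s)) return("masks/special must be integer matrices")
  if (!identical(dim(m), dim(s))) return("masks and special must have identical dimensions")
  if (is.null(rownames(m))) return("taxa (rownames) required")
  if (anyDuplicated(rownames(m))) return("duplicate taxon labels")
  if (length(object@alphabet) != ncol(m)) return("alphabet length must equal character count")
  if (any(object@alphabet < 1L) || any(object@alphabet > 30L))
    return("alphabet sizes must be in 1..30")
  if (!all(s %in% 0:2)) return("special codes must be 0 (observed), 1 (missing) or 2 (inapplicable)")
  if (any(s == 0L & m == 0L)) return("observed cells must have a non-empty state set")
  if (any(s != 0L & m != 0L)) return("missing/inapplicable cells must have empty state sets")
  full <- bitwShiftL(1L, object@alphabet) - 1L
  if (any(bitwAnd(m, rep(bitwNot(full), each = nrow(m))) != 0L))
    return("observed state codes exceed the character's alphabet")
  for (nm in names(object@charsets)) {
    cs <- object@charsets[[nm]]
    if (any(cs < 1L) || any(cs > ncol(m))) return(sprintf("charset '%s' out of range", nm))
  }
  TRUE
})

#' Character partition scheme
#'
#' Assigns every character of a matrix to exactly one of the labels
#' \code{craniodental}, \code{postcranial} or \code{other}. Characters
#' labelled \code{other} take no part in any incongruence test.
#'
#' @slot labels factor of length = number of characters with levels
#'   \code{craniodental}, \code{postcranial}, \code{other}.
#' @export
setClass("PartitionScheme", representation(labels = "factor"))

setValidity("PartitionScheme", function(object) {
  if (!identical(levels(object@labels), c("craniodental", "postcranial", "other")))
    return("labels must have levels craniodental, postcranial, other")
  if (anyNA(object@labels)) return("every character must be labelled")
  TRUE
})

#' Heuristic parsimony search settings
#'
#' Mirrors the classic PAUP*-style search: random taxon-addition sequences,
#' a fixed number of trees held at each addition step, TBR branch swapping,
#' and caps on the number of equally optimal trees stored and on the number
#' of trees entering nearest-neighbour distance computations.
#'
#' @slot nadd number of random addition sequences.
#' @slot hold trees retained at each stepwise-addition step.
#' @slot maxtrees cap on stored equally parsimonious trees.
#' @slot swapmax cap on how many stored equal-best trees are themselves
#'   TBR-swapped per addition sequence (plateau control).
#' @slot nndTreeCap cap on trees per set in nearest-neighbour distances.
#' @slot collapseZero collapse branches of minimum length zero.
#' @export
setClass("SearchConfig",
  representation(nadd = "integer", hold = "integer", maxtrees = "integer",
                 swapmax = "integer", nndTreeCap = "integer",
                 collapseZero = "logical"))

setValidity("SearchConfig", function(object) {
  if (object@nadd < 1L || object@hold < 1L || object@maxtrees < 1L ||
      object@nndTreeCap < 1L || object@swapmax < 1L)
    return("all search counts must be >= 1")
  TRUE
})

#' Set of equally parsimonious trees
#'
#' @slot trees list of unrooted \code{phylo} objects sharing one leaf set.
#' @slot score optimal parsimony length in steps.
#' @slot leafLabels common leaf labels.
#' @slot metadata list of search provenance (seed, config, characters used).
#' @export
setClass("TreeSet",
  representation(trees = "list", score = "numeric",
                 leafLabels = "character", metadata = "list"))

#' Result of an ILD or IRD permutation test
#'
#' @slot method "ILD" or "IRD".
#' @slot metric "steps", "RF" or "matching".
#' @slot mode "NND" or "MR" (majority-rule consensus) for IRD; "" for ILD.
#' @slot observed observed incongruence statistic.
#' @slot null permutation null values (length = replicates).
#' @slot pValue add-one permutation p-value.
#' @slot replicates number of random bipartitions.
#' @slot seed master seed used.
#' @slot sizes character counts of the two partitions.
#' @export
setClass("IncongruenceResult",
  representation(method = "character", metric = "character", mode = "character",
                 observed = "numeric", null = "numeric", pValue = "numeric",
                 replicates = "integer", seed = "integer", sizes = "integer"))

setValidity("IncongruenceResult", function(object) {
  if (length(object@null) != object@replicates) return("null length must equal replicates")
  if (object@pValue <= 0 || object@pValue > 1) return("p-value must lie in (0, 1]")
  TRUE
})

#' Result of the jackknife partition-versus-entire-matrix test
#'
#' @slot pairs data.frame with one row per resample: columns
#'   \code{d_cranio} and \code{d_post}, the mean nearest-neighbour matching
#'   distances from the partition samples to the entire-matrix sample.
#' @slot n jackknife sample size (smaller partition's character count).
#' @slot nResamples number of resamples.
#' @slot means,medians named numeric summaries per side.
#' @slot winner "Cranio" or "Post" (side with smaller mean distance).
#' @slot pPairedWilcoxon,pMannWhitney test p-values (NA when undefined).
#' @slot seed master seed.
#' @export
setClass("SimilarityResult",
  representation(pairs = "data.frame", n = "integer", nResamples = "integer",
                 means = "numeric", medians = "numeric", winner = "character",
                 pPairedWilcoxon = "numeric", pMannWhitney = "numeric",
                 seed = "integer"))

#' Stratigraphic congruence summary for a tree set
#'
#' @slot perTree data.frame with one row per tree: MIG, Gmin, Gmax, GER,
#'   MSM, SCI, GERstar.
#' @slot means column means across trees.
#' @slot permutations number of random age reassignments behind GER*.
#' @slot seed seed used for the permutations.
#' @export
setClass("StratResult",
  representation(perTree = "data.frame", means = "numeric",
                 permutations = "integer", seed = "integer"))

#' Per-character parsimony score report with ensemble indices
#'
#' @slot perChar data.frame with per-character observed steps \code{s},
#'   minimum steps \code{m} and star-tree maximum \code{g}.
#' @slot S,M,G column totals.
#' @slot CI ensemble consistency index M/S.
#' @slot RI ensemble retention index (G-S)/(G-M); NA when G == M.
#' @export
setClass("ScoreReport",
  representation(perChar = "data.frame", S = "numeric", M = "numeric",
                 G = "numeric", CI = "numeric", RI = "numeric"))

#' Record of dataset curation
#'
#' @slot removedTaxa data.frame: taxon, missing fraction in each analysis
#'   partition (missing + inapplicable cells over partition characters).
#' @slot removedCharacters data.frame: character index, id and reason.
#' @slot threshold missing-data threshold applied.
#' @export
setClass("CurationReport",
  representation(removedTaxa = "data.frame", removedCharacters = "data.frame",
                 threshold = "numeric"))
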