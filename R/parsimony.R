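# Maximum-parsimony scoring and heuristic search. The numerical engine
# (bit-parallel Fitch/Hartigan scoring, stepwise addition with TBR branch
# swapping, zero-length-branch collapse) lives in src/parsimony.cpp; these
# wrappers handle the phylo <-> edge-list conversions and bookkeeping.

#' Heuristic search settings
#'
#' Builds a \linkS4class{SearchConfig}. The \code{"paper"} preset follows the
#' classic settings for desk-sized morphological matrices (25 random
#' addition sequences, 10 trees held per step); the \code{"desk"} preset is
#' a reduced-effort variant (5 additions, tree caps of 100) for simulation
#' studies and test suites.
#'
#' @param nadd random addition sequences.
#' @param hold trees held at each stepwise-addition step.
#' @param maxtrees cap on stored equally parsimonious trees.
#' @param swapmax cap on the number of stored equal-best trees that are
#'   themselves TBR-swapped within an addition sequence; bounds time spent
#'   traversing large plateaus of equally parsimonious trees.
#' @param nndTreeCap cap on trees per set entering nearest-neighbour
#'   distance calculations.
#' @param collapseZero collapse branches whose minimum length over all
#'   optimal reconstructions is zero, then drop duplicate topologies.
#' @param preset \code{"paper"} or \code{"desk"}; explicit arguments
#'   override preset values.
#' @return a \linkS4class{SearchConfig}.
#' @export
searchConfig <- function(nadd = NULL, hold = NULL, maxtrees = NULL,
                         swapmax = NULL, nndTreeCap = NULL,
                         collapseZero = TRUE, preset = c("paper", "desk")) {
  preset <- match.arg(preset)
  def <- if (preset == "paper")
    list(nadd = 25L, hold = 10L, maxtrees = 100000L, swapmax = 100L,
         nndTreeCap = 1000L)
  else
    list(nadd = 5L, hold = 10L, maxtrees = 100L, swapmax = 8L,
         nndTreeCap = 100L)
  new("SearchConfig",
      nadd = as.integer(nadd %||% def$nadd),
      hold = as.integer(hold %||% def$hold),
      maxtrees = as.integer(maxtrees %||% def$maxtrees),
      swapmax = as.integer(swapmax %||% def$swapmax),
      nndTreeCap = as.integer(nndTreeCap %||% def$nndTreeCap),
      collapseZero = isTRUE(collapseZero))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parsimony length of a tree
#'
#' Minimum number of unordered state changes summed over the selected
#' characters (Fitch optimization; Hartigan's generalization on
#' multifurcating trees). Missing and inapplicable cells carry the full
#' alphabet and never force a step; polymorphic cells enter as their state
#' set.
#'
#' @param tree a \code{phylo} tree whose leaves are taxa of \code{cm}.
#' @param cm a \linkS4class{CharacterMatrix}.
#' @param chars character selection (indices, ids or a charset name);
#'   default all characters.
#' @param perCharacter return the per-character step vector instead of the
#'   total.
#' @return total steps, or an integer vector when \code{perCharacter}.
#' @export
fitchLength <- function(tree, cm, chars = NULL, perCharacter = FALSE) {
  chars <- .resolveChars(cm, chars)
  if (!all(tree$tip.label %in% taxa(cm)))
    stop("tree has leaves without a matrix row")
  masks <- .masksForScoring(cm, chars, taxaOrder = tree$tip.label)
  edges <- .phyloToEdges(.unrootKeep(tree), tree$tip.label)
  steps <- .fitch_steps_cpp(edges, masks)
  if (perCharacter) steps else sum(steps)
}

#' Per-character step bounds
#'
#' Minimum conceivable steps \code{m} (distinct fixed observed states minus
#' one) and the star-tree maximum \code{g} (scored taxa minus the count of
#' the most frequent state), both computed on fixed singleton scores only.
#'
#' @param cm a \linkS4class{CharacterMatrix}.
#' @param char single character index.
#' @return named numeric vector \code{c(m = , g = )}.
#' @export
characterStepBounds <- function(cm, char) {
  char <- .resolveChars(cm, char)
  stopifnot(length(char) == 1L)
  col <- cm@masks[, char]
  obs <- col[cm@special[, char] == 0L]
  fixed <- obs[bitwAnd(obs, obs - 1L) == 0L]
  if (!length(fixed)) return(c(m = 0, g = 0))
  tab <- table(fixed)
  c(m = max(0L, length(tab) - 1L), g = length(fixed) - max(tab))
}

.starTree <- function(labels) {
  ape::read.tree(text = paste0("(", paste(labels, collapse = ","), ");"))
}

#' Heuristic maximum-parsimony search
#'
#' For each random taxon-addition sequence, stepwise addition holds the
#' \code{hold} best partial trees at every step (ties beyond the hold
#' broken by the seeded RNG); the resulting trees are then refined by TBR
#' branch swapping to a local optimum, pooling equally optimal topologies
#' across addition sequences up to \code{maxtrees}. Zero-minimum-length
#' branches are collapsed and duplicate topologies removed when
#' \code{collapseZero} is set. Deterministic given \code{seed}.
#'
#' @param cm a \linkS4class{CharacterMatrix} (at least 4 taxa).
#' @param chars character selection; default all characters.
#' @param config a \linkS4class{SearchConfig}.
#' @param seed integer seed for the addition sequences and tie-breaks.
#' @return a \linkS4class{TreeSet}.
#' @export
heuristicSearch <- function(cm, chars = NULL, config = searchConfig(),
                            seed = NULL) {
  chars <- .resolveChars(cm, chars)
  if (nTaxa(cm) < 4L) stop("heuristic search needs at least 4 taxa")
  if (nTaxa(cm) > 64L) stop("searches support at most 64 taxa")
  if (!is.null(seed)) set.seed(seed)
  nInf <- sum(.informativeFlags(cm, chars))
  if (nInf == 0L) {
    warning("no parsimony-informative characters: returning the star tree")
    star <- .starTree(taxa(cm))
    masks <- .masksForScoring(cm, chars)
    len <- sum(.fitch_steps_cpp(.phyloToEdges(star, taxa(cm)), masks))
    return(new("TreeSet", trees = list(star), score = len,
               leafLabels = taxa(cm),
               metadata = list(chars = chars, seed = seed, star = TRUE)))
  }
  masks <- .masksForScoring(cm, chars)
  res <- .heuristic_search_cpp(masks, config@nadd, config@hold,
                               config@maxtrees, config@swapmax,
                               config@collapseZero)
  phyl <- lapply(res$trees, .edgesToPhylo, refLabels = taxa(cm))
  new("TreeSet", trees = phyl, score = res$score, leafLabels = taxa(cm),
      metadata = list(chars = chars, seed = seed,
                      config = list(nadd = config@nadd, hold = config@hold,
                                    maxtrees = config@maxtrees)))
}

#' Collapse zero-minimum-length branches and drop duplicates
#'
#' Contracts every internal branch whose minimum length over all optimal
#' state reconstructions is zero (the PAUP* "amb-" convention, realized by
#' a contract-and-rescore test), then removes duplicate topologies. Tree
#' length is unchanged.
#'
#' @param ts a \linkS4class{TreeSet}.
#' @param cm the matrix the trees were inferred from.
#' @param chars the character selection used for inference.
#' @return a \linkS4class{TreeSet} with possibly fewer, possibly
#'   polytomous trees.
#' @export
collapseAndDedupe <- function(ts, cm, chars = NULL) {
  chars <- .resolveChars(cm, chars)
  masks <- .masksForScoring(cm, chars, taxaOrder = ts@leafLabels)
  seen <- character(0)
  out <- list()
  for (tr in ts@trees) {
    e <- .phyloToEdges(.unrootKeep(tr), ts@leafLabels)
    ce <- .collapse_zero_cpp(e, masks)
    key <- paste(sort(.tree_splits_cpp(ce, length(ts@leafLabels))),
                 collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- .edgesToPhylo(ce, ts@leafLabels)
  }
  new("TreeSet", trees = out, score = ts@score, leafLabels = ts@leafLabels,
      metadata = c(ts@metadata, list(collapsed = TRUE)))
}

#' Ensemble consistency and retention indices
#'
#' Per-character observed steps \code{s} on the optimal trees, minimum
#' steps \code{m} and star-tree maximum \code{g}, with ensemble totals
#' S, M, G and the homoplasy indices CI = M/S and RI = (G-S)/(G-M). By
#' default only parsimony-informative characters enter the totals;
#' \code{includeUninformative} adds the rest (the PAUP* default differs).
#'
#' @param ts a \linkS4class{TreeSet} of optimal trees.
#' @param cm the matrix searched.
#' @param chars the character selection used for inference.
#' @param includeUninformative include parsimony-uninformative characters.
#' @return a \linkS4class{ScoreReport}; RI is NA (flagged) when G = M.
#' @export
ensembleIndices <- function(ts, cm, chars = NULL,
                            includeUninformative = FALSE) {
  chars <- .resolveChars(cm, chars)
  if (!includeUninformative) chars <- chars[.informativeFlags(cm, chars)]
  if (!length(chars)) stop("no characters selected")
  masks <- .masksForScoring(cm, chars, taxaOrder = ts@leafLabels)
  e <- .phyloToEdges(.unrootKeep(ts@trees[[1]]), ts@leafLabels)
  s <- .fitch_steps_cpp(e, masks)
  bounds <- vapply(chars, function(j) characterStepBounds(cm, j), numeric(2))
  m <- bounds["m", ]
  g <- bounds["g", ]
  S <- sum(s); M <- sum(m); G <- sum(g)
  CI <- if (S > 0) M / S else 1
  RI <- if (G > M) (G - S) / (G - M) else NA_real_
  new("ScoreReport",
      perChar = data.frame(char = chars, s = s, m = m, g = g),
      S = S, M = M, G = G, CI = CI, RI = RI)
}
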