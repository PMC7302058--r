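# Split extraction, tree-to-tree and set-to-set distances, consensus and
# tree-shape statistics.

.asTreeList <- function(x) {
  if (is(x, "TreeSet")) x@trees
  else if (inherits(x, "phylo")) list(x)
  else if (is.list(x)) x
  else stop("expected a TreeSet, a phylo or a list of phylo")
}

#' Nontrivial splits of an unrooted tree
#'
#' One bipartition per internal edge, each returned as the sorted vector of
#' leaf labels on the side not containing the reference (alphabetically
#' first) leaf. Trees with fewer than 4 leaves have no nontrivial splits.
#'
#' @param tree a \code{phylo}.
#' @return list of character vectors.
#' @export
treeSplits <- function(tree) {
  labs <- sort(tree$tip.label)
  if (length(labs) < 4L) return(list())
  e <- .phyloToEdges(.unrootKeep(tree), labs)
  words <- .tree_splits_cpp(e, length(labs))
  lapply(words, function(w) {
    bits <- .splitWordToLogical(w, length(labs))
    sort(labs[bits])
  })
}

# decode the uint64 bit pattern smuggled through a double
.splitWordToLogical <- function(w, ntip) {
  raw8 <- writeBin(w, raw(), size = 8L, endian = "little")
  bits <- rawToBits(raw8)[seq_len(ntip)]
  as.logical(bits)
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of nontrivial splits present in one tree but
#' not the other.
#'
#' @param t1,t2 \code{phylo} trees on an identical leaf set.
#' @return non-negative integer.
#' @export
rfDistance <- function(t1, t2) {
  labs <- .commonLeafCheck(t1, t2)
  .rf_dist_cpp(.phyloToEdges(.unrootKeep(t1), labs),
               .phyloToEdges(.unrootKeep(t2), labs), length(labs))
}

#' Matching split distance
#'
#' Minimum-cost perfect matching between the two split sets, where the cost
#' of pairing splits A|B and C|D is min(|A xor C|, |A xor D|). When the
#' trees have unequal split counts (common for polytomous trees) the
#' smaller set is padded with dummy splits costing min(|A|, |B|) against a
#' real split A|B and nothing against another dummy. The assignment is
#' solved exactly by the Hungarian algorithm.
#'
#' @param t1,t2 \code{phylo} trees on an identical leaf set.
#' @return non-negative number; 0 exactly when the RF distance is 0.
#' @export
matchingDistance <- function(t1, t2) {
  labs <- .commonLeafCheck(t1, t2)
  .matching_dist_cpp(.phyloToEdges(.unrootKeep(t1), labs),
                     .phyloToEdges(.unrootKeep(t2), labs), length(labs))
}

#' Mean nearest-neighbour distance between two tree sets
#'
#' For each tree in one set, the distance to the most similar tree in the
#' other set; these minima are averaged within each direction and the two
#' directional means averaged (set \code{symmetric = FALSE} for the
#' one-directional A-to-B variant). Sets larger than \code{cap} are
#' first subsampled uniformly at random.
#'
#' @param setA,setB \linkS4class{TreeSet}s (or lists of \code{phylo}).
#' @param metric \code{"matching"} or \code{"RF"}.
#' @param cap maximum trees per set entering the computation.
#' @param seed optional seed for the subsampling.
#' @param symmetric average both directions.
#' @return mean nearest-neighbour distance.
#' @export
meanNND <- function(setA, setB, metric = c("matching", "RF"), cap = 1000L,
                    seed = NULL, symmetric = TRUE) {
  metric <- match.arg(metric)
  ta <- .asTreeList(setA)
  tb <- .asTreeList(setB)
  if (!length(ta) || !length(tb)) stop("tree sets must be non-empty")
  labs <- .commonLeafCheck(ta[[1]], tb[[1]])
  if (!is.null(seed)) set.seed(seed)
  if (length(ta) > cap) ta <- ta[sample.int(length(ta), cap)]
  if (length(tb) > cap) tb <- tb[sample.int(length(tb), cap)]
  ea <- lapply(ta, function(t) .phyloToEdges(.unrootKeep(t), labs))
  eb <- lapply(tb, function(t) .phyloToEdges(.unrootKeep(t), labs))
  # duplicate topologies within a set do not affect the mean
  dedupe <- function(es) {
    keys <- vapply(es, function(e)
      paste(sort(.tree_splits_cpp(e, length(labs))), collapse = "|"), "")
    es[!duplicated(keys)]
  }
  ea <- dedupe(ea)
  eb <- dedupe(eb)
  d <- .pair_dist_cpp(ea, eb, length(labs),
                      if (metric == "RF") 0L else 1L)
  ab <- mean(apply(d, 1, min))
  if (!symmetric) return(ab)
  ba <- mean(apply(d, 2, min))
  (ab + ba) / 2
}

.splitKeyMatrix <- function(treeList, labs) {
  # logical matrix of distinct splits x frequency across trees
  keys <- list()
  counts <- integer(0)
  ntip <- length(labs)
  for (tr in treeList) {
    e <- .phyloToEdges(.unrootKeep(tr), labs)
    words <- .tree_splits_cpp(e, ntip)
    ks <- vapply(words, function(w)
      paste(as.integer(.splitWordToLogical(w, ntip)), collapse = ""), "")
    for (k in unique(ks)) {
      if (is.null(keys[[k]])) { keys[[k]] <- TRUE; counts[k] <- 0L }
      counts[k] <- counts[k] + 1L
    }
  }
  counts
}

.splitsCompatible <- function(a, b) {
  # splits as logical vectors over a common leaf order
  !(any(a & b) && any(a & !b) && any(!a & b) && any(!a & !b))
}

#' Majority-rule consensus (plus compatible groupings)
#'
#' Retains every split occurring in more than half of the trees; when
#' \code{plusCompatible} is set, the remaining splits are then added
#' greedily in descending frequency (ties broken by the lexicographic
#' canonical form) whenever compatible with all splits accepted so far.
#'
#' @param x a \linkS4class{TreeSet} or list of \code{phylo} on one leaf set.
#' @param plusCompatible add minority yet compatible groupings.
#' @return a \code{phylo} consensus tree (possibly polytomous).
#' @export
majorityRuleConsensus <- function(x, plusCompatible = TRUE) {
  tl <- .asTreeList(x)
  if (!length(tl)) stop("no trees supplied")
  labs <- sort(tl[[1]]$tip.label)
  counts <- .splitKeyMatrix(tl, labs)
  n <- length(tl)
  keys <- names(counts)
  freq <- as.integer(counts)
  ord <- order(-freq, keys)
  accepted <- list()
  for (i in ord) {
    v <- as.logical(as.integer(strsplit(keys[i], "")[[1]]))
    if (freq[i] * 2L > n) {
      accepted[[length(accepted) + 1L]] <- v
    } else if (plusCompatible) {
      ok <- all(vapply(accepted, .splitsCompatible, logical(1), b = v))
      if (ok) accepted[[length(accepted) + 1L]] <- v
    }
  }
  .treeFromClades(accepted, labs)
}

.treeFromClades <- function(clades, labs) {
  # clades: logical vectors over labs, none containing labs[1]; mutually
  # compatible, hence nested or disjoint -> build the rooted nesting
  sizes <- vapply(clades, sum, 0L)
  ord <- order(-sizes)
  clades <- clades[ord]
  build <- function(members, cl) {
    # cl: clades strictly inside `members`
    if (length(cl)) {
      tops <- which(vapply(seq_along(cl), function(i) {
        !any(vapply(seq_along(cl), function(j)
          j != i && all(cl[[i]] <= cl[[j]]) && sum(cl[[j]]) > sum(cl[[i]]),
          logical(1)))
      }, logical(1)))
    } else tops <- integer(0)
    parts <- character(0)
    covered <- rep(FALSE, length(labs))
    for (i in tops) {
      inner <- Filter(function(cj) all(cj <= cl[[i]]) && sum(cj) < sum(cl[[i]]),
                      cl)
      parts <- c(parts, build(cl[[i]], inner))
      covered <- covered | cl[[i]]
    }
    singles <- which(members & !covered)
    parts <- c(parts, labs[singles])
    paste0("(", paste(parts, collapse = ","), ")")
  }
  all_ <- rep(TRUE, length(labs))
  nwk <- paste0(build(all_, clades), ";")
  ape::read.tree(text = nwk)
}

#' Tree balance and resolution
#'
#' Colless's imbalance index (sum over bifurcating internal nodes of the
#' absolute difference in descendant leaf counts) and percentage resolution
#' (100 x internal nodes / (terminals - 1)) of the rooted tree. Supply
#' \code{rootOn} to root an unrooted tree on the pendant edge of that
#' taxon; rooted input is used as is.
#'
#' @param tree a \code{phylo}.
#' @param rootOn optional outgroup taxon label.
#' @return named numeric vector \code{c(colless = , resolution = )}.
#' @export
treeShapeStats <- function(tree, rootOn = NULL) {
  if (!is.null(rootOn)) {
    if (!rootOn %in% tree$tip.label) stop("root taxon absent from the tree")
    tree <- ape::root(tree, outgroup = rootOn, resolve.root = TRUE)
  }
  # with rootOn = NULL the basal node of the phylo is taken as the root
  # (a basal polytomy is a legitimate rooted star)
  ntip <- length(tree$tip.label)
  e <- tree$edge
  # descendant leaf counts per node
  cnt <- c(rep(1L, ntip), rep(0L, tree$Nnode))
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(eo))) cnt[eo[r, 1]] <- cnt[eo[r, 1]] + cnt[eo[r, 2]]
  colless <- 0L
  for (node in unique(e[, 1])) {
    kids <- e[e[, 1] == node, 2]
    if (length(kids) == 2L) colless <- colless + abs(cnt[kids[1]] - cnt[kids[2]])
  }
  c(colless = colless, resolution = 100 * tree$Nnode / (ntip - 1))
}
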