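# Stratigraphic congruence: minimum implied gap (ghost lineage total) and
# the GER, GER*, MSM* and SCI indices for rooted trees given taxon
# first-appearance ages (FADs, time before present: larger = older).

.checkRanges <- function(ranges) {
  if (!all(c("taxon", "fad") %in% names(ranges)))
    stop("ranges need columns 'taxon' and 'fad'")
  if (anyDuplicated(ranges$taxon)) stop("duplicate taxa in ranges")
  if ("lad" %in% names(ranges) &&
      any(!is.na(ranges$lad) & ranges$fad < ranges$lad))
    stop("FAD must be at least LAD for every taxon")
  invisible(ranges)
}

#' Read a stratigraphic range table
#'
#' CSV with columns \code{taxon}, \code{fad} and optionally \code{lad}
#' (ages in consistent units, larger = older).
#'
#' @param path CSV file path.
#' @return a validated data.frame.
#' @export
readStratRanges <- function(path) {
  .checkRanges(read.csv(path, stringsAsFactors = FALSE))
}

.rootedTree <- function(tree, rootOn) {
  if (!is.null(rootOn)) {
    if (!rootOn %in% tree$tip.label) stop("root taxon absent from the tree")
    tree <- ape::root(tree, outgroup = rootOn, resolve.root = TRUE)
  } else if (!ape::is.rooted(tree)) {
    stop("tree is unrooted: supply rootOn")
  }
  tree
}

.migFromAges <- function(postEdge, ntip, nnode, tipAges) {
  # node age = oldest descendant FAD; MIG = sum of positive parent-child
  # age drops over all edges
  age <- c(tipAges, rep(-Inf, nnode))
  for (r in seq_len(nrow(postEdge)))
    age[postEdge[r, 1]] <- max(age[postEdge[r, 1]], age[postEdge[r, 2]])
  sum(pmax(0, age[postEdge[, 1]] - age[postEdge[, 2]]))
}

#' Minimum implied gap (MIG)
#'
#' Total ghost-lineage duration the rooted tree forces given the FADs:
#' each internal node is dated by its oldest descendant FAD and the
#' positive age drops along every branch are summed.
#'
#' @param tree a \code{phylo}; rooted, or rootable via \code{rootOn}.
#' @param ranges data.frame with \code{taxon} and \code{fad} for every leaf.
#' @param rootOn optional outgroup taxon for rooting.
#' @return MIG in age units.
#' @export
mig <- function(tree, ranges, rootOn = NULL) {
  .checkRanges(ranges)
  tree <- .rootedTree(tree, rootOn)
  fad <- ranges$fad[match(tree$tip.label, ranges$taxon)]
  if (anyNA(fad)) stop("missing FAD for: ",
    paste(tree$tip.label[is.na(fad)], collapse = ", "))
  pe <- ape::reorder.phylo(tree, "postorder")$edge
  .migFromAges(pe, length(tree$tip.label), tree$Nnode, fad)
}

#' Best- and worst-case implied gaps
#'
#' With ages sorted oldest first (t1 >= t2 >= ... >= tn), the minimum
#' possible MIG over all topologies is \code{Gmin = t1 - tn} and the
#' maximum is \code{Gmax = sum(t1 - ti, i >= 2)}.
#'
#' @param ranges range table, or a numeric vector of ages (>= 3 taxa).
#' @return named numeric vector \code{c(Gmin = , Gmax = )}.
#' @export
stratBaselines <- function(ranges) {
  ages <- if (is.numeric(ranges)) ranges else .checkRanges(ranges)$fad
  if (length(ages) < 3L) stop("need at least 3 dated taxa")
  c(Gmin = max(ages) - min(ages), Gmax = sum(max(ages) - ages))
}

#' Stratigraphic congruence indices
#'
#' GER = 1 - (MIG - Gmin) / (Gmax - Gmin) (NA when Gmax = Gmin);
#' MSM* = Gmin / MIG (1 when both are 0); SCI = the fraction of non-root
#' internal nodes whose clade's oldest FAD is no older than the oldest FAD
#' of its sister lineage(s). At a polytomy each child clade is compared
#' against the oldest of its siblings.
#'
#' @inheritParams mig
#' @return named numeric vector \code{c(GER = , MSM = , SCI = )}.
#' @export
stratIndices <- function(tree, ranges, rootOn = NULL) {
  .checkRanges(ranges)
  tree <- .rootedTree(tree, rootOn)
  fad <- ranges$fad[match(tree$tip.label, ranges$taxon)]
  ntip <- length(tree$tip.label)
  pe <- ape::reorder.phylo(tree, "postorder")$edge
  m <- .migFromAges(pe, ntip, tree$Nnode, fad)
  bl <- stratBaselines(fad)
  ger <- if (bl[["Gmax"]] > bl[["Gmin"]])
    1 - (m - bl[["Gmin"]]) / (bl[["Gmax"]] - bl[["Gmin"]]) else NA_real_
  msm <- if (m > 0) bl[["Gmin"]] / m else 1
  # SCI on node ages (oldest descendant FAD per node)
  age <- c(fad, rep(-Inf, tree$Nnode))
  for (r in seq_len(nrow(pe))) age[pe[r, 1]] <- max(age[pe[r, 1]], age[pe[r, 2]])
  e <- tree$edge
  root <- setdiff(e[, 1], e[, 2])
  internals <- setdiff(unique(e[, 1]), root)
  consistent <- vapply(internals, function(v) {
    par <- e[e[, 2] == v, 1]
    sibs <- setdiff(e[e[, 1] == par, 2], v)
    age[v] <= max(age[sibs])
  }, logical(1))
  sci <- if (length(internals)) mean(consistent) else NA_real_
  c(GER = unname(ger), MSM = unname(msm), SCI = sci)
}

#' Permutation-calibrated gap excess ratio (GER*)
#'
#' FADs are randomly reassigned to the leaves \code{permutations} times and
#' MIG recomputed for each reassignment; GER* is the proportion of permuted
#' MIGs at least as large as the observed MIG (ties count), so larger
#' values mean better-than-chance congruence. Invariant to affine
#' rescaling of the ages.
#'
#' @inheritParams mig
#' @param permutations random age reassignments.
#' @param seed optional seed.
#' @return GER* in \code{[0, 1]}.
#' @export
gerStar <- function(tree, ranges, rootOn = NULL, permutations = 10000L,
                    seed = NULL) {
  .checkRanges(ranges)
  tree <- .rootedTree(tree, rootOn)
  fad <- ranges$fad[match(tree$tip.label, ranges$taxon)]
  ntip <- length(tree$tip.label)
  pe <- ape::reorder.phylo(tree, "postorder")$edge
  obs <- .migFromAges(pe, ntip, tree$Nnode, fad)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(permutations), function(i)
    .migFromAges(pe, ntip, tree$Nnode, sample(fad)), 0)
  mean(perm >= obs)
}

#' Stratigraphic congruence of a tree set
#'
#' Computes MIG, the baselines and all four indices for every tree and
#' reports per-tree values together with their means across the set
#' (the per-dataset summary convention: means across all most
#' parsimonious trees).
#'
#' @param ts a \linkS4class{TreeSet} or list of \code{phylo}.
#' @param ranges range table covering all leaves.
#' @param rootOn outgroup taxon used to root every tree.
#' @param permutations reassignments behind GER*.
#' @param seed master seed.
#' @return a \linkS4class{StratResult}.
#' @export
stratCongruence <- function(ts, ranges, rootOn = NULL,
                            permutations = 10000L, seed = NULL) {
  tl <- .asTreeList(ts)
  if (!is.null(seed)) set.seed(seed)
  seeds <- .deriveSeeds(length(tl))
  rows <- lapply(seq_along(tl), function(i) {
    tr <- tl[[i]]
    m <- mig(tr, ranges, rootOn)
    fad <- ranges$fad[match(tr$tip.label, ranges$taxon)]
    bl <- stratBaselines(fad)
    ix <- stratIndices(tr, ranges, rootOn)
    gs <- gerStar(tr, ranges, rootOn, permutations, seed = seeds[i])
    data.frame(MIG = m, Gmin = bl[["Gmin"]], Gmax = bl[["Gmax"]],
               GER = ix[["GER"]], MSM = ix[["MSM"]], SCI = ix[["SCI"]],
               GERstar = gs)
  })
  perTree <- do.call(rbind, rows)
  new("StratResult", perTree = perTree, means = colMeans(perTree),
      permutations = as.integer(permutations),
      seed = as.integer(seed %||% NA_integer_))
}
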