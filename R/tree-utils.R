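# Conversions between ape's phylo representation and the 0-based edge-list
# encoding used by the C++ engines (tips 0..n-1 in a fixed reference label
# order, internal nodes >= n).

.phyloToEdges <- function(phy, refLabels) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' tree")
  idx <- match(phy$tip.label, refLabels)
  if (anyNA(idx)) stop("tree has leaves absent from the reference label set: ",
                       paste(phy$tip.label[is.na(idx)], collapse = ", "))
  ntip <- length(refLabels)
  e <- phy$edge
  nn <- max(e)
  map <- integer(nn)
  map[seq_along(phy$tip.label)] <- idx - 1L
  internal <- sort(unique(e[e > length(phy$tip.label)]))
  map[internal] <- ntip + seq_along(internal) - 1L
  cbind(map[e[, 1]], map[e[, 2]])
}

.edgesToPhylo <- function(edges, refLabels) {
  ntip <- length(refLabels)
  present <- sort(unique(as.integer(edges)))
  tipsPresent <- present[present < ntip]
  adj <- split(
    c(edges[, 2], edges[, 1]),
    factor(c(edges[, 1], edges[, 2]), levels = present)
  )
  ids <- as.integer(names(adj))
  deg <- lengths(adj)
  root <- ids[which(ids >= ntip)[1]]
  if (is.na(root)) root <- ids[1]
  # preorder DFS
  nTipOut <- length(tipsPresent)
  apeId <- integer(max(present) + 1L)
  tipCounter <- 0L
  nodeCounter <- nTipOut
  parent <- integer(0); child <- integer(0)
  stack <- list(c(root, -1L))
  order <- list()
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top[1]; p <- top[2]
    order[[length(order) + 1L]] <- c(v, p)
    for (w in adj[[as.character(v)]]) {
      if (w != p) stack[[length(stack) + 1L]] <- c(w, v)
    }
  }
  tipLab <- character(nTipOut)
  for (vp in order) {
    v <- vp[1]
    if (v < ntip) {
      tipCounter <- tipCounter + 1L
      apeId[v + 1L] <- tipCounter
      tipLab[tipCounter] <- refLabels[v + 1L]
    } else {
      nodeCounter <- nodeCounter + 1L
      apeId[v + 1L] <- nodeCounter
    }
  }
  for (vp in order) {
    if (vp[2] >= 0L) {
      parent <- c(parent, apeId[vp[2] + 1L])
      child <- c(child, apeId[vp[1] + 1L])
    }
  }
  # preorder above pushes children in stack order; reorder rows parent-first
  em <- cbind(parent, child)
  phy <- structure(list(edge = em, tip.label = tipLab,
                        Nnode = nodeCounter - nTipOut),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

.commonLeafCheck <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share an identical leaf set")
  invisible(sort(t1$tip.label))
}

.unrootKeep <- function(phy) {
  if (ape::is.rooted(phy)) ape::unroot(phy) else phy
}

# integer masks ready for the C++ scorer: rows follow `taxaOrder`, columns
# `chars`; missing/inapplicable cells expanded to the full-alphabet mask
.masksForScoring <- function(cm, chars, taxaOrder = taxa(cm)) {
  rows <- match(taxaOrder, taxa(cm))
  if (anyNA(rows)) stop("unknown taxa requested")
  m <- cm@masks[rows, chars, drop = FALSE]
  s <- cm@special[rows, chars, drop = FALSE]
  full <- bitwShiftL(1L, cm@alphabet[chars]) - 1L
  fullM <- matrix(rep(full, each = nrow(m)), nrow = nrow(m))
  m[s != 0L] <- fullM[s != 0L]
  storage.mode(m) <- "integer"
  m
}

.resolveChars <- function(cm, chars) {
  if (is.null(chars)) return(seq_len(nCharacters(cm)))
  if (is.character(chars) && length(chars) == 1L && chars %in% names(charsets(cm)))
    return(charsets(cm)[[chars]])
  if (is.character(chars)) {
    idx <- match(chars, characterIds(cm))
    if (anyNA(idx)) stop("unknown character ids")
    return(idx)
  }
  chars <- as.integer(chars)
  if (any(chars < 1L) || any(chars > nCharacters(cm)))
    stop("character indices out of range")
  chars
}
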