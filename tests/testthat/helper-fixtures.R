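# Shared fixture builders and independent oracles used across the suite.

# i.i.d. random matrix with a craniodental/postcranial charset split
randomMatrix <- function(nTaxa, nChar, states = 0:1, missingRate = 0,
                         split = nChar %/% 2) {
  tok <- matrix(as.character(sample(states, nTaxa * nChar, TRUE)),
                nTaxa, nChar)
  if (missingRate > 0) tok[runif(nTaxa * nChar) < missingRate] <- "?"
  rownames(tok) <- paste0("t", seq_len(nTaxa))
  characterMatrix(tok, charsets = list(cranio = seq_len(split),
                                       post = (split + 1):nChar))
}

# all permutations of a vector (factorial enumeration oracle)
allPerms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in allPerms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# brute-force matching split distance: exhaustive minimum over all
# assignments of one split set (plus dummies) to the other
matchingDistBrute <- function(t1, t2) {
  labs <- sort(t1$tip.label)
  ntip <- length(labs)
  asLogical <- function(tr) lapply(treeSplits(tr), function(s) labs %in% s)
  s1 <- asLogical(t1)
  s2 <- asLogical(t2)
  if (length(s1) < length(s2)) { tmp <- s1; s1 <- s2; s2 <- tmp }
  cost <- function(a, b) {
    if (is.null(b)) { p <- sum(a); return(min(p, ntip - p)) }
    h <- sum(xor(a, b))
    min(h, ntip - h)
  }
  best <- Inf
  for (p in allPerms(seq_along(s1))) {
    tot <- 0
    for (j in seq_along(s1)) {
      b <- if (j <= length(s2)) s2[[j]] else NULL
      tot <- tot + cost(s1[[p[j]]], b)
    }
    best <- min(best, tot)
  }
  best
}

# noise-diluted two-partition matrix: craniodental characters all carry
# tree signal; half the postcranial characters are i.i.d. noise, so the
# craniodental side holds twice the signal-bearing characters
doubledSignalMatrix <- function(seed) {
  set.seed(seed)
  sim <- simulateMatrix(simConfig(
    nTaxa = 20, nCranio = 100, nPost = 50, sprSeparation = 5,
    meanChanges = c(1.5, 1.5), gammaShape = 8,
    missingCranio = 0, missingPost = 0, seed = seed))
  tok <- partcong:::.cellTokens(sim$matrix)
  noise <- matrix(as.character(sample(0:1, 20 * 50, TRUE)), 20, 50)
  tok2 <- cbind(tok, noise)
  colnames(tok2) <- sprintf("c%d", seq_len(ncol(tok2)))
  cm <- characterMatrix(tok2, charsets = list(cranio = 1:100, post = 101:200))
  list(matrix = cm, scheme = buildPartitionScheme(cm, "cranio", "post"))
}
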