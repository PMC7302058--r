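test_that("Fitch lengths match hand-worked examples", {
  cm <- characterMatrix(rbind(A = "0", B = "0", C = "1", D = "1"))
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(fitchLength(t1, cm), 1L)
  expect_equal(fitchLength(t2, cm), 2L)
  allMissing <- characterMatrix(rbind(A = "?", B = "?", C = "?", D = "?"))
  expect_equal(fitchLength(t1, allMissing), 0L)
  # polymorphic cells are satisfiable at no cost
  cmPoly <- characterMatrix(rbind(A = "{01}", B = "0", C = "1", D = "1"))
  expect_equal(fitchLength(t2, cmPoly), 1L)
  expect_error(fitchLength(ape::read.tree(text = "((A,B),(C,X));"), cm),
               "without a matrix row")
})

test_that("Fitch length agrees with an independent scorer on random matrices", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:9, 1)
    nc <- sample(4:12, 1)
    tok <- matrix(as.character(sample(0:2, n * nc, TRUE)), n, nc)
    tok[runif(n * nc) < 0.15] <- "?"
    rownames(tok) <- paste0("t", 1:n)
    cm <- characterMatrix(tok)
    tr <- ape::unroot(ape::rtree(n, tip.label = paste0("t", 1:n)))
    pd <- phangorn::phyDat(tok, type = "USER", levels = c("0", "1", "2"),
                           ambiguity = "?")
    expect_equal(fitchLength(tr, cm), phangorn::parsimony(tr, pd))
  }
})

test_that("Fitch length is invariant to leaf order and rerooting", {
  set.seed(7)
  cm <- randomMatrix(7, 10, missingRate = 0.2)
  tr <- ape::rtree(7, tip.label = paste0("t", 1:7))
  base <- fitchLength(tr, cm)
  expect_equal(fitchLength(ape::unroot(tr), cm), base)
  expect_equal(fitchLength(ape::root(ape::unroot(tr), outgroup = "t3",
                                     resolve.root = TRUE), cm), base)
  perm <- sample(7)
  cm2 <- characterMatrix(partcong:::.cellTokens(cm)[perm, , drop = FALSE])
  expect_equal(fitchLength(tr, cm2), base)
})

test_that("character step bounds follow the star-tree formulas", {
  expect_equal(characterStepBounds(
    characterMatrix(rbind(A = "0", B = "0", C = "1", D = "1")), 1),
    c(m = 1, g = 2))
  expect_equal(characterStepBounds(
    characterMatrix(rbind(A = "0", B = "0", C = "0", D = "0")), 1),
    c(m = 0, g = 0))
  expect_equal(characterStepBounds(
    characterMatrix(rbind(A = "0", B = "1", C = "2")), 1),
    c(m = 2, g = 2))
  # bounds bracket the realized steps on any tree: m <= s <= g
  set.seed(9)
  cm <- randomMatrix(8, 15, states = 0:2, missingRate = 0.2)
  tr <- ape::rtree(8, tip.label = paste0("t", 1:8))
  s <- fitchLength(tr, cm, perCharacter = TRUE)
  for (j in 1:15) {
    b <- characterStepBounds(cm, j)
    expect_lte(b[["m"]], s[j])
    expect_gte(b[["g"]], s[j])
  }
})

test_that("heuristic search recovers a strongly supported tree and is deterministic", {
  sim <- simulateMatrix(simConfig(nTaxa = 6, nCranio = 20, nPost = 20,
                                  meanChanges = c(0.6, 0.6), gammaShape = 8,
                                  missingCranio = 0, missingPost = 0,
                                  sprSeparation = 0, seed = 11))
  cfg <- searchConfig(preset = "desk")
  ts <- heuristicSearch(sim$matrix, NULL, cfg, seed = 3)
  expect_equal(length(ts), 1L)
  expect_equal(rfDistance(trees(ts)[[1]], sim$trees$cranio), 0)
  ts2 <- heuristicSearch(sim$matrix, NULL, cfg, seed = 3)
  expect_equal(score(ts2), score(ts))
  expect_identical(lapply(trees(ts2), ape::write.tree),
                   lapply(trees(ts), ape::write.tree))
  # local optimality: no user-supplied tree beats the search
  set.seed(5)
  for (i in 1:5) {
    rt <- ape::rtree(6, tip.label = paste0("t", 1:6))
    expect_gte(fitchLength(rt, sim$matrix), score(ts))
  }
})

test_that("searches with no informative characters return a star tree", {
  tok <- rbind(A = c("0", "0"), B = c("0", "0"), C = c("0", "1"),
               D = c("0", "0"))
  cm <- characterMatrix(tok)
  expect_warning(ts <- heuristicSearch(cm, NULL, searchConfig(preset = "desk"),
                                       seed = 1), "star tree")
  expect_equal(length(treeSplits(trees(ts)[[1]])), 0L)
})

test_that("collapse preserves length and merges duplicate topologies", {
  set.seed(31)
  for (i in 1:10) {
    cm <- randomMatrix(7, 12, missingRate = 0.25)
    ts <- heuristicSearch(cm, NULL,
                          searchConfig(preset = "desk", collapseZero = FALSE),
                          seed = i)
    cl <- collapseAndDedupe(ts, cm)
    expect_lte(length(cl), length(ts))
    for (tr in trees(cl)) expect_equal(fitchLength(tr, cm), score(ts))
  }
})

test_that("ensemble indices reproduce hand counts and are tree-invariant", {
  cm <- characterMatrix(rbind(A = c("0", "0"), B = c("0", "0"),
                              C = c("1", "1"), D = c("1", "1")))
  good <- ape::read.tree(text = "((A,B),(C,D));")
  bad <- ape::read.tree(text = "((A,C),(B,D));")
  tsGood <- new("TreeSet", trees = list(good), score = 2,
                leafLabels = c("A", "B", "C", "D"), metadata = list())
  tsBad <- new("TreeSet", trees = list(bad), score = 4,
               leafLabels = c("A", "B", "C", "D"), metadata = list())
  rGood <- ensembleIndices(tsGood, cm)
  expect_equal(rGood@S, 2); expect_equal(rGood@CI, 1); expect_equal(rGood@RI, 1)
  rBad <- ensembleIndices(tsBad, cm)
  expect_equal(rBad@CI, 0.5); expect_equal(rBad@RI, 0)
  # CI identical across all trees of a TreeSet
  set.seed(13)
  cmr <- randomMatrix(8, 20, missingRate = 0.3)
  ts <- heuristicSearch(cmr, NULL, searchConfig(preset = "desk"), seed = 2)
  cis <- vapply(seq_along(ts@trees), function(i) {
    one <- new("TreeSet", trees = ts@trees[i], score = ts@score,
               leafLabels = ts@leafLabels, metadata = list())
    ensembleIndices(one, cmr)@CI
  }, 0)
  expect_true(all(abs(cis - cis[1]) < 1e-12))
})
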