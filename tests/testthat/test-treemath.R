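test_that("split extraction reads bipartitions off internal edges", {
  tr <- ape::read.tree(text = "((A,B),C,(D,E));")
  sp <- treeSplits(tr)
  expect_equal(length(sp), 2L)
  key <- vapply(sp, paste, "", collapse = "")
  expect_setequal(key, c("CDE", "DE"))  # canonical side excludes leaf A
  expect_equal(length(treeSplits(ape::read.tree(text = "(A,B,C,D,E);"))), 0L)
  bin6 <- ape::rtree(6)
  expect_equal(length(treeSplits(bin6)), 3L)  # n - 3 for binary unrooted
})

test_that("RF distance matches examples and an independent implementation", {
  t1 <- ape::read.tree(text = "((A,B),C,(D,E));")
  t2 <- ape::read.tree(text = "((A,C),B,(D,E));")
  expect_equal(rfDistance(t1, t1), 0)
  expect_equal(rfDistance(t1, t2), 2)
  expect_error(rfDistance(t1, ape::read.tree(text = "((A,B),C,(D,X));")),
               "leaf set")
  set.seed(6)
  for (i in 1:15) {
    n <- sample(5:12, 1)
    a <- ape::unroot(ape::rtree(n, tip.label = paste0("x", 1:n)))
    b <- ape::unroot(ape::rtree(n, tip.label = paste0("x", 1:n)))
    expect_equal(rfDistance(a, b), as.numeric(phangorn::RF.dist(a, b)))
  }
})

test_that("matching distance solves the assignment exactly", {
  t1 <- ape::read.tree(text = "((A,B),C,(D,E));")
  t2 <- ape::read.tree(text = "((A,C),B,(D,E));")
  expect_equal(matchingDistance(t1, t1), 0)
  expect_equal(matchingDistance(t1, t2), 2)  # DE<->DE free, AB<->AC costs 2
  set.seed(5)
  for (i in 1:12) {
    n <- sample(5:8, 1)
    a <- ape::unroot(ape::rtree(n, tip.label = paste0("x", 1:n)))
    b <- ape::unroot(ape::rtree(n, tip.label = paste0("x", 1:n)))
    expect_equal(matchingDistance(a, b), matchingDistBrute(a, b))
  }
})

test_that("tree distances behave as metrics and agree on zero", {
  set.seed(8)
  for (i in 1:10) {
    n <- 7
    tr <- replicate(3, ape::unroot(ape::rtree(n, tip.label = paste0("x", 1:n))),
                    simplify = FALSE)
    for (f in c(rfDistance, matchingDistance)) {
      expect_equal(f(tr[[1]], tr[[2]]), f(tr[[2]], tr[[1]]))
      expect_lte(f(tr[[1]], tr[[3]]),
                 f(tr[[1]], tr[[2]]) + f(tr[[2]], tr[[3]]))
    }
    expect_equal(matchingDistance(tr[[1]], tr[[2]]) == 0,
                 rfDistance(tr[[1]], tr[[2]]) == 0)
  }
})

test_that("mean NND averages directional nearest-neighbour distances", {
  t1 <- ape::read.tree(text = "((A,B),C,(D,E));")
  t2 <- ape::read.tree(text = "((A,C),B,(D,E));")
  expect_equal(meanNND(list(t1, t2), list(t1, t2), metric = "RF"), 0)
  expect_equal(meanNND(list(t1), list(t2), metric = "RF"), 2)
  # A = {t1, t2}, B = {t1}: ((0+2)/2 + 0)/2
  expect_equal(meanNND(list(t1, t2), list(t1), metric = "RF"), 0.5)
  expect_equal(meanNND(list(t1, t2), list(t1), metric = "RF",
                       symmetric = FALSE), 1)
  # invariant to duplicating trees within a set
  expect_equal(meanNND(list(t1, t1, t2), list(t1), metric = "RF"), 0.5)
  expect_error(meanNND(list(), list(t1)), "non-empty")
})

test_that("majority-rule consensus keeps >50% splits and can add compatible ones", {
  trs <- ape::read.tree(text = c("((A,B),(C,(D,E)));",
                                 "((A,B),(D,(C,E)));",
                                 "((A,C),(B,(D,E)));"))
  key <- function(tr) vapply(treeSplits(tr), paste, "", collapse = "")
  mr <- majorityRuleConsensus(trs, plusCompatible = FALSE)
  expect_setequal(key(mr), c("CDE", "DE"))
  # identical trees: consensus is that tree
  same <- list(trs[[1]], trs[[1]], trs[[1]])
  expect_setequal(key(majorityRuleConsensus(same)), key(trs[[1]]))
  # a minority split compatible with every accepted split enters only
  # under plus-compatible grouping
  # six taxa: CD occurs once but is compatible with both majority splits
  trs2 <- ape::read.tree(text = c("((A,B),((C,D),(E,F)));",
                                  "((A,B),((C,E),(D,F)));",
                                  "((E,F),((A,C),(B,D)));"))
  mrOff <- majorityRuleConsensus(trs2, plusCompatible = FALSE)
  mrOn <- majorityRuleConsensus(trs2, plusCompatible = TRUE)
  expect_setequal(key(mrOff), c("CDEF", "EF"))
  expect_setequal(key(mrOn), c("CDEF", "EF", "CD"))
  # consensus splits are mutually compatible (a tree was built at all)
  expect_s3_class(mrOn, "phylo")
})

test_that("Colless imbalance and resolution match direct counts", {
  expect_equal(treeShapeStats(ape::read.tree(text = "((A,B),(C,D));")),
               c(colless = 0, resolution = 100))
  expect_equal(treeShapeStats(ape::read.tree(text = "(((A,B),C),D);")),
               c(colless = 3, resolution = 100))
  expect_equal(treeShapeStats(ape::read.tree(text = "(A,B,C,D,E);")),
               c(colless = 0, resolution = 25))
  unrooted <- ape::unroot(ape::rtree(5, tip.label = paste0("t", 1:5)))
  expect_error(treeShapeStats(unrooted, rootOn = "zz"), "absent")
  out <- treeShapeStats(unrooted, rootOn = "t1")
  expect_true(out[["resolution"]] <= 100)
})
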