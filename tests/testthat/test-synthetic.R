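test_that("tree pairs are separated by the requested SPR moves", {
  p0 <- simulateTreePair(10, 0, seed = 1)
  expect_equal(rfDistance(p0$tree1, p0$tree2), 0)
  expect_equal(length(p0$moves), 0L)
  set.seed(2)
  rfs <- vapply(1:30, function(i) {
    p <- simulateTreePair(8, 1)
    rfDistance(p$tree1, p$tree2)
  }, 0)
  expect_true(all(rfs > 0))  # one SPR almost surely changes the topology
  p5 <- simulateTreePair(12, 5, seed = 3)
  expect_equal(length(p5$moves), 5L)
})

test_that("the generator is deterministic under a fixed seed", {
  s1 <- simulateMatrix(simConfig(nTaxa = 8, nCranio = 15, nPost = 12,
                                 sprSeparation = 2, seed = 9))
  s2 <- simulateMatrix(simConfig(nTaxa = 8, nCranio = 15, nPost = 12,
                                 sprSeparation = 2, seed = 9))
  expect_identical(s1$matrix@masks, s2$matrix@masks)
  expect_identical(s1$matrix@special, s2$matrix@special)
  expect_identical(ape::write.tree(s1$trees$post),
                   ape::write.tree(s2$trees$post))
})

test_that("missingness is injected at the configured rate", {
  sim <- simulateMatrix(simConfig(nTaxa = 20, nCranio = 150, nPost = 150,
                                  missingCranio = 0.3, missingPost = 0.1,
                                  seed = 12))
  fr <- missingPercent(sim$matrix, sim$scheme) / 100
  n <- 20 * 150
  ciBand <- function(p) qbinom(c(0.0005, 0.9995), n, p) / n
  expect_gte(fr[["cranio"]], ciBand(0.3)[1])
  expect_lte(fr[["cranio"]], ciBand(0.3)[2])
  expect_gte(fr[["post"]], ciBand(0.1)[1])
  expect_lte(fr[["post"]], ciBand(0.1)[2])
})

test_that("the homoplasy dial moves the ensemble CI monotonically", {
  cfgAt <- function(mc) simConfig(nTaxa = 12, nCranio = 60, nPost = 10,
                                  meanChanges = c(mc, mc), gammaShape = 2,
                                  missingCranio = 0, missingPost = 0,
                                  seed = 77)
  ciAt <- function(mc) {
    sim <- simulateMatrix(cfgAt(mc))
    ts <- heuristicSearch(sim$matrix, charsets(sim$matrix)$cranio,
                          searchConfig(preset = "desk"), seed = 1)
    ensembleIndices(ts, sim$matrix, charsets(sim$matrix)$cranio)@CI
  }
  cis <- vapply(c(0.3, 2, 8), ciAt, 0)
  expect_true(all(diff(cis) < 0))
  expect_gt(cis[1], 0.85)  # near-zero homoplasy limit
})

test_that("increasing tree separation raises the observed incongruence", {
  obsAt <- function(spr) {
    sim <- simulateMatrix(simConfig(nTaxa = 14, nCranio = 60, nPost = 60,
                                    sprSeparation = spr,
                                    meanChanges = c(1.5, 1.5), gammaShape = 8,
                                    missingCranio = 0, missingPost = 0,
                                    seed = 100 + spr))
    cfg <- searchConfig(preset = "desk")
    tsA <- heuristicSearch(sim$matrix, charsets(sim$matrix)$cranio, cfg, 1)
    tsB <- heuristicSearch(sim$matrix, charsets(sim$matrix)$post, cfg, 2)
    irdStatistic(tsA, tsB, "matching", "NND", cap = 50, seed = 3)
  }
  expect_lt(obsAt(0), obsAt(6))
})

test_that("simulated ranges are non-negative and perfect on pectinate trees", {
  # hand-built pectinate (age-ordered) tree: zero noise gives GER = 1
  pec <- ape::read.tree(text = "(t1:4,(t2:3,(t3:2,(t4:1,t5:1):1):1):1);")
  rg <- simulateStratRanges(pec, noise = 0, rootAge = 40)
  expect_equal(stratIndices(pec, rg)[["GER"]], 1)
  sim <- simulateMatrix(simConfig(nTaxa = 10, nCranio = 10, nPost = 10,
                                  seed = 31))
  rgN <- simulateStratRanges(sim$trees$cranio, noise = 30, seed = 4)
  expect_true(all(rgN$fad >= 0))
  # noise degrades congruence on the generating tree (rooted on t1)
  rg0 <- simulateStratRanges(sim$trees$cranio, noise = 0)
  g0 <- gerStar(sim$trees$cranio, rg0, rootOn = "t1",
                permutations = 400, seed = 8)
  gN <- mean(vapply(1:5, function(i) {
    r <- simulateStratRanges(sim$trees$cranio, noise = 200, seed = i)
    gerStar(sim$trees$cranio, r, rootOn = "t1", permutations = 400, seed = i)
  }, 0))
  expect_gt(g0, gN)
})
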