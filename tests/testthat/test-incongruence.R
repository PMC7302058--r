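test_that("ILD statistic matches enumeration on a 4-taxon toy", {
  cm <- characterMatrix(rbind(A = c("0", "0"), B = c("0", "1"),
                              C = c("1", "0"), D = c("1", "1")))
  tops <- lapply(c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));"),
                 function(s) ape::read.tree(text = s))
  lA <- min(vapply(tops, fitchLength, 0L, cm = cm, chars = 1))
  lB <- min(vapply(tops, fitchLength, 0L, cm = cm, chars = 2))
  lAB <- min(vapply(tops, fitchLength, 0L, cm = cm))
  expect_equal(lA, 1L); expect_equal(lB, 1L); expect_equal(lAB, 3L)
  expect_equal(ildStatistic(lAB, lA, lB), 1L)
  expect_warning(ildStatistic(1, 2, 3), "not optimal")
  # perfectly congruent partitions give ILD 0
  sim <- simulateMatrix(simConfig(nTaxa = 8, nCranio = 30, nPost = 30,
                                  meanChanges = c(0.5, 0.5), gammaShape = 8,
                                  sprSeparation = 0, missingCranio = 0,
                                  missingPost = 0, seed = 5))
  r <- ildTest(sim$matrix, sim$scheme, searchConfig(preset = "desk"),
               replicates = 9, seed = 1)
  expect_equal(r@observed, 0)
})

test_that("random bipartitions are uniform and respect the requested sizes", {
  set.seed(10)
  counts <- table(replicate(6000, paste(randomBipartition(1:5, 3)$A,
                                        collapse = "")))
  expect_equal(length(counts), 10L)  # all C(5,3) outcomes appear
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.001)
  expect_error(randomBipartition(1:5, 5), "non-empty")
  expect_error(randomBipartition(1:5, 0), "non-empty")
  set.seed(3); a1 <- randomBipartition(1:10, 4)
  set.seed(3); a2 <- randomBipartition(1:10, 4)
  expect_identical(a1, a2)
})

test_that("permutation p-values sit on the add-one grid", {
  set.seed(20)
  cm <- randomMatrix(8, 20, states = 0:2, missingRate = 0.1)
  sch <- buildPartitionScheme(cm, "cranio", "post")
  cfg <- searchConfig(preset = "desk")
  for (reps in c(9, 19)) {
    r <- ildTest(cm, sch, cfg, replicates = reps, seed = reps)
    expect_equal(length(r@null), reps)
    expect_true(pValue(r) %in% ((1:(reps + 1)) / (reps + 1)))
  }
  r2 <- irdTest(cm, sch, cfg, "matching", "NND", replicates = 9, seed = 2)
  expect_true(pValue(r2) %in% ((1:10) / 10))
  expect_gte(min(r2@null), 0)
})

test_that("IRD statistic reduces to the pairwise distance for singleton sets", {
  t1 <- ape::read.tree(text = "((A,B),C,(D,E));")
  t2 <- ape::read.tree(text = "((A,C),B,(D,E));")
  mk <- function(tr) new("TreeSet", trees = list(tr), score = 0,
                         leafLabels = sort(tr$tip.label), metadata = list())
  for (metric in c("matching", "RF")) {
    dPair <- if (metric == "RF") rfDistance(t1, t2) else matchingDistance(t1, t2)
    expect_equal(irdStatistic(mk(t1), mk(t2), metric, "NND"), dPair)
    expect_equal(irdStatistic(mk(t1), mk(t2), metric, "MR"), dPair)
  }
  expect_equal(irdStatistic(mk(t1), mk(t1), "matching", "NND"), 0)
  expect_equal(irdStatistic(mk(t1), mk(t1), "RF", "MR"), 0)
})

test_that("ILD test is reproducible under a fixed master seed", {
  set.seed(77)
  cm <- randomMatrix(8, 16, states = 0:1)
  sch <- buildPartitionScheme(cm, "cranio", "post")
  cfg <- searchConfig(preset = "desk")
  r1 <- ildTest(cm, sch, cfg, replicates = 19, seed = 4)
  r2 <- ildTest(cm, sch, cfg, replicates = 19, seed = 4)
  expect_identical(r1@null, r2@null)
  expect_identical(pValue(r1), pValue(r2))
})
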