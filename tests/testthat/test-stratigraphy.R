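rg4 <- data.frame(taxon = c("A", "B", "C", "D"), fad = c(10, 8, 6, 4))
bal4 <- ape::read.tree(text = "((A,B),(C,D));")
pec4 <- ape::read.tree(text = "(A,(B,(C,D)));")

test_that("MIG sums implied ghost lineages branch by branch", {
  expect_equal(mig(pec4, rg4), 6)
  expect_equal(mig(bal4, rg4), 8)
  same <- data.frame(taxon = c("A", "B", "C", "D"), fad = rep(5, 4))
  expect_equal(mig(bal4, same), 0)
  expect_error(mig(bal4, rg4[1:3, ]), "missing FAD")
})

test_that("baselines follow the sorted-age formulas", {
  expect_equal(stratBaselines(rg4), c(Gmin = 6, Gmax = 12))
  expect_equal(stratBaselines(c(5, 5, 5)), c(Gmin = 0, Gmax = 0))
  # two distinct ages x > y with k taxa at x: Gmax = (n-k)(x-y)
  expect_equal(stratBaselines(c(9, 9, 2, 2, 2))[["Gmax"]], 3 * 7)
  expect_error(stratBaselines(c(1, 2)), "at least 3")
})

test_that("GER, MSM* and SCI match the hand-worked 4-taxon example", {
  ix <- stratIndices(bal4, rg4)
  expect_equal(ix[["GER"]], 1 - (8 - 6) / (12 - 6), tolerance = 1e-12)
  expect_equal(ix[["MSM"]], 6 / 8)
  expect_equal(ix[["SCI"]], 0.5)
  # age-ordered pectinate tree is perfectly congruent
  ixp <- stratIndices(pec4, rg4)
  expect_equal(unname(ixp), c(1, 1, 1))
  # reverse-ordered pectinate achieves the worst-case gap
  rev4 <- ape::read.tree(text = "(D,(C,(B,A)));")
  expect_equal(stratIndices(rev4, rg4)[["GER"]], 0)
})

test_that("Gmin <= MIG <= Gmax on random trees and ages", {
  set.seed(40)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    rg <- data.frame(taxon = paste0("t", 1:n),
                     fad = round(runif(n, 0, 50), 1))
    m <- mig(tr, rg)
    bl <- stratBaselines(rg)
    expect_gte(m, bl[["Gmin"]] - 1e-9)
    expect_lte(m, bl[["Gmax"]] + 1e-9)
  }
})

test_that("GER and GER* are invariant to affine rescaling of ages", {
  set.seed(41)
  tr <- ape::rtree(7, tip.label = paste0("t", 1:7))
  rg <- data.frame(taxon = paste0("t", 1:7), fad = runif(7, 10, 90))
  rg2 <- transform(rg, fad = 3.7 * fad + 12)
  expect_equal(stratIndices(tr, rg)[["GER"]], stratIndices(tr, rg2)[["GER"]],
               tolerance = 1e-9)
  expect_equal(gerStar(tr, rg, permutations = 300, seed = 5),
               gerStar(tr, rg2, permutations = 300, seed = 5))
})

test_that("GER* permutation estimate matches exhaustive enumeration", {
  exact <- mean(vapply(allPerms(rg4$fad), function(a)
    mig(bal4, data.frame(taxon = rg4$taxon, fad = a)), 0) >= mig(bal4, rg4))
  est <- gerStar(bal4, rg4, permutations = 4000, seed = 7)
  expect_equal(est, exact, tolerance = 0.05)
  # observed MIG below every permuted MIG gives GER* = 1
  expect_equal(gerStar(pec4, rg4, permutations = 500, seed = 2), 1)
})

test_that("per-tree-set reporting averages across trees", {
  res <- stratCongruence(list(bal4, pec4), rg4, permutations = 400, seed = 3)
  expect_equal(nrow(res@perTree), 2L)
  expect_equal(res@means[["MIG"]], mean(c(8, 6)))
  expect_equal(res@means[["SCI"]], mean(c(0.5, 1)))
})

test_that("range tables are validated on read", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(taxon = c("A", "B", "C"), fad = c(3, 2, 1),
                       lad = c(2, 1, 0)), f, row.names = FALSE)
  rg <- readStratRanges(f)
  expect_equal(rg$fad, c(3, 2, 1))
  write.csv(data.frame(taxon = c("A", "B"), fad = c(1, 2), lad = c(2, 1)),
            f, row.names = FALSE)
  expect_error(readStratRanges(f), "FAD must be at least LAD")
})
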