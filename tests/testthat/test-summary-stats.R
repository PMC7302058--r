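tab <- loadTable1Fixture()

test_that("the packaged study table has the documented shape", {
  expect_equal(nrow(tab), 81L)
  expect_equal(as.integer(table(tab$clade)[c("Theropoda", "Sauropodomorpha",
                                             "Cerapoda", "Ornithopoda",
                                             "Thyreophora")]),
               c(29L, 17L, 6L, 15L, 14L))
  expect_equal(tab$n_cranio_chars[1], 74L)
  expect_true(all(tab$p_ild > 0 & tab$p_ild <= 1))
  expect_true(all(tab$winner %in% c("Cranio", "Post")))
})

test_that("significance tallies count strict sub-alpha rows per clade", {
  t1 <- tallySignificance(tab, "p_ild")
  expect_equal(t1$total, 27L)
  expect_equal(sum(t1$perGroup), t1$total)
  expect_equal(tallySignificance(tab, "p_ird_nnd_matching")$total, 41L)
  expect_equal(tallySignificance(tab, "p_ild", alpha = 0)$total, 0L)
  expect_error(tallySignificance(tab, "no_such_column"), "unknown column")
})

test_that("the likelihood-ratio G test matches hand results and is symmetric", {
  even <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(gTest(even)$statistic, 0)
  prop <- rbind(c(10, 20), c(5, 10), c(20, 40))
  expect_equal(gTest(prop)$statistic, 0, tolerance = 1e-12)
  m <- rbind(c(12, 3), c(4, 11))
  expect_equal(gTest(m)$statistic, gTest(t(m))$statistic)
  expect_equal(gTest(m)$df, 1L)
  expect_error(gTest(rbind(c(0, 0), c(1, 2))), "zero margin")
})

test_that("Wilcoxon V follows the positive-rank-sum convention", {
  w <- wilcoxonSignedRankV(c(2, 4, 0), c(1, 2, 3))
  expect_equal(w$statistic, 3)  # diffs (1, 2, -3) -> ranks 1, 2, 3
  expect_equal(w$n, 3L)
  deg <- wilcoxonSignedRankV(c(1, 2), c(1, 2))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$statistic))
})

test_that("the binomial and Spearman helpers match canonical cases", {
  expect_equal(exactBinomialTest(0, 1)$p.value, 1)
  expect_equal(spearmanRho(1:8, 1:8)$statistic, 1)
  expect_equal(spearmanRho(1:8, 8:1)$statistic, -1)
  expect_true(spearmanRho(rep(1, 5), 1:5)$degenerate)
})

test_that("CI residual comparison removes dimension effects", {
  r <- ciResidualCompare(tab)
  expect_equal(sum(r$residuals), 0, tolerance = 1e-8)  # intercept model
  expect_true(r$p.value > 0 && r$p.value <= 1)
  # slope recovery: CI generated as a - b*log(chars) + noise
  set.seed(50)
  fake <- tab
  b <- 0.1
  fake$ci_cranio <- 1.2 - b * log(fake$n_cranio_chars) + rnorm(81, 0, 0.02)
  fake$ci_post <- 1.2 - b * log(fake$n_post_chars) + rnorm(81, 0, 0.02)
  fit <- ciResidualCompare(fake)$model
  ci <- confint(fit)["lchars", ]
  expect_true(-b >= ci[1] && -b <= ci[2])
})

test_that("consilience association cross-tabulates winners correctly", {
  flat <- data.frame(ref_no = 1:20,
                     winner = rep(c("Cranio", "Post"), each = 10))
  sw <- data.frame(ref_no = 1:20,
                   strat_winner = rep(c("Cranio", "Post"), 10))
  r <- associationConsilience(flat, sw)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$df, 1L)
  # perfectly concordant winners maximize G for the margins
  sw2 <- data.frame(ref_no = 1:20, strat_winner = flat$winner)
  r2 <- associationConsilience(flat, sw2)
  expect_equal(r2$statistic, 2 * 20 * log(2), tolerance = 1e-9)
  expect_lt(r2$p.value, 0.001)
})

test_that("simulated winner data under independence keep G near zero", {
  set.seed(51)
  gs <- replicate(50, {
    flat <- data.frame(ref_no = 1:40,
                       winner = sample(c("Cranio", "Post"), 40, TRUE))
    sw <- data.frame(ref_no = 1:40,
                     strat_winner = sample(c("Cranio", "Post"), 40, TRUE))
    tryCatch(associationConsilience(flat, sw)$statistic, error = function(e) NA)
  })
  expect_lt(mean(gs, na.rm = TRUE), 2.5)  # E[G] ~ df = 1 under independence
})
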