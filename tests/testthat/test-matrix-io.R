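test_that("NEXUS decoding handles missing, inapplicable and polymorphism", {
  f <- tempfile(fileext = ".nex")
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    "  DIMENSIONS NTAX=4 NCHAR=3;",
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
    "  MATRIX",
    "    A 0?1",
    "    B 01{01}",
    "    C 10-",
    "    D 111",
    "  ;",
    "END;",
    "BEGIN SETS;",
    "  CHARSET cranio = 1-2;",
    "  CHARSET post = 3;",
    "END;"), f)
  cm <- readNexus(f)
  expect_equal(nTaxa(cm), 4L)
  expect_equal(nCharacters(cm), 3L)
  expect_equal(sum(cm@special == 1L), 1L)  # one missing cell
  expect_equal(sum(cm@special == 2L), 1L)  # one inapplicable cell
  expect_equal(cm@masks["B", 3], 3L)       # {01} decoded as a 2-state set
  expect_equal(charsets(cm)$cranio, 1:2)
  expect_equal(charsets(cm)$post, 3L)
})

test_that("write/read round-trip is the identity", {
  sim <- simulateMatrix(simConfig(nTaxa = 9, nCranio = 12, nPost = 10,
                                  missingCranio = 0.3, missingPost = 0.2,
                                  pInapplicable = 0.3, seed = 21))
  f <- tempfile(fileext = ".nex")
  writeNexus(sim$matrix, f)
  cm2 <- readNexus(f)
  expect_identical(cm2@masks, sim$matrix@masks)
  expect_identical(cm2@special, sim$matrix@special)
  expect_identical(lapply(cm2@charsets, as.integer),
                   lapply(sim$matrix@charsets, as.integer))
  # second round trip reproduces the file verbatim
  f2 <- tempfile(fileext = ".nex")
  writeNexus(cm2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("partition schemes label unlisted characters as other", {
  set.seed(1)
  cm <- randomMatrix(5, 10)
  sch <- buildPartitionScheme(cm, 1:4, 5:9)
  expect_equal(as.character(partitionLabels(sch)[10]), "other")
  expect_error(buildPartitionScheme(cm, 1:4, 4:9), "overlap")
  # named charsets agree with explicit indices
  sch2 <- buildPartitionScheme(cm, "cranio", "post")
  sch3 <- buildPartitionScheme(cm, 1:5, 6:10)
  expect_identical(partitionLabels(sch2), partitionLabels(sch3))
})

test_that("matrix overlap counts shared cells against the smaller matrix", {
  set.seed(2)
  tok1 <- matrix("0", 8, 5,
                 dimnames = list(paste0("s", 1:8), paste0("c", 1:5)))
  tok2 <- matrix("1", 20, 10,
                 dimnames = list(c(paste0("s", 1:5), paste0("x", 1:15)),
                                 c(paste0("c", 1:4), paste0("z", 1:6))))
  m1 <- characterMatrix(tok1)
  m2 <- characterMatrix(tok2)
  # 5 shared taxa x 4 shared characters over 40 cells of the smaller
  expect_equal(matrixOverlap(m1, m2), 50)
  expect_equal(matrixOverlap(m1, m1), 100)
  expect_equal(matrixOverlap(m2, m1), 50)  # symmetric
  tok3 <- tok1; rownames(tok3) <- paste0("q", 1:8)
  expect_equal(matrixOverlap(m1, characterMatrix(tok3)), 0)
})

test_that("curation removes over-threshold taxa and newly uninformative characters", {
  # taxon E is 50% missing in the craniodental partition; character 5
  # varies only in E and becomes invariant after E is dropped
  tok <- rbind(A = c("0", "0", "0", "0", "0"),
               B = c("0", "1", "0", "1", "0"),
               C = c("1", "0", "1", "0", "0"),
               D = c("1", "1", "1", "1", "0"),
               E = c("?", "?", "0", "1", "1"))
  cm <- characterMatrix(tok)
  sch <- buildPartitionScheme(cm, 1:4, 5)
  cur <- curateMatrix(cm, sch, threshold = 0.40)
  expect_equal(cur$report@removedTaxa$taxon, "E")
  expect_false("E" %in% taxa(cur$matrix))
  expect_equal(nCharacters(cur$matrix), 4L)
  expect_equal(cur$report@removedCharacters$reason,
               "rendered invariant by taxon removal")
  # clean matrices come through untouched; threshold 1 removes nothing
  tok2 <- tok[1:4, ]
  cm2 <- characterMatrix(tok2)
  sch2 <- buildPartitionScheme(cm2, 1:4, 5)
  cur2 <- curateMatrix(cm2, sch2)
  expect_equal(nrow(cur2$report@removedTaxa), 0L)
  expect_identical(cur2$matrix@masks, cm2@masks)
  cur3 <- curateMatrix(cm, sch, threshold = 1.0)
  expect_equal(nrow(cur3$report@removedTaxa), 0L)
  # surviving taxa never violate the threshold in either partition
  fr <- rowMeans(cur$matrix@special[, partitionLabels(cur$scheme) ==
                                      "craniodental", drop = FALSE] != 0L)
  expect_true(all(fr <= 0.40))
})

test_that("uninformative characters are detected and removed", {
  tok <- rbind(A = c("0", "0", "0"),
               B = c("0", "0", "0"),
               C = c("0", "0", "1"),
               D = c("0", "1", "1"))
  cm <- characterMatrix(tok)
  out <- removeUninformative(cm)  # constant + autapomorphic removed
  expect_equal(nCharacters(out), 1L)
  expect_equal(characterIds(out), "c3")
  # uninformative characters add a constant to every tree's length
  set.seed(3)
  cmr <- randomMatrix(6, 12, missingRate = 0.2)
  informative <- which(partcong:::.informativeFlags(cmr))
  t1 <- ape::rtree(6, tip.label = paste0("t", 1:6))
  t2 <- ape::rtree(6, tip.label = paste0("t", 1:6))
  d1 <- fitchLength(t1, cmr) - fitchLength(t1, cmr, informative)
  d2 <- fitchLength(t2, cmr) - fitchLength(t2, cmr, informative)
  expect_equal(d1, d2)
})
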