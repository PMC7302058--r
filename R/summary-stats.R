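# Cross-study summary statistics over a table of per-study partition-test
# results (one row per published matrix): significance tallies, likelihood
# ratio G tests of heterogeneity across clades, paired Wilcoxon V,
# two-sided exact binomial tests, Spearman correlations, and the
# regression-residual comparison of consistency indices.

.table1Md5 <- "1955fb822647ccf29da3b4f5ec150a68"

#' Load the packaged 81-study summary table
#'
#' Returns the packaged transcription of the published per-study summary
#' table: 81 partitioned dinosaur data sets with character/taxon counts,
#' the five partition-test p-values (ILD and four IRD variants), missing
#' percentages, ensemble CI/RI per partition, and the
#' partition-most-similar-to-entire winner with its p-value. The file is
#' checksummed; a mismatch aborts.
#'
#' @return data.frame with 81 rows.
#' @export
loadTable1Fixture <- function() {
  path <- system.file("extdata", "table1_studies.csv", package = "partcong")
  if (path == "") stop("fixture not found")
  sum_ <- unname(tools::md5sum(path))
  if (!identical(sum_, .table1Md5))
    stop("table1_studies.csv checksum mismatch: file corrupted")
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(d) == 81L,
            all(c("clade", "p_ild", "p_ird_nnd_matching", "winner") %in% names(d)),
            all(d$clade %in% c("Theropoda", "Sauropodomorpha", "Cerapoda",
                               "Ornithopoda", "Thyreophora")),
            all(d$p_ild > 0 & d$p_ild <= 1))
  d
}

.cladeLevels <- c("Theropoda", "Sauropodomorpha", "Cerapoda",
                  "Ornithopoda", "Thyreophora")

#' Tally significant tests
#'
#' Counts rows with p below \code{alpha} in the given column, in total and
#' per group.
#'
#' @param table a study table (see [loadTable1Fixture()]).
#' @param column name of a p-value column.
#' @param alpha significance level (strict inequality).
#' @param by optional grouping column (default \code{"clade"}).
#' @return list with \code{total} and \code{perGroup} counts.
#' @export
tallySignificance <- function(table, column, alpha = 0.05, by = "clade") {
  if (!column %in% names(table)) stop("unknown column: ", column)
  sig <- table[[column]] < alpha
  grp <- factor(table[[by]],
                levels = if (by == "clade") .cladeLevels else unique(table[[by]]))
  list(total = sum(sig), perGroup = tapply(sig, grp, sum, default = 0L))
}

#' Likelihood-ratio (G) test of a k x 2 contingency table
#'
#' G = 2 sum O log(O/E) with the convention 0 log 0 = 0, compared to a
#' chi-square with k - 1 degrees of freedom.
#'
#' @param tab numeric matrix of non-negative counts with positive margins.
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
gTest <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  keep <- tab > 0
  G <- 2 * sum(tab[keep] * log(tab[keep] / E[keep]))
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = G, df = df, p.value = pchisq(G, df, lower.tail = FALSE))
}

#' Paired Wilcoxon signed-rank statistic V
#'
#' V is the sum of the average ranks (of absolute differences) attached to
#' positive differences x - y, after dropping zero differences. The
#' p-value uses exact enumeration when there are no ties or zeros and the
#' tie-corrected normal approximation otherwise.
#'
#' @param x,y paired numeric vectors.
#' @return list with \code{statistic} (V), \code{p.value} and \code{n}
#'   (non-zero pairs); statistic and p are NA when all differences vanish.
#' @export
wilcoxonSignedRankV <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  dn <- d[d != 0]
  if (!length(dn))
    return(list(statistic = NA_real_, p.value = NA_real_, n = 0L,
                degenerate = TRUE))
  r <- rank(abs(dn))
  V <- sum(r[dn > 0])
  exact <- !any(duplicated(abs(dn))) && length(dn) == length(d)
  p <- suppressWarnings(
    wilcox.test(x, y, paired = TRUE, exact = exact)$p.value)
  list(statistic = V, p.value = p, n = length(dn), degenerate = FALSE)
}

#' Two-sided exact binomial test
#'
#' Exact two-sided p-value using the small-p-values method: the sum of all
#' point probabilities not exceeding that of the observed count.
#'
#' @param k successes, \code{n} trials, \code{p0} null probability.
#' @param n number of trials.
#' @param p0 null success probability.
#' @return list with \code{statistic} (k) and \code{p.value}.
#' @export
exactBinomialTest <- function(k, n, p0 = 0.5) {
  if (k < 0 || k > n) stop("k must lie in 0..n")
  list(statistic = k, p.value = binom.test(k, n, p = p0)$p.value)
}

#' Spearman rank correlation with tie correction
#'
#' Pearson correlation of the average ranks; p-value from the
#' t-approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{statistic} (rho) and \code{p.value}; NA when a
#'   vector is constant.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors with at least 3 values")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(statistic = NA_real_, p.value = NA_real_, degenerate = TRUE))
  rho <- cor(rank(x), rank(y))
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(statistic = rho, p.value = 2 * stats::pt(-abs(tstat), n - 2),
       degenerate = FALSE)
}

#' Compare dimension-corrected consistency indices between partitions
#'
#' Pools the craniodental and postcranial CI values (two observations per
#' study), fits an ordinary least-squares regression of CI on log(character
#' count), log(taxon count) and their interaction, and compares the
#' craniodental versus postcranial residuals with the paired signed-rank
#' test.
#'
#' @param table a study table with CI, character-count and taxon columns.
#' @return list with the fitted \code{model}, the residual matrix and the
#'   paired test (\code{statistic} = V, \code{p.value}).
#' @export
ciResidualCompare <- function(table) {
  need <- c("ci_cranio", "ci_post", "n_cranio_chars", "n_post_chars", "n_taxa")
  if (!all(need %in% names(table))) stop("missing required columns")
  long <- data.frame(
    ci = c(table$ci_cranio, table$ci_post),
    lchars = log(c(table$n_cranio_chars, table$n_post_chars)),
    ltaxa = log(rep(table$n_taxa, 2)))
  if (!all(complete.cases(long))) stop("incomplete CI or dimension data")
  fit <- lm(ci ~ lchars * ltaxa, data = long)
  res <- resid(fit)
  n <- nrow(table)
  rc <- res[seq_len(n)]
  rp <- res[n + seq_len(n)]
  w <- wilcoxonSignedRankV(rc, rp)
  list(model = fit, residuals = cbind(cranio = rc, post = rp),
       statistic = w$statistic, p.value = w$p.value)
}

#' Association between total-evidence winner and stratigraphic winner
#'
#' Cross-tabulates, per study, which partition was most similar to the
#' entire-matrix trees against which partition was most stratigraphically
#' congruent, and applies the likelihood-ratio G test (1 df) to the
#' resulting 2 x 2 table.
#'
#' @param table a study table with columns \code{ref_no} and \code{winner}.
#' @param stratWinners data.frame with \code{ref_no} and
#'   \code{strat_winner} (values \code{"Cranio"}/\code{"Post"}).
#' @return list with the 2 x 2 \code{table}, \code{statistic}, \code{df}
#'   and \code{p.value}.
#' @export
associationConsilience <- function(table, stratWinners) {
  m <- merge(table[, c("ref_no", "winner")], stratWinners, by = "ref_no")
  if (!nrow(m)) stop("no matching study ids")
  tab <- table(factor(m$winner, levels = c("Cranio", "Post")),
               factor(m$strat_winner, levels = c("Cranio", "Post")))
  g <- gTest(unclass(tab))
  list(table = tab, statistic = g$statistic, df = g$df, p.value = g$p.value)
}
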