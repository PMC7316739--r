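rankedFixture <- function(n = 8) {
  setNames(c(4, 3, 2, 1, -1, -2, -3, -4)[seq_len(n)],
           paste0("g", seq_len(n)))
}

test_that("single-member sets at the extremes give ES of exactly +1
           and -1", {
  scores <- rankedFixture()
  expect_identical(enrichmentScore(scores, "g1")$ES, 1)
  expect_identical(enrichmentScore(scores, "g8")$ES, -1)
})

test_that("enrichment score equals the brute-force running sum on every
           3-subset of an 8-gene ranking", {
  scores <- rankedFixture()
  for (w in c(0, 1)) {
    for (sub in utils::combn(names(scores), 3, simplify = FALSE)) {
      got <- enrichmentScore(scores, sub, weight = w)$ES
      expect_equal(got, esOracle(scores, sub, weight = w),
                   tolerance = 1e-12)
    }
  }
})

test_that("ES matches fgsea's statistic on random instances", {
  skip_if_not_installed("fgsea")
  set.seed(5)
  scores <- sort(rnorm(50), decreasing = TRUE)
  names(scores) <- paste0("g", 1:50)
  for (rep in 1:20) {
    mem <- sample(names(scores), sample(3:10, 1))
    got <- enrichmentScore(scores, mem, weight = 1)$ES
    want <- fgsea::calcGseaStat(scores,
                                selectedStats = which(names(scores) %in%
                                                        mem),
                                gseaParam = 1)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("ES is invariant to positive rescaling of the scores", {
  set.seed(9)
  scores <- sort(rnorm(40), decreasing = TRUE)
  names(scores) <- paste0("g", 1:40)
  mem <- sample(names(scores), 6)
  for (w in c(0, 1)) {
    a <- enrichmentScore(scores, mem, weight = w)$ES
    b <- enrichmentScore(scores * 7.3, mem, weight = w)$ES
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("reversing the ranking and negating scores negates ES", {
  set.seed(4)
  scores <- sort(rnorm(30), decreasing = TRUE)
  names(scores) <- paste0("g", 1:30)
  flipped <- rev(-scores)
  for (rep in 1:10) {
    mem <- sample(names(scores), 5)
    a <- enrichmentScore(scores, mem)$ES
    b <- enrichmentScore(flipped, mem)$ES
    expect_equal(b, -a, tolerance = 1e-12)
  }
})

test_that("leading edge sits at the correct side of the extremum", {
  scores <- rankedFixture()
  up <- enrichmentScore(scores, c("g1", "g2", "g6"))
  expect_true(all(up$leadingEdge %in% c("g1", "g2")))
  down <- enrichmentScore(scores, c("g7", "g8", "g3"))
  expect_true(all(down$leadingEdge %in% c("g7", "g8")))
})

test_that("degenerate sets are rejected", {
  scores <- rankedFixture()
  expect_error(enrichmentScore(scores, c("zz", "yy")), "no member")
  expect_error(enrichmentScore(scores, names(scores)), "entire ranking")
})

test_that("an implanted top set reaches the smallest attainable nominal
           p-value", {
  set.seed(2)
  scores <- c(sort(runif(20, 5, 10), decreasing = TRUE),
              sort(rnorm(980, 0, 0.5), decreasing = TRUE))
  names(scores) <- sprintf("g%04d", seq_along(scores))
  gsc <- GeneSetCollection(list(top = names(scores)[1:20]))
  res <- gseaPreranked(scores, gsc, nPerm = 1000, seed = 8, minSize = 5)
  expect_gt(res$NES, 0)
  expect_lte(res$nominal_p, 1 / 1001)
})

test_that("nominal p is uniform for a random set under a random
           ranking", {
  set.seed(6)
  ps <- replicate(200, {
    scores <- sort(rnorm(100), decreasing = TRUE)
    names(scores) <- paste0("g", 1:100)
    gsc <- GeneSetCollection(list(s = sample(names(scores), 10)))
    gseaPreranked(scores, gsc, nPerm = 99, seed = sample.int(1e6, 1),
                  minSize = 2)$nominal_p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("preranked GSEA is deterministic under a seed and filters by
           size", {
  set.seed(3)
  scores <- sort(rnorm(60), decreasing = TRUE)
  names(scores) <- paste0("g", 1:60)
  gsc <- GeneSetCollection(list(a = names(scores)[c(2, 5, 11, 20)],
                                big = names(scores)[1:40],
                                absent = c("x1", "x2")))
  r1 <- suppressWarnings(suppressMessages(
    gseaPreranked(scores, gsc, nPerm = 50, seed = 10, minSize = 3,
                  maxSize = 20)))
  r2 <- suppressWarnings(suppressMessages(
    gseaPreranked(scores, gsc, nPerm = 50, seed = 10, minSize = 3,
                  maxSize = 20)))
  expect_identical(r1, r2)
  expect_identical(r1$set, "a")  # 'big' filtered by maxSize, 'absent' skipped
})

test_that("top-set selection filters, orders by |NES| and truncates per
           sign", {
  res <- data.frame(
    set = paste0("S", 1:6),
    size = 10,
    ES = c(0.5, -0.4, 0.3, -0.6, 0.2, 0.7),
    NES = c(1.5, -1.2, 0.9, -1.8, 0.6, 2.1),
    nominal_p = c(0.01, 0.04, 0.2, 0.001, 0.03, 0.04),
    fdr = 0.1, leading_edge = "")
  sel <- selectTopSets(res, pCutoff = 0.05, nTop = 100)
  expect_identical(sel$set, c("S6", "S1", "S5", "S4", "S2"))
  expect_true(all(diff(abs(sel$NES[sel$direction == "positive"])) <= 0))
  sel2 <- selectTopSets(res, pCutoff = 0.05, nTop = 1)
  expect_identical(sel2$set, c("S6", "S4"))
  none <- selectTopSets(transform(res, nominal_p = 1), pCutoff = 0.05)
  expect_identical(nrow(none), 0L)
})

test_that("overlap partition is exact for identical, disjoint and random
           selections", {
  a <- paste0("S", 1:10)
  ov <- overlapTopSets(a = a, b = a)
  expect_identical(unname(ov$counts["a&b"]), 10L)
  ov2 <- overlapTopSets(a = paste0("S", 1:5), b = paste0("T", 1:5))
  expect_identical(sort(names(ov2$counts)), c("a", "b"))
  # hypergeometric expectation for random selections
  set.seed(40)
  universe <- paste0("S", 1:500)
  overlaps <- replicate(100, {
    x <- sample(universe, 50)
    y <- sample(universe, 50)
    ov <- overlapTopSets(x = x, y = y)
    sum(ov$counts[grepl("x&y", names(ov$counts), fixed = TRUE)])
  })
  expectMean <- 50 * 50 / 500
  sdHyper <- sqrt(50 * (50 / 500) * (450 / 500) * (450 / 499))
  expect_lt(abs(mean(overlaps) - expectMean), 3 * sdHyper / sqrt(100) * 3)
})

test_that("three-way overlap regions are exclusive", {
  ov <- overlapTopSets(a = c("1", "2", "3"), b = c("2", "3", "4"),
                       c = c("3", "5"))
  expect_identical(unname(ov$counts[["a&b&c"]]), 1L)
  expect_identical(unname(ov$counts[["a&b"]]), 1L)  # set "2" only
  expect_identical(sort(ov$members[["a&b&c"]]), "3")
})

test_that("ranked scores order descending with lexicographic tie-break", {
  tab <- data.frame(transcript_id = c("b", "a", "c"),
                    n_detected = c(1L, 1L, 2L),
                    sum_logFC = c(2, 2, -1),
                    kw_H = 0, kw_p = 1, kw_q = 1, significant = FALSE)
  rk <- rankedScores(tab)
  expect_identical(names(rk), c("a", "b", "c"))
  expect_identical(unname(rk), c(2, 2, -1))
})
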