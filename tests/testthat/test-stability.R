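test_that("the admissible draw space is counted correctly and exhausted
           draws are distinct", {
  se <- makeNullExperiment(20, nPerGroup = 6, seed = 3)  # 3M + 3F per group
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  # k=2 at balance 1M+1F: (C(3,1)*C(3,1))^2 = 81 admissible pairs
  draws <- enumerateBalancedDraws(meta, "MSA-P", "CTRL", k = 2, nIter = 81,
                                  seed = 1)
  keys <- vapply(draws, function(d)
    paste(c(d$samplesA, "|", d$samplesB), collapse = ","), "")
  expect_length(unique(keys), 81L)
  # every draw is gender balanced
  gender <- setNames(meta$gender, meta$sample_id)
  for (d in draws) {
    expect_identical(unname(as.vector(table(gender[d$samplesA]))), c(1L, 1L))
    expect_identical(unname(as.vector(table(gender[d$samplesB]))), c(1L, 1L))
  }
  expect_error(
    enumerateBalancedDraws(meta, "MSA-P", "CTRL", k = 2, nIter = 82,
                           seed = 1),
    "81")
})

test_that("the default design's draw space matches the combinatorial
           count", {
  se <- makeNullExperiment(10, nPerGroup = 10, seed = 1)  # 5M + 5F
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  # (C(5,2) * C(5,2))^2 = 10,000
  expect_error(
    enumerateBalancedDraws(meta, "MSA-P", "CTRL", k = 4, nIter = 10001),
    "10,000")
  draws <- enumerateBalancedDraws(meta, "MSA-P", "CTRL", k = 4,
                                  nIter = 100, seed = 5)
  expect_length(draws, 100L)
})

test_that("boundary: a single admissible draw cannot supply two
           iterations", {
  se <- makeNullExperiment(10, nPerGroup = 4, seed = 2)  # 2M + 2F
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  one <- enumerateBalancedDraws(meta, "PD", "CTRL", k = 4, nIter = 1,
                                seed = 1)
  expect_length(one, 1L)
  expect_error(
    enumerateBalancedDraws(meta, "PD", "CTRL", k = 4, nIter = 2, seed = 1),
    "1 pairs")
})

test_that("draw enumeration and the permutation null are deterministic
           under a seed", {
  se <- makeNullExperiment(40, seed = 6)
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  d1 <- enumerateBalancedDraws(meta, "MSA-P", "CTRL", nIter = 10, seed = 9)
  d2 <- enumerateBalancedDraws(meta, "MSA-P", "CTRL", nIter = 10, seed = 9)
  expect_identical(d1, d2)
  n1 <- runPermutationNull(se, "MSA-P", "CTRL", nPerm = 5, seed = 4)
  n2 <- runPermutationNull(se, "MSA-P", "CTRL", nPerm = 5, seed = 4)
  expect_identical(n1, n2)
})

test_that("a single-iteration resampling run equals the direct moderated
           test on that subgroup", {
  se <- makeNullExperiment(60, seed = 8)
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  draws <- enumerateBalancedDraws(meta, "MSA-C", "CTRL", nIter = 1,
                                  seed = 2)
  rs <- runResampling(se, "MSA-C", "CTRL", draws)
  direct <- moderatedDE(se, "MSA-C", "CTRL",
                        samples = c(draws[[1]]$samplesA,
                                    draws[[1]]$samplesB))
  expect_equal(unname(rs$p[, 1]), direct$p, tolerance = 1e-14)
  expect_equal(unname(rs$logFC[, 1]), direct$logFC, tolerance = 1e-14)
})

test_that("Kruskal-Wallis comparison matches an exhaustive rank oracle on
           all small inputs", {
  # the spec's worked example
  ex <- kruskalWallisCompare(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  or <- kwOracle(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(ex$H, or$H, tolerance = 1e-12)
  # randomized small instances up to total length 10, including ties
  set.seed(31)
  for (rep in 1:60) {
    nA <- sample(1:8, 1)
    nB <- sample(1:(10 - max(nA, 2)), 1)
    vals <- round(runif(nA + nB), sample(c(1, 2, 6), 1))  # forces ties
    a <- vals[seq_len(nA)]
    b <- vals[nA + seq_len(nB)]
    if (all(c(a, b) == c(a, b)[1])) next
    got <- kruskalWallisCompare(a, b)
    want <- kwOracle(a, b)
    expect_equal(got$H, want$H, tolerance = 1e-12)
  }
})

test_that("identical distributions give H = 0, p = 1 and constant input
           is not an error", {
  same <- runif(20)
  res <- kruskalWallisCompare(same, same)
  expect_equal(res$H, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  expect_identical(kruskalWallisCompare(rep(0.2, 5), rep(0.2, 7)),
                   list(H = 0, p = 1))
  expect_error(kruskalWallisCompare(numeric(), runif(3)), "non-empty")
})

test_that("an extreme separation yields an extreme Kruskal-Wallis p", {
  set.seed(13)
  res <- kruskalWallisCompare(runif(100, 0, 0.01), runif(100))
  expect_lt(res$p, 1e-10)
})

test_that("Storey q-values: BH equivalence at pi0 = 1, monotonicity,
           boundary cases", {
  expect_equal(storeyQValues(c(0.01, 0.02, 0.03), pi0 = 1),
               c(0.03, 0.03, 0.03), ignore_attr = TRUE)
  expect_equal(as.numeric(storeyQValues(rep(1, 200))), rep(1, 200))
  set.seed(17)
  p <- runif(500)^1.5
  q <- storeyQValues(p)
  expect_true(all(q >= 0 & q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-14))
  expect_equal(as.numeric(storeyQValues(p, pi0 = 1)),
               p.adjust(p, "BH"), tolerance = 1e-12)
  expect_warning(qs <- storeyQValues(runif(20)), "fewer than 100")
  expect_identical(attr(qs, "pi0"), 1)
})

test_that("stability table: detection counting, ordering and contract
           errors", {
  ids <- c("b", "a", "c")
  P <- matrix(c(0.5, 0.6, 0.9,
                0.01, 0.2, 0.03,
                0.01, 0.02, 0.03), 3, 3, byrow = TRUE,
              dimnames = list(ids, paste0("iter", 1:3)))
  L <- matrix(c(0.1, -0.1, 0.05,
                1, 1, 1,
                -2, -2, -2), 3, 3, byrow = TRUE,
              dimnames = dimnames(P))
  NP <- matrix(runif(30), 3, 10, dimnames = list(ids, paste0("perm", 1:10)))
  tab <- suppressWarnings(
    buildStabilityTable(list(p = P, logFC = L), list(p = NP)))
  expect_identical(tab$transcript_id, c("c", "a", "b"))
  expect_identical(tab$n_detected, c(3L, 2L, 0L))
  expect_equal(tab$sum_logFC, c(-6, 3, 0.05))
  expect_true(all(tab$significant == (tab$kw_q < 1e-4)))
  badNP <- NP[c(2, 1, 3), ]
  expect_error(
    buildStabilityTable(list(p = P, logFC = L), list(p = badNP)),
    "different transcript sets")
})

test_that("recurrence/q correlation: exact linear case and degenerate
           input", {
  tab <- data.frame(transcript_id = paste0("t", 1:50),
                    n_detected = 0:49,
                    sum_logFC = rnorm(50),
                    kw_H = 0, kw_p = 1,
                    kw_q = 1 - (0:49) / 100,
                    significant = FALSE)
  expect_equal(correlateRecurrenceQ(tab), -1, tolerance = 1e-12)
  tab$kw_q <- 0.5
  expect_error(correlateRecurrenceQ(tab), "zero variance")
})

test_that("observed and null p-values share a uniform marginal
           distribution on null data", {
  se <- makeNullExperiment(400, seed = 21)
  res <- runStability(se, "MSA-P", "CTRL", nIter = 40, nPerm = 40,
                      seed = 33)
  P <- observedPValues(res)
  NP <- nullPValues(res)
  # pooled over transcripts, both stages draw from the same uniform;
  # per-transcript observed profiles are NOT exchangeable with the null
  # (iterations share the transcript's chance full-cohort difference),
  # which is the documented anti-conservativeness of the KW stage
  expect_lt(abs(mean(rowMeans(P)) - 0.5), 0.05)
  expect_lt(abs(mean(rowMeans(NP)) - 0.5), 0.05)
  ksPooled <- suppressWarnings(ks.test(as.vector(P), as.vector(NP)))
  expect_lt(unname(ksPooled$statistic), 0.05)
  # the typical transcript still shows no distribution difference
  ksP <- vapply(seq_len(nrow(P)), function(i)
    suppressWarnings(ks.test(P[i, ], NP[i, ])$p.value), 1.0)
  expect_gt(median(ksP), 0.2)
})

test_that("injected effects shift observed p-values left while the
           permutation null stays uniform", {
  cfg <- simulationConfig(400, seed = 12, baselineSd = 0.5,
                          deSpec = list(list(size = 40, group = "MSA-P",
                                             logFC = 1.5)))
  se <- simulateExpression(cfg)
  res <- runStability(se, "MSA-P", "CTRL", nIter = 40, nPerm = 40,
                      seed = 3)
  tab <- stabilityTable(res)
  block <- sprintf("TC%06d", 1:40)
  inBlock <- tab$transcript_id %in% block
  P <- observedPValues(res)
  expect_lt(median(P[rownames(P) %in% block, ]),
            median(P[!rownames(P) %in% block, ]))
  NP <- nullPValues(res)
  # the label-permuted null strongly attenuates the injected effect:
  # pseudo-groups mix shifted and unshifted samples, so block null
  # p-values shift left far less than the observed ones collapse
  blockNP <- mean(NP[rownames(NP) %in% block, ])
  blockP <- mean(P[rownames(P) %in% block, ])
  expect_gt(blockNP, 0.25)
  expect_lt(blockP, 0.1)
  expect_gt(blockNP, 3 * blockP)
  # block transcripts dominate the top of the ranking
  expect_gte(mean(tab$transcript_id[1:40] %in% block), 0.9)
  expect_lt(correlateRecurrenceQ(res), -0.5)
})

test_that("the full stability stage is reproducible bit-for-bit", {
  se <- makeNullExperiment(120, seed = 14)
  r1 <- runStability(se, "PD", "CTRL", nIter = 15, nPerm = 15, seed = 27)
  r2 <- runStability(se, "PD", "CTRL", nIter = 15, nPerm = 15, seed = 27)
  expect_identical(stabilityTable(r1), stabilityTable(r2))
  expect_identical(observedPValues(r1), observedPValues(r2))
  expect_identical(nullPValues(r1), nullPValues(r2))
  expect_identical(subgroupDraws(r1), subgroupDraws(r2))
})
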