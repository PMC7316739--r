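## Deterministic sub-seed derivation: mixes a master seed with a string
## key so stages/contrasts can be rerun in isolation. Kept below 2^31.
deriveSeed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

## One gender-balanced subset of size k from one group's samples.
## Returns NULL when the group cannot supply the required gender counts.
drawBalancedSubset <- function(sampleIds, gender, k, kM) {
  males <- sampleIds[gender == "M"]
  females <- sampleIds[gender == "F"]
  kF <- k - kM
  if (length(males) < kM || length(females) < kF) return(NULL)
  sort(c(
    if (kM > 0) males[sample.int(length(males), kM)] else character(),
    if (kF > 0) females[sample.int(length(females), kF)] else character()))
}

#' Enumerate balanced subgroup draws for a two-group contrast
#'
#' Draws `nIter` distinct pairs of gender-balanced subgroups of size `k`
#' (default 2 male + 2 female from each group), uniformly without
#' replacement from the space of admissible pairs, via rejection sampling
#' with a retry cap. The admissible space size is
#' `(choose(nMa, kM) * choose(nFa, kF)) * (choose(nMb, kM) * choose(nFb, kF))`
#' and a request exceeding it is an error reporting that size.
#'
#' @param metadata `data.frame` with `sample_id`, `group`, `gender` (or the
#'   colData of a `SummarizedExperiment`).
#' @param groupA,groupB contrast group labels.
#' @param k subgroup size per side (default 4).
#' @param nIter number of distinct draws (default 100).
#' @param seed integer RNG seed; identical seeds give identical draw lists.
#' @param genderBalance male proportion within each subgroup; `k *
#'   genderBalance` must be an integer.
#' @return list of length `nIter`; each element has `iteration`,
#'   `samplesA`, `samplesB` (sorted sample ids).
#' @export
enumerateBalancedDraws <- function(metadata, groupA, groupB, k = 4L,
                                   nIter = 100L, seed = 1L,
                                   genderBalance = 0.5) {
  if (is(metadata, "SummarizedExperiment"))
    metadata <- as.data.frame(SummarizedExperiment::colData(metadata))
  kM <- k * genderBalance
  if (abs(kM - round(kM)) > 1e-8)
    stop("k (", k, ") x genderBalance (", genderBalance,
         ") must be an integer male count")
  kM <- as.integer(round(kM))
  kF <- k - kM

  sideSpace <- function(g) {
    nM <- sum(metadata$group == g & metadata$gender == "M")
    nF <- sum(metadata$group == g & metadata$gender == "F")
    if (nM < kM || nF < kF)
      stop("group '", g, "' cannot supply ", kM, "M + ", kF, "F (has ",
           nM, "M + ", nF, "F)")
    choose(nM, kM) * choose(nF, kF)
  }
  space <- sideSpace(groupA) * sideSpace(groupB)
  if (space < nIter)
    stop("requested ", nIter, " distinct draws but the admissible space ",
         "holds only ", format(space, big.mark = ","), " pairs")

  idsA <- metadata$sample_id[metadata$group == groupA]
  genA <- metadata$gender[metadata$group == groupA]
  idsB <- metadata$sample_id[metadata$group == groupB]
  genB <- metadata$gender[metadata$group == groupB]

  set.seed(seed)
  draws <- vector("list", nIter)
  seen <- new.env(hash = TRUE)
  got <- 0L
  attempts <- 0L
  cap <- 1000L * nIter
  while (got < nIter) {
    attempts <- attempts + 1L
    if (attempts > cap)
      stop("could not find ", nIter, " distinct draws after ", cap,
           " attempts (space size ", format(space, big.mark = ","), ")")
    a <- drawBalancedSubset(idsA, genA, k, kM)
    b <- drawBalancedSubset(idsB, genB, k, kM)
    key <- paste(c(a, "|", b), collapse = ",")
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    got <- got + 1L
    draws[[got]] <- list(iteration = got, samplesA = a, samplesB = b)
  }
  draws
}

#' Run the resampling differential-expression stage
#'
#' One moderated two-group test ([moderatedDE()]) per subgroup draw; the
#' per-iteration p-values and log2 fold changes are collected into
#' transcripts x iterations matrices.
#'
#' @inheritParams moderatedDE
#' @param draws draw list from [enumerateBalancedDraws()].
#' @return list with matrices `p` and `logFC` (transcripts x iterations,
#'   columns `iter1`, `iter2`, ...).
#' @export
runResampling <- function(se, groupA, groupB, draws) {
  n <- length(draws)
  first <- NULL
  P <- NULL
  L <- NULL
  for (i in seq_len(n)) {
    d <- draws[[i]]
    res <- tryCatch(
      moderatedDE(se, groupA, groupB, samples = c(d$samplesA, d$samplesB)),
      error = function(e)
        stop("resampling iteration ", i, ": ", conditionMessage(e),
             call. = FALSE))
    if (is.null(P)) {
      first <- res$transcript_id
      P <- matrix(NA_real_, length(first), n,
                  dimnames = list(first, paste0("iter", seq_len(n))))
      L <- P
    }
    P[, i] <- res$p
    L[, i] <- res$logFC
  }
  list(p = P, logFC = L)
}

#' Run the class-label-permutation null stage
#'
#' For each permutation, the group labels of the contrast's samples (or of
#' all samples when `scope = "all"`) are randomly reassigned preserving
#' the original group sizes; one gender-balanced subgroup pair is then
#' drawn from the permuted labels and a single moderated test is run.
#' Permutations whose pseudo-groups cannot satisfy the gender balance are
#' redrawn (with a retry cap).
#'
#' @inheritParams enumerateBalancedDraws
#' @param se expression `SummarizedExperiment`.
#' @param nPerm number of permuted contrasts (default 100).
#' @param scope `"contrast"` (default): permute labels across the union of
#'   the two contrast groups only; `"all"`: permute across every sample in
#'   the experiment.
#' @return list with matrices `p` and `logFC` (transcripts x permutations)
#'   and the list of permuted draws under `draws`.
#' @export
runPermutationNull <- function(se, groupA, groupB, k = 4L, nPerm = 100L,
                               seed = 1L, genderBalance = 0.5,
                               scope = c("contrast", "all")) {
  scope <- match.arg(scope)
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  kM <- as.integer(round(k * genderBalance))
  kF <- k - kM

  pool <- if (scope == "contrast")
    meta[meta$group %in% c(groupA, groupB), ] else meta
  nA <- sum(meta$group == groupA)
  nB <- sum(meta$group == groupB)
  if (nA < k || nB < k)
    stop("groups must hold >= k samples (have ", nA, " and ", nB, ")")

  x <- SummarizedExperiment::assay(se, "log2")
  genderOf <- setNames(meta$gender, meta$sample_id)
  set.seed(seed)
  P <- NULL
  L <- NULL
  permDraws <- vector("list", nPerm)
  for (i in seq_len(nPerm)) {
    a <- NULL
    b <- NULL
    for (try in 1:100) {
      perm <- pool$sample_id[sample.int(nrow(pool))]
      pseudoA <- perm[seq_len(nA)]
      pseudoB <- perm[nA + seq_len(nB)]
      a <- drawBalancedSubset(pseudoA, genderOf[pseudoA], k, kM)
      b <- drawBalancedSubset(pseudoB, genderOf[pseudoB], k, kM)
      if (!is.null(a) && !is.null(b)) break
      a <- NULL
    }
    if (is.null(a))
      stop("permutation ", i, ": could not satisfy the gender balance ",
           "after 100 label reshuffles")
    res <- moderatedDE(x[, c(a, b), drop = FALSE], "permA", "permB",
                       groups = rep(c("permA", "permB"), c(length(a),
                                                           length(b))))
    permDraws[[i]] <- list(iteration = i, samplesA = a, samplesB = b)
    if (is.null(P)) {
      P <- matrix(NA_real_, nrow(res), nPerm,
                  dimnames = list(res$transcript_id,
                                  paste0("perm", seq_len(nPerm))))
      L <- P
    }
    P[, i] <- res$p
    L[, i] <- res$logFC
  }
  list(p = P, logFC = L, draws = permDraws)
}

#' Compare a transcript's observed and null p-value distributions
#'
#' Tie-corrected Kruskal-Wallis test (via [stats::kruskal.test()]) between
#' the observed p-values from the real-contrast resampling and the
#' permutation-null p-values; with two groups the statistic is referred to
#' a chi-square on 1 degree of freedom. If all values are identical the
#' statistic is 0 with p = 1 (equal rank sums are not an error).
#'
#' @param observed numeric vector of real-contrast p-values.
#' @param null numeric vector of permutation-null p-values.
#' @return named list with `H` (statistic) and `p`.
#' @export
kruskalWallisCompare <- function(observed, null) {
  if (!length(observed) || !length(null))
    stop("both p-value vectors must be non-empty")
  vals <- c(observed, null)
  if (all(vals == vals[1L])) return(list(H = 0, p = 1))
  kt <- kruskal.test(list(observed, null))
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Storey q-values with smoother pi0 estimation
#'
#' Converts p-values to q-values `q(p) = pi0 * min_{t >= p} m t / #{p <= t}`
#' where the null proportion `pi0` is estimated by the smoother method: a
#' cubic smoothing spline is fit to `pi0(lambda) = #{p > lambda} / (m (1 -
#' lambda))` over a lambda grid and evaluated at the largest lambda. With
#' `pi0 = 1` (the forced fallback) the result is exactly the
#' Benjamini-Hochberg step-up adjustment.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param pi0 optional override of the null proportion; fewer than 100
#'   p-values triggers a warning and forces `pi0 = 1`.
#' @param lambda grid for the smoother estimate.
#' @return q-values in \[0, 1\], monotone non-decreasing in p, carrying the
#'   estimate as attribute `pi0`.
#' @export
storeyQValues <- function(p, pi0 = NULL,
                          lambda = seq(0.05, 0.95, by = 0.05)) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100L) {
      warning("fewer than 100 p-values; forcing pi0 = 1 (BH-equivalent)")
      pi0 <- 1
    } else {
      pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 1.0)
      fit <- smooth.spline(lambda, pi0l, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(pi0, 1)
      if (!is.finite(pi0) || pi0 <= 0) {
        warning("smoother pi0 estimate non-positive; forcing pi0 = 1")
        pi0 <- 1
      }
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o]))[ro]
  attr(q, "pi0") <- pi0
  q
}

#' Assemble the per-transcript stability table
#'
#' Combines the resampling stage and the permutation-null stage into the
#' pipeline's headline object: per transcript, the detection recurrence
#' (`n_detected`, iterations with p below `detectP`), the summed log2 fold
#' change across iterations, the Kruskal-Wallis comparison of observed vs
#' null p-value distributions, its Storey q-value, and the significance
#' call at `qCutoff`. Rows are ordered by decreasing recurrence, then
#' decreasing `|sum_logFC|`, then transcript id.
#'
#' @param resampling result of [runResampling()].
#' @param nullMatrix result of [runPermutationNull()] (or any list with a
#'   `p` matrix over the same transcripts).
#' @param detectP per-iteration detection threshold (default 0.05).
#' @param qCutoff Kruskal-Wallis q-value significance cutoff (default
#'   1e-4).
#' @param pi0 optional forced null proportion for [storeyQValues()].
#' @return `data.frame` with columns `transcript_id`, `n_detected`,
#'   `sum_logFC`, `kw_H`, `kw_p`, `kw_q`, `significant`.
#' @export
buildStabilityTable <- function(resampling, nullMatrix, detectP = 0.05,
                                qCutoff = 1e-4, pi0 = NULL) {
  P <- resampling$p
  L <- resampling$logFC
  NP <- nullMatrix$p
  if (!identical(rownames(P), rownames(NP)))
    stop("observed and null matrices cover different transcript sets")
  nDetected <- rowSums(P < detectP)
  sumLogFC <- rowSums(L)
  kw <- vapply(seq_len(nrow(P)), function(i) {
    r <- kruskalWallisCompare(P[i, ], NP[i, ])
    c(r$H, r$p)
  }, numeric(2))
  kwQ <- storeyQValues(kw[2L, ], pi0 = pi0)
  tab <- data.frame(
    transcript_id = rownames(P),
    n_detected = as.integer(nDetected),
    sum_logFC = sumLogFC,
    kw_H = kw[1L, ],
    kw_p = kw[2L, ],
    kw_q = as.numeric(kwQ),
    significant = as.numeric(kwQ) < qCutoff,
    row.names = NULL,
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$n_detected, -abs(tab$sum_logFC),
                   tab$transcript_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Pearson correlation between recurrence and Kruskal-Wallis q-value
#'
#' Under real effects, recurrent transcripts carry low q-values, so the
#' correlation is negative.
#'
#' @param table a stability table ([buildStabilityTable()]) or a
#'   [StabilityResult-class].
#' @return Pearson r in \[-1, 1\].
#' @export
correlateRecurrenceQ <- function(table) {
  if (is(table, "StabilityResult")) table <- stabilityTable(table)
  if (nrow(table) < 3L)
    stop("need >= 3 transcripts to correlate")
  if (sd(table$n_detected) == 0 || sd(table$kw_q) == 0)
    stop("undefined correlation: zero variance in n_detected or kw_q")
  cor(table$n_detected, table$kw_q)
}

#' Run the full resampling-stability analysis for one contrast
#'
#' Convenience wrapper chaining [enumerateBalancedDraws()],
#' [runResampling()], [runPermutationNull()] and [buildStabilityTable()].
#' The real-contrast draws and the permutation null use independently
#' derived sub-seeds of `seed`.
#'
#' @inheritParams runPermutationNull
#' @param nIter number of real-contrast resampling iterations.
#' @param detectP per-iteration detection p threshold.
#' @param qCutoff Kruskal-Wallis q-value cutoff.
#' @param pi0 optional forced null proportion.
#' @return a [StabilityResult-class].
#' @examples
#' sim <- simulateExpression(simulationConfig(300, nPerGroup = 6, seed = 1))
#' res <- runStability(sim, "MSA-P", "CTRL", nIter = 20, nPerm = 20,
#'                     seed = 1)
#' head(stabilityTable(res))
#' @export
runStability <- function(se, groupA, groupB, k = 4L, nIter = 100L,
                         nPerm = 100L, seed = 1L, genderBalance = 0.5,
                         detectP = 0.05, qCutoff = 1e-4,
                         scope = c("contrast", "all"), pi0 = NULL) {
  scope <- match.arg(scope)
  contrastKey <- paste0(groupA, "_vs_", groupB)
  draws <- enumerateBalancedDraws(
    se, groupA, groupB, k = k, nIter = nIter,
    seed = deriveSeed(seed, paste0("draws:", contrastKey)),
    genderBalance = genderBalance)
  obs <- runResampling(se, groupA, groupB, draws)
  nul <- runPermutationNull(
    se, groupA, groupB, k = k, nPerm = nPerm,
    seed = deriveSeed(seed, paste0("null:", contrastKey)),
    genderBalance = genderBalance, scope = scope)
  tab <- buildStabilityTable(obs, nul, detectP = detectP,
                             qCutoff = qCutoff, pi0 = pi0)
  new("StabilityResult",
      table = tab,
      observedP = obs$p[tab$transcript_id, , drop = FALSE],
      observedLogFC = obs$logFC[tab$transcript_id, , drop = FALSE],
      nullP = nul$p[tab$transcript_id, , drop = FALSE],
      draws = list(observed = draws, null = nul$draws),
      params = list(contrast = contrastKey, groupA = groupA,
                    groupB = groupB, k = k, nIter = nIter, nPerm = nPerm,
                    seed = seed, genderBalance = genderBalance,
                    detectP = detectP, qCutoff = qCutoff, scope = scope))
}
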