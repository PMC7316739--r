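# Independent brute-force oracles used across test files. These never call
# package internals: each re-derives its statistic from first principles.

# Tie-corrected Kruskal-Wallis H for two samples, straight from the rank
# formula, plus the exact permutation p-value over all C(n, n1) splits.
kwOracle <- function(a, b) {
  vals <- c(a, b)
  n <- length(vals)
  statOf <- function(idxA) {
    r <- rank(vals)
    rA <- r[idxA]
    rB <- r[-idxA]
    H <- 12 / (n * (n + 1)) *
      (sum(rA)^2 / length(rA) + sum(rB)^2 / length(rB)) - 3 * (n + 1)
    ties <- table(vals)
    corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    if (corr == 0) return(NA_real_)
    H / corr
  }
  obs <- statOf(seq_along(a))
  splits <- utils::combn(n, length(a), simplify = FALSE)
  stats <- vapply(splits, statOf, 1.0)
  list(H = obs, permP = mean(stats >= obs - 1e-12))
}

# Brute-force weighted running-sum enrichment score.
esOracle <- function(scores, members, weight = 1) {
  ids <- names(scores)
  N <- length(ids)
  hit <- ids %in% members
  NR <- sum(abs(scores[hit])^weight)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) abs(scores[i])^weight / NR
                 else -1 / (N - sum(hit))
    run[i] <- cur
  }
  if (max(run) >= -min(run)) max(run) else min(run)
}

# Worst-donor BH-adjusted p per transcript for one region pair,
# recomputed from the long table without the builder's bookkeeping.
donorMaxFdr <- function(atlas, A, B) {
  out <- NULL
  for (d in unique(atlas$donor)) {
    sub <- atlas[atlas$donor == d & atlas$region %in% c(A, B), ]
    wide <- stats::reshape(sub[c("sample", "transcript", "value")],
                           idvar = "transcript", timevar = "sample",
                           direction = "wide")
    x <- as.matrix(wide[-1])
    rownames(x) <- wide$transcript
    colnames(x) <- sub("^value\\.", "", colnames(x))
    regionOf <- setNames(sub$region, sub$sample)[colnames(x)]
    res <- moderatedDE(x, A, B, groups = regionOf)
    fdr <- setNames(adjustFDR(res$p), res$transcript_id)
    out <- if (is.null(out)) fdr else pmax(out, fdr[names(out)])
  }
  out
}

# Small null experiment shared by several files.
makeNullExperiment <- function(nTranscripts = 300, nPerGroup = 10,
                               seed = 11, ...) {
  simulateExpression(simulationConfig(
    nTranscripts = nTranscripts, nPerGroup = nPerGroup, seed = seed, ...))
}
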