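#' Build a ranked list from a stability table
#'
#' The pre-ranked GSEA score is the summed log2 fold change across
#' resampling iterations; ids are ordered by decreasing score with
#' lexicographic id tie-break so runs are reproducible.
#'
#' @param table a stability table or [StabilityResult-class].
#' @return named numeric vector of scores, sorted descending.
#' @export
rankedScores <- function(table) {
  if (is(table, "StabilityResult")) table <- stabilityTable(table)
  if (anyDuplicated(table$transcript_id))
    stop("ranked list ids must be unique")
  o <- order(-table$sum_logFC, table$transcript_id)
  setNames(table$sum_logFC[o], table$transcript_id[o])
}

#' Weighted running-sum enrichment score
#'
#' The classic weighted Kolmogorov-Smirnov-like statistic: walking down
#' the ranked list, hits increment the running sum by
#' `|score|^weight / sum(|score|^weight over hits)` and misses decrement
#' it by `1 / (N - N_hits)`; the enrichment score is the deviation of
#' maximum magnitude. The leading edge contains the member ids at or
#' before the positive extremum (at or after the negative extremum for a
#' negative ES).
#'
#' @param scores named numeric vector sorted by decreasing score (see
#'   [rankedScores()]).
#' @param members character vector of member ids; at least one must occur
#'   in `scores`, and the set must not cover the whole ranking.
#' @param weight weight exponent on `|score|` (default 1; 0 gives the
#'   unweighted classic statistic).
#' @return list with `ES`, `runningSum` (length-N numeric) and
#'   `leadingEdge` (character).
#' @export
enrichmentScore <- function(scores, members, weight = 1) {
  N <- length(scores)
  ids <- names(scores)
  hit <- ids %in% members
  nHit <- sum(hit)
  if (nHit == 0L)
    stop("no member of the set occurs in the ranking")
  if (nHit == N)
    stop("degenerate set: members cover the entire ranking")
  w <- abs(scores[hit])^weight
  if (sum(w) == 0) w <- rep(1, nHit)  # all-zero hit scores: equal weights
  inc <- numeric(N)
  inc[hit] <- w / sum(w)
  inc[!hit] <- -1 / (N - nHit)
  running <- cumsum(inc)
  iMax <- which.max(running)
  iMin <- which.min(running)
  ES <- if (running[iMax] >= -running[iMin]) running[iMax] else running[iMin]
  leading <- if (ES >= 0) ids[seq_len(iMax)][hit[seq_len(iMax)]]
             else ids[iMin:N][hit[iMin:N]]
  list(ES = unname(ES), runningSum = unname(running),
       leadingEdge = leading)
}

#' Pre-ranked gene set enrichment analysis
#'
#' For each set intersected with the ranking (and inside
#' `[minSize, maxSize]`), the observed enrichment score is compared with a
#' gene-label permutation null: `nPerm` random id sets of the same size
#' drawn from the ranking. The nominal p-value is the add-one-smoothed
#' frequency, over all permutations, of null scores at least as extreme in
#' magnitude as the observed score (so its attainable minimum is
#' `1 / (nPerm + 1)` and it is uniform for a null set); NES is the
#' observed ES divided by the mean magnitude of same-sign null scores. A pooled-NES FDR is reported alongside, but the shipped
#' selection rule ([selectTopSets()]) follows nominal p.
#'
#' @inheritParams enrichmentScore
#' @param collection a [GeneSetCollection-class].
#' @param nPerm permutations per set (default 1000).
#' @param seed integer RNG seed.
#' @param minSize,maxSize post-intersection set size bounds (defaults 15
#'   and 500); filtered counts are reported in a message.
#' @return `data.frame` with one row per retained set: `set`, `size`,
#'   `ES`, `NES`, `nominal_p`, `fdr`, `leading_edge` (comma-joined).
#' @export
gseaPreranked <- function(scores, collection, nPerm = 1000L, seed = 1L,
                          minSize = 15L, maxSize = 500L, weight = 1) {
  if (!length(collection))
    stop("gene set collection is empty")
  ids <- names(scores)
  N <- length(ids)

  kept <- list()
  nSkippedSize <- 0L
  nSkippedAbsent <- 0L
  for (i in seq_along(collection@setNames)) {
    mem <- intersect(collection@members[[i]], ids)
    if (length(mem) == 0L) {
      nSkippedAbsent <- nSkippedAbsent + 1L
      next
    }
    if (length(mem) < minSize || length(mem) > maxSize) {
      nSkippedSize <- nSkippedSize + 1L
      next
    }
    kept[[collection@setNames[i]]] <- mem
  }
  if (nSkippedAbsent)
    warning(nSkippedAbsent, " set(s) with no member in the ranking skipped")
  if (nSkippedSize)
    message(nSkippedSize, " set(s) outside [", minSize, ", ", maxSize,
            "] after intersection filtered")
  if (!length(kept))
    return(data.frame(set = character(), size = integer(), ES = numeric(),
                      NES = numeric(), nominal_p = numeric(),
                      fdr = numeric(), leading_edge = character(),
                      stringsAsFactors = FALSE))

  set.seed(seed)
  sizes <- vapply(kept, length, 1L)
  res <- vector("list", length(kept))
  nullNESPool <- list()
  for (j in seq_along(kept)) {
    mem <- kept[[j]]
    obs <- enrichmentScore(scores, mem, weight = weight)
    nullES <- vapply(seq_len(nPerm), function(b) {
      enrichmentScore(scores, ids[sample.int(N, length(mem))],
                      weight = weight)$ES
    }, 1.0)
    sameSign <- if (obs$ES >= 0) nullES[nullES >= 0] else nullES[nullES < 0]
    pNom <- (1 + sum(abs(nullES) >= abs(obs$ES))) / (1 + nPerm)
    meanMag <- if (length(sameSign)) mean(abs(sameSign)) else mean(abs(nullES))
    NES <- if (meanMag > 0) obs$ES / meanMag else 0
    posMean <- mean(abs(nullES[nullES >= 0]))
    negMean <- mean(abs(nullES[nullES < 0]))
    nullNES <- ifelse(nullES >= 0,
                      nullES / ifelse(posMean > 0, posMean, 1),
                      nullES / ifelse(negMean > 0, negMean, 1))
    nullNESPool[[j]] <- nullNES
    res[[j]] <- data.frame(
      set = names(kept)[j], size = length(mem), ES = obs$ES, NES = NES,
      nominal_p = pNom, fdr = NA_real_,
      leading_edge = paste(obs$leadingEdge, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL

  pool <- unlist(nullNESPool)
  obsNES <- out$NES
  out$fdr <- vapply(obsNES, function(nes) {
    if (nes >= 0) {
      nullFrac <- mean(pool >= nes)
      obsFrac <- mean(obsNES >= nes)
    } else {
      nullFrac <- mean(pool <= nes)
      obsFrac <- mean(obsNES <= nes)
    }
    min(1, nullFrac / max(obsFrac, 1 / length(obsNES)))
  }, 1.0)
  out
}

#' Select top enriched sets by the nominal-p rule
#'
#' Sets passing `nominal_p < pCutoff` are ordered by decreasing `|NES|`
#' within each enrichment sign and truncated at `nTop` per sign (default
#' 100); positively enriched sets come first.
#'
#' @param results `data.frame` from [gseaPreranked()].
#' @param pCutoff nominal p cutoff (default 0.05).
#' @param nTop maximum sets retained per sign (default 100).
#' @return filtered, ordered `data.frame` with an added `direction` column
#'   (`"positive"`/`"negative"`); may be empty.
#' @export
selectTopSets <- function(results, pCutoff = 0.05, nTop = 100L) {
  keep <- results[results$nominal_p < pCutoff, , drop = FALSE]
  pos <- keep[keep$NES >= 0, , drop = FALSE]
  neg <- keep[keep$NES < 0, , drop = FALSE]
  pos <- head(pos[order(-abs(pos$NES), pos$set), , drop = FALSE], nTop)
  neg <- head(neg[order(-abs(neg$NES), neg$set), , drop = FALSE], nTop)
  if (nrow(pos)) pos$direction <- "positive"
  if (nrow(neg)) neg$direction <- "negative"
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  out
}

#' Overlaps between top-set selections across contrasts
#'
#' Exact Venn partition of two or more selections (by set name):
#' membership lists and counts for every non-empty combination of the
#' inputs.
#'
#' @param ... two or more selections: `data.frame`s from
#'   [selectTopSets()] (their `set` column is used) or character vectors
#'   of set names. Arguments should be named; unnamed ones get `sel1`,
#'   `sel2`, ...
#' @return list with `counts` (named integer vector, names like
#'   `"a&b"`) and `members` (list of character vectors, same names).
#'   Regions are exclusive: `"a&b"` counts sets in both a and b but in no
#'   other selection.
#' @export
overlapTopSets <- function(...) {
  sels <- list(...)
  if (length(sels) < 2L) stop("need at least two selections")
  nm <- names(sels)
  if (is.null(nm)) nm <- rep("", length(sels))
  nm[nm == ""] <- paste0("sel", which(nm == ""))
  sels <- lapply(sels, function(s)
    if (is.data.frame(s)) unique(s$set) else unique(as.character(s)))
  names(sels) <- nm

  universe <- unique(unlist(sels))
  inSel <- vapply(sels, function(s) universe %in% s,
                  logical(length(universe)))
  if (length(universe) == 1L) inSel <- matrix(inSel, nrow = 1L)
  pattern <- apply(inSel, 1L, function(row) paste(nm[row], collapse = "&"))
  members <- split(universe, pattern)
  counts <- vapply(members, length, 1L)
  list(counts = counts, members = members)
}
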