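## Wide transcripts x samples matrix for one donor restricted to two
## regions, plus the per-sample region labels.
donorPairMatrix <- function(atlas, donorId, regionA, regionB) {
  sub <- atlas[atlas$donor == donorId & atlas$region %in%
                 c(regionA, regionB), , drop = FALSE]
  samples <- unique(sub[c("sample", "region")])
  transcripts <- sort(unique(sub$transcript))
  x <- matrix(NA_real_, length(transcripts), nrow(samples),
              dimnames = list(transcripts, samples$sample))
  idx <- cbind(match(sub$transcript, transcripts),
               match(sub$sample, samples$sample))
  x[idx] <- sub$value
  if (anyNA(x))
    stop("donor '", donorId, "': incomplete transcript coverage for pair ",
         regionA, "/", regionB)
  list(x = x, regions = setNames(samples$region, samples$sample))
}

#' Filter atlas regions by per-donor sample support
#'
#' A region is retained only if it has at least `minSamples` samples in
#' every donor (regions absent from a donor are excluded too).
#'
#' @param atlas long-format atlas `data.frame` (see [readAtlas()]).
#' @param minSamples minimum samples per region per donor (default 3).
#' @return list with `retained` (character vector), `excluded` (character
#'   vector) and `counts` (region x donor integer matrix of sample
#'   counts). Exclusions are reported in a message. No region retained is
#'   an error.
#' @export
filterRegions <- function(atlas, minSamples = 3L) {
  donors <- sort(unique(atlas$donor))
  regions <- sort(unique(atlas$region))
  samp <- unique(atlas[c("donor", "region", "sample")])
  counts <- table(factor(samp$region, levels = regions),
                  factor(samp$donor, levels = donors))
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  retained <- regions[apply(counts >= minSamples, 1L, all)]
  excluded <- setdiff(regions, retained)
  if (length(excluded))
    message("excluding region(s) below ", minSamples,
            " samples in some donor: ", paste(excluded, collapse = ", "))
  if (!length(retained))
    stop("no region has >= ", minSamples, " samples in every donor")
  list(retained = retained, excluded = excluded, counts = counts)
}

#' Build consensus brain-region gene sets from a multi-donor atlas
#'
#' For every ordered pair of retained regions, a moderated two-group test
#' ([moderatedDE()]) is run for each donor separately between the two
#' regions' samples. A transcript enters the pair's "up" set only if, in
#' every donor, its BH-adjusted p-value is below `fdrCutoff` and its
#' linear fold change exceeds `fcCutoff` (i.e. logFC > log2(fcCutoff));
#' "down" sets mirror this. Sets exceeding `maxGenes` keep the members
#' with the best consensus p summary (worst donor-adjusted p by default).
#'
#' @param atlas long-format atlas `data.frame`.
#' @param regions regions to use; defaults to [filterRegions()] with
#'   `minSamples`.
#' @param minSamples per-donor sample threshold used when `regions` is
#'   NULL.
#' @param fdrCutoff per-donor BH-adjusted p cutoff (default 0.01).
#' @param fcCutoff per-donor linear fold-change cutoff (default 2, i.e.
#'   |logFC| > 1).
#' @param maxGenes cap on members per set (default 800).
#' @param summary consensus p summary across donors used for the cap:
#'   `"max"` (worst donor, default) or `"mean"`.
#' @return list with `collection` (a [GeneSetCollection-class]; set names
#'   like `"SNr_gt_GPE_up"`) and `provenance` (`data.frame`: pair,
#'   direction, per-donor DE counts, pre/post-cap sizes). Pairs whose
#'   consensus is empty yield no set.
#' @export
buildRegionGeneSets <- function(atlas, regions = NULL, minSamples = 3L,
                                fdrCutoff = 0.01, fcCutoff = 2,
                                maxGenes = 800L,
                                summary = c("max", "mean")) {
  summary <- match.arg(summary)
  if (is.null(regions))
    regions <- filterRegions(atlas, minSamples)$retained
  if (length(regions) < 2L)
    stop("need >= 2 retained regions")
  donors <- sort(unique(atlas$donor))
  lfcCut <- log2(fcCutoff)

  members <- list()
  descriptions <- character()
  prov <- list()
  pairs <- utils::combn(sort(regions), 2L, simplify = FALSE)
  for (pr in pairs) {
    A <- pr[1L]; B <- pr[2L]
    upAll <- NULL; downAll <- NULL
    upP <- list(); downP <- list()
    donorCounts <- integer(length(donors))
    names(donorCounts) <- donors
    for (d in donors) {
      dm <- donorPairMatrix(atlas, d, A, B)
      res <- moderatedDE(dm$x, A, B, groups = dm$regions[colnames(dm$x)])
      fdr <- adjustFDR(res$p)
      up <- res$transcript_id[fdr < fdrCutoff & res$logFC > lfcCut]
      down <- res$transcript_id[fdr < fdrCutoff & res$logFC < -lfcCut]
      donorCounts[d] <- length(up) + length(down)
      upAll <- if (is.null(upAll)) up else intersect(upAll, up)
      downAll <- if (is.null(downAll)) down else intersect(downAll, down)
      upP[[d]] <- setNames(fdr, res$transcript_id)
      downP[[d]] <- setNames(fdr, res$transcript_id)
    }
    capSet <- function(ids, pList) {
      if (!length(ids)) return(list(ids = character(), pre = 0L))
      pMat <- vapply(pList, function(v) v[ids], numeric(length(ids)))
      if (length(ids) == 1L) pMat <- matrix(pMat, nrow = 1L)
      pSum <- if (summary == "max") apply(pMat, 1L, max)
              else rowMeans(pMat)
      pre <- length(ids)
      if (pre > maxGenes) {
        o <- order(pSum, ids)
        ids <- ids[o][seq_len(maxGenes)]
      } else {
        ids <- ids[order(pSum, ids)]
      }
      list(ids = ids, pre = pre)
    }
    up <- capSet(upAll, upP)
    down <- capSet(downAll, downP)

    addSet <- function(name, ids, desc) {
      if (!length(ids)) return()
      members[[name]] <<- ids
      descriptions[name] <<- desc
    }
    addSet(paste0(A, "_gt_", B, "_up"), up$ids,
           paste0("higher in ", A, " than ", B, " in all donors"))
    addSet(paste0(A, "_gt_", B, "_down"), down$ids,
           paste0("lower in ", A, " than ", B, " in all donors"))
    addSet(paste0(B, "_gt_", A, "_up"), down$ids,
           paste0("higher in ", B, " than ", A, " in all donors"))
    addSet(paste0(B, "_gt_", A, "_down"), up$ids,
           paste0("lower in ", B, " than ", A, " in all donors"))

    prov[[paste(A, B)]] <- data.frame(
      region_a = A, region_b = B,
      direction = c("up", "down"),
      consensus_pre_cap = c(up$pre, down$pre),
      consensus_post_cap = c(length(up$ids), length(down$ids)),
      donor_de_counts = paste(donors, donorCounts, sep = "=",
                              collapse = ";"),
      stringsAsFactors = FALSE)
  }
  provenance <- do.call(rbind, prov)
  rownames(provenance) <- NULL
  collection <- if (length(members))
    GeneSetCollection(members, descriptions[names(members)])
  else
    new("GeneSetCollection", setNames = character(),
        descriptions = character(), members = list())
  list(collection = collection, provenance = provenance)
}

#' Summarize per-region enrichment proportions
#'
#' Given GSEA results over a region gene-set collection (set names of the
#' form `"<A>_gt_<B>_up"`), reports for each region the proportion of its
#' pairwise "up" sets that are positively enriched below the p cutoff.
#'
#' @param results `data.frame` from [gseaPreranked()] run on a
#'   [buildRegionGeneSets()] collection.
#' @param pCutoff nominal p cutoff (default 0.05).
#' @return `data.frame` with `region`, `n_pairs`, `n_enriched`,
#'   `proportion`. Proportions need not sum to 1 across regions.
#' @export
summarizeRegionEnrichment <- function(results, pCutoff = 0.05) {
  m <- regmatches(results$set,
                  regexec("^(.+)_gt_(.+)_(up|down)$", results$set))
  ok <- vapply(m, length, 1L) == 4L
  if (!any(ok))
    stop("no set name parses as '<region>_gt_<region>_<up|down>'")
  parsed <- do.call(rbind, lapply(m[ok], function(f)
    data.frame(region = f[2L], other = f[3L], dir = f[4L],
               stringsAsFactors = FALSE)))
  up <- results[ok, , drop = FALSE][parsed$dir == "up", , drop = FALSE]
  parsedUp <- parsed[parsed$dir == "up", , drop = FALSE]
  regions <- sort(unique(c(parsedUp$region, parsedUp$other)))
  out <- lapply(regions, function(r) {
    sel <- parsedUp$region == r
    nPairs <- sum(sel)
    nEnriched <- sum(sel & up$NES > 0 & up$nominal_p < pCutoff)
    data.frame(region = r, n_pairs = nPairs, n_enriched = nEnriched,
               proportion = if (nPairs) nEnriched / nPairs else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
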